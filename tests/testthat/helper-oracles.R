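# Test-local numerical oracles, kept independent of the package internals.

# Composite trapezoid integration on a fine grid.
trapz_oracle <- function(f, lo, hi, n = 20001L) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1L] + y[-n]) / 2 * diff(x))
}

# Bin-averaged value of a density: mean of f over each bin (Simpson, 9
# nodes per bin), for comparing analytic densities with histograms.
bin_average <- function(f, edges) {
  w <- c(1, 4, 2, 4, 2, 4, 2, 4, 1)
  vapply(seq_len(length(edges) - 1L), function(i) {
    x <- seq(edges[i], edges[i + 1L], length.out = 9L)
    sum(w * f(x)) / sum(w)
  }, numeric(1L))
}

# Random convex polygon: convex hull of points on a noisy circle.
random_convex_polygon <- function(n_pts = 8L, scale = 1) {
  th <- sort(stats::runif(n_pts, 0, 2 * pi))
  r <- scale * (0.5 + 0.5 * stats::runif(n_pts))
  v <- cbind(r * cos(th), r * sin(th))
  hull <- grDevices::chull(v)
  polygon_domain(v[rev(hull), , drop = FALSE])
}

# Chi-squared statistic of binned samples against bin probabilities.
chisq_stat <- function(x, edges, probs) {
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  expected <- probs / sum(probs) * length(x)
  sum((counts - expected)^2 / expected)
}
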