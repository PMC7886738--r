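# Estimation of empirical step densities with ensemble uncertainty
# envelopes, and reconstruction of the intrinsic step distribution by
# inverting the shaper multiplication: f_i is proportional to f_t / h on
# every bin where the shaper is informative. Information about steps at or
# beyond the domain diameter is irrecoverable and those bins are reported
# as explicitly missing, never as zero.

#' Per-run binned density estimate with ensemble envelope
#'
#' Histograms each run on common bins, normalises each run to a density,
#' and reports per-bin mean and across-run standard deviation (the
#' ensemble envelope).
#'
#' @param steps Step data grouped by run: a matrix with one column per run
#'   (as returned by [steps_of()] or [step_magnitudes()]), a list of
#'   numeric vectors, or a single numeric vector (one run).
#' @param bin_edges Ordered bin edges. Data outside the bins are counted
#'   and reported with a warning; the per-run normalisation then uses the
#'   full count, so the estimate integrates to less than one.
#' @return An object of class `density_estimate` with `bin_edges`, `mid`,
#'   `mean`, `sd` (`NA` when there is a single run), `n_runs`,
#'   `normalised` (TRUE when no data fell outside the bins).
#' @export
estimate_density <- function(steps, bin_edges) {
  if (is.matrix(steps)) {
    runs <- lapply(seq_len(ncol(steps)), function(j) steps[, j])
  } else if (is.list(steps)) {
    runs <- steps
  } else {
    runs <- list(as.numeric(steps))
  }
  if (any(vapply(runs, length, integer(1L)) == 0L)) {
    stop("every run must contain at least one step", call. = FALSE)
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  nb <- length(bin_edges) - 1L
  width <- diff(bin_edges)
  dens <- vapply(runs, function(x) {
    cut_idx <- findInterval(x, bin_edges, rightmost.closed = TRUE,
                            left.open = FALSE)
    counts <- tabulate(cut_idx[cut_idx >= 1L & cut_idx <= nb], nbins = nb)
    counts / (length(x) * width)
  }, numeric(nb))
  dens <- matrix(dens, nrow = nb)
  n_outside <- sum(vapply(runs, function(x) {
    sum(x < bin_edges[1L] | x > bin_edges[length(bin_edges)])
  }, numeric(1L)))
  if (n_outside > 0L) {
    warning(sprintf("%d step(s) fell outside the bins and were not binned",
                    n_outside), call. = FALSE)
  }
  m <- length(runs)
  structure(list(
    bin_edges = bin_edges,
    mid = (bin_edges[-1L] + bin_edges[-length(bin_edges)]) / 2,
    mean = rowMeans(dens),
    sd = if (m > 1L) apply(dens, 1L, stats::sd) else rep(NA_real_, nb),
    n_runs = m,
    normalised = n_outside == 0L
  ), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "Binned density estimate: %d bins on [%.4g, %.4g], %d run(s)%s\n",
    length(x$mid), x$bin_edges[1L], x$bin_edges[length(x$bin_edges)],
    x$n_runs, if (x$normalised) "" else " (data outside bins)"))
  invisible(x)
}

#' Default bins for step data
#'
#' 60 equal-width bins on `[0, diameter]` for magnitude data, or
#' symmetric bins on `[-diameter, diameter]` for signed 1D steps.
#'
#' @param domain The enclosing domain.
#' @param n_bins Number of bins (default 60).
#' @param signed Use a symmetric signed-step range (default: TRUE for 1D
#'   domains).
#' @return A vector of bin edges.
#' @export
default_bins <- function(domain, n_bins = 60L, signed = domain$dim == 1L) {
  d <- domain_diameter(domain)
  if (signed) seq(-d, d, length.out = n_bins + 1L)
  else seq(0, d, length.out = n_bins + 1L)
}

#' Reconstruct the intrinsic step distribution
#'
#' Inverts the multiplicative boundary bias of no-go confinement: divides
#' the estimated transformed step density (and its ensemble envelope,
#' scaled identically) by the shaper function at the bin centres. Bins
#' where the shaper falls below `shaper_floor` times its value at zero, or
#' that lie at or beyond the cutoff (the domain diameter), are excluded
#' and reported as `NA`: no information about such steps survives
#' confinement, and near the cutoff the reciprocal of the shaper amplifies
#' noise without bound.
#'
#' The result is left un-normalised by default (the reconstruction is
#' defined up to a constant); `renormalise = TRUE` rescales so the
#' retained bins integrate to one.
#'
#' @param ft_est A [estimate_density()] of the observed steps: signed 1D
#'   steps for a 1D shaper, step magnitudes for a 2D shaper.
#' @param shaper A [shaper_function()] of the enclosing domain.
#' @param shaper_floor Exclusion threshold as a fraction of the shaper
#'   value at zero lag (default 0.01).
#' @param renormalise Rescale retained bins to unit mass (default FALSE).
#' @param n_angles Angular quadrature nodes for the 2D magnitude shaper.
#' @return An object of class `reconstruction`: the input estimate plus
#'   `fi_mean`, `fi_sd` (`NA` on excluded bins), `shaper_values`,
#'   `excluded` (logical), `shaper_floor`.
#' @export
reconstruct_intrinsic <- function(ft_est, shaper, shaper_floor = 0.01,
                                  renormalise = FALSE, n_angles = 720L) {
  stopifnot(inherits(ft_est, "density_estimate"),
            inherits(shaper, "shaper_fn"))
  if (shaper_floor <= 0 || shaper_floor >= 1) {
    stop("`shaper_floor` must be a fraction in (0, 1)", call. = FALSE)
  }
  mid <- ft_est$mid
  if (shaper$dim == 1L) {
    h <- shaper$vec(mid)
    h_ref <- shaper$h0
  } else {
    if (any(mid < 0)) {
      stop("2D reconstruction expects magnitude bins (nonnegative centres)",
           call. = FALSE)
    }
    h <- magnitude_shaper(shaper, mid, n_angles)
    h_ref <- 2 * pi * shaper$h0     # magnitude shaper at zero lag
  }
  excluded <- h < shaper_floor * h_ref | abs(mid) >= shaper$cutoff
  if (all(excluded)) {
    stop("all bins excluded: shaper floor too high or bins beyond cutoff",
         call. = FALSE)
  }
  fi_mean <- ifelse(excluded, NA_real_, ft_est$mean / h)
  fi_sd <- ifelse(excluded, NA_real_, ft_est$sd / h)
  if (renormalise) {
    width <- diff(ft_est$bin_edges)
    z <- sum((fi_mean * width)[!excluded])
    fi_mean <- fi_mean / z
    fi_sd <- fi_sd / z
  }
  structure(list(
    bin_edges = ft_est$bin_edges, mid = mid,
    ft_mean = ft_est$mean, ft_sd = ft_est$sd,
    fi_mean = fi_mean, fi_sd = fi_sd,
    shaper_values = h, excluded = excluded,
    shaper_floor = shaper_floor, n_runs = ft_est$n_runs,
    renormalised = renormalise
  ), class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf(
    "Intrinsic-step reconstruction: %d bins, %d excluded (floor %.3g of h(0))%s\n",
    length(x$mid), sum(x$excluded), x$shaper_floor,
    if (x$renormalised) ", renormalised" else ""))
  invisible(x)
}

#' @export
as.data.frame.reconstruction <- function(x, ...) {
  data.frame(bin_center = x$mid, ft_mean = x$ft_mean, ft_sd = x$ft_sd,
             shaper = x$shaper_values, fi_mean = x$fi_mean,
             fi_sd = x$fi_sd, excluded = x$excluded)
}
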