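# Internal numerical helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Composite Simpson quadrature on [lo, hi] with n nodes (n odd, >= 3).
# Accurate enough (error << 1e-9 on the piecewise-smooth densities used
# here) and robust to the kinks that adaptive quadrature may warn about.
simpson_int <- function(f, lo, hi, n = 4097L) {
  if (hi <= lo) return(0)
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  h <- (hi - lo) / (n - 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1
  w[n] <- 1
  sum(w * y) * h / 3
}

# Trapezoid weights for an arbitrary ordered grid.
trapezoid_weights <- function(grid) {
  n <- length(grid)
  if (n < 2L) return(rep(1, n))
  d <- diff(grid)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-1L] + d[-(n - 1L)]) / 2
  w
}

trapz <- function(grid, values) sum(trapezoid_weights(grid) * values)

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
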