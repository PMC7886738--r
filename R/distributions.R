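# Intrinsic step distributions: the step law a walker would follow in
# unbounded space. One-dimensional laws are symmetric about zero;
# two-dimensional laws are rotationally symmetric, so they are fully
# specified by the radial profile f_i(l, 0).

#' Intrinsic one-dimensional step distribution
#'
#' Constructs the intrinsic step law \eqn{f_i(\ell)}, i.e. the probability
#' density of a signed step in unbounded one-dimensional space. All shipped
#' families are symmetric, \eqn{f_i(\ell) = f_i(-\ell)}.
#'
#' Families:
#' \describe{
#'   \item{`parabolic`}{\eqn{f_i(\ell) = 3(a^2 - \ell^2)/(4a^3)} for
#'     \eqn{|\ell| < a}, zero outside; `a` is the half-support.}
#'   \item{`gaussian`}{zero-mean normal with standard deviation `sigma`.}
#'   \item{`uniform`}{uniform on \eqn{[-a, a]}.}
#'   \item{`tabulated`}{user-supplied density on a grid, linearly
#'     interpolated, symmetrised about zero and renormalised.}
#' }
#'
#' @param family One of `"parabolic"`, `"gaussian"`, `"uniform"`,
#'   `"tabulated"`.
#' @param a Half-support length (parabolic, uniform families).
#' @param sigma Standard deviation (gaussian family).
#' @param grid,values Tabulated family only: ordered step values and the
#'   corresponding density values. The table may cover either the full
#'   signed range or only \eqn{\ell \ge 0}; it is symmetrised and
#'   renormalised in both cases.
#' @return An object of class `step_dist_1d` with the density, the
#'   cumulative distribution and a cached inverse-CDF sampler.
#' @seealso [pdf_1d()], [cdf_1d()], [sample_1d()], [step_dist_2d()]
#' @examples
#' d <- step_dist_1d("parabolic", a = 0.75)
#' pdf_1d(d, 0)          # 3/(4a) = 1 for a = 0.75
#' sample_1d(d, 5, seed = 1)
#' @export
step_dist_1d <- function(family = c("parabolic", "gaussian", "uniform",
                                    "tabulated"),
                         a = NULL, sigma = NULL, grid = NULL, values = NULL) {
  family <- match.arg(family)
  obj <- switch(family,
    parabolic = {
      stopifnot_scalar_pos(a, "a")
      list(
        family = "parabolic", params = list(a = a), support_radius = a,
        pdf = function(l) ifelse(abs(l) < a, 3 * (a^2 - l^2) / (4 * a^3), 0),
        cdf = function(l) {
          l <- pmin(pmax(l, -a), a)
          0.5 + (3 * a^2 * l - l^3) / (4 * a^3)
        }
      )
    },
    gaussian = {
      stopifnot_scalar_pos(sigma, "sigma")
      list(
        family = "gaussian", params = list(sigma = sigma),
        support_radius = Inf,
        pdf = function(l) stats::dnorm(l, sd = sigma),
        cdf = function(l) stats::pnorm(l, sd = sigma),
        sampler = function(n) stats::rnorm(n, sd = sigma)
      )
    },
    uniform = {
      stopifnot_scalar_pos(a, "a")
      list(
        family = "uniform", params = list(a = a), support_radius = a,
        # mid-value at the jump: keeps trapezoid quadrature second order
        pdf = function(l) {
          at_edge <- abs(abs(l) - a) < 1e-12
          ifelse(at_edge, 1 / (4 * a), ifelse(abs(l) < a, 1 / (2 * a), 0))
        },
        cdf = function(l) pmin(pmax((l + a) / (2 * a), 0), 1),
        sampler = function(n) stats::runif(n, -a, a)
      )
    },
    tabulated = {
      if (is.null(grid) || is.null(values) || length(grid) != length(values)) {
        stop("tabulated family needs `grid` and `values` of equal length",
             call. = FALSE)
      }
      if (is.unsorted(grid)) stop("`grid` must be increasing", call. = FALSE)
      if (any(values < 0)) stop("tabulated density must be nonnegative",
                                call. = FALSE)
      r <- max(abs(grid))
      g <- seq(-r, r, length.out = 4097L)
      fv <- function(x) stats::approx(grid, values, xout = x,
                                      yleft = 0, yright = 0)$y
      # tables on l >= 0 are mirrored; two-sided tables are symmetrised
      dens <- if (min(grid) >= 0) fv(abs(g)) else (fv(g) + fv(-g)) / 2
      dens <- dens / trapz(g, dens)
      pdf_fun <- stats::approxfun(g, dens, yleft = 0, yright = 0)
      cdf_vals <- cumsum(trapezoid_weights(g) * dens)
      cdf_vals <- cdf_vals / cdf_vals[length(cdf_vals)]
      cdf_fun <- stats::approxfun(g, cdf_vals, yleft = 0, yright = 1)
      list(
        family = "tabulated", params = list(n_table = length(grid)),
        support_radius = r, pdf = pdf_fun, cdf = cdf_fun
      )
    }
  )
  if (is.null(obj$sampler)) {
    obj$sampler <- inverse_cdf_sampler(obj$cdf, obj$support_radius)
  }
  structure(obj, class = "step_dist_1d")
}

# Grid inverse-CDF sampler on 4096 intervals; interpolation error is far
# below Monte-Carlo error at the sample sizes used here.
inverse_cdf_sampler <- function(cdf, support_radius, lo = NULL) {
  r <- if (is.finite(support_radius)) support_radius else
    stop("inverse-CDF sampler needs finite support", call. = FALSE)
  lo <- lo %||% -r
  x <- seq(lo, r, length.out = 4097L)
  p <- cdf(x)
  # make strictly increasing for interpolation
  p <- cummax(p + seq_along(p) * 1e-15)
  p <- (p - p[1L]) / (p[length(p)] - p[1L])
  function(n) stats::approx(p, x, xout = stats::runif(n), rule = 2)$y
}

#' @export
print.step_dist_1d <- function(x, ...) {
  cat("Intrinsic 1D step distribution (symmetric)\n")
  cat("  family:", x$family, "\n")
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  }
  cat("  support radius:", x$support_radius, "\n")
  invisible(x)
}

#' Density of a one-dimensional step distribution
#'
#' Evaluates \eqn{f_i(\ell)}; values outside the support are 0.
#'
#' @param dist A [step_dist_1d()] object.
#' @param l Step values (vectorised).
#' @return Density values (1/length).
#' @export
pdf_1d <- function(dist, l) {
  stopifnot(inherits(dist, "step_dist_1d"))
  dist$pdf(l)
}

#' Cumulative distribution of a one-dimensional step distribution
#'
#' @inheritParams pdf_1d
#' @return \eqn{P(L \le \ell)} values.
#' @export
cdf_1d <- function(dist, l) {
  stopifnot(inherits(dist, "step_dist_1d"))
  dist$cdf(l)
}

#' Sample steps from a one-dimensional step distribution
#'
#' @inheritParams pdf_1d
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return Numeric vector of `n` i.i.d. steps.
#' @export
sample_1d <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "step_dist_1d"))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set_seed_if(seed)
  dist$sampler(n)
}

#' Intrinsic two-dimensional step distribution
#'
#' Constructs a rotationally symmetric planar step law
#' \eqn{f_i(\ell_x, \ell_y)}, specified through its radial profile
#' \eqn{f_i(\ell, 0)}. The induced step-magnitude density is
#' \eqn{\tilde f_i(\ell) = 2\pi\ell\, f_i(\ell, 0)}.
#'
#' Families mirror [step_dist_1d()]: `parabolic` has planar density
#' \eqn{\propto (a^2-\ell^2)} inside radius `a` (normalised to
#' \eqn{2(a^2-\ell^2)/(\pi a^4)}), `gaussian` is the isotropic bivariate
#' normal, `uniform` is uniform on the disk of radius `a`, and `tabulated`
#' takes a radial-profile table on \eqn{\ell \ge 0}.
#'
#' @inheritParams step_dist_1d
#' @param grid,values Tabulated family: magnitudes (>= 0) and radial
#'   profile values \eqn{f_i(\ell,0)}; renormalised so the planar density
#'   integrates to one.
#' @return An object of class `step_dist_2d`.
#' @seealso [magnitude_pdf_2d()], [sample_2d()]
#' @export
step_dist_2d <- function(family = c("parabolic", "gaussian", "uniform",
                                    "tabulated"),
                         a = NULL, sigma = NULL, grid = NULL, values = NULL) {
  family <- match.arg(family)
  obj <- switch(family,
    parabolic = {
      stopifnot_scalar_pos(a, "a")
      list(
        family = "parabolic", params = list(a = a), support_radius = a,
        profile = function(l) ifelse(abs(l) < a,
                                     2 * (a^2 - l^2) / (pi * a^4), 0)
      )
    },
    gaussian = {
      stopifnot_scalar_pos(sigma, "sigma")
      list(
        family = "gaussian", params = list(sigma = sigma),
        support_radius = Inf,
        profile = function(l) exp(-l^2 / (2 * sigma^2)) / (2 * pi * sigma^2),
        sampler = function(n) cbind(stats::rnorm(n, sd = sigma),
                                    stats::rnorm(n, sd = sigma))
      )
    },
    uniform = {
      stopifnot_scalar_pos(a, "a")
      list(
        family = "uniform", params = list(a = a), support_radius = a,
        profile = function(l) ifelse(abs(l) <= a, 1 / (pi * a^2), 0)
      )
    },
    tabulated = {
      if (is.null(grid) || is.null(values) || length(grid) != length(values)) {
        stop("tabulated family needs `grid` and `values` of equal length",
             call. = FALSE)
      }
      if (any(grid < 0)) stop("radial grid must be nonnegative", call. = FALSE)
      if (any(values < 0)) stop("radial profile must be nonnegative",
                                call. = FALSE)
      r <- max(grid)
      g <- seq(0, r, length.out = 4097L)
      prof <- stats::approx(grid, values, xout = g, yleft = values[1L],
                            yright = 0, rule = 2)$y
      z <- trapz(g, 2 * pi * g * prof)
      prof <- prof / z
      pf <- stats::approxfun(g, prof, yright = 0,
                             yleft = prof[1L])
      list(
        family = "tabulated", params = list(n_table = length(grid)),
        support_radius = r,
        profile = function(l) ifelse(l > r, 0, pf(pmin(abs(l), r)))
      )
    }
  )
  if (is.null(obj$sampler)) {
    r <- obj$support_radius
    mag_cdf <- local({
      g <- seq(0, r, length.out = 4097L)
      dens <- 2 * pi * g * obj$profile(g)
      cv <- cumsum(trapezoid_weights(g) * dens)
      cv <- cv / cv[length(cv)]
      stats::approxfun(g, cv, yleft = 0, yright = 1)
    })
    mag_sampler <- inverse_cdf_sampler(mag_cdf, r, lo = 0)
    obj$sampler <- function(n) {
      m <- mag_sampler(n)
      th <- stats::runif(n, 0, 2 * pi)
      cbind(m * cos(th), m * sin(th))
    }
  }
  structure(obj, class = "step_dist_2d")
}

#' @export
print.step_dist_2d <- function(x, ...) {
  cat("Intrinsic 2D step distribution (rotationally symmetric)\n")
  cat("  family:", x$family, "\n")
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  }
  cat("  support radius:", x$support_radius, "\n")
  invisible(x)
}

#' Step-magnitude density of a two-dimensional step distribution
#'
#' Returns \eqn{\tilde f_i(\ell) = 2\pi\ell\, f_i(\ell, 0)}, the density of
#' the step magnitude induced by a rotationally symmetric planar step law.
#'
#' @param dist A [step_dist_2d()] object.
#' @param l Step magnitudes (>= 0, vectorised).
#' @return Density values (1/length).
#' @export
magnitude_pdf_2d <- function(dist, l) {
  stopifnot(inherits(dist, "step_dist_2d"))
  if (any(l < 0)) stop("step magnitudes must be >= 0", call. = FALSE)
  2 * pi * l * dist$profile(l)
}

#' Sample step vectors from a two-dimensional step distribution
#'
#' Directions are uniform on \eqn{[0, 2\pi)}; magnitudes follow
#' [magnitude_pdf_2d()].
#'
#' @inheritParams magnitude_pdf_2d
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @return An `n` by 2 matrix of step vectors.
#' @export
sample_2d <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "step_dist_2d"))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set_seed_if(seed)
  dist$sampler(n)
}

#' Mean-square step of an intrinsic distribution
#'
#' Computes \eqn{\langle \ell^2 \rangle_i} by quadrature: the second moment
#' of the signed step (1D) or of the step magnitude (2D).
#'
#' @param dist A [step_dist_1d()] or [step_dist_2d()] object.
#' @return A single number (length^2).
#' @export
dist_mean_square <- function(dist) {
  if (inherits(dist, "step_dist_1d")) {
    r <- if (is.finite(dist$support_radius)) dist$support_radius else
      10 * dist$params$sigma
    simpson_int(function(l) l^2 * dist$pdf(l), -r, r)
  } else if (inherits(dist, "step_dist_2d")) {
    r <- if (is.finite(dist$support_radius)) dist$support_radius else
      10 * dist$params$sigma
    simpson_int(function(l) l^2 * 2 * pi * l * dist$profile(l), 0, r)
  } else {
    stop("`dist` must be a step distribution", call. = FALSE)
  }
}
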