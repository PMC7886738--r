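# Shaper functions: the set covariance of a bounded convex domain,
# h(l) = measure(Omega intersect (Omega - l)). Under no-go boundaries the
# observed (transformed) step density is proportional to the intrinsic
# density multiplied by h, so h carries all of the geometric bias.
# Shapers are exposed un-normalised, as overlap measures: every use
# divides by an explicit normalisation.

#' Interval shaper function
#'
#' Overlap length of \eqn{[0, L]} with its translate by \eqn{\ell}:
#' \eqn{h(\ell) = (L - |\ell|)\,\theta(L - |\ell|)}.
#'
#' @param l Signed step values (vectorised).
#' @param L Interval length (default 1).
#' @return Overlap lengths; zero for \eqn{|\ell| \ge L}.
#' @export
shaper_interval <- function(l, L = 1) {
  pmax(L - abs(l), 0)
}

#' Square (rectangle) shaper function
#'
#' Overlap area of the axis-aligned rectangle \eqn{[0,w]\times[0,h]} with
#' its translate: the product of two interval shapers,
#' \eqn{h(\ell_x,\ell_y) = h_{1D}(\ell_x)\,h_{1D}(\ell_y)}. The default is
#' the unit square. Unlike the disk shaper this function is not
#' rotationally symmetric: confinement in a square breaks the rotational
#' symmetry of the intrinsic step law.
#'
#' @param lx,ly Step components (vectorised together).
#' @param side Side length (default 1); `width`/`height` override it for
#'   non-square rectangles.
#' @param width,height Optional rectangle dimensions.
#' @return Overlap areas.
#' @export
shaper_square <- function(lx, ly, side = 1, width = side, height = side) {
  shaper_interval(lx, width) * shaper_interval(ly, height)
}

#' Disk shaper function
#'
#' Overlap (lens) area of the disk of radius `radius` with its translate by
#' \eqn{(\ell_x, \ell_y)}. For the unit disk,
#' \deqn{h(\ell) = 2\cos^{-1}(\ell/2) - \tfrac12\sqrt{(4 - \ell^2)\,\ell^2},}
#' with \eqn{\ell = \sqrt{\ell_x^2+\ell_y^2}}; a general radius rescales
#' lengths by `radius` and areas by `radius^2`. Rotationally symmetric and
#' zero for \eqn{\ell \ge 2\,\mathrm{radius}} (the diameter).
#'
#' @param lx,ly Step components (vectorised together).
#' @param radius Disk radius (default 1).
#' @return Overlap areas.
#' @export
shaper_circle <- function(lx, ly, radius = 1) {
  l <- sqrt(lx^2 + ly^2) / radius
  out <- numeric(length(l))
  inside <- l < 2
  li <- l[inside]
  out[inside] <- 2 * acos(li / 2) - 0.5 * sqrt((4 - li^2) * li^2)
  out * radius^2
}

#' Convex-polygon shaper function (set covariance)
#'
#' Area of the intersection of a convex polygon with its translate by
#' \eqn{(\ell_x, \ell_y)}, computed exactly by half-plane clipping.
#'
#' @param poly A [polygon_domain()].
#' @param lx,ly Step components (vectorised together).
#' @return Overlap areas.
#' @export
shaper_polygon <- function(poly, lx, ly) {
  stopifnot(inherits(poly, "polygon_domain"))
  n <- max(length(lx), length(ly))
  lx <- rep_len(lx, n)
  ly <- rep_len(ly, n)
  vapply(seq_len(n), function(i) {
    shifted <- translate_polygon(poly, c(-lx[i], -ly[i]))
    inter <- clip_polygons(poly, shifted)
    if (is.null(inter)) 0 else domain_measure(inter)
  }, numeric(1L))
}

#' Grid-integration oracle for the set covariance
#'
#' Brute-force evaluation of \eqn{\int I_\Omega(r)\,I_\Omega(r+\ell)\,dr}
#' on a regular grid over the bounding box. Intended as an independent
#' cross-check of the exact clipping computation, not for production use.
#'
#' @param domain A 2D domain object (polygon or disk).
#' @param lx,ly Step components (vectorised together).
#' @param n_grid Grid resolution per axis (default 400).
#' @return Approximate overlap areas.
#' @export
shaper_grid_oracle <- function(domain, lx, ly, n_grid = 400L) {
  stopifnot(inherits(domain, "domain"), domain$dim == 2L)
  if (inherits(domain, "polygon_domain")) {
    v <- domain$vertices
    lo <- apply(v, 2L, min)
    hi <- apply(v, 2L, max)
  } else {
    lo <- domain$center - domain$radius
    hi <- domain$center + domain$radius
  }
  gx <- seq(lo[1L], hi[1L], length.out = n_grid)
  gy <- seq(lo[2L], hi[2L], length.out = n_grid)
  cell <- (gx[2L] - gx[1L]) * (gy[2L] - gy[1L])
  pts <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  in0 <- contains(domain, pts)
  n <- max(length(lx), length(ly))
  lx <- rep_len(lx, n)
  ly <- rep_len(ly, n)
  vapply(seq_len(n), function(i) {
    shifted <- cbind(pts[, 1L] + lx[i], pts[, 2L] + ly[i])
    sum(in0 & contains(domain, shifted)) * cell
  }, numeric(1L))
}

#' Shaper function object for a domain
#'
#' Bundles the geometry-specific shaper of a domain: its vector form, the
#' cutoff (the domain diameter, beyond which the shaper vanishes) and the
#' value at zero lag (the domain measure). Closed forms are used for the
#' interval, axis-aligned rectangles and the disk; other convex polygons
#' use the exact clipping covariance.
#'
#' @param domain A domain object.
#' @param method `"auto"` (closed form where available, else clipping),
#'   `"covariance"` (force clipping; 2D polygons only) or `"grid"` (the
#'   grid oracle; test use).
#' @param n_grid Grid resolution for `method = "grid"`.
#' @return An object of class `shaper_fn` with elements `vec` (a function
#'   of `l` in 1D or `lx, ly` in 2D), `cutoff`, `h0` and `dim`.
#' @seealso [magnitude_shaper()]
#' @export
shaper_function <- function(domain, method = c("auto", "covariance", "grid"),
                            n_grid = 400L) {
  method <- match.arg(method)
  stopifnot(inherits(domain, "domain"))
  cutoff <- domain_diameter(domain)
  h0 <- domain_measure(domain)
  if (domain$dim == 1L) {
    L <- domain$L
    vec <- function(l) shaper_interval(l, L)
    mode <- "closed_form_interval"
  } else if (method == "grid") {
    vec <- function(lx, ly) shaper_grid_oracle(domain, lx, ly, n_grid)
    mode <- "grid_oracle"
  } else if (inherits(domain, "disk_domain") && method == "auto") {
    R <- domain$radius
    vec <- function(lx, ly) shaper_circle(lx, ly, R)
    mode <- "closed_form_circle"
  } else if (inherits(domain, "polygon_domain")) {
    rect <- rectangle_dims(domain)
    if (method == "auto" && !is.null(rect)) {
      w <- rect[1L]
      h <- rect[2L]
      vec <- function(lx, ly) shaper_square(lx, ly, width = w, height = h)
      mode <- "closed_form_square"
    } else {
      vec <- function(lx, ly) shaper_polygon(domain, lx, ly)
      mode <- "polygon_covariance"
    }
  } else {
    stop("`method = \"covariance\"` requires a polygon domain", call. = FALSE)
  }
  structure(list(domain = domain, vec = vec, cutoff = cutoff, h0 = h0,
                 dim = domain$dim, mode = mode),
            class = "shaper_fn")
}

# Detect an axis-aligned rectangle; returns c(width, height) or NULL.
rectangle_dims <- function(poly) {
  v <- poly$vertices
  if (nrow(v) != 4L) return(NULL)
  e <- v[c(2:4, 1L), ] - v
  axis_aligned <- all(abs(e[, 1L]) < 1e-12 | abs(e[, 2L]) < 1e-12)
  if (!axis_aligned) return(NULL)
  c(max(v[, 1L]) - min(v[, 1L]), max(v[, 2L]) - min(v[, 2L]))
}

#' @export
print.shaper_fn <- function(x, ...) {
  cat("Shaper function (set covariance of the domain)\n")
  cat("  mode:", x$mode, "\n")
  cat(sprintf("  h(0) = domain measure = %.6g; cutoff (diameter) = %.6g\n",
              x$h0, x$cutoff))
  invisible(x)
}

#' Magnitude (angle-averaged) shaper function
#'
#' Angular integral of a 2D shaper at fixed step magnitude,
#' \eqn{\tilde h(\ell) = \int_0^{2\pi} h(\ell\cos\theta, \ell\sin\theta)\,
#' d\theta}, evaluated by trapezoidal quadrature. The central symmetry
#' \eqn{h(-\ell) = h(\ell)} is exploited: the integral over \eqn{[0,\pi]}
#' is doubled.
#'
#' @param shaper A 2D [shaper_function()] object.
#' @param l Step magnitudes (>= 0, vectorised).
#' @param n_angles Number of angular nodes over the full circle
#'   (default 720, minimum 64).
#' @return \eqn{\tilde h(\ell)} values; \eqn{\tilde h(0) = 2\pi h(0)}.
#' @export
magnitude_shaper <- function(shaper, l, n_angles = 720L) {
  stopifnot(inherits(shaper, "shaper_fn"))
  if (shaper$dim != 2L) {
    stop("magnitude shaper is defined for 2D domains", call. = FALSE)
  }
  if (n_angles < 64L) stop("`n_angles` must be >= 64", call. = FALSE)
  if (any(l < 0)) stop("step magnitudes must be >= 0", call. = FALSE)
  m <- as.integer(n_angles / 2L)
  th <- seq(0, pi, length.out = m + 1L)
  w <- trapezoid_weights(th)
  vapply(l, function(li) {
    if (li >= shaper$cutoff) return(0)
    2 * sum(w * shaper$vec(li * cos(th), li * sin(th)))
  }, numeric(1L))
}
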