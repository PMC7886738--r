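# Bounded convex domains: interval, convex polygon, disk. Domains are
# closed sets: boundary points count as inside. For the continuous step
# laws used here the boundary has measure zero, so no statistic depends on
# this choice, but it keeps stop-go termination points representable.

HALF_PLANE_TOL <- 1e-12

#' Interval domain
#'
#' The one-dimensional domain \eqn{[0, L]}.
#'
#' @param L Positive length of the interval (default 1).
#' @return An object of classes `interval_domain` and `domain`.
#' @export
interval_domain <- function(L = 1) {
  stopifnot_scalar_pos(L, "L")
  structure(list(L = L, dim = 1L), class = c("interval_domain", "domain"))
}

#' Convex polygon domain
#'
#' A bounded convex polygon given by its vertices. Vertices are normalised
#' to counter-clockwise order on construction (clockwise input is silently
#' reversed, with a message); non-convex vertex lists are rejected.
#'
#' @param vertices A numeric matrix (or two-column data frame) of vertex
#'   coordinates, one row per vertex, at least three rows, no repeated
#'   closing vertex.
#' @return An object of classes `polygon_domain` and `domain` with the
#'   half-plane representation (inward unit normals and offsets) attached.
#' @export
polygon_domain <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L || !is.numeric(v)) {
    stop("`vertices` must be a numeric matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  }
  if (sum((v[1L, ] - v[nrow(v), ])^2) < HALF_PLANE_TOL^2) {
    v <- v[-nrow(v), , drop = FALSE]   # drop repeated closing vertex
  }
  a <- polygon_area_signed(v)
  if (abs(a) < HALF_PLANE_TOL) stop("polygon has zero area", call. = FALSE)
  if (a < 0) {
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    message("polygon vertices given clockwise; reversed to counter-clockwise")
  }
  n <- nrow(v)
  e <- v[c(2:n, 1L), , drop = FALSE] - v
  scale <- max(abs(v)) + 1
  cross <- e[, 1L] * e[c(2:n, 1L), 2L] - e[, 2L] * e[c(2:n, 1L), 1L]
  if (any(cross < -1e-9 * scale^2)) {
    stop("vertex list is not convex", call. = FALSE)
  }
  # inward unit normal of each directed (CCW) edge
  len <- sqrt(rowSums(e^2))
  if (any(len < HALF_PLANE_TOL)) stop("repeated vertices", call. = FALSE)
  normals <- cbind(-e[, 2L], e[, 1L]) / len
  offsets <- rowSums(normals * v)
  structure(list(vertices = v, normals = normals, offsets = offsets,
                 dim = 2L),
            class = c("polygon_domain", "domain"))
}

polygon_area_signed <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

#' Axis-aligned square domain
#'
#' Convenience constructor for the square \eqn{[0, s]^2} as a
#' [polygon_domain()].
#'
#' @param side Side length (default 1, the unit square).
#' @export
square_domain <- function(side = 1) {
  stopifnot_scalar_pos(side, "side")
  polygon_domain(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}

#' Regular polygon domain
#'
#' Regular `n`-gon inscribed in the circle of radius `radius` centred at
#' the origin; useful for studying polygonal approximations of the disk.
#'
#' @param n Number of vertices (>= 3).
#' @param radius Circumradius.
#' @export
regular_polygon_domain <- function(n, radius = 1) {
  if (n < 3) stop("`n` must be >= 3", call. = FALSE)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  polygon_domain(cbind(radius * cos(th), radius * sin(th)))
}

#' Disk domain
#'
#' @param center Centre of the disk (length-2 numeric).
#' @param radius Positive radius.
#' @return An object of classes `disk_domain` and `domain`.
#' @export
disk_domain <- function(center = c(0, 0), radius = 1) {
  stopifnot_scalar_pos(radius, "radius")
  stopifnot(is.numeric(center), length(center) == 2L)
  structure(list(center = as.numeric(center), radius = radius, dim = 2L),
            class = c("disk_domain", "domain"))
}

#' @export
print.domain <- function(x, ...) {
  if (inherits(x, "interval_domain")) {
    cat(sprintf("Interval domain [0, %g]\n", x$L))
  } else if (inherits(x, "polygon_domain")) {
    cat(sprintf("Convex polygon domain, %d vertices, area %.6g\n",
                nrow(x$vertices), domain_measure(x)))
  } else {
    cat(sprintf("Disk domain, centre (%g, %g), radius %g\n",
                x$center[1L], x$center[2L], x$radius))
  }
  invisible(x)
}

#' Domain membership
#'
#' Tests whether points lie inside a closed bounded domain (boundary points
#' count as inside).
#'
#' @param domain A domain object.
#' @param points For 1D domains a numeric vector of coordinates; for 2D
#'   domains a two-column matrix (a length-2 vector is taken as one point).
#' @return Logical vector, one entry per point.
#' @export
contains <- function(domain, points) UseMethod("contains")

#' @export
contains.interval_domain <- function(domain, points) {
  points >= -HALF_PLANE_TOL & points <= domain$L + HALF_PLANE_TOL
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2L) {
      stop("2D points must be a two-column matrix or a length-2 vector",
           call. = FALSE)
    }
    points <- matrix(points, ncol = 2L)
  }
  as.matrix(points)
}

#' @export
contains.polygon_domain <- function(domain, points) {
  p <- as_point_matrix(points)
  s <- p %*% t(domain$normals)
  rowSums(s < matrix(domain$offsets - HALF_PLANE_TOL, nrow(p),
                     length(domain$offsets), byrow = TRUE)) == 0L
}

#' @export
contains.disk_domain <- function(domain, points) {
  p <- as_point_matrix(points)
  dx <- p[, 1L] - domain$center[1L]
  dy <- p[, 2L] - domain$center[2L]
  dx * dx + dy * dy <= domain$radius^2 + HALF_PLANE_TOL
}

#' Measure of a domain
#'
#' Length of an interval, shoelace area of a polygon, \eqn{\pi R^2} for a
#' disk. This is also the value every shaper function takes at zero lag.
#'
#' @param domain A domain object.
#' @return The Lebesgue measure (length or area).
#' @export
domain_measure <- function(domain) UseMethod("domain_measure")

#' @export
domain_measure.interval_domain <- function(domain) domain$L

#' @export
domain_measure.polygon_domain <- function(domain) {
  polygon_area_signed(domain$vertices)
}

#' @export
domain_measure.disk_domain <- function(domain) pi * domain$radius^2

#' Diameter of a domain
#'
#' Supremum of pairwise point distances: `L` for the interval, the maximum
#' vertex-vertex distance for a convex polygon, `2R` for a disk. Steps of
#' magnitude at or beyond the diameter can never be observed inside the
#' domain.
#'
#' @param domain A domain object.
#' @return The diameter (length).
#' @export
domain_diameter <- function(domain) UseMethod("domain_diameter")

#' @export
domain_diameter.interval_domain <- function(domain) domain$L

#' @export
domain_diameter.polygon_domain <- function(domain) {
  v <- domain$vertices
  d2 <- as.matrix(stats::dist(v))
  max(d2)
}

#' @export
domain_diameter.disk_domain <- function(domain) 2 * domain$radius

#' Uniform random points in a domain
#'
#' @param domain A domain object.
#' @param n Number of points.
#' @param seed Optional integer seed.
#' @return Numeric vector (1D) or `n` by 2 matrix (2D) of points, all
#'   inside the domain.
#' @export
uniform_sample <- function(domain, n, seed = NULL) {
  set_seed_if(seed)
  UseMethod("uniform_sample")
}

#' @export
uniform_sample.interval_domain <- function(domain, n, seed = NULL) {
  stats::runif(n, 0, domain$L)
}

#' @export
uniform_sample.polygon_domain <- function(domain, n, seed = NULL) {
  v <- domain$vertices
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  # rejection from the bounding box; acceptance >= 1/2 for convex domains
  # is not guaranteed but is bounded below by area / box area
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    cand <- cbind(stats::runif(m, lo[1L], hi[1L]),
                  stats::runif(m, lo[2L], hi[2L]))
    keep <- cand[contains(domain, cand), , drop = FALSE]
    take <- min(nrow(keep), n - got)
    if (take > 0L) {
      out[(got + 1L):(got + take), ] <- keep[seq_len(take), ]
      got <- got + take
    }
  }
  out
}

#' @export
uniform_sample.disk_domain <- function(domain, n, seed = NULL) {
  r <- domain$radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(domain$center[1L] + r * cos(th), domain$center[2L] + r * sin(th))
}

#' Intersection of two convex polygons
#'
#' Successive half-plane clipping (Sutherland-Hodgman on convex input).
#' The intersection of convex polygons is convex, possibly empty.
#'
#' @param polyA,polyB [polygon_domain()] objects.
#' @return A `polygon_domain`, or `NULL` when the intersection is empty or
#'   degenerate (zero area).
#' @export
clip_polygons <- function(polyA, polyB) {
  stopifnot(inherits(polyA, "polygon_domain"),
            inherits(polyB, "polygon_domain"))
  subj <- polyA$vertices
  nb <- nrow(polyB$vertices)
  for (i in seq_len(nb)) {
    subj <- clip_half_plane(subj, polyB$normals[i, ], polyB$offsets[i])
    if (is.null(subj)) return(NULL)
  }
  if (nrow(subj) < 3L) return(NULL)
  if (abs(polygon_area_signed(subj)) < 1e-14) return(NULL)
  suppressMessages(polygon_domain(dedupe_vertices(subj)))
}

# Clip a vertex loop against {x : n.x >= c}; returns NULL when empty.
clip_half_plane <- function(v, normal, offset) {
  n <- nrow(v)
  if (n == 0L) return(NULL)
  s <- as.numeric(v %*% normal) - offset
  inside <- s >= -HALF_PLANE_TOL
  if (!any(inside)) return(NULL)
  if (all(inside)) return(v)
  out <- matrix(NA_real_, 2L * n, 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      k <- k + 1L
      out[k, ] <- v[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1L
      out[k, ] <- v[i, ] + t * (v[j, ] - v[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

dedupe_vertices <- function(v, tol = 1e-10) {
  n <- nrow(v)
  if (n < 2L) return(v)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i] && sum((v[i, ] - v[j, ])^2) < tol^2) keep[j] <- FALSE
  }
  v[keep, , drop = FALSE]
}

translate_polygon <- function(poly, shift) {
  suppressMessages(polygon_domain(sweep(poly$vertices, 2L, -shift)))
}

#' Fold a coordinate into an interval by specular reflection
#'
#' Maps any real coordinate into \eqn{[0, L]} by repeated reflection at 0
#' and at `L` (the image map of a reflecting boundary; multiple
#' reflections within a single step are handled by the modular form).
#'
#' @param x Coordinates (vectorised).
#' @param L Interval length.
#' @return Coordinates in \eqn{[0, L]}.
#' @examples
#' reflect_fold(c(1.2, -0.3, 2.4), 1)  # 0.8, 0.3, 0.4
#' @export
reflect_fold <- function(x, L = 1) {
  stopifnot_scalar_pos(L, "L")
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}
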