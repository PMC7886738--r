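# Steady-state stopping-location densities g and transformed (observed)
# step densities f_t for each boundary condition. Under no-go boundaries
# the stationary Fredholm equation g = K g is solved by g proportional to
# the one-step acceptance probability N(r); the Nystrom/power-iteration
# solver here verifies that ansatz numerically and also handles the
# boundary conditions with no closed-form stationary density.

effective_support <- function(dist) {
  if (is.finite(dist$support_radius)) dist$support_radius
  else 10 * dist$params$sigma
}

#' One-step acceptance probability N(r)
#'
#' Probability that an unconstrained step drawn from the intrinsic law and
#' started at `r` lands inside the domain. Under no-go boundaries the
#' steady-state stopping density is proportional to this quantity.
#'
#' @param domain A domain object.
#' @param dist A matching step distribution.
#' @param r Start points: numeric vector of coordinates (1D) or points as
#'   a two-column matrix / length-2 vector (2D).
#' @return Probabilities in \eqn{[0, 1]}, one per start point.
#' @export
step_normalisation <- function(domain, dist, r) {
  UseMethod("step_normalisation")
}

#' @export
step_normalisation.interval_domain <- function(domain, dist, r) {
  stopifnot(inherits(dist, "step_dist_1d"))
  dist$cdf(domain$L - r) - dist$cdf(-r)
}

#' @export
step_normalisation.disk_domain <- function(domain, dist, r) {
  stopifnot(inherits(dist, "step_dist_2d"))
  p <- as_point_matrix(r)
  rho <- sqrt((p[, 1L] - domain$center[1L])^2 +
              (p[, 2L] - domain$center[2L])^2)
  disk_normalisation(domain$radius, dist, rho)
}

# N at distance rho from the centre of a disk of radius R: radial
# quadrature of the magnitude density weighted by the fraction of the
# circle of radius l that lies inside the disk.
disk_normalisation <- function(R, dist, rho) {
  supp <- effective_support(dist)
  vapply(rho, function(p) {
    upper <- min(supp, R + p)
    if (upper <= 0) return(1)
    simpson_int(function(l) {
      magnitude_pdf_2d(dist, l) * circle_fraction(p, l, R)
    }, 0, upper, n = 2049L)
  }, numeric(1L))
}

# Fraction of the circle of radius l centred at distance rho from the
# disk centre that lies inside the disk of radius R.
circle_fraction <- function(rho, l, R) {
  out <- numeric(length(l))
  if (rho <= 0) return(as.numeric(l < R))
  full <- l <= R - rho
  out[full] <- 1
  part <- !full & l < R + rho & l > 0
  lp <- l[part]
  arg <- (rho^2 + lp^2 - R^2) / (2 * rho * lp)
  out[part] <- acos(pmin(pmax(arg, -1), 1)) / pi
  out
}

#' Angular overlap fraction for the unit disk
#'
#' \eqn{\gamma(R, \ell) = \cos^{-1}\!\big((R^2 + \ell^2 - 1) / (2R\ell)\big)
#' / \pi}: the fraction of the circle of radius \eqn{\ell} centred at
#' distance \eqn{R} from the centre of the unit disk that falls inside the
#' disk, for \eqn{|1 - R| < \ell < 1 + R}.
#'
#' @param R Distance of the start point from the disk centre.
#' @param l Step magnitude.
#' @return The fraction in \eqn{[0, 1]}.
#' @examples
#' circle_gamma(1, 1)  # acos(1/2)/pi = 1/3
#' @export
circle_gamma <- function(R, l) {
  arg <- (R^2 + l^2 - 1) / (2 * R * l)
  acos(pmin(pmax(arg, -1), 1)) / pi
}

#' @export
step_normalisation.polygon_domain <- function(domain, dist, r) {
  stopifnot(inherits(dist, "step_dist_2d"))
  p <- as_point_matrix(r)
  q <- polygon_quadrature(domain, 201L)
  vapply(seq_len(nrow(p)), function(i) {
    d <- sqrt((q$pts[, 1L] - p[i, 1L])^2 + (q$pts[, 2L] - p[i, 2L])^2)
    sum(dist$profile(d)) * q$cell
  }, numeric(1L))
}

# Midpoint grid restricted to the polygon interior.
polygon_quadrature <- function(poly, n = 201L) {
  v <- poly$vertices
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  dx <- (hi[1L] - lo[1L]) / n
  dy <- (hi[2L] - lo[2L]) / n
  gx <- lo[1L] + (seq_len(n) - 0.5) * dx
  gy <- lo[2L] + (seq_len(n) - 0.5) * dy
  pts <- cbind(rep(gx, times = n), rep(gy, each = n))
  keep <- contains(poly, pts)
  list(pts = pts[keep, , drop = FALSE], cell = dx * dy)
}

new_grid_density <- function(grid, values, weights, coordinate) {
  z <- sum(weights * values)
  structure(list(grid = grid, values = values / z, weights = weights,
                 coordinate = coordinate),
            class = "grid_density")
}

#' @export
print.grid_density <- function(x, ...) {
  cat(sprintf(
    "Grid density on %d %s nodes (weighted mass %.6g)\n",
    length(x$grid), x$coordinate, sum(x$weights * x$values)))
  invisible(x)
}

#' Steady-state stopping density under no-go boundaries
#'
#' The stationary stopping-location density, proportional to the one-step
#' acceptance probability [step_normalisation()]. For intervals the
#' density is returned on a coordinate grid; for disks on a radial grid
#' (planar density values, radial weights \eqn{2\pi r\,dr}); for general
#' convex polygons by two-dimensional quadrature over the domain (slower
#' path, announced with a message).
#'
#' @param domain A domain object.
#' @param dist A matching step distribution.
#' @param n_grid Nodes per axis (default 201).
#' @return A `grid_density` (polygons: with a `points` matrix instead of a
#'   one-dimensional grid).
#' @export
stopping_density_nogo <- function(domain, dist, n_grid = 201L) {
  if (inherits(domain, "interval_domain")) {
    g <- seq(0, domain$L, length.out = n_grid)
    vals <- step_normalisation(domain, dist, g)
    new_grid_density(g, vals, trapezoid_weights(g), "position")
  } else if (inherits(domain, "disk_domain")) {
    g <- seq(0, domain$radius, length.out = n_grid)
    vals <- disk_normalisation(domain$radius, dist, g)
    w <- 2 * pi * g * trapezoid_weights(g)
    new_grid_density(g, vals, w, "radius")
  } else if (inherits(domain, "polygon_domain")) {
    message("polygon domain: stopping density by 2D quadrature (slower path)")
    q <- polygon_quadrature(domain, n_grid)
    vals <- step_normalisation(domain, dist, q$pts)
    out <- new_grid_density(seq_len(nrow(q$pts)), vals,
                            rep(q$cell, nrow(q$pts)), "point-index")
    out$points <- q$pts
    out
  } else {
    stop("unsupported domain", call. = FALSE)
  }
}

# --- Nystrom / power-iteration stationary solver ------------------------

# Row-stochastic transition matrix on a 1D grid (+ two boundary atoms for
# stop-go). Row j holds the probabilities of moving from node j to every
# node; rows are renormalised to sum exactly to one, which removes the
# trapezoid discretisation error in the row sums.
kernel_matrix_1d <- function(domain, dist, bc, grid) {
  L <- domain$L
  n <- length(grid)
  w <- trapezoid_weights(grid)
  dx <- outer(grid, grid, "-")    # dx[i, j] = x_i - x_j
  # sources at the integration endpoints are approached from inside the
  # domain: one-sided kernel limits there keep trapezoid quadrature
  # second order when a density jump falls exactly on an endpoint
  one_sided <- function(K) {
    K[1L, ] <- dist$pdf(pmax(abs(grid - grid[1L]) - 1e-9, 0))
    K[n, ] <- dist$pdf(pmax(abs(grid - grid[n]) - 1e-9, 0))
    K
  }
  K <- switch(bc,
    no_go = one_sided(t(dist$pdf(dx))),
    reflecting = {
      supp <- effective_support(dist)
      n_img <- ceiling((supp + 2 * L) / (2 * L))
      S <- outer(grid, grid, "+")   # x_i + x_j, symmetric
      M <- matrix(0, n, n)
      for (k in -n_img:n_img) {
        # preimages of landing at x_i from x_j: steps x_i - x_j + 2kL
        # (direct image) and -x_i - x_j + 2kL (reflected image)
        M <- M + t(dist$pdf(dx + 2 * k * L)) + dist$pdf(2 * k * L - S)
      }
      M
    },
    stop_go = one_sided(t(dist$pdf(dx)))
  )
  # K[j, i]: density of landing at x_i from x_j; apply target weights
  Kw <- sweep(K, 2L, w, "*")
  if (bc == "stop_go") {
    # two boundary atoms (nodes n+1 at x=0 and n+2 at x=L)
    to0 <- dist$cdf(-grid)
    toL <- 1 - dist$cdf(L - grid)
    Kw <- cbind(Kw, to0, toL)
    from0 <- c(dist$pdf(grid) * w, dist$cdf(0), 1 - dist$cdf(L))
    fromL <- c(dist$pdf(grid - L) * w, dist$cdf(-L), 1 - dist$cdf(0))
    Kw <- rbind(Kw, from0, fromL)
  }
  Kw / rowSums(Kw)
}

#' Stationary stopping density by Nystrom discretisation
#'
#' Discretises the stationary integral equation
#' \eqn{g(x) = \int g(x')\,P(x - x' \mid x')\,dx'} on a quadrature grid
#' (trapezoid weights; the stop-go boundary atoms are represented by two
#' extra point-mass nodes at the interval ends) and finds the
#' eigenvalue-one stationary density by power iteration from a uniform
#' start. Supported: all three boundary conditions on an interval, and
#' no-go on a disk (radial kernel on a midpoint grid).
#'
#' This is the numerical cross-check of the closed-form results: under
#' no-go the solution reproduces the normalised acceptance probability
#' N(x); under reflecting boundaries it reproduces the uniform density.
#'
#' @param domain [interval_domain()] or [disk_domain()].
#' @param dist Matching step distribution.
#' @param bc Boundary condition (disk: `"no_go"` only).
#' @param n_grid Number of grid nodes (default 201).
#' @param tol Power-iteration stopping tolerance on the sup-norm change of
#'   the density (default 1e-10).
#' @param max_iter Iteration cap (default 1e4); non-convergence raises an
#'   error reporting the last change.
#' @return An object of class `fredholm_solution`: a `grid_density` plus
#'   `residual` (sup-norm of g - Kg), `iterations`, for stop-go the two
#'   boundary `atoms`, and the row-stochastic `kernel`.
#' @export
fredholm_stationary <- function(domain, dist,
                                bc = c("no_go", "stop_go", "reflecting"),
                                n_grid = 201L, tol = 1e-10, max_iter = 1e4) {
  bc <- match.arg(bc)
  if (inherits(domain, "disk_domain")) {
    if (bc != "no_go") {
      stop("disk domains support only no-go boundary conditions",
           call. = FALSE)
    }
    return(fredholm_disk(domain, dist, n_grid, tol, max_iter))
  }
  if (!inherits(domain, "interval_domain")) {
    stop("Nystrom solver supports interval and disk domains", call. = FALSE)
  }
  grid <- seq(0, domain$L, length.out = n_grid)
  w <- trapezoid_weights(grid)
  Kw <- kernel_matrix_1d(domain, dist, bc, grid)
  p <- rep(1 / nrow(Kw), nrow(Kw))
  dens_of <- function(p) p[seq_len(n_grid)] / w
  it <- 0L
  repeat {
    it <- it + 1L
    p_new <- as.numeric(crossprod(Kw, p))
    p_new <- p_new / sum(p_new)
    delta <- max(abs(dens_of(p_new) - dens_of(p)))
    p <- p_new
    if (delta < tol) break
    if (it >= max_iter) {
      stop(sprintf(
        "power iteration did not converge (last sup-norm change %.3g); the kernel may have slowly separated stationary modes",
        delta), call. = FALSE)
    }
  }
  resid <- max(abs(as.numeric(crossprod(Kw, p)) / sum(p) - p))
  gd <- new_grid_density(grid, dens_of(p), w, "position")
  # rescale so that continuous density + atom mass integrates to one
  cont_mass <- sum(p[seq_len(n_grid)])
  gd$values <- gd$values * cont_mass
  out <- list(grid = gd$grid, values = gd$values, weights = gd$weights,
              coordinate = gd$coordinate, residual = resid, iterations = it,
              bc = bc, kernel = Kw)
  if (bc == "stop_go") out$atoms <- c(at0 = p[n_grid + 1L],
                                      atL = p[n_grid + 2L])
  class(out) <- c("fredholm_solution", "grid_density")
  out
}

fredholm_disk <- function(domain, dist, n_grid, tol, max_iter) {
  R <- domain$radius
  h <- R / n_grid
  grid <- (seq_len(n_grid) - 0.5) * h       # midpoint radial grid
  w <- rep(h, n_grid)
  n_ang <- 512L
  phi <- seq(0, pi, length.out = n_ang + 1L)
  wphi <- trapezoid_weights(phi)
  # K[j, i]: from radius r_j to radius r_i
  Kw <- matrix(0, n_grid, n_grid)
  for (j in seq_len(n_grid)) {
    d <- sqrt(outer(grid^2 + grid[j]^2, rep(1, n_ang + 1L)) -
              2 * grid[j] * outer(grid, cos(phi)))
    ang <- 2 * as.numeric(dist$profile(d) %*% wphi)
    Kw[j, ] <- grid * ang * w
  }
  Kw <- Kw / rowSums(Kw)
  p <- rep(1 / n_grid, n_grid)
  it <- 0L
  repeat {
    it <- it + 1L
    p_new <- as.numeric(crossprod(Kw, p))
    p_new <- p_new / sum(p_new)
    delta <- max(abs(p_new - p)) / h
    p <- p_new
    if (delta < tol) break
    if (it >= max_iter) {
      stop(sprintf("power iteration did not converge (last change %.3g)",
                   delta), call. = FALSE)
    }
  }
  resid <- max(abs(as.numeric(crossprod(Kw, p)) - p))
  planar <- p / (2 * pi * grid * w)
  out <- new_grid_density(grid, planar, 2 * pi * grid * w, "radius")
  out$residual <- resid
  out$iterations <- it
  out$bc <- "no_go"
  out$kernel <- Kw
  class(out) <- c("fredholm_solution", "grid_density")
  out
}

#' @export
print.fredholm_solution <- function(x, ...) {
  cat(sprintf(
    "Stationary stopping density (Nystrom, %s): %d nodes, %d iterations, residual %.2e\n",
    x$bc, length(x$grid), x$iterations, x$residual))
  if (!is.null(x$atoms)) {
    cat(sprintf("  boundary atoms: %.4g (at 0), %.4g (at L)\n",
                x$atoms[1L], x$atoms[2L]))
  }
  invisible(x)
}

# --- transformed step densities ----------------------------------------

#' Transformed step density under no-go boundaries
#'
#' The step density actually observed inside the domain: the intrinsic
#' density multiplied by the shaper function and renormalised. For a 1D
#' distribution returns the signed-step density
#' \eqn{f_t(\ell) \propto f_i(\ell) h(\ell)}; for a 2D distribution
#' returns the step-magnitude density
#' \eqn{\tilde f_t(\ell) \propto f_i(\ell, 0)\,\ell\,\tilde h(\ell)}.
#'
#' @param dist A step distribution matching the shaper's dimension.
#' @param shaper A [shaper_function()] for the enclosing domain.
#' @param n_angles Angular nodes for the magnitude shaper (2D only).
#' @return A vectorised density function of the signed step (1D) or step
#'   magnitude (2D), zero beyond the shaper cutoff.
#' @export
transformed_pdf_nogo <- function(dist, shaper, n_angles = 720L) {
  stopifnot(inherits(shaper, "shaper_fn"))
  if (inherits(dist, "step_dist_1d")) {
    if (shaper$dim != 1L) stop("1D distribution needs a 1D shaper",
                               call. = FALSE)
    cut <- min(shaper$cutoff, effective_support(dist))
    f <- function(l) dist$pdf(l) * shaper$vec(l)
    z <- simpson_int(f, -cut, cut)
    function(l) f(l) / z
  } else if (inherits(dist, "step_dist_2d")) {
    if (shaper$dim != 2L) stop("2D distribution needs a 2D shaper",
                               call. = FALSE)
    cut <- min(shaper$cutoff, effective_support(dist))
    g <- seq(0, cut, length.out = 1025L)
    ht <- magnitude_shaper(shaper, g, n_angles)
    hfun <- stats::approxfun(g, ht, yleft = ht[1L], yright = 0)
    f <- function(l) ifelse(l > cut, 0, dist$profile(l) * l * hfun(pmin(l, cut)))
    z <- trapz(g, f(g))
    function(l) f(l) / z
  } else {
    stop("`dist` must be a step distribution", call. = FALSE)
  }
}

#' Transformed step density under stop-go boundaries (1D)
#'
#' Observed signed-step density on the interval \eqn{[0, L]} under
#' stop-go boundaries, assuming a uniform stopping density (as in an
#' experiment where subjects are placed uniformly at random and only
#' first-step statistics are collected):
#' \deqn{f_t(\ell) \propto f_i(\ell)\,h_{1D}(\ell) +
#'   \big(1 - F_i(|\ell|)\big)\,\theta(L - |\ell|),}
#' where the second term collects the boundary-truncation atoms
#' integrated over the uniform start.
#'
#' @param dist A [step_dist_1d()].
#' @param L Interval length (default 1).
#' @return A vectorised density function of the signed step.
#' @export
transformed_pdf_stopgo <- function(dist, L = 1) {
  stopifnot(inherits(dist, "step_dist_1d"))
  f <- function(l) {
    inside <- abs(l) < L
    out <- numeric(length(l))
    out[inside] <- dist$pdf(l[inside]) * shaper_interval(l[inside], L) +
      (1 - dist$cdf(abs(l[inside])))
    out
  }
  z <- simpson_int(f, -L, L)
  function(l) f(l) / z
}

#' Transformed step density under reflecting boundaries (1D)
#'
#' Observed signed-step density on \eqn{[0, L]} under reflecting
#' boundaries with the (exact) uniform stationary stopping density. The
#' contribution of each reflection image is integrated over the start
#' point in closed form through the intrinsic CDF; `n_images` bounds the
#' number of reflections per step and is exact (all omitted terms vanish)
#' whenever `2 * n_images * L` exceeds the support radius.
#'
#' @param dist A [step_dist_1d()].
#' @param L Interval length (default 1).
#' @param n_images Maximum number of reflections (default: enough for the
#'   support of `dist`, so the sum is exact).
#' @return A vectorised density function of the signed step.
#' @export
transformed_pdf_reflecting <- function(dist, L = 1, n_images = NULL) {
  stopifnot(inherits(dist, "step_dist_1d"))
  supp <- effective_support(dist)
  n_img <- as.integer(n_images %||% (ceiling((supp + 2 * L) / (2 * L))))
  f <- function(l) {
    inside <- abs(l) < L
    out <- numeric(length(l))
    li <- l[inside]
    x_min <- pmax(0, -li)
    x_max <- pmin(L, L - li)
    acc <- numeric(length(li))
    for (k in -n_img:n_img) {
      # direct image: preimage step l + 2kL, independent of the start
      acc <- acc + (x_max - x_min) * dist$pdf(li + 2 * k * L) / L
      # reflected image: preimage step 2kL - 2x - l, integrated over x
      acc <- acc + (dist$cdf(2 * k * L - 2 * x_min - li) -
                    dist$cdf(2 * k * L - 2 * x_max - li)) / (2 * L)
    }
    out[inside] <- acc
    out
  }
  z <- simpson_int(f, -L, L)
  function(l) f(l) / z
}
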