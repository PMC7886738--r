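# Stationary stopping densities, the Nystrom solver, transformed step
# densities for the three boundary conditions.

test_that("acceptance probability N behaves as the window integral", {
  dom <- interval_domain()
  # uniform step law on [-1, 1]: the window [-x, 1-x] always holds mass 1/2
  du <- step_dist_1d("uniform", a = 1)
  expect_equal(step_normalisation(dom, du, c(0, 0.25, 0.5, 0.9)),
               rep(0.5, 4))
  # symmetry about the interval midpoint
  dp <- step_dist_1d("parabolic", a = 0.75)
  x <- c(0.1, 0.3, 0.45)
  expect_equal(step_normalisation(dom, dp, x),
               step_normalisation(dom, dp, 1 - x))
  # short-ranged law started centrally: every step lands inside
  ds <- step_dist_1d("parabolic", a = 0.2)
  expect_equal(step_normalisation(dom, ds, 0.5), 1)
  # disk and polygon paths agree for a common geometry
  d2 <- step_dist_2d("parabolic", a = 0.5)
  n_disk <- step_normalisation(disk_domain(), d2, c(0, 0))
  expect_equal(n_disk, 1, tolerance = 1e-6)   # support inside the disk
  n_poly <- step_normalisation(regular_polygon_domain(64), d2,
                               rbind(c(0, 0), c(0.6, 0)))
  n_circ <- step_normalisation(disk_domain(), d2, rbind(c(0, 0), c(0.6, 0)))
  expect_equal(n_poly, n_circ, tolerance = 5e-3)
})

test_that("disk angular fraction gamma matches a Monte-Carlo oracle", {
  expect_equal(circle_gamma(1, 1), 1 / 3)
  # fraction of the circle of radius l, centred at distance R from the
  # disk centre, that lies inside the unit disk
  set.seed(2)
  th <- runif(2e5, 0, 2 * pi)
  for (case in list(c(0.5, 0.8), c(0.9, 1.2))) {
    R <- case[1]
    l <- case[2]
    frac <- mean((R + l * cos(th))^2 + (l * sin(th))^2 <= 1)
    expect_equal(circle_gamma(R, l), frac, tolerance = 5e-3)
  }
})

test_that("no-go stopping densities are normalised and symmetric", {
  dp <- step_dist_1d("parabolic", a = 0.75)
  g <- stopping_density_nogo(interval_domain(), dp)
  expect_equal(sum(g$weights * g$values), 1, tolerance = 1e-9)
  expect_equal(g$values, rev(g$values), tolerance = 1e-12)
  d2 <- step_dist_2d("parabolic", a = 0.75)
  gd <- stopping_density_nogo(disk_domain(), d2)
  expect_equal(sum(gd$weights * gd$values), 1, tolerance = 1e-6)
  expect_true(all(diff(gd$values) <= 1e-9))   # densest at the centre
})

test_that("Nystrom stationary solution verifies the no-go ansatz", {
  dom <- interval_domain()
  for (d in list(step_dist_1d("parabolic", a = 0.75),
                 step_dist_1d("gaussian", sigma = 0.25),
                 step_dist_1d("uniform", a = 0.75))) {
    sol <- fredholm_stationary(dom, d, "no_go", n_grid = 201)
    expect_true(all(abs(rowSums(sol$kernel) - 1) < 1e-10))
    expect_lt(sol$residual, 1e-8)
    g <- stopping_density_nogo(dom, d, n_grid = 201)
    expect_lt(max(abs(sol$values - g$values)), 1e-3)
  }
})

test_that("Nystrom solver recovers the uniform reflecting density", {
  dom <- interval_domain()
  for (d in list(step_dist_1d("parabolic", a = 0.75),
                 step_dist_1d("gaussian", sigma = 0.25))) {
    sol <- fredholm_stationary(dom, d, "reflecting", n_grid = 201)
    expect_lt(max(abs(sol$values - 1)), 1e-3)
  }
})

test_that("stop-go stationary solution carries symmetric boundary atoms", {
  d <- step_dist_1d("parabolic", a = 0.75)
  sol <- fredholm_stationary(interval_domain(), d, "stop_go", n_grid = 201)
  expect_equal(unname(sol$atoms[1]), unname(sol$atoms[2]), tolerance = 1e-8)
  expect_gt(sol$atoms[1], 0)
  # continuous density + atoms integrate to one
  expect_equal(sum(sol$weights * sol$values) + sum(sol$atoms), 1,
               tolerance = 1e-8)
  expect_equal(sol$values, rev(sol$values), tolerance = 1e-8)
})

test_that("disk Nystrom solution matches the radial closed form", {
  d2 <- step_dist_2d("parabolic", a = 0.75)
  sol <- fredholm_stationary(disk_domain(), d2, "no_go", n_grid = 101)
  g <- stopping_density_nogo(disk_domain(), d2, n_grid = 401)
  gi <- approx(g$grid, g$values, xout = sol$grid)$y
  expect_lt(max(abs(sol$values - gi)) / max(gi), 1e-3)
})

test_that("no-go transformed density is the shaper-weighted intrinsic law", {
  # uniform intrinsic law on [-1, 1] gives the triangular density exactly
  du <- step_dist_1d("uniform", a = 1)
  ft <- transformed_pdf_nogo(du, shaper_function(interval_domain()))
  l <- seq(-1.5, 1.5, length.out = 61)
  expect_equal(ft(l), pmax(1 - abs(l), 0), tolerance = 1e-9)
  # vanishes beyond the cutoff for every family
  dp <- step_dist_1d("gaussian", sigma = 0.5)
  ftg <- transformed_pdf_nogo(dp, shaper_function(interval_domain()))
  expect_equal(ftg(c(-1.2, 1.01, 2)), c(0, 0, 0))
  expect_equal(trapz_oracle(ftg, -1, 1), 1, tolerance = 1e-8)
})

test_that("confinement strictly reduces the mean-square step", {
  geoms_1d <- list(shaper_function(interval_domain()))
  for (d in list(step_dist_1d("parabolic", a = 0.75),
                 step_dist_1d("gaussian", sigma = 0.25),
                 step_dist_1d("uniform", a = 0.75))) {
    ft <- transformed_pdf_nogo(d, geoms_1d[[1]])
    vt <- trapz_oracle(function(l) l^2 * ft(l), -1, 1)
    expect_lt(vt, dist_mean_square(d))
  }
  for (sh in list(shaper_function(square_domain()),
                  shaper_function(disk_domain()))) {
    for (d in list(step_dist_2d("parabolic", a = 0.75),
                   step_dist_2d("gaussian", sigma = 0.25))) {
      ft <- transformed_pdf_nogo(d, sh)
      vt <- trapz_oracle(function(l) l^2 * ft(l), 0, sh$cutoff)
      expect_lt(vt, dist_mean_square(d))
    }
  }
})

test_that("stop-go transformed density follows the truncation closed form", {
  d <- step_dist_1d("parabolic", a = 0.75)
  ft <- transformed_pdf_stopgo(d, 1)
  l <- seq(-0.99, 0.99, length.out = 101)
  expect_equal(ft(l), ft(-l))                       # depends on |l| only
  expect_equal(ft(c(0.8, -0.9, 1.2)), c(0, 0, 0))   # support ends with f_i here
  expect_equal(trapz_oracle(ft, -1, 1), 1, tolerance = 1e-6)
  # un-normalised structure: f_i h + upper tail mass of f_i
  raw <- function(x) pdf_1d(d, x) * shaper_interval(x) + (1 - cdf_1d(d, abs(x)))
  z <- trapz_oracle(raw, -1, 1)
  expect_equal(ft(0.3), raw(0.3) / z, tolerance = 1e-7)
})

test_that("reflecting transformed density: finite image sum is exact", {
  d <- step_dist_1d("parabolic", a = 0.75)   # support within (-2, 2)
  f1 <- transformed_pdf_reflecting(d, 1, n_images = 1)
  f5 <- transformed_pdf_reflecting(d, 1, n_images = 5)
  l <- seq(-1, 1, length.out = 201)
  expect_equal(f1(l), f5(l), tolerance = 1e-12)
  expect_equal(trapz_oracle(f1, -1, 1), 1, tolerance = 1e-6)
  # wide gaussian needs higher images; default picks enough
  dg <- step_dist_1d("gaussian", sigma = 1.5)
  fd <- transformed_pdf_reflecting(dg, 1)
  expect_equal(trapz_oracle(fd, -1, 1), 1, tolerance = 1e-6)
})
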