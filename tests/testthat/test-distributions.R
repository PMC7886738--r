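# Intrinsic step laws: symmetry, normalisation, sampler consistency.

shipped_1d <- function() {
  list(
    parabolic = step_dist_1d("parabolic", a = 0.75),
    gaussian = step_dist_1d("gaussian", sigma = 0.25),
    uniform = step_dist_1d("uniform", a = 0.75),
    tabulated = step_dist_1d("tabulated",
                             grid = seq(-0.75, 0.75, length.out = 301),
                             values = 3 * (0.75^2 -
                                           seq(-0.75, 0.75,
                                               length.out = 301)^2) /
                                      (4 * 0.75^3))
  )
}

test_that("1D families are symmetric, nonnegative and normalised", {
  for (nm in names(shipped_1d())) {
    d <- shipped_1d()[[nm]]
    l <- seq(-2, 2, length.out = 401)
    expect_equal(pdf_1d(d, l), pdf_1d(d, -l), info = nm)
    expect_true(all(pdf_1d(d, l) >= 0), info = nm)
    r <- if (is.finite(d$support_radius)) d$support_radius else 10 * 0.25
    mass <- trapz_oracle(function(x) pdf_1d(d, x), -2 * r, 2 * r,
                         n = 200001L)
    tol <- if (nm == "tabulated") 1e-6 else 1e-8
    expect_lt(abs(mass - 1), tol)
  }
})

test_that("parabolic density matches its closed form", {
  d <- step_dist_1d("parabolic", a = 0.75)
  expect_equal(pdf_1d(d, 0), 1)              # 3/(4a) with a = 0.75
  expect_equal(pdf_1d(d, 0.9), 0)            # outside the half-support
  expect_equal(pdf_1d(d, 0.5), 3 * (0.75^2 - 0.25) / (4 * 0.75^3))
  expect_equal(cdf_1d(d, c(-1, 0, 1)), c(0, 0.5, 1))
})

test_that("1D samplers are seeded and match the analytic law", {
  d <- step_dist_1d("parabolic", a = 0.75)
  expect_identical(sample_1d(d, 100, seed = 9), sample_1d(d, 100, seed = 9))
  x <- sample_1d(d, 1e5, seed = 1)
  v <- trapz_oracle(function(l) l^2 * pdf_1d(d, l), -0.75, 0.75)
  expect_equal(v, 0.75^2 / 5, tolerance = 1e-6)
  expect_lt(abs(mean(x)), 3 * sqrt(v / length(x)))
  ks <- suppressWarnings(stats::ks.test(x, function(q) cdf_1d(d, q)))
  expect_gt(ks$p.value, 0.01)
  # tabulated sampler against its own quadrature CDF
  dt <- shipped_1d()$tabulated
  xt <- sample_1d(dt, 2e4, seed = 2)
  ks2 <- suppressWarnings(stats::ks.test(xt, function(q) cdf_1d(dt, q)))
  expect_gt(ks2$p.value, 0.01)
})

test_that("2D magnitude density is 2*pi*l times the radial profile", {
  dg <- step_dist_2d("gaussian", sigma = 0.3)
  l <- seq(0, 2, length.out = 101)
  rayleigh <- l / 0.3^2 * exp(-l^2 / (2 * 0.3^2))
  expect_equal(magnitude_pdf_2d(dg, l), rayleigh, tolerance = 1e-12)
  expect_equal(magnitude_pdf_2d(dg, 0), 0)
  expect_error(magnitude_pdf_2d(dg, -0.1), "magnitudes")
  for (d in list(step_dist_2d("parabolic", a = 0.75),
                 step_dist_2d("uniform", a = 0.75), dg)) {
    r <- if (is.finite(d$support_radius)) d$support_radius else 3
    mass <- trapz_oracle(function(x) magnitude_pdf_2d(d, x), 0, r,
                         n = 200001L)
    expect_lt(abs(mass - 1), 1e-8)
  }
})

test_that("2D sampler is isotropic, centred and magnitude-consistent", {
  d <- step_dist_2d("parabolic", a = 0.75)
  expect_identical(sample_2d(d, 50, seed = 3), sample_2d(d, 50, seed = 3))
  s <- sample_2d(d, 1e5, seed = 4)
  ang <- atan2(s[, 2], s[, 1])
  cs <- suppressWarnings(
    stats::chisq.test(table(cut(ang, seq(-pi, pi, length.out = 21)))))
  expect_gt(cs$p.value, 0.01)
  msq <- trapz_oracle(function(l) l^2 * magnitude_pdf_2d(d, l), 0, 0.75)
  se <- sqrt(msq / 2 / nrow(s))    # per-coordinate variance is msq/2
  expect_lt(abs(mean(s[, 1])), 3 * se)
  expect_lt(abs(mean(s[, 2])), 3 * se)
  # magnitudes against the quadrature CDF of the magnitude density
  g <- seq(0, 0.75, length.out = 4001)
  cdfv <- cumsum(c(0, (magnitude_pdf_2d(d, g[-1]) +
                       magnitude_pdf_2d(d, g[-length(g)])) / 2 * diff(g)))
  mag_cdf <- stats::approxfun(g, cdfv / cdfv[length(cdfv)])
  ks <- suppressWarnings(stats::ks.test(sqrt(rowSums(s^2)), mag_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("tabulated families reproduce their source density", {
  dt <- shipped_1d()$tabulated
  dp <- shipped_1d()$parabolic
  l <- seq(-0.7, 0.7, length.out = 101)
  expect_equal(pdf_1d(dt, l), pdf_1d(dp, l), tolerance = 1e-3)
  # radial table for the 2D parabolic profile
  g <- seq(0, 0.75, length.out = 301)
  d2 <- step_dist_2d("tabulated", grid = g,
                     values = 2 * (0.75^2 - g^2) / (pi * 0.75^4))
  expect_equal(magnitude_pdf_2d(d2, 0.4),
               magnitude_pdf_2d(step_dist_2d("parabolic", a = 0.75), 0.4),
               tolerance = 1e-3)
  expect_error(step_dist_1d("tabulated", grid = 1:3, values = c(1, -1, 1)),
               "nonnegative")
  expect_error(step_dist_1d("tabulated", grid = 1:3), "equal length")
})
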