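# Ensemble simulation: confinement, determinism, stationarity, agreement
# with the analytic step densities along an independent code path.

test_that("walkers never leave the domain and runs are reproducible", {
  d <- step_dist_1d("parabolic", a = 0.75)
  dom <- interval_domain()
  for (bc in c("no_go", "stop_go", "reflecting")) {
    ens <- simulate_walk(dom, d, bc, n_steps = 200, n_runs = 5, seed = 1)
    expect_true(all(ens$locations >= 0 & ens$locations <= 1), info = bc)
  }
  d2 <- step_dist_2d("parabolic", a = 0.75)
  sq <- square_domain()
  ens2 <- simulate_walk(sq, d2, "no_go", n_steps = 100, n_runs = 5, seed = 2)
  pts <- cbind(as.vector(ens2$locations[, , 1]),
               as.vector(ens2$locations[, , 2]))
  expect_true(all(contains(sq, pts)))
  rerun <- simulate_walk(sq, d2, "no_go", n_steps = 100, n_runs = 5, seed = 2)
  expect_identical(ens2$locations, rerun$locations)
})

test_that("unsupported boundary/dimension pairs are configuration errors", {
  d2 <- step_dist_2d("parabolic", a = 0.75)
  expect_error(simulate_walk(square_domain(), d2, "reflecting", 10),
               "only available in 1D")
  expect_error(simulate_walk(square_domain(), d2, "stop_go", 10),
               "only available in 1D")
  expect_error(simulate_walk(interval_domain(), d2, "no_go", 10),
               "step_dist_1d")
  expect_error(
    simulate_walk(square_domain(), step_dist_1d("uniform", a = 1), "no_go",
                  10), "step_dist_2d")
})

test_that("no-go resampling guard reports a stuck walker", {
  # step law far wider than the domain: acceptance ~ 1%, cap of 2 redraws
  d <- step_dist_1d("uniform", a = 5)
  expect_error(
    simulate_walk(interval_domain(0.1), d, "no_go", n_steps = 50,
                  n_runs = 4, seed = 3, max_attempts = 2),
    "max_attempts")
})

test_that("steps_of respects burn-in and run boundaries", {
  d <- step_dist_1d("uniform", a = 0.3)
  ens <- simulate_walk(interval_domain(), d, "reflecting", n_steps = 10,
                       n_runs = 2, burn_in = 3, seed = 4)
  s <- steps_of(ens)
  expect_equal(dim(s), c(7, 2))           # (10 - 3) x 2 runs
  expect_equal(length(steps_of(ens, burn_in = 0)), 20)
  expect_error(steps_of(ens, burn_in = 10), "burn_in")
  expect_error(simulate_walk(interval_domain(), d, "no_go", n_steps = 10,
                             burn_in = 10), "burn_in")
  # steps are successive differences of the stopping locations
  expect_equal(s[, 1], diff(ens$locations[, 1])[4:10])
})

test_that("confinement reduces the empirical step variance (no-go)", {
  d <- step_dist_1d("parabolic", a = 0.75)
  ens <- simulate_walk(interval_domain(), d, "no_go", n_steps = 2000,
                       n_runs = 100, burn_in = 100, seed = 5)
  s <- steps_of(ens)
  intrinsic <- 0.75^2 / 5
  expect_lt(mean(s^2), intrinsic)
  ft <- transformed_pdf_nogo(d, shaper_function(interval_domain()))
  analytic <- trapz_oracle(function(l) l^2 * ft(l), -0.75, 0.75)
  se <- sd(colMeans(s^2)) / sqrt(ncol(s))
  expect_lt(abs(mean(s^2) - analytic), 3 * se)
})

test_that("stationary stopping locations match the analytic densities", {
  d <- step_dist_1d("parabolic", a = 0.75)
  dom <- interval_domain()
  edges <- seq(0, 1, length.out = 21)
  # reflecting: uniform stationary density, chi-squared at the 1% level
  ens_r <- simulate_walk(dom, d, "reflecting", n_steps = 1000, n_runs = 100,
                         burn_in = 50, seed = 11)
  x_r <- as.vector(stops_of(ens_r))
  chi_r <- chisq_stat(x_r, edges, rep(1 / 20, 20))
  expect_lt(chi_r, qchisq(0.99, df = 19))
  # no-go: density proportional to the acceptance probability N(x)
  ens_n <- simulate_walk(dom, d, "no_go", n_steps = 1000, n_runs = 100,
                         burn_in = 50, seed = 12)
  x_n <- as.vector(stops_of(ens_n))
  g <- stopping_density_nogo(dom, d, n_grid = 2001)
  gfun <- approxfun(g$grid, g$values)
  probs <- vapply(seq_len(20), function(i) {
    trapz_oracle(gfun, edges[i], edges[i + 1], n = 201)
  }, numeric(1))
  chi_n <- chisq_stat(x_n, edges, probs)
  expect_lt(chi_n, qchisq(0.99, df = 19))
})

test_that("disk stopping radii follow the radial closed form", {
  d2 <- step_dist_2d("gaussian", sigma = 0.4)
  dk <- disk_domain()
  ens <- simulate_walk(dk, d2, "no_go", n_steps = 500, n_runs = 100,
                       burn_in = 20, seed = 6)
  st <- stops_of(ens)
  r <- sqrt(as.vector(st[, , 1])^2 + as.vector(st[, , 2])^2)
  g <- stopping_density_nogo(dk, d2, n_grid = 401)
  gfun <- approxfun(g$grid, g$values)
  edges <- seq(0, 1, length.out = 21)
  probs <- vapply(seq_len(20), function(i) {
    trapz_oracle(function(x) 2 * pi * x * gfun(x), edges[i], edges[i + 1],
                 n = 201)
  }, numeric(1))
  expect_lt(chisq_stat(r, edges, probs), qchisq(0.99, df = 19))
})

test_that("first stop-go steps reproduce the uniform-start closed form", {
  d <- step_dist_1d("parabolic", a = 0.75)
  ens <- simulate_walk(interval_domain(), d, "stop_go", n_steps = 1,
                       n_runs = 2e4, burn_in = 0, seed = 13)
  s <- as.vector(steps_of(ens))
  ft <- transformed_pdf_stopgo(d, 1)
  edges <- seq(-1, 1, length.out = 41)
  probs <- bin_average(ft, edges) * diff(edges)
  keep <- probs * length(s) >= 10
  counts <- tabulate(findInterval(s, edges, rightmost.closed = TRUE),
                     nbins = 40)
  chi <- sum(((counts - probs * length(s))^2 / (probs * length(s)))[keep])
  expect_lt(chi, qchisq(0.99, df = sum(keep) - 1))
})

test_that("reflecting step histogram matches the image-sum density", {
  # the simulator folds; the analytic density sums images: independent paths
  d <- step_dist_1d("parabolic", a = 0.75)
  ens <- simulate_walk(interval_domain(), d, "reflecting", n_steps = 1000,
                       n_runs = 100, burn_in = 50, seed = 14)
  s <- as.vector(steps_of(ens))
  ft <- transformed_pdf_reflecting(d, 1)
  edges <- seq(-1, 1, length.out = 41)
  probs <- bin_average(ft, edges) * diff(edges)
  keep <- probs * length(s) >= 10
  counts <- tabulate(findInterval(s, edges, rightmost.closed = TRUE),
                     nbins = 40)
  dev <- (counts - probs * length(s)) / sqrt(probs * length(s))
  expect_gte(mean(abs(dev[keep]) < 3), 0.95)
})

test_that("time averages agree with ensemble averages (ergodicity)", {
  d <- step_dist_1d("parabolic", a = 0.75)
  dom <- interval_domain()
  long <- simulate_walk(dom, d, "no_go", n_steps = 20000, n_runs = 1,
                        burn_in = 200, seed = 15)
  short <- simulate_walk(dom, d, "no_go", n_steps = 200, n_runs = 100,
                         burn_in = 20, seed = 16)
  m_time <- mean(steps_of(long)^2)
  per_run <- colMeans(steps_of(short)^2)
  se <- sd(per_run) / sqrt(length(per_run))
  expect_lt(abs(m_time - mean(per_run)), 3 * se)
})
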