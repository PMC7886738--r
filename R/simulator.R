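# Ensemble simulation of stopping-location sequences. A run starts
# uniformly at random in the domain; each step is drawn from the intrinsic
# law and resolved against the boundary: no-go redraws steps that would
# exit (rejection re-sampling of the full step vector), stop-go truncates
# them at the boundary, reflecting folds the landing point back inside.
# All runs of an ensemble are advanced in lockstep from a single seeded
# RNG stream, so the whole ensemble is reproducible from its seed.

#' Simulate an ensemble of bounded random walks
#'
#' Generates `n_runs` independent stopping-location sequences of `n_steps`
#' steps each inside a bounded convex domain. Boundary conditions:
#' `"no_go"` (out-of-domain proposals are rejected and redrawn; available
#' in 1D and 2D), `"stop_go"` (proposals are truncated at the first
#' boundary crossing; 1D only) and `"reflecting"` (landing points are
#' folded back by specular reflection; 1D only).
#'
#' @param domain A domain object ([interval_domain()], [polygon_domain()]
#'   or [disk_domain()]).
#' @param dist A matching step distribution: [step_dist_1d()] for
#'   intervals, [step_dist_2d()] for 2D domains.
#' @param bc Boundary condition, one of `"no_go"`, `"stop_go"`,
#'   `"reflecting"`.
#' @param n_steps Steps per run (N).
#' @param n_runs Independent runs (M, default 1).
#' @param burn_in Initial steps of every run excluded from statistics;
#'   default 1 percent of `n_steps`. Must satisfy
#'   `0 <= burn_in < n_steps`.
#' @param seed Optional integer seed for the whole ensemble.
#' @param max_attempts No-go only: maximum redraws for a single step
#'   before aborting with an error naming the stuck location (default
#'   1e6); guards against step laws too short-ranged for the geometry.
#' @return An object of class `walk_ensemble` with the stopping-location
#'   array (`n_steps + 1` rows including the start), the per-run
#'   rejection counts (no-go) and the simulation metadata.
#' @seealso [steps_of()], [step_magnitudes()]
#' @export
simulate_walk <- function(domain, dist,
                          bc = c("no_go", "stop_go", "reflecting"),
                          n_steps, n_runs = 1L, burn_in = NULL, seed = NULL,
                          max_attempts = 1e6) {
  bc <- match.arg(bc)
  stopifnot(inherits(domain, "domain"))
  n_steps <- as.integer(n_steps)
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("`n_runs` must be >= 1", call. = FALSE)
  burn_in <- as.integer(burn_in %||% floor(0.01 * n_steps))
  if (burn_in < 0L || burn_in >= n_steps) {
    stop("`burn_in` must satisfy 0 <= burn_in < n_steps", call. = FALSE)
  }
  if (domain$dim == 1L) {
    if (!inherits(dist, "step_dist_1d")) {
      stop("interval domains require a `step_dist_1d`", call. = FALSE)
    }
  } else {
    if (!inherits(dist, "step_dist_2d")) {
      stop("2D domains require a `step_dist_2d`", call. = FALSE)
    }
    if (bc != "no_go") {
      stop(sprintf("boundary condition '%s' is only available in 1D", bc),
           call. = FALSE)
    }
  }
  set_seed_if(seed)
  res <- if (domain$dim == 1L) {
    walk_1d(domain, dist, bc, n_steps, n_runs, max_attempts)
  } else {
    walk_2d(domain, dist, n_steps, n_runs, max_attempts)
  }
  structure(list(locations = res$locations, rejections = res$rejections,
                 bc = bc, domain = domain, dist = dist, n_steps = n_steps,
                 n_runs = n_runs, burn_in = burn_in, seed = seed),
            class = "walk_ensemble")
}

walk_1d <- function(domain, dist, bc, n_steps, n_runs, max_attempts) {
  L <- domain$L
  x <- stats::runif(n_runs, 0, L)
  loc <- matrix(NA_real_, n_steps + 1L, n_runs)
  loc[1L, ] <- x
  rej <- integer(n_runs)
  for (i in seq_len(n_steps)) {
    y <- x + dist$sampler(n_runs)
    if (bc == "no_go") {
      bad <- which(y < 0 | y > L)
      attempts <- 0
      while (length(bad)) {
        attempts <- attempts + 1
        if (attempts > max_attempts) {
          stop(sprintf(
            "no-go resampling exceeded max_attempts at step %d (stuck near x = %.6g)",
            i, x[bad[1L]]), call. = FALSE)
        }
        rej[bad] <- rej[bad] + 1L
        y[bad] <- x[bad] + dist$sampler(length(bad))
        bad <- bad[y[bad] < 0 | y[bad] > L]
      }
    } else if (bc == "stop_go") {
      y <- pmin(pmax(y, 0), L)
    } else {
      y <- reflect_fold(y, L)
    }
    x <- y
    loc[i + 1L, ] <- x
  }
  list(locations = loc, rejections = rej)
}

walk_2d <- function(domain, dist, n_steps, n_runs, max_attempts) {
  x <- uniform_sample(domain, n_runs)
  loc <- array(NA_real_, c(n_steps + 1L, n_runs, 2L))
  loc[1L, , ] <- x
  rej <- integer(n_runs)
  for (i in seq_len(n_steps)) {
    y <- x + dist$sampler(n_runs)
    bad <- which(!contains(domain, y))
    attempts <- 0
    while (length(bad)) {
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        stop(sprintf(
          "no-go resampling exceeded max_attempts at step %d (stuck near (%.6g, %.6g))",
          i, x[bad[1L], 1L], x[bad[1L], 2L]), call. = FALSE)
      }
      rej[bad] <- rej[bad] + 1L
      y[bad, ] <- x[bad, , drop = FALSE] + dist$sampler(length(bad))
      bad <- bad[!contains(domain, y[bad, , drop = FALSE])]
    }
    x <- y
    loc[i + 1L, , ] <- x
  }
  list(locations = loc, rejections = rej)
}

#' @export
print.walk_ensemble <- function(x, ...) {
  cat("Bounded random-walk ensemble\n")
  cat(sprintf("  boundary condition: %s; %d run(s) x %d steps (burn-in %d)\n",
              x$bc, x$n_runs, x$n_steps, x$burn_in))
  print(x$domain)
  if (x$bc == "no_go") {
    cat(sprintf("  mean rejections per run: %.1f\n", mean(x$rejections)))
  }
  invisible(x)
}

#' Post-burn-in steps of an ensemble
#'
#' Successive differences of the stopping locations, with the first
#' `burn_in` steps of every run excluded. Run boundaries are preserved:
#' each column (1D) or each slice index (2D) is one run.
#'
#' @param ensemble A [simulate_walk()] result.
#' @param burn_in Override of the ensemble's burn-in (optional).
#' @return 1D: a `(n_steps - burn_in)` by `n_runs` matrix of signed steps.
#'   2D: an array with a trailing length-2 coordinate dimension.
#' @export
steps_of <- function(ensemble, burn_in = NULL) {
  stopifnot(inherits(ensemble, "walk_ensemble"))
  b <- as.integer(burn_in %||% ensemble$burn_in)
  n <- ensemble$n_steps
  if (b < 0L || b >= n) {
    stop("`burn_in` must satisfy 0 <= burn_in < n_steps", call. = FALSE)
  }
  loc <- ensemble$locations
  if (ensemble$domain$dim == 1L) {
    steps <- loc[2:(n + 1L), , drop = FALSE] - loc[1:n, , drop = FALSE]
    steps[(b + 1L):n, , drop = FALSE]
  } else {
    steps <- loc[2:(n + 1L), , , drop = FALSE] - loc[1:n, , , drop = FALSE]
    steps[(b + 1L):n, , , drop = FALSE]
  }
}

#' Post-burn-in step magnitudes of a 2D ensemble
#'
#' @inheritParams steps_of
#' @return A `(n_steps - burn_in)` by `n_runs` matrix of step magnitudes.
#' @export
step_magnitudes <- function(ensemble, burn_in = NULL) {
  stopifnot(inherits(ensemble, "walk_ensemble"))
  if (ensemble$domain$dim != 2L) {
    stop("step magnitudes are defined for 2D ensembles; use abs() on 1D steps",
         call. = FALSE)
  }
  s <- steps_of(ensemble, burn_in)
  m <- sqrt(s[, , 1L, drop = FALSE]^2 + s[, , 2L, drop = FALSE]^2)
  dim(m) <- dim(m)[1:2]
  m
}

#' Post-burn-in stopping locations of an ensemble
#'
#' @inheritParams steps_of
#' @return 1D: matrix of coordinates (rows: retained stops, columns:
#'   runs). 2D: array with a trailing coordinate dimension.
#' @export
stops_of <- function(ensemble, burn_in = NULL) {
  stopifnot(inherits(ensemble, "walk_ensemble"))
  b <- as.integer(burn_in %||% ensemble$burn_in)
  n <- ensemble$n_steps
  if (ensemble$domain$dim == 1L) {
    ensemble$locations[(b + 2L):(n + 1L), , drop = FALSE]
  } else {
    ensemble$locations[(b + 2L):(n + 1L), , , drop = FALSE]
  }
}
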