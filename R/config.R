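# Run configuration and pipeline entry point. A run config (YAML or JSON)
# declares the domain, the intrinsic step distribution, the boundary
# condition and the simulation/estimation parameters; `run_pipeline()`
# wires it to the package functions, writes CSV artifacts plus a JSON
# manifest, and is fully reproducible from the manifest alone.

#' Read a run configuration
#'
#' Reads a YAML (or JSON) run configuration and validates it field by
#' field. Required blocks: `domain` (with `type` one of `interval`,
#' `polygon`, `disk`) and `distribution` (with `family`); simulation
#' fields (`n_steps`, `n_runs`, `burn_in`, `seed`,
#' `boundary_condition`, `bins`, `shaper_floor`) have defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg, dirname(path))
}

#' Validate a run configuration list
#'
#' @param cfg A configuration list (as from [read_run_config()]).
#' @param base_dir Directory against which relative CSV paths in the
#'   config are resolved.
#' @return The validated config, with defaults filled in, of class
#'   `run_config`.
#' @export
validate_run_config <- function(cfg, base_dir = ".") {
  fail <- function(field, msg) {
    stop(sprintf("config field `%s`: %s", field, msg), call. = FALSE)
  }
  if (is.null(cfg$domain) || is.null(cfg$domain$type)) {
    fail("domain.type", "missing")
  }
  if (!cfg$domain$type %in% c("interval", "polygon", "disk")) {
    fail("domain.type", "must be interval, polygon or disk")
  }
  if (is.null(cfg$distribution) || is.null(cfg$distribution$family)) {
    fail("distribution.family", "missing")
  }
  cfg$boundary_condition <- cfg$boundary_condition %||% "no_go"
  if (!cfg$boundary_condition %in% c("no_go", "stop_go", "reflecting")) {
    fail("boundary_condition", "must be no_go, stop_go or reflecting")
  }
  cfg$n_steps <- as.integer(cfg$n_steps %||% 10000L)
  cfg$n_runs <- as.integer(cfg$n_runs %||% 50L)
  cfg$burn_in <- as.integer(cfg$burn_in %||% floor(0.01 * cfg$n_steps))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$bins <- as.integer(cfg$bins %||% 60L)
  cfg$shaper_floor <- as.numeric(cfg$shaper_floor %||% 0.01)
  if (cfg$n_steps < 1L) fail("n_steps", "must be >= 1")
  if (cfg$n_runs < 1L) fail("n_runs", "must be >= 1")
  if (cfg$burn_in < 0L || cfg$burn_in >= cfg$n_steps) {
    fail("burn_in", "must satisfy 0 <= burn_in < n_steps")
  }
  if (cfg$shaper_floor <= 0 || cfg$shaper_floor >= 1) {
    fail("shaper_floor", "must be in (0, 1)")
  }
  dom <- config_domain(cfg, base_dir)   # validates the domain block
  if (dom$dim == 2L && cfg$boundary_condition != "no_go") {
    fail("boundary_condition",
         sprintf("'%s' is only available for interval domains",
                 cfg$boundary_condition))
  }
  config_dist(cfg, dom, base_dir)       # validates the distribution block
  cfg$base_dir <- base_dir
  class(cfg) <- "run_config"
  cfg
}

config_domain <- function(cfg, base_dir = ".") {
  d <- cfg$domain
  switch(d$type,
    interval = interval_domain(d$L %||% 1),
    disk = disk_domain(unlist(d$center %||% c(0, 0)), d$radius %||% 1),
    polygon = {
      if (!is.null(d$csv)) {
        path <- if (file.exists(d$csv)) d$csv else file.path(base_dir, d$csv)
        v <- utils::read.csv(path)
        polygon_domain(as.matrix(v[, 1:2]))
      } else if (!is.null(d$vertices)) {
        v <- d$vertices
        if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
        polygon_domain(v)
      } else if (!is.null(d$side)) {
        square_domain(d$side)
      } else {
        stop("config field `domain`: polygon needs `vertices`, `csv` or `side`",
             call. = FALSE)
      }
    }
  )
}

config_dist <- function(cfg, domain, base_dir = ".") {
  d <- cfg$distribution
  ctor <- if (domain$dim == 1L) step_dist_1d else step_dist_2d
  if (identical(d$family, "tabulated")) {
    path <- d$csv
    if (is.null(path)) {
      stop("config field `distribution`: tabulated family needs `csv`",
           call. = FALSE)
    }
    if (!file.exists(path)) path <- file.path(base_dir, path)
    tab <- utils::read.csv(path)
    ctor("tabulated", grid = tab[[1L]], values = tab[[2L]])
  } else {
    ctor(d$family, a = d$a, sigma = d$sigma)
  }
}

#' Run a configured analysis
#'
#' Executes one subcommand of the analysis pipeline against a validated
#' run configuration and writes its CSV artifacts plus a JSON manifest
#' (config echo, seed, package version, wall time) into `out_dir`.
#' Identical config and seed give identical numeric output.
#'
#' Subcommands: `simulate` (stopping locations + steps CSV), `shaper`
#' (shaper function tables), `steady_state` (stationary stopping
#' density), `transformed` (analytic transformed step density),
#' `reconstruct` (simulate, estimate and invert the shaper bias; or
#' invert a user-supplied steps CSV given as `cfg$steps_csv`), `demo`
#' (simulate + transformed + reconstruct).
#'
#' @param cfg A `run_config` (see [read_run_config()]) or a path to one.
#' @param subcommand One of `"simulate"`, `"shaper"`, `"steady_state"`,
#'   `"transformed"`, `"reconstruct"`, `"demo"`.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(cfg, subcommand = c("simulate", "shaper",
                                             "steady_state", "transformed",
                                             "reconstruct", "demo"),
                         out_dir = ".", quiet = FALSE) {
  subcommand <- match.arg(subcommand)
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(sprintf(...))
  domain <- config_domain(cfg, cfg$base_dir %||% ".")
  dist <- config_dist(cfg, domain, cfg$base_dir %||% ".")
  files <- list()
  extra <- list()

  write_tab <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files[[name]] <<- path
  }

  if (subcommand %in% c("simulate", "reconstruct", "demo") &&
      !(subcommand == "reconstruct" && !is.null(cfg$steps_csv))) {
    say("simulating %d run(s) of %d steps (%s)...",
        cfg$n_runs, cfg$n_steps, cfg$boundary_condition)
    ens <- simulate_walk(domain, dist, cfg$boundary_condition,
                         n_steps = cfg$n_steps, n_runs = cfg$n_runs,
                         burn_in = cfg$burn_in, seed = cfg$seed)
    extra$rejections <- unname(ens$rejections)
    if (subcommand %in% c("simulate", "demo")) {
      loc <- ens$locations
      if (domain$dim == 1L) {
        df <- data.frame(
          run = rep(seq_len(cfg$n_runs), each = nrow(loc)),
          index = rep(seq_len(nrow(loc)) - 1L, cfg$n_runs),
          x = as.vector(loc))
      } else {
        df <- data.frame(
          run = rep(seq_len(cfg$n_runs), each = nrow(loc)),
          index = rep(seq_len(nrow(loc)) - 1L, cfg$n_runs),
          x = as.vector(loc[, , 1L]), y = as.vector(loc[, , 2L]))
      }
      write_tab(df, "locations.csv")
      s <- steps_of(ens)
      if (domain$dim == 1L) {
        sdf <- data.frame(run = rep(seq_len(cfg$n_runs), each = nrow(s)),
                          step = as.vector(s))
      } else {
        sdf <- data.frame(run = rep(seq_len(cfg$n_runs), each = dim(s)[1L]),
                          dx = as.vector(s[, , 1L]),
                          dy = as.vector(s[, , 2L]),
                          magnitude = as.vector(step_magnitudes(ens)))
      }
      write_tab(sdf, "steps.csv")
    }
  }

  if (subcommand == "shaper") {
    sh <- shaper_function(domain)
    d <- domain_diameter(domain)
    if (domain$dim == 1L) {
      l <- seq(-d, d, length.out = 201L)
      write_tab(data.frame(l = l, h = sh$vec(l)), "shaper.csv")
    } else {
      g <- seq(-d, d, length.out = 41L)
      grid <- expand.grid(lx = g, ly = g)
      write_tab(data.frame(grid, h = sh$vec(grid$lx, grid$ly)), "shaper.csv")
      lm <- seq(0, d, length.out = 201L)
      write_tab(data.frame(l = lm, h_mag = magnitude_shaper(sh, lm)),
                "shaper_magnitude.csv")
    }
  }

  if (subcommand == "steady_state") {
    if (cfg$boundary_condition == "no_go") {
      gd <- stopping_density_nogo(domain, dist)
      if (!is.null(gd$points)) {
        write_tab(data.frame(x = gd$points[, 1L], y = gd$points[, 2L],
                             density = gd$values), "steady_state.csv")
      } else {
        write_tab(data.frame(grid = gd$grid, density = gd$values),
                  "steady_state.csv")
      }
    } else {
      sol <- fredholm_stationary(domain, dist, cfg$boundary_condition)
      write_tab(data.frame(grid = sol$grid, density = sol$values),
                "steady_state.csv")
      extra$atoms <- as.list(sol$atoms)
      extra$residual <- sol$residual
    }
  }

  if (subcommand == "transformed") {
    if (domain$dim == 1L) {
      ft <- switch(cfg$boundary_condition,
        no_go = transformed_pdf_nogo(dist, shaper_function(domain)),
        stop_go = transformed_pdf_stopgo(dist, domain$L),
        reflecting = transformed_pdf_reflecting(dist, domain$L))
      l <- seq(-domain$L, domain$L, length.out = 401L)
      write_tab(data.frame(l = l, ft = ft(l)), "transformed.csv")
    } else {
      ft <- transformed_pdf_nogo(dist, shaper_function(domain))
      l <- seq(0, domain_diameter(domain), length.out = 401L)
      write_tab(data.frame(l = l, ft_magnitude = ft(l)), "transformed.csv")
    }
  }

  if (subcommand %in% c("reconstruct", "demo")) {
    sh <- shaper_function(domain)
    edges <- default_bins(domain, cfg$bins, signed = domain$dim == 1L)
    if (!is.null(cfg$steps_csv) && subcommand == "reconstruct") {
      path <- cfg$steps_csv
      if (!file.exists(path)) path <- file.path(cfg$base_dir %||% ".", path)
      sdf <- utils::read.csv(path)
      col <- if (domain$dim == 1L) "step" else "magnitude"
      if (!all(c("run", col) %in% names(sdf))) {
        stop(sprintf("steps CSV needs columns `run` and `%s`", col),
             call. = FALSE)
      }
      runs <- split(sdf[[col]], sdf$run)
    } else {
      runs <- if (domain$dim == 1L) steps_of(ens) else step_magnitudes(ens)
    }
    est <- estimate_density(runs, edges)
    rec <- reconstruct_intrinsic(est, sh, cfg$shaper_floor)
    write_tab(as.data.frame(rec), "reconstruction.csv")
  }

  if (subcommand == "demo" && domain$dim == 2L) {
    ft <- transformed_pdf_nogo(dist, shaper_function(domain))
    l <- seq(0, domain_diameter(domain), length.out = 401L)
    write_tab(data.frame(l = l, ft_magnitude = ft(l)), "transformed.csv")
  }

  manifest <- list(
    subcommand = subcommand,
    config = unclass(cfg)[setdiff(names(cfg), "base_dir")],
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("boundedwalk")),
    r_version = R.version.string,
    wall_time_s = proc.time()[["elapsed"]] - t0,
    outputs = names(files)
  )
  manifest <- c(manifest, extra)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files[["manifest.json"]] <- mpath
  say("wrote %d file(s) to %s", length(files), out_dir)
  invisible(files)
}
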