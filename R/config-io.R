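#' Read a simulation configuration file
#'
#' YAML or JSON (by extension) with optional blocks `ecology`, `drive`,
#' `release`, `two_deme` and `solver`, whose fields mirror the arguments of
#' [ecology_params()], [drive_config()], [release_spec()], the migration
#' rate `psi`, and the solver settings (`t_end`, `max_step`, `save_dt`).
#' Missing blocks and fields fall back to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with components `ecology`, `drive`, `release`, `psi`,
#'   `t_end`, `max_step`, `save_dt`.
#' @examples
#' cfg <- read_drive_config(system.file("extdata", "example-config.yaml",
#'                                      package = "drivedyn"))
#' cfg$drive
#' @export
read_drive_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("config must be a .yaml, .yml or .json file")
  )
  if (is.null(raw)) raw <- list()
  take <- function(block, fn, defaults = list()) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    exec(fn, !!!utils::modifyList(defaults, as.list(args)))
  }
  solver <- utils::modifyList(list(t_end = 2000, max_step = 0.05,
                                   save_dt = 0.1),
                              as.list(raw$solver %||% list()))
  list(
    ecology = take("ecology", ecology_params),
    drive = take("drive", drive_config),
    release = take("release", release_spec),
    psi = as.numeric(raw$two_deme$psi %||% 0),
    t_end = solver$t_end,
    max_step = solver$max_step,
    save_dt = solver$save_dt
  )
}

write_manifest <- function(out_dir, command, config, outputs, solver) {
  manifest <- list(
    command = command,
    package = "drivedyn",
    version = as.character(utils::packageVersion("drivedyn")),
    config = config,
    solver = solver,
    outputs = outputs
  )
  path <- file.path(out_dir, paste0(command, "-manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  path
}

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  path
}

#' Equilibrium population sweep
#'
#' Evaluates the closed-form equilibrium `N*` while one ecological parameter
#' is varied and the others are held at their base values.
#'
#' @param param One of `"alpha"`, `"beta"`, `"rho"`, `"mu"`.
#' @param values Values to sweep.
#' @param ecology Base parameters.
#' @return A tibble with columns `param`, `value`, `N_star`.
#' @examples
#' run_equilibrium_sweep("alpha", c(0.02, 0.7))
#' @export
run_equilibrium_sweep <- function(param = c("alpha", "beta", "rho", "mu"),
                                  values, ecology = ecology_params()) {
  param <- arg_match(param)
  n_star <- purrr::map_dbl(values, function(v) {
    eco <- ecology
    eco[[param]] <- v
    equilibrium_population(ecology_params(eco$alpha, eco$beta, eco$rho,
                                          eco$mu, eco$tau))
  })
  tibble(param = rep(param, length(values)), value = values, N_star = n_star)
}

#' Run one simulation from a configuration and write CSVs
#'
#' Writes `trajectory.csv` (per-deme population summary series),
#' `metrics.csv` (one row per deme) and a JSON run manifest into `out_dir`.
#'
#' @param config A list as returned by [read_drive_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (config$psi > 0) {
    simulate_two_deme(config$drive, config$ecology, config$release,
                      psi = config$psi, t_end = config$t_end,
                      max_step = config$max_step, save_dt = config$save_dt)
  } else {
    simulate_release(config$drive, config$ecology, config$release,
                     t_end = config$t_end, max_step = config$max_step,
                     save_dt = config$save_dt)
  }
  paths <- c(
    write_csv_plain(tidy(sim), file.path(out_dir, "trajectory.csv")),
    write_csv_plain(drive_metrics(sim), file.path(out_dir, "metrics.csv"))
  )
  paths <- c(paths, write_manifest(
    out_dir, "simulate", config[c("psi", "t_end")], paths,
    list(max_step = config$max_step, save_dt = config$save_dt, h = sim$h)
  ))
  invisible(paths)
}

#' Run a threshold scan from a configuration and write CSVs
#'
#' @inheritParams run_simulation
#' @param thetas,eps Grid values.
#' @param refine Refine per-theta thresholds by bisection.
#' @return Invisibly, the paths written (`scan.csv`, `thresholds.csv`,
#'   manifest).
#' @export
run_scan <- function(config, out_dir, thetas = 1,
                     eps = seq(0, 1, by = 0.01), refine = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  criterion <- if (config$drive$system == "UD") "ud_introgression" else
    "kr_increase"
  scan <- threshold_scan(config$drive, thetas = thetas, eps = eps,
                         criterion = criterion, ecology = config$ecology,
                         release_sexes = config$release$sexes,
                         t_end = config$t_end, max_step = config$max_step,
                         refine = refine)
  paths <- c(
    write_csv_plain(scan$grid, file.path(out_dir, "scan.csv")),
    write_csv_plain(scan$thresholds, file.path(out_dir, "thresholds.csv"))
  )
  paths <- c(paths, write_manifest(
    out_dir, "scan", config["t_end"], paths,
    list(max_step = config$max_step)
  ))
  invisible(paths)
}

#' Run a migration-rate sweep of the two-deme model and write CSVs
#'
#' One two-deme simulation per `psi`; writes per-deme metrics for each rate
#' (`two-deme-metrics.csv`) and the summary series of each run
#' (`two-deme-trajectories.csv`).
#'
#' @inheritParams run_simulation
#' @param psis Migration rates per day to sweep.
#' @return Invisibly, the paths written.
#' @export
run_two_deme <- function(config, out_dir, psis = c(0, 0.001, 0.01)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runs <- purrr::map(psis, function(p) {
    simulate_two_deme(config$drive, config$ecology, config$release, psi = p,
                      t_end = config$t_end, max_step = config$max_step,
                      save_dt = config$save_dt)
  })
  metrics <- purrr::map2_dfr(runs, psis, function(s, p) {
    mutate(drive_metrics(s), psi = p)
  })
  series <- purrr::map2_dfr(runs, psis, function(s, p) {
    mutate(population_series(s), psi = p)
  })
  paths <- c(
    write_csv_plain(metrics, file.path(out_dir, "two-deme-metrics.csv")),
    write_csv_plain(series, file.path(out_dir, "two-deme-trajectories.csv"))
  )
  paths <- c(paths, write_manifest(
    out_dir, "two-deme", list(psis = psis, t_end = config$t_end), paths,
    list(max_step = config$max_step, save_dt = config$save_dt)
  ))
  invisible(paths)
}
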