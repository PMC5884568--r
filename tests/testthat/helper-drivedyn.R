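# shared defaults for fast test simulations: coarser step, short horizon
quick_sim <- function(drive, ..., t_end = 300, max_step = 0.25,
                      save_dt = 0.5) {
  simulate_release(drive, t_end = t_end, max_step = max_step,
                   save_dt = save_dt, ...)
}

base_eco <- function(...) ecology_params(...)

# lazily computed, shared across acceptance test blocks: the full
# eps-by-0.01, t_end = 5000 d scans behind the headline suppression numbers
the_scans <- new.env(parent = emptyenv())

acceptance_ud_threshold <- function() {
  if (is.null(the_scans$ud_th)) {
    the_scans$ud_th <- find_fitness_threshold(
      drive_config("UD", timing = "early"), criterion = "ud_introgression"
    )
  }
  the_scans$ud_th
}

acceptance_scan <- function(system, timing) {
  key <- paste(system, timing, sep = "_")
  if (is.null(the_scans[[key]])) {
    criterion <- if (system == "UD") "ud_introgression" else "kr_increase"
    the_scans[[key]] <- threshold_scan(
      drive_config(system, timing = timing),
      thetas = 1, eps = seq(0, 1, by = 0.01), criterion = criterion,
      t_end = 5000, max_step = 0.05, refine = FALSE
    )$grid
  }
  the_scans[[key]]
}
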