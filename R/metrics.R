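# per-deme genotype count matrix (M + F) over time
deme_counts <- function(sim, deme = 1) {
  ix <- (deme - 1L) * 18L
  sim$state[, ix + 1:9, drop = FALSE] + sim$state[, ix + 10:18, drop = FALSE]
}

#' Total adult population over time
#'
#' @param sim A `drive_sim`.
#' @param deme Deme index.
#' @return Numeric vector aligned with `sim$time`.
#' @export
total_population <- function(sim, deme = 1) {
  rowSums(deme_counts(sim, deme))
}

#' Transgene frequency of a population state
#'
#' Allele frequency of a construct among adults:
#' `sum_i eta_iX * (M_i + F_i) / (2 * N)`.  `mode = "overall"` averages the
#' two construct frequencies; for killer-rescue the rescue frequency is the
#' construct B frequency.
#'
#' @param M,F Numeric vectors of length 9 (counts per genotype and sex).
#' @param mode `"overall"`, `"construct_A"`, `"construct_B"` or `"rescue"`
#'   (alias for construct B).
#' @return A frequency in \[0, 1\]; errors for an empty population.
#' @examples
#' st <- make_state(AABB = 100, aabb = 100)
#' transgene_frequency(st$M, st$F) # 0.5
#' @export
transgene_frequency <- function(M, F, mode = c("overall", "construct_A",
                                               "construct_B", "rescue")) {
  mode <- arg_match(mode)
  stopifnot(length(M) == 9, length(F) == 9)
  cnt <- M + F
  N <- sum(cnt)
  if (N <= 0) abort("transgene frequency undefined for an empty population")
  fA <- sum(eta_A_vec() * cnt) / (2 * N)
  fB <- sum(eta_B_vec() * cnt) / (2 * N)
  switch(mode, overall = (fA + fB) / 2, construct_A = fA,
         construct_B = fB, rescue = fB)
}

#' Transgene frequency along a trajectory
#'
#' @param sim A `drive_sim`.
#' @param deme Deme index.
#' @inheritParams transgene_frequency
#' @return Numeric vector aligned with `sim$time` (NA where the deme is
#'   empty).
#' @export
frequency_series <- function(sim, deme = 1,
                             mode = c("overall", "construct_A",
                                      "construct_B", "rescue")) {
  mode <- arg_match(mode)
  cnt <- deme_counts(sim, deme)
  N <- rowSums(cnt)
  fA <- as.numeric(cnt %*% eta_A_vec()) / (2 * N)
  fB <- as.numeric(cnt %*% eta_B_vec()) / (2 * N)
  out <- switch(mode, overall = (fA + fB) / 2, construct_A = fA,
                construct_B = fB, rescue = fB)
  out[N <= 0] <- NA_real_
  out
}

#' Classify the fate of an underdominance release
#'
#' Final-state classification per deme from the overall transgene frequency:
#' below `low_cutoff` the transgenes were eliminated; above `high_cutoff`
#' they reached (near-)fixation; otherwise the deme sits at an intermediate
#' equilibrium (e.g. partial introgression sustained by migration).
#'
#' @param final_freq Final overall transgene frequency (vector allowed).
#' @param low_cutoff,high_cutoff Classification cutoffs.
#' @return Character vector: `"eliminated"`, `"intermediate"` or
#'   `"fixation"`.
#' @export
classify_ud_outcome <- function(final_freq, low_cutoff = 0.01,
                                high_cutoff = 0.95) {
  dplyr::case_when(
    final_freq < low_cutoff ~ "eliminated",
    final_freq > high_cutoff ~ "fixation",
    TRUE ~ "intermediate"
  )
}

#' Did the rescue construct increase in frequency?
#'
#' A killer-rescue system "drives" when the rescue (construct B) frequency
#' rises at some point after the release: selection against the killer's
#' victims boosts the rescue while the killer is common.  Because the
#' multiplicative fitness cost is paid immediately, the rescue frequency
#' first dips before any rise, so the test is for a rising segment of the
#' trajectory: `max_t (B(t) - min_{s <= t} B(s)) > tol`.
#'
#' @param sim A `drive_sim`.
#' @param deme Deme index.
#' @param tol Minimum rise treated as real (guards integration noise).
#' @return `TRUE` if the rescue frequency increased.
#' @export
kr_drive_condition <- function(sim, deme = 1, tol = 1e-4) {
  B <- frequency_series(sim, deme, mode = "construct_B")
  B <- B[!is.na(B)]
  if (!length(B)) {
    return(FALSE)
  }
  max(B - cummin(B)) > tol
}

# rising-segment test for a plain frequency series (shared with the
# discrete-generation model)
frequency_rises <- function(B, tol = 1e-4) {
  B <- B[!is.na(B)]
  length(B) > 0 && max(B - cummin(B)) > tol
}

#' Performance metrics of a simulated release
#'
#' Extremal and final statistics per deme over `t >= 0`: population extrema,
#' wild-type female extrema, peak percentage suppression relative to the
#' pre-release equilibrium `N*` and the time taken to reach it, equilibrium
#' (final-state) suppression, transgene frequency extrema and the outcome
#' class.
#'
#' @param sim A `drive_sim`.
#' @param low_cutoff,high_cutoff Passed to [classify_ud_outcome()].
#' @return A tibble with one row per deme.
#' @examples
#' sim <- simulate_release(drive_config("KR", timing = "late", eps_A = 0.95),
#'                         t_end = 300, max_step = 0.25)
#' drive_metrics(sim)
#' @export
drive_metrics <- function(sim, low_cutoff = 0.01, high_cutoff = 0.95) {
  stopifnot(inherits(sim, "drive_sim"))
  Ns <- sim$N_star
  purrr::map_dfr(seq_len(sim$ndeme), function(d) {
    tot <- total_population(sim, d)
    wtF <- sim$state[, (d - 1L) * 18L + 10L]
    ov <- frequency_series(sim, d, "overall")
    B <- frequency_series(sim, d, "construct_B")
    imin <- which.min(tot)
    final_freq <- ov[length(ov)]
    tibble(
      deme = d,
      N_star = Ns,
      max_total = max(tot),
      min_total = tot[imin],
      max_wt_female = max(wtF),
      min_wt_female = min(wtF),
      max_suppression_pct = max(0, (1 - tot[imin] / Ns) * 100),
      time_to_max_suppression = sim$time[imin],
      equilibrium_suppression_pct = max(0, (1 - tot[length(tot)] / Ns) * 100),
      max_transgene_freq = max(ov, na.rm = TRUE),
      max_rescue_freq = max(B, na.rm = TRUE),
      final_transgene_freq = final_freq,
      rescue_increased = frequency_rises(B),
      outcome = classify_ud_outcome(final_freq, low_cutoff, high_cutoff)
    )
  })
}

#' @export
glance.drive_sim <- function(x, ...) drive_metrics(x, ...)

# did the UD release achieve lasting introgression?  The final overall
# frequency settles near one of two attractors (0, or the high internal
# equilibrium >= ~0.89); 0.5 separates them.
ud_introgression <- function(sim, deme = 1, cutoff = 0.5) {
  f <- frequency_series(sim, deme, "overall")
  f <- f[!is.na(f)]
  length(f) > 0 && f[length(f)] > cutoff
}

#' Minimal construct fitness for a drive criterion, by bisection
#'
#' Finds the threshold equal construct fitness `eps_A = eps_B` above which a
#' release succeeds: lasting transgene introgression for underdominance
#' (final overall frequency beyond the bistability separatrix), or a rising
#' rescue frequency for killer-rescue.  The criterion is checked at the
#' range ends (it must fail at the low end and hold at the high end) and the
#' boundary is then bisected to `tol`.
#'
#' @param drive A [drive_config()]; its `eps_A`/`eps_B` are overridden by
#'   the bisection variable.
#' @param theta Release ratio.
#' @param criterion `"ud_introgression"` or `"kr_increase"`.
#' @param eps_range Search interval for `eps_A = eps_B`.
#' @param tol Bisection tolerance on eps.
#' @param ecology,release_sexes,t_end,max_step Simulation settings;
#'   `t_end = 5000` d gives converged threshold decisions.
#' @return The threshold fitness `eps_star`.  If the criterion already holds
#'   at the range minimum, that minimum is returned with attribute
#'   `at_range_min = TRUE`.
#' @export
find_fitness_threshold <- function(drive, theta = 1,
                                   criterion = c("ud_introgression",
                                                 "kr_increase"),
                                   eps_range = c(0, 1), tol = 1e-3,
                                   ecology = ecology_params(),
                                   release_sexes = "bisex",
                                   t_end = 5000, max_step = 0.05) {
  criterion <- arg_match(criterion)
  ok <- function(eps) {
    cfg <- drive_config(drive$system, drive$suppression, drive$lethality,
                        drive$timing, eps_A = eps)
    sim <- simulate_release(cfg, ecology,
                            release_spec(theta = theta, sexes = release_sexes),
                            t_end = t_end, max_step = max_step, save_dt = 0.5)
    if (criterion == "ud_introgression") ud_introgression(sim) else
      kr_drive_condition(sim)
  }
  lo <- eps_range[1]
  hi <- eps_range[2]
  if (ok(lo)) {
    return(structure(lo, at_range_min = TRUE))
  }
  if (!ok(hi)) abort("no threshold in range: criterion fails at eps_range[2]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Scan release ratio and construct fitness for drive success
#'
#' Simulates one release per grid cell and records whether the drive
#' criterion holds, plus summary quantities; optionally refines the per-theta
#' threshold fitness by bisection.
#'
#' @inheritParams find_fitness_threshold
#' @param thetas,eps Grid values for the release ratio and the equal
#'   construct fitness.
#' @param refine If `TRUE`, add a per-theta bisection of the threshold.
#' @return An object of class `drive_scan`: list with `grid` (tibble:
#'   `theta`, `eps`, `criterion_met`, `final_freq`, `max_suppression_pct`,
#'   `outcome`) and `thresholds` (tibble: `theta`, `eps_star`; `NA` when
#'   `refine = FALSE`).
#' @export
threshold_scan <- function(drive, thetas = 1, eps = seq(0, 1, by = 0.01),
                           criterion = c("ud_introgression", "kr_increase"),
                           ecology = ecology_params(),
                           release_sexes = "bisex", t_end = 5000,
                           max_step = 0.05, refine = FALSE, tol = 1e-3) {
  criterion <- arg_match(criterion)
  grid <- tidyr::expand_grid(theta = thetas, eps = eps)
  rows <- purrr::pmap_dfr(grid, function(theta, eps) {
    cfg <- drive_config(drive$system, drive$suppression, drive$lethality,
                        drive$timing, eps_A = eps)
    sim <- simulate_release(cfg, ecology,
                            release_spec(theta = theta, sexes = release_sexes),
                            t_end = t_end, max_step = max_step, save_dt = 0.5)
    met <- drive_metrics(sim)
    tibble(
      theta = theta, eps = eps,
      criterion_met = if (criterion == "ud_introgression")
        ud_introgression(sim) else kr_drive_condition(sim),
      final_freq = met$final_transgene_freq,
      max_suppression_pct = met$max_suppression_pct,
      time_to_max_suppression = met$time_to_max_suppression,
      equilibrium_suppression_pct = met$equilibrium_suppression_pct,
      outcome = met$outcome
    )
  })
  thresholds <- tibble(
    theta = thetas,
    eps_star = if (refine) {
      purrr::map_dbl(thetas, function(th) {
        tryCatch(
          as.numeric(find_fitness_threshold(
            drive, theta = th, criterion = criterion,
            eps_range = range(eps), tol = tol, ecology = ecology,
            release_sexes = release_sexes, t_end = t_end,
            max_step = max_step)),
          error = function(e) NA_real_
        )
      })
    } else {
      NA_real_
    }
  )
  structure(list(grid = rows, thresholds = thresholds,
                 criterion = criterion),
            class = "drive_scan")
}

#' @export
print.drive_scan <- function(x, ...) {
  cat(sprintf("<drive_scan> %s criterion, %d cells\n", x$criterion,
              nrow(x$grid)))
  print(x$grid, n = 5)
  invisible(x)
}

#' @export
tidy.drive_scan <- function(x, ...) x$grid
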