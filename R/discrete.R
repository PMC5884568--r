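#' Discrete-generation genotype-frequency model
#'
#' Infinite-population, non-overlapping-generation comparator for the delay
#' model: random union of gametes weighted by parental genotype frequencies,
#' followed by viability selection with the per-sex total fitnesses
#' `Omega_i`, then renormalisation (selection happens before the adult
#' census).  Frequencies are tracked per sex so sex-specific lethality is
#' represented.
#'
#' @param freqs A list with numeric components `m` and `f`: male and female
#'   genotype frequencies (each length 9, summing to 1).
#' @param drive A [drive_config()].
#' @return The next generation's frequencies (same structure), with
#'   attribute `extinct = TRUE` if total fitness was zero.
#' @examples
#' wt <- discrete_release_freqs(theta = 0)
#' discrete_step(wt, drive_config("UD"))  # fixed point
#' @export
discrete_step <- function(freqs, drive) {
  m <- freqs$m
  f <- freqs$f
  stopifnot(length(m) == 9, length(f) == 9)
  if (abs(sum(m) - 1) > 1e-9 || abs(sum(f) - 1) > 1e-9 ||
      any(m < -1e-12) || any(f < -1e-12)) {
    abort("frequencies must be non-negative and sum to 1")
  }
  om <- omega_vectors(drive)
  pairw <- as.numeric(outer(m, f)) # (j - 1) * 9 + k, father j x mother k
  off <- as.numeric(pairw %*% cross_matrix())
  sm <- sum(off * om$M)
  sf <- sum(off * om$F)
  labs <- genotype_labels()
  if (sm <= 0 || sf <= 0) {
    out <- list(m = setNames(numeric(9), labs),
                f = setNames(numeric(9), labs))
    attr(out, "extinct") <- TRUE
    return(out)
  }
  list(m = setNames(off * om$M / sm, labs),
       f = setNames(off * om$F / sf, labs))
}

#' Post-release genotype frequencies for the discrete model
#'
#' A bisex release at ratio `theta` makes the released genotype a fraction
#' `theta / (1 + theta)` of both sexes; a male-only release (scaled against
#' all wild adults) makes it `2 * theta / (1 + 2 * theta)` of the males
#' only.
#'
#' @inheritParams release_spec
#' @return A list with components `m` and `f`.
#' @export
discrete_release_freqs <- function(theta = 1, sexes = c("bisex", "male_only"),
                                   genotype = "AABB") {
  sexes <- arg_match(sexes)
  gi <- genotype_index(genotype)
  wt <- setNames(numeric(9), genotype_labels())
  wt[1] <- 1
  m <- f <- wt
  if (theta > 0) {
    if (sexes == "bisex") {
      m[1] <- f[1] <- 1 / (1 + theta)
      m[gi] <- m[gi] + theta / (1 + theta)
      f[gi] <- f[gi] + theta / (1 + theta)
    } else {
      m[1] <- 1 / (1 + 2 * theta)
      m[gi] <- m[gi] + 2 * theta / (1 + 2 * theta)
    }
  }
  list(m = m, f = f)
}

#' Iterate the discrete-generation model
#'
#' @param drive A [drive_config()].
#' @param theta Release ratio (builds the initial frequencies).
#' @param sexes Release sexes.
#' @param generations Maximum generations.
#' @param conv_tol Stop when no genotype frequency (either sex) changes by
#'   more than this between generations.
#' @return A tibble with one row per generation (including generation 0):
#'   `generation`, `freq_A`, `freq_B`, `freq_overall`, `extinct`.
#' @examples
#' discrete_simulate(drive_config("UD", eps_A = 0.95), theta = 1)
#' @export
discrete_simulate <- function(drive, theta = 1, sexes = "bisex",
                              generations = 10000, conv_tol = 1e-10) {
  fr <- discrete_release_freqs(theta, sexes)
  snap <- function(gen, fr, extinct = FALSE) {
    g <- (fr$m + fr$f) / 2
    fA <- sum(eta_A_vec() * g) / 2
    fB <- sum(eta_B_vec() * g) / 2
    tibble(generation = gen, freq_A = fA, freq_B = fB,
           freq_overall = (fA + fB) / 2, extinct = extinct)
  }
  out <- vector("list", generations + 1)
  out[[1]] <- snap(0L, fr)
  n <- 1L
  for (g in seq_len(generations)) {
    prev <- fr
    fr <- discrete_step(fr, drive)
    if (isTRUE(attr(fr, "extinct"))) {
      out[[g + 1]] <- snap(g, fr, extinct = TRUE)
      n <- g + 1L
      break
    }
    out[[g + 1]] <- snap(g, fr)
    n <- g + 1L
    if (max(abs(fr$m - prev$m), abs(fr$f - prev$f)) < conv_tol) break
  }
  bind_rows(out[seq_len(n)])
}

#' Threshold fitness in the discrete-generation model
#'
#' Bisection on `eps_A = eps_B` for the same criteria as
#' [find_fitness_threshold()], with the discrete recursion iterated to its
#' fixed point as the underlying dynamic.  Serves as an independent check on
#' the delay-model thresholds.
#'
#' @inheritParams find_fitness_threshold
#' @param generations,conv_tol Iteration controls for [discrete_simulate()].
#' @export
discrete_fitness_threshold <- function(drive, theta = 1,
                                       criterion = c("ud_introgression",
                                                     "kr_increase"),
                                       eps_range = c(0, 1), tol = 1e-3,
                                       release_sexes = "bisex",
                                       generations = 10000,
                                       conv_tol = 1e-10) {
  criterion <- arg_match(criterion)
  ok <- function(eps) {
    cfg <- drive_config(drive$system, drive$suppression, drive$lethality,
                        drive$timing, eps_A = eps)
    tr <- discrete_simulate(cfg, theta, release_sexes, generations, conv_tol)
    if (criterion == "ud_introgression") {
      tr$freq_overall[nrow(tr)] > 0.5
    } else {
      frequency_rises(tr$freq_B)
    }
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

#' Threshold scan with the discrete-generation model
#'
#' @inheritParams threshold_scan
#' @param generations,conv_tol Iteration controls.
#' @return A `drive_scan` object (see [threshold_scan()]).
#' @export
discrete_threshold_scan <- function(drive, thetas = 1,
                                    eps = seq(0, 1, by = 0.01),
                                    criterion = c("ud_introgression",
                                                  "kr_increase"),
                                    release_sexes = "bisex",
                                    generations = 10000, conv_tol = 1e-10,
                                    refine = FALSE, tol = 1e-3) {
  criterion <- arg_match(criterion)
  grid <- tidyr::expand_grid(theta = thetas, eps = eps)
  rows <- purrr::pmap_dfr(grid, function(theta, eps) {
    cfg <- drive_config(drive$system, drive$suppression, drive$lethality,
                        drive$timing, eps_A = eps)
    tr <- discrete_simulate(cfg, theta, release_sexes, generations, conv_tol)
    fin <- tr$freq_overall[nrow(tr)]
    tibble(
      theta = theta, eps = eps,
      criterion_met = if (criterion == "ud_introgression") fin > 0.5 else
        frequency_rises(tr$freq_B),
      final_freq = fin,
      generations_run = nrow(tr) - 1L,
      converged = nrow(tr) - 1L < generations
    )
  })
  thresholds <- tibble(
    theta = thetas,
    eps_star = if (refine) {
      purrr::map_dbl(thetas, function(th) {
        tryCatch(
          as.numeric(discrete_fitness_threshold(
            drive, theta = th, criterion = criterion,
            eps_range = range(eps), tol = tol,
            release_sexes = release_sexes, generations = generations,
            conv_tol = conv_tol)),
          error = function(e) NA_real_
        )
      })
    } else {
      NA_real_
    }
  )
  structure(list(grid = rows, thresholds = thresholds, criterion = criterion),
            class = "drive_scan")
}
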