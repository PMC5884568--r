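#' Specify a transgenic release
#'
#' A single instantaneous release of adults of one genotype (default the
#' double homozygote `AABB`) at time 0 into the target deme, at a ratio
#' `theta` of introduced to wild adults at equilibrium.  Bisex releases are
#' split 1:1 male:female (`theta * N* / 2` of each); male-only releases
#' introduce males only, with `theta` scaled against all wild adults by
#' default (`theta * N*` males) or against wild males
#' (`male_only_basis = "males"`, `theta * N* / 2` males).
#'
#' @param theta Release ratio, introduced/wild (>= 0).
#' @param sexes `"bisex"` or `"male_only"`.
#' @param genotype Released genotype label or index (default `"AABB"`).
#' @param male_only_basis For male-only releases, whether `theta` counts
#'   against `"total"` wild adults or wild `"males"`.
#' @return An object of class `release_spec`.
#' @examples
#' release_spec(theta = 1)
#' release_spec(theta = 2, sexes = "male_only")
#' @export
release_spec <- function(theta = 1, sexes = c("bisex", "male_only"),
                         genotype = "AABB",
                         male_only_basis = c("total", "males")) {
  sexes <- arg_match(sexes)
  male_only_basis <- arg_match(male_only_basis)
  stopifnot(is.numeric(theta), length(theta) == 1, is.finite(theta))
  if (theta < 0) abort("`theta` must be non-negative")
  structure(
    list(theta = theta, sexes = sexes,
         genotype = genotype_labels()[genotype_index(genotype)],
         male_only_basis = male_only_basis),
    class = "release_spec"
  )
}

#' @export
print.release_spec <- function(x, ...) {
  cat(sprintf("<release_spec> theta = %g, %s, genotype %s\n",
              x$theta, x$sexes, x$genotype))
  invisible(x)
}

#' Initial conditions for a release simulation
#'
#' Every deme starts at the wild-type equilibrium (`M_1 = F_1 = N*/2`).  The
#' release adds `theta * N*` adults of the release genotype to the target
#' deme (deme 1) at time 0.  The constant initial function supplied to the
#' integrator for `t <= 0` includes the released adults, so transgenic
#' progeny begin to emerge immediately at `t = 0` and the effective
#' introduction frequency matches the release ratio (a release modelled as
#' arriving strictly at `t = 0` would decay by `exp(-mu * tau)` before its
#' first progeny emerged, which contradicts the discrete-generation
#' behaviour of these systems).
#'
#' @param ecology An [ecology_params()].
#' @param release A [release_spec()].
#' @param demes 1 or 2.
#' @return A list with `state0` (state at t = 0), `history` (constant
#'   pre-release state) and `N_star`.
#' @examples
#' initial_conditions(ecology_params(), release_spec(theta = 1))
#' @export
initial_conditions <- function(ecology = ecology_params(),
                               release = release_spec(), demes = 1) {
  stopifnot(inherits(release, "release_spec"), demes %in% 1:2)
  N <- equilibrium_population(ecology)
  y <- setNames(numeric(18 * demes), state_names(demes))
  for (d in seq_len(demes)) {
    y[(d - 1) * 18 + 1] <- N / 2   # M_1
    y[(d - 1) * 18 + 10] <- N / 2  # F_1
  }
  gi <- genotype_index(release$genotype)
  if (release$theta > 0) {
    if (release$sexes == "bisex") {
      y[gi] <- y[gi] + release$theta * N / 2
      y[9 + gi] <- y[9 + gi] + release$theta * N / 2
    } else {
      scale <- if (release$male_only_basis == "total") 1 else 0.5
      y[gi] <- y[gi] + release$theta * N * scale
    }
  }
  list(state0 = y, history = y, N_star = N)
}

# choose a step that divides tau (and is <= max_step)
resolve_step <- function(tau, max_step) {
  if (max_step <= 0) abort("`max_step` must be positive")
  if (tau <= 0) {
    return(max_step)
  }
  tau / ceiling(tau / max_step - 1e-9)
}

#' Integrate the model from explicit initial data
#'
#' Low-level entry point behind [simulate_release()] and
#' [simulate_two_deme()]: integrates the delay model from an arbitrary state
#' and constant pre-release history.  The fixed step is the largest value not
#' exceeding `max_step` that divides the delay `tau` exactly, so the release
#' discontinuity and its images at `t = k * tau` fall on mesh points.
#' Integration aborts on non-finite states or counts below `-nonneg_tol`
#' (the model preserves positivity; negativity signals a numerical fault).
#'
#' @param drive A [drive_config()].
#' @param ecology An [ecology_params()].
#' @param state0 State at t = 0 (length `18 * demes`).
#' @param history Constant state for t <= 0 (same length).
#' @param t_end Horizon in days.
#' @param psi Migration rate per day (ignored for one deme).
#' @param max_step Upper bound on the integration step in days.
#' @param save_dt Approximate spacing of stored output times in days.
#' @param nonneg_tol Negativity abort threshold.
#' @return A `drive_sim` object; see [simulate_release()].
#' @export
integrate_drive <- function(drive, ecology, state0, history, t_end,
                            psi = 0, max_step = 0.05, save_dt = 0.1,
                            nonneg_tol = 1e-6) {
  stopifnot(inherits(drive, "drive_config"), inherits(ecology, "ecology_params"))
  if (t_end <= 0) abort("`t_end` must be positive")
  if (psi < 0) abort("`psi` must be non-negative")
  ndeme <- length(state0) %/% 18L
  stopifnot(ndeme %in% 1:2, length(state0) == 18 * ndeme,
            length(history) == length(state0))
  h <- resolve_step(ecology$tau, max_step)
  om <- omega_vectors(drive)
  res <- dd_integrate_cpp(
    y0 = as.numeric(state0), history = as.numeric(history), t_end = t_end,
    h = h, tau = ecology$tau, crossT = cross_matrix_t(),
    OmM = om$M, OmF = om$F, alpha = ecology$alpha, beta = ecology$beta,
    rho = ecology$rho, mu = ecology$mu, psi = psi, ndeme = ndeme,
    early = drive$timing == "early",
    save_every = max(1L, as.integer(round(save_dt / h))),
    nonneg_tol = nonneg_tol
  )
  state <- res$state
  colnames(state) <- state_names(ndeme)
  structure(
    list(time = as.numeric(res$time), state = state, ndeme = ndeme,
         drive = drive, ecology = ecology, psi = psi,
         N_star = tryCatch(equilibrium_population(ecology),
                           error = function(e) NA_real_),
         h = h, max_step = max_step, t_end = t_end),
    class = "drive_sim"
  )
}

#' Simulate a gene drive release in a single closed population
#'
#' Builds the wild-type equilibrium initial conditions, applies the release
#' at t = 0 and integrates the early- or late-acting delay model to `t_end`.
#'
#' @inheritParams integrate_drive
#' @param release A [release_spec()].
#' @param t_end Horizon in days; at least 2000 d is recommended before
#'   reading equilibrium metrics, 5000 d for threshold decisions.
#' @return A `drive_sim` object: trajectory (`$time`, `$state`), the
#'   configuration, and `N_star`.  Use [tidy()] for a long tibble,
#'   [drive_metrics()] / [glance()] for summaries and [autoplot()] to plot.
#' @examples
#' sim <- simulate_release(drive_config("KR", timing = "late", eps_A = 0.95),
#'                         t_end = 300, max_step = 0.25)
#' drive_metrics(sim)
#' @export
simulate_release <- function(drive, ecology = ecology_params(),
                             release = release_spec(), t_end = 2000,
                             max_step = 0.05, save_dt = 0.1) {
  ic <- initial_conditions(ecology, release, demes = 1)
  sim <- integrate_drive(drive, ecology, ic$state0, ic$history, t_end,
                         psi = 0, max_step = max_step, save_dt = save_dt)
  sim$release <- release
  sim
}

#' Simulate a release with migration to a non-target deme
#'
#' Two demes with identical ecology, coupled by continuous two-way exchange
#' at rate `psi` per day; the release enters the target deme (deme 1) only.
#' `psi = 0` recovers two independent single-deme systems.
#'
#' @inheritParams simulate_release
#' @param psi Migration rate per day (>= 0).
#' @param release_both If `TRUE`, apply the same release to both demes (a
#'   symmetry-check utility mode).
#' @return A `drive_sim` object with `ndeme = 2`.
#' @examples
#' sim <- simulate_two_deme(drive_config("KR", timing = "late", eps_A = 0.95),
#'                          psi = 0.01, t_end = 200, max_step = 0.25)
#' drive_metrics(sim)
#' @export
simulate_two_deme <- function(drive, ecology = ecology_params(),
                              release = release_spec(), psi = 0.01,
                              t_end = 2000, max_step = 0.05, save_dt = 0.1,
                              release_both = FALSE) {
  ic <- initial_conditions(ecology, release, demes = 2)
  if (release_both) {
    ic$state0[19:36] <- ic$state0[1:18]
    ic$history[19:36] <- ic$history[1:18]
  }
  sim <- integrate_drive(drive, ecology, ic$state0, ic$history, t_end,
                         psi = psi, max_step = max_step, save_dt = save_dt)
  sim$release <- release
  sim
}

#' @export
print.drive_sim <- function(x, ...) {
  cat(sprintf(
    "<drive_sim> %s %s-acting, %d deme(s), t in [0, %g] d (%d saved states, step %g d)\n",
    x$drive$system, x$drive$timing, x$ndeme, max(x$time), length(x$time), x$h
  ))
  if (!is.na(x$N_star)) cat(sprintf("  pre-release equilibrium N* = %.2f\n", x$N_star))
  invisible(x)
}
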