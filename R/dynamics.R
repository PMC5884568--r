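# state vector layout helpers: per deme [M_1..M_9, F_1..F_9]
state_names <- function(ndeme = 1) {
  nm <- c(paste0("M", 1:9), paste0("F", 1:9))
  if (ndeme == 1) {
    return(nm)
  }
  as.character(vapply(seq_len(ndeme), function(d) paste0("d", d, "_", nm),
                      character(18)))
}

deme_block <- function(state, deme) {
  state[(deme - 1L) * 18L + 1:18]
}

#' Right-hand side of the delay-differential model
#'
#' Reference (pure R) evaluation of the model derivatives.  Recruitment at
#' time `t` comes from eggs laid at `t - tau` (the `lagged` state), survives
#' density-dependent larval competition
#' `1 / (1 + (alpha * L)^beta)` where `L` is the competing larval load, and
#' enters the adult pool at rate `rho`; adults die at rate `mu`.  With
#' early-acting fitness/lethal effects the load `L` counts only surviving
#' larvae (`Omega` inside the sum); late-acting effects apply after
#' competition so `L` counts all larvae.  In the two-deme model the demes are
#' coupled by un-delayed exchange at rate `psi` per day.
#'
#' The compiled integrator behind [simulate_release()] evaluates the same
#' expressions; this function is the readable single-evaluation form.
#'
#' @param now,lagged Numeric state vectors of length `18 * ndeme`
#'   (`[M_1..M_9, F_1..F_9]` per deme): the current state and the state at
#'   `t - tau`.
#' @param drive A [drive_config()].
#' @param ecology An [ecology_params()].
#' @param psi Migration rate per day (two-deme states only).
#' @return The derivative vector, same length and layout as `now`.
#' @examples
#' eco <- ecology_params()
#' N <- equilibrium_population(eco)
#' wt <- unlist(make_state(aabb = N))
#' # the wild-type equilibrium is a fixed point
#' drive_rhs(wt, wt, drive_config("UD"), eco)
#' @export
drive_rhs <- function(now, lagged, drive, ecology = ecology_params(),
                      psi = 0) {
  stopifnot(inherits(drive, "drive_config"), inherits(ecology, "ecology_params"))
  if (length(now) %% 18L != 0L || length(now) != length(lagged)) {
    abort("states must have length 18 per deme and agree")
  }
  ndeme <- length(now) %/% 18L
  if (!ndeme %in% 1:2) abort("only 1 or 2 demes are supported")
  if (psi < 0) abort("`psi` must be non-negative")
  om <- omega_vectors(drive)
  dy <- numeric(length(now))
  for (d in seq_len(ndeme)) {
    ix <- (d - 1L) * 18L
    M <- now[ix + 1:9]
    F <- now[ix + 10:18]
    lag <- lagged[ix + 1:18]
    p <- offspring_pools(pmax(lag[1:9], 0), pmax(lag[10:18], 0))$v
    load <- if (drive$timing == "early") {
      sum(p * (om$M + om$F))
    } else {
      2 * sum(p)
    }
    den <- 1 + (ecology$alpha * load)^ecology$beta
    dy[ix + 1:9] <- ecology$rho * p * om$M / den - ecology$mu * M
    dy[ix + 10:18] <- ecology$rho * p * om$F / den - ecology$mu * F
  }
  if (ndeme == 2L && psi != 0) {
    ex <- psi * (now[19:36] - now[1:18])
    dy[1:18] <- dy[1:18] + ex
    dy[19:36] <- dy[19:36] - ex
  }
  names(dy) <- state_names(ndeme)
  dy
}
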