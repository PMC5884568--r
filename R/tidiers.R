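#' Tidy a simulated trajectory
#'
#' @param x A `drive_sim`.
#' @param ... Unused.
#' @return A long tibble with columns `t` (days), `deme`, `sex` (`"M"`/
#'   `"F"`), `genotype`, `count`.
#' @examples
#' sim <- simulate_release(drive_config("UD", eps_A = 0.95),
#'                         t_end = 100, max_step = 0.25)
#' tidy(sim)
#' @export
tidy.drive_sim <- function(x, ...) {
  labs <- genotype_labels()
  purrr::map_dfr(seq_len(x$ndeme), function(d) {
    ix <- (d - 1L) * 18L
    purrr::map_dfr(c(M = 0L, F = 9L), function(off) {
      cnt <- x$state[, ix + off + 1:9, drop = FALSE]
      tibble(
        t = rep(x$time, times = 9),
        genotype = rep(labs, each = length(x$time)),
        count = as.numeric(cnt)
      )
    }, .id = "sex") %>%
      mutate(deme = d)
  }) %>%
    select("t", "deme", "sex", "genotype", "count") %>%
    arrange(.data$t, .data$deme, .data$sex)
}

#' Population summary series of a simulation
#'
#' Per-deme time series of the quantities the performance metrics are read
#' from: total adults, wild-type females, and overall / rescue transgene
#' frequencies.
#'
#' @param sim A `drive_sim`.
#' @return A tibble with columns `t`, `deme`, `total`, `wt_female`,
#'   `freq_overall`, `freq_rescue`.
#' @export
population_series <- function(sim) {
  purrr::map_dfr(seq_len(sim$ndeme), function(d) {
    tibble(
      t = sim$time,
      deme = d,
      total = total_population(sim, d),
      wt_female = sim$state[, (d - 1L) * 18L + 10L],
      freq_overall = frequency_series(sim, d, "overall"),
      freq_rescue = frequency_series(sim, d, "construct_B")
    )
  })
}
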