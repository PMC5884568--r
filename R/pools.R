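#' Offspring pools from random mating
#'
#' Genotype-resolved egg production of the current adult population under
#' panmixia.  Reproduction is female-limited: each female contributes one
#' male-egg unit and one female-egg unit per unit time (1:1 primary sex
#' ratio), partitioned over offspring genotypes by Mendelian inheritance,
#' with fathers drawn in proportion to male genotype frequencies:
#' `v_i = w_i = sum_k F_k * sum_j (M_j / sum(M)) * P(i | father j, mother k)`.
#'
#' The per-capita growth rate `rho` scales these pools in the dynamics
#' equations, not here.  With no males present all pools are zero.
#'
#' @param M,F Numeric vectors of length 9: adult male and female counts per
#'   genotype in canonical order.
#' @return A list with components `v` and `w` (male and female egg pools per
#'   genotype); `sum(v) == sum(w) == sum(F)` whenever males are present.
#' @examples
#' N <- equilibrium_population(ecology_params())
#' wt <- make_state(aabb = N)
#' offspring_pools(wt$M, wt$F)$v
#' @export
offspring_pools <- function(M, F) {
  stopifnot(length(M) == 9, length(F) == 9)
  if (any(M < 0) || any(F < 0)) abort("adult counts must be non-negative")
  Mtot <- sum(M)
  if (Mtot <= 0) {
    z <- numeric(9)
    return(list(v = z, w = z))
  }
  pairw <- as.numeric(outer(M / Mtot, F)) # index (j - 1) * 9 + k
  p <- as.numeric(pairw %*% cross_matrix())
  list(v = p, w = p)
}
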