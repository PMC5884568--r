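# Per-genotype lethal effects (gamma) for each drive class x suppression
# strength, in canonical genotype order aabb..AABB.  Strong suppression (SS):
# one suppressor copy rescues two lethal copies; weak suppression (WS): two
# copies are required.  For killer-rescue, construct A is the killer and B the
# rescue.
gamma_tables <- function() {
  list(
    UD_strong = c(0, 1, 1, 1, 0, 0, 1, 0, 0),
    UD_weak   = c(0, 1, 1, 1, 0, 1, 1, 1, 0),
    KR_strong = c(0, 0, 0, 1, 0, 0, 1, 0, 0),
    KR_weak   = c(0, 0, 0, 1, 0, 0, 1, 1, 0),
    none_strong = numeric(9),
    none_weak = numeric(9)
  )
}

#' Specify a gene drive configuration
#'
#' Bundles the genetic system (two-locus engineered underdominance `"UD"` or
#' killer-rescue `"KR"`), the suppression strength of lethals, the sexes the
#' lethal effects act on, the developmental timing of fitness/lethal effects
#' relative to density-dependent larval competition, and the relative fitness
#' per construct copy.
#'
#' Lethality is complete (`gamma` 0 or 1); incomplete penetrance is out of
#' scope and rejected.  Fitness costs are multiplicative across copies:
#' genotype `i` has total relative fitness
#' `Omega_i = eps_A^eta_A * eps_B^eta_B * (1 - gamma_i)`, evaluated per sex.
#' Female-specific lethality zeroes the male lethal effect only; the `eps`
#' cost components still apply to both sexes.
#'
#' @param system `"UD"`, `"KR"`, or `"none"` for constructs with no lethal
#'   elements (fitness costs only) -- a neutral control configuration used
#'   e.g. for allele-frequency conservation checks.
#' @param suppression `"strong"` (one suppressor copy rescues two lethal
#'   copies) or `"weak"` (two copies required).
#' @param lethality `"bisex"` or `"female_specific"`.
#' @param timing `"early"` (fitness/lethal effects act before larval
#'   competition) or `"late"` (after competition, before mating).
#' @param eps_A,eps_B Relative fitness per copy of constructs A and B, in
#'   \[0, 1\].  `eps_B` defaults to `eps_A`.
#' @return An object of class `drive_config`.
#' @examples
#' drive_config("UD", eps_A = 0.95)
#' drive_config("KR", suppression = "weak", timing = "late", eps_A = 0.9)
#' @export
drive_config <- function(system = c("UD", "KR", "none"),
                         suppression = c("strong", "weak"),
                         lethality = c("bisex", "female_specific"),
                         timing = c("early", "late"),
                         eps_A = 1, eps_B = eps_A) {
  system <- arg_match(system)
  suppression <- arg_match(suppression)
  lethality <- arg_match(lethality)
  timing <- arg_match(timing)
  stopifnot(is.numeric(eps_A), length(eps_A) == 1, is.numeric(eps_B),
            length(eps_B) == 1)
  if (eps_A < 0 || eps_A > 1 || eps_B < 0 || eps_B > 1) {
    abort("`eps_A` and `eps_B` must lie in [0, 1]")
  }
  structure(
    list(system = system, suppression = suppression, lethality = lethality,
         timing = timing, eps_A = eps_A, eps_B = eps_B),
    class = "drive_config"
  )
}

#' @export
print.drive_config <- function(x, ...) {
  cat(sprintf(
    "<drive_config> %s, %s suppression, %s lethality, %s-acting, eps_A = %g, eps_B = %g\n",
    x$system, x$suppression, x$lethality, x$timing, x$eps_A, x$eps_B
  ))
  invisible(x)
}

#' Per-genotype lethal effects
#'
#' The lethal effect `gamma` received by each sex of a genotype under a drive
#' configuration: 1 means the genotype is non-viable, 0 viable.  With
#' female-specific lethality the male effect is zero for every genotype.
#'
#' @param config A [drive_config()].
#' @param i Optional genotype label or index; default all nine.
#' @return A tibble with columns `index`, `label`, `gamma_M`, `gamma_F`.
#' @examples
#' lethality(drive_config("UD", suppression = "weak"))
#' lethality(drive_config("UD", lethality = "female_specific"), "Aabb")
#' @export
lethality <- function(config, i = 1:9) {
  stopifnot(inherits(config, "drive_config"))
  idx <- genotype_index(i)
  gf <- gamma_tables()[[paste(config$system, config$suppression, sep = "_")]]
  gm <- if (config$lethality == "bisex") gf else rep(0, 9)
  tibble(
    index = idx,
    label = genotype_labels()[idx],
    gamma_M = gm[idx],
    gamma_F = gf[idx]
  )
}

#' Total relative fitness per genotype
#'
#' Multiplicative fitness `Omega_i = eps_A^eta_A * eps_B^eta_B * (1 - gamma_i)`
#' per sex: the cost of carrying construct copies times the lethal effect.
#'
#' @inheritParams lethality
#' @return A tibble with columns `index`, `label`, `eta_A`, `eta_B`,
#'   `Omega_M`, `Omega_F`.
#' @examples
#' fitness(drive_config("UD", eps_A = 0.95))
#' @export
fitness <- function(config, i = 1:9) {
  leth <- lethality(config, i)
  gt <- genotype_table()[leth$index, ]
  base <- config$eps_A^gt$eta_A * config$eps_B^gt$eta_B
  tibble(
    index = gt$index,
    label = gt$label,
    eta_A = gt$eta_A,
    eta_B = gt$eta_B,
    Omega_M = base * (1 - leth$gamma_M),
    Omega_F = base * (1 - leth$gamma_F)
  )
}

# fitness as a list of two length-9 vectors (hot paths)
omega_vectors <- function(config) {
  f <- fitness(config)
  list(M = f$Omega_M, F = f$Omega_F)
}
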