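#' Ecological parameters of the mosquito population model
#'
#' Defaults are the base parameterisation for *Aedes aegypti*: density
#' parameter `alpha` = 0.02 (carrying capacity is proportional to `1/alpha`,
#' i.e. breeding-site availability), density-dependence strength `beta` = 1.1,
#' per-capita growth rate `rho` = 1.01 per day, adult mortality `mu` = 0.12
#' per day, and egg-to-adult development delay `tau` = 18 days.
#'
#' @param alpha Density parameter (> 0); `1/alpha` scales the number of
#'   breeding sites.
#' @param beta Strength of density-dependent larval competition (> 0).
#' @param rho Per-capita population growth rate per day (>= 0).
#' @param mu Adult mortality rate per day (> 0).
#' @param tau Egg-to-adult development delay in days (>= 0).
#' @return An object of class `ecology_params`.
#' @examples
#' ecology_params()
#' ecology_params(alpha = 0.7)
#' @export
ecology_params <- function(alpha = 0.02, beta = 1.1, rho = 1.01, mu = 0.12,
                           tau = 18) {
  vals <- list(alpha = alpha, beta = beta, rho = rho, mu = mu, tau = tau)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a finite number"))
    }
  }
  if (alpha <= 0 || beta <= 0 || mu <= 0 || rho < 0 || tau < 0) {
    abort("require alpha > 0, beta > 0, mu > 0, rho >= 0, tau >= 0")
  }
  structure(vals, class = "ecology_params")
}

#' @export
print.ecology_params <- function(x, ...) {
  cat(sprintf(
    "<ecology_params> alpha = %g, beta = %g, rho = %g/d, mu = %g/d, tau = %g d\n",
    x$alpha, x$beta, x$rho, x$mu, x$tau
  ))
  invisible(x)
}

#' Closed-form equilibrium adult population size
#'
#' The pre-release steady state of the wild-type population,
#' `N* = (1/alpha) * (rho/mu - 1)^(1/beta)`.  At the default parameters this
#' is 309.08 adults; `alpha = 0.7` gives 8.83.
#'
#' @param ecology An [ecology_params()].
#' @return The equilibrium total adult count `N*` (0 when `rho == mu`).
#' @examples
#' equilibrium_population(ecology_params())
#' equilibrium_population(ecology_params(alpha = 0.7))
#' @export
equilibrium_population <- function(ecology = ecology_params()) {
  stopifnot(inherits(ecology, "ecology_params"))
  if (ecology$rho < ecology$mu) {
    abort("no positive equilibrium: rho < mu")
  }
  (1 / ecology$alpha) * (ecology$rho / ecology$mu - 1)^(1 / ecology$beta)
}
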