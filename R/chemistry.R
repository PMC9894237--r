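#' Carbonate-system constants
#'
#' Physicochemical constants for the CO2/HCO3- system: the uncatalyzed
#' hydration rate constant, the effective first acid dissociation constant,
#' and the Henry's-law solubility of CO2. Defaults are standard freshwater
#' values at 25 degrees C. Carbonate ion and carbamate chemistry are ignored
#' (negligible below pH 8), and no temperature dependence is modelled: the
#' cell model is built for order-of-magnitude comparisons.
#'
#' @param k_h Uncatalyzed CO2 hydration rate constant (s^-1).
#' @param pK1_eff Effective first pKa of the CO2/HCO3- couple (pH units).
#' @param K_H Henry's-law solubility of CO2 (mol L^-1 atm^-1).
#' @param temperature Nominal temperature (degrees C); recorded, not used.
#'
#' @return An object of class `carbonate_params`.
#' @examples
#' carbonate_params()
#' @export
carbonate_params <- function(k_h = 0.037, pK1_eff = 6.35, K_H = 0.034,
                             temperature = 25) {
  if (!is.numeric(k_h) || length(k_h) != 1L || !is.finite(k_h) || k_h <= 0) {
    abort("`k_h` must be a single positive number (s^-1).")
  }
  if (!is.numeric(pK1_eff) || length(pK1_eff) != 1L ||
      pK1_eff <= 5 || pK1_eff >= 8) {
    abort("`pK1_eff` must lie in (5, 8).")
  }
  if (!is.numeric(K_H) || length(K_H) != 1L || !is.finite(K_H) || K_H <= 0) {
    abort("`K_H` must be a single positive number (M/atm).")
  }
  structure(
    list(k_h = k_h, pK1_eff = pK1_eff, K_H = K_H, temperature = temperature),
    class = "carbonate_params"
  )
}

#' @export
print.carbonate_params <- function(x, ...) {
  cat("Carbonate system constants\n")
  cat(sprintf("  k_h      %.4g s^-1 (uncatalyzed hydration)\n", x$k_h))
  cat(sprintf("  pK1_eff  %.3g\n", x$pK1_eff))
  cat(sprintf("  K_H      %.4g M/atm\n", x$K_H))
  cat(sprintf("  T        %g C (nominal)\n", x$temperature))
  invisible(x)
}

#' Growth environment
#'
#' A single (pCO2, pH) condition. `pCO2` is the CO2 partial pressure as a
#' fraction of `total_pressure`; the five assay conditions used throughout
#' the package are 0.04% (ambient), 0.5%, 1.5%, 5% and 10% CO2
#' (see [assay_pco2_levels()]).
#'
#' @param pCO2 CO2 partial pressure as a fraction of 1 bar (0 to 1).
#' @param pH_out Extracellular pH.
#' @param pH_in Cytosolic pH.
#' @param total_pressure Total pressure (atm).
#'
#' @return An object of class `ci_environment`.
#' @examples
#' ci_environment(pCO2 = 0.0004)
#' @export
ci_environment <- function(pCO2, pH_out = 7, pH_in = 7, total_pressure = 1) {
  if (!is.numeric(pCO2) || length(pCO2) != 1L || is.na(pCO2) ||
      pCO2 < 0 || pCO2 > 1) {
    abort("`pCO2` must be a single number in [0, 1] (fraction of 1 bar).")
  }
  for (nm in c("pH_out", "pH_in")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 4 || v > 10) {
      abort(sprintf("`%s` must lie in [4, 10].", nm))
    }
  }
  if (total_pressure <= 0) abort("`total_pressure` must be positive (atm).")
  structure(
    list(pCO2 = pCO2, pH_out = pH_out, pH_in = pH_in,
         total_pressure = total_pressure),
    class = "ci_environment"
  )
}

#' @export
print.ci_environment <- function(x, ...) {
  cat(sprintf("Environment: %.4g%% CO2 of %g atm, pH_out %.2f, pH_in %.2f\n",
              100 * x$pCO2, x$total_pressure, x$pH_out, x$pH_in))
  invisible(x)
}

#' The five experimental CO2 levels
#'
#' @return Named numeric vector of pCO2 fractions: ambient (0.04%), low
#'   (0.5%), moderate (1.5%), high (5%) and very high (10%).
#' @export
assay_pco2_levels <- function() {
  c(ambient = 0.0004, low = 0.005, moderate = 0.015,
    high = 0.05, very_high = 0.10)
}

#' Dissolved CO2 at equilibrium with a gas phase
#'
#' Henry's law: `K_H * pCO2 * total_pressure`, returned in uM. Water
#' equilibrated with the present-day atmosphere (~0.04% CO2) holds roughly
#' 10-20 uM dissolved CO2.
#'
#' @param env A [ci_environment()].
#' @param chem A [carbonate_params()].
#' @return Dissolved CO2 concentration (uM).
#' @examples
#' dissolved_co2(ci_environment(0.0004)) # ~13.6 uM
#' @export
dissolved_co2 <- function(env, chem = carbonate_params()) {
  stopifnot(inherits(env, "ci_environment"), inherits(chem, "carbonate_params"))
  chem$K_H * env$pCO2 * env$total_pressure * 1e6
}

#' Equilibrium HCO3-/CO2 ratio at a given pH
#'
#' Henderson-Hasselbalch speciation: `K_eq = [HCO3-]/[CO2] = 10^(pH - pK1_eff)`.
#' Monotone increasing in pH; one pH unit is a tenfold change.
#'
#' @param pH pH at which to evaluate the ratio.
#' @inheritParams dissolved_co2
#' @return Dimensionless concentration ratio.
#' @examples
#' equilibrium_ratio(7.0) # ~4.5
#' @export
equilibrium_ratio <- function(pH, chem = carbonate_params()) {
  stopifnot(inherits(chem, "carbonate_params"))
  if (any(pH < 4 | pH > 10)) abort("`pH` must lie in [4, 10].")
  10^(pH - chem$pK1_eff)
}

#' Relaxation time of the uncatalyzed CO2/HCO3- system
#'
#' E-folding time of the closed two-pool linear system
#' CO2 <-> HCO3- at fixed pH: `1 / (k_h + k_d)` with
#' `k_d = k_h / K_eq(pH)`. At neutral pH with default constants this is
#' a few tens of seconds -- slow enough that HCO3- and CO2 pools can be
#' far from equilibrium on physiological timescales.
#'
#' @inheritParams equilibrium_ratio
#' @return Relaxation time (s).
#' @examples
#' relaxation_time(7.0) # ~22 s
#' @export
relaxation_time <- function(pH, chem = carbonate_params()) {
  stopifnot(inherits(chem, "carbonate_params"))
  if (chem$k_h <= 0) abort("`k_h` must be positive.")
  K_eq <- equilibrium_ratio(pH, chem)
  1 / (chem$k_h + chem$k_h / K_eq)
}

#' Boundary concentrations implied by an environment
#'
#' Extracellular CO2 from Henry's law, extracellular HCO3- from the
#' equilibrium speciation at `pH_out` (bulk medium assumed equilibrated).
#'
#' @inheritParams dissolved_co2
#' @return A one-row tibble with `C_out` and `H_out` (uM).
#' @export
boundary_concentrations <- function(env, chem = carbonate_params()) {
  C_out <- dissolved_co2(env, chem)
  H_out <- C_out * equilibrium_ratio(env$pH_out, chem)
  tibble::tibble(C_out = C_out, H_out = H_out)
}
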