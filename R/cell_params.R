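#' Cell-level parameters of the colimitation model
#'
#' All rate constants are first-order (s^-1) and act on the intracellular
#' CO2 pool `C_in`, the intracellular HCO3- pool `H_in`, or (for uptake) an
#' extracellular substrate pool. Membrane exchange is parameterized either
#' by permeabilities and a surface-to-volume ratio (`alpha = P_C * sa_v`,
#' `beta = P_H * sa_v`) or by `alpha`/`beta` directly.
#'
#' Defaults describe a 1 fL bacterium with a highly CO2-permeable membrane
#' (`alpha ~ 1e4 s^-1`), a membrane that is many orders of magnitude less
#' permeable to the HCO3- anion, substantial rubisco activity, and no CCM
#' components (`delta = chi = 0`). `gamma = 90 s^-1` corresponds to roughly
#' a tenth of the physiological ceiling `[rubisco] * k_cat/K_M < 1e3 s^-1`;
#' with this choice the default cell is bicarboxylation-limited unless Ci
#' supply is boosted by CA or uptake (see the package vignette for how the
#' defaults were derived).
#'
#' @param P_C Membrane CO2 permeability (cm s^-1); measured values are
#'   ~0.1-1 cm/s.
#' @param P_H Membrane HCO3- permeability (cm s^-1); anions cross lipid
#'   bilayers orders of magnitude more slowly than CO2.
#' @param sa_v Surface-to-volume ratio (cm^-1).
#' @param alpha Effective CO2 exchange rate constant (s^-1); default
#'   `P_C * sa_v`.
#' @param beta Effective HCO3- exchange rate constant (s^-1); default
#'   `P_H * sa_v`.
#' @param gamma Rubisco consumption rate constant `[sites] * k_cat/K_M`
#'   (s^-1), acting on `C_in`.
#' @param delta CA catalytic enhancement of hydration (s^-1). Applied
#'   Haldane-consistently: hydration gains `delta`, dehydration gains
#'   `delta / K_eq(pH_in)`, so CA never shifts the equilibrium point.
#' @param chi Energized Ci uptake rate constant (s^-1), first-order in the
#'   external substrate selected by `uptake_substrate`; the imported carbon
#'   enters the intracellular HCO3- pool (vectorial hydration for
#'   DAB-type CO2 uptake, direct import for SbtA-type HCO3- uptake).
#' @param phi Bicarboxylation consumption rate constant (s^-1), acting on
#'   `H_in`.
#' @param f_H Fraction of biomass carbon fixed from HCO3- (0 < f_H < 0.5);
#'   a small minority of total carbon.
#' @param volume Cell volume (L).
#' @param uptake_substrate `"CO2"` (DAB-like, default) or `"HCO3"`
#'   (SbtA-like): which external pool the uptake system draws on.
#' @param q_C Biomass carbon demand per unit growth rate (uM per cell
#'   volume); default corresponds to ~1e10 carbon atoms in a 1 fL cell.
#' @param mu_max Growth-rate ceiling (h^-1) from resources outside the model
#'   (energy, nutrients); `Inf` (default) disables the ceiling.
#'
#' @return An object of class `cell_params`.
#' @examples
#' cell_params()
#' cell_params(delta = 100, chi = 5) # CA + Ci uptake expressed
#' @export
cell_params <- function(P_C = 0.3, P_H = 3e-8, sa_v = 1e4 / 0.3,
                        alpha = NULL, beta = NULL,
                        gamma = 90, delta = 0, chi = 0, phi = 1,
                        f_H = 0.02, volume = 1e-15,
                        uptake_substrate = c("CO2", "HCO3"),
                        q_C = 1e10 / (.N_AVOGADRO * 1e-15) * 1e6,
                        mu_max = Inf) {
  uptake_substrate <- match.arg(uptake_substrate)
  alpha <- alpha %||% (P_C * sa_v)
  beta <- beta %||% (P_H * sa_v)
  rates <- c(P_C = P_C, P_H = P_H, sa_v = sa_v, alpha = alpha, beta = beta,
             gamma = gamma, delta = delta, chi = chi, phi = phi)
  bad <- names(rates)[!is.finite(rates) | rates < 0]
  if (length(bad)) {
    abort(sprintf("Parameter(s) must be finite and >= 0: %s",
                  paste(bad, collapse = ", ")))
  }
  if (!is.numeric(f_H) || length(f_H) != 1L || f_H <= 0 || f_H >= 0.5) {
    abort("`f_H` must lie in (0, 0.5): HCO3- fixes a minority of biomass carbon.")
  }
  if (volume <= 0) abort("`volume` must be positive (L).")
  if (q_C <= 0) abort("`q_C` must be positive (uM per unit growth rate).")
  if (mu_max <= 0) abort("`mu_max` must be positive (h^-1).")
  structure(
    list(P_C = P_C, P_H = P_H, sa_v = sa_v, alpha = alpha, beta = beta,
         gamma = gamma, delta = delta, chi = chi, phi = phi,
         f_H = f_H, volume = volume, uptake_substrate = uptake_substrate,
         q_C = q_C, mu_max = mu_max),
    class = "cell_params"
  )
}

#' Modify a `cell_params` object
#'
#' Returns a copy with the named fields replaced. If `P_C`, `P_H` or `sa_v`
#' change and `alpha`/`beta` are not set explicitly in the same call, the
#' exchange rates are recomputed from the permeabilities.
#'
#' @param cell A [cell_params()] object.
#' @param ... Named fields to replace.
#' @return A new `cell_params` object.
#' @export
update_cell <- function(cell, ...) {
  stopifnot(inherits(cell, "cell_params"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cell))
  if (length(unknown)) {
    abort(sprintf("Unknown cell parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  geom_changed <- any(c("P_C", "P_H", "sa_v") %in% names(dots))
  fields <- utils::modifyList(unclass(cell), dots)
  args <- fields
  if (!geom_changed || "alpha" %in% names(dots)) args["alpha"] <- fields["alpha"]
  else args$alpha <- NULL
  if (!geom_changed || "beta" %in% names(dots)) args["beta"] <- fields["beta"]
  else args$beta <- NULL
  do.call(cell_params, args)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Cell parameters (colimitation model)\n")
  cat(sprintf("  alpha (CO2 exchange)   %.4g s^-1  [P_C %.3g cm/s x SA/V %.3g cm^-1]\n",
              x$alpha, x$P_C, x$sa_v))
  cat(sprintf("  beta  (HCO3- exchange) %.4g s^-1\n", x$beta))
  cat(sprintf("  gamma (rubisco)        %.4g s^-1\n", x$gamma))
  cat(sprintf("  delta (CA)             %.4g s^-1\n", x$delta))
  cat(sprintf("  chi   (Ci uptake, %s) %.4g s^-1\n", x$uptake_substrate, x$chi))
  cat(sprintf("  phi   (bicarboxylation)%.4g s^-1\n", x$phi))
  cat(sprintf("  f_H %.3g, volume %.3g L, q_C %.4g uM, mu_max %.3g h^-1\n",
              x$f_H, x$volume, x$q_C, x$mu_max))
  invisible(x)
}
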