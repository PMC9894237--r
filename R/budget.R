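#' Naive depletion ratio of intracellular CO2
#'
#' Closed form for the steady-state `C_in / C_out` when CO2 only enters by
#' passive exchange (rate `alpha`) and leaves by rubisco fixation (rate
#' `gamma`), with no interconversion or uptake: `alpha / (alpha + gamma)`.
#' With `alpha ~ 1e4 s^-1` and even an extreme rubisco activity
#' `gamma = 1e3 s^-1`, the ratio stays above 0.9: passive CO2 exchange is
#' too fast for rubisco to deplete the cytosol.
#'
#' @param alpha Effective CO2 exchange rate constant (s^-1), > 0.
#' @param gamma Rubisco consumption rate constant (s^-1), >= 0.
#' @return Dimensionless ratio in (0, 1].
#' @examples
#' naive_depletion_ratio(1e4, 1e3) # ~0.909
#' @export
naive_depletion_ratio <- function(alpha, gamma) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    abort("`alpha` must be positive (s^-1).")
  }
  if (any(!is.finite(gamma)) || any(gamma < 0)) {
    abort("`gamma` must be >= 0 (s^-1).")
  }
  alpha / (alpha + gamma)
}

#' Maximum rubisco active-site concentration
#'
#' Budget arithmetic: if rubisco is at most a given fraction of total
#' soluble protein and each active site carries a fixed protein mass,
#' the site concentration is `(fraction * total) / mass_per_site`
#' (mg ml^-1 divided by kDa gives mM directly, since
#' 1 mg/ml / (1 kDa) = 1 mmol/L).
#'
#' @param fraction_of_soluble_protein Rubisco share of soluble protein
#'   (dimensionless, > 0; ~0.2 at the very most in bacteria).
#' @param total_soluble_protein Total soluble protein (mg ml^-1).
#' @param mass_per_site Protein mass per active site (kDa).
#' @return A one-row tibble: `rubisco_mass_mg_per_ml`, `site_concentration_mM`.
#' @examples
#' max_rubisco_site_concentration(0.2, 300, 60) # 60 mg/ml, 1 mM
#' @export
max_rubisco_site_concentration <- function(fraction_of_soluble_protein,
                                           total_soluble_protein = 300,
                                           mass_per_site = 60) {
  vals <- c(fraction = fraction_of_soluble_protein,
            total = total_soluble_protein, mass = mass_per_site)
  if (any(!is.finite(vals)) || total_soluble_protein <= 0 ||
      mass_per_site <= 0 || fraction_of_soluble_protein < 0) {
    abort("All inputs must be positive (fraction may be 0).")
  }
  mass <- fraction_of_soluble_protein * total_soluble_protein
  tibble::tibble(
    rubisco_mass_mg_per_ml = mass,
    site_concentration_mM = mass / mass_per_site
  )
}

#' Per-cell CO2 fixation rate of the naive model
#'
#' Evaluates `gamma * C_in * volume * N_A * 3600` at the naive
#' (`delta = chi = 0`) steady state: how many CO2 molecules rubisco fixes
#' per hour in one cell, and the doubling time implied by a per-cell carbon
#' demand. At `alpha ~ 1e4 s^-1`, `gamma ~ 1e3 s^-1` and ambient-like
#' dissolved CO2 this is ~1e10 CO2/h, supporting doubling in well under 2 h.
#'
#' @inheritParams steady_state
#' @param carbon_demand Carbon atoms needed to build one cell (molecules).
#' @return A one-row tibble: `fixation_per_hour` (molecules h^-1),
#'   `implied_doubling_time_h`.
#' @examples
#' percell_fixation_rate(cell_params(gamma = 1e3), ci_environment(0.0004))
#' @export
percell_fixation_rate <- function(cell, env, chem = carbonate_params(),
                                  carbon_demand = 1e10) {
  stopifnot(inherits(cell, "cell_params"))
  if (cell$volume <= 0) abort("`volume` must be positive (L).")
  if (carbon_demand <= 0) abort("`carbon_demand` must be positive.")
  naive <- update_cell(cell, delta = 0, chi = 0)
  ss <- steady_state(naive, env, chem)
  # uM s^-1 -> mol L^-1 s^-1 -> molecules per cell per hour
  rate <- naive$gamma * ss$C_in * 1e-6 * naive$volume * .N_AVOGADRO * 3600
  tibble::tibble(
    fixation_per_hour = rate,
    implied_doubling_time_h = ifelse(rate > 0, carbon_demand / rate, Inf)
  )
}
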