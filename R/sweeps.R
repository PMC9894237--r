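#' Log-spaced sweep axis
#'
#' @param from,to Positive endpoints (inclusive).
#' @param n Number of points (>= 2).
#' @return Numeric vector of `n` log-spaced values.
#' @examples
#' log_axis(1e-2, 1e4, 25)
#' @export
log_axis <- function(from, to, n = 25) {
  if (!is.numeric(n) || n < 2) abort("`n` must be >= 2.")
  if (from <= 0 || to <= 0) abort("Log axis endpoints must be positive.")
  10^seq(log10(from), log10(to), length.out = n)
}

new_colim_sweep <- function(x, type, ...) {
  class(x) <- c("colim_sweep", class(x))
  attr(x, "sweep_type") <- type
  extra <- list(...)
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  x
}

#' Growth versus CA activity across a rubisco ladder
#'
#' Sweeps the CA rate constant `delta` for each rubisco activity `gamma` in
#' a ladder and records the growth prediction. At low `gamma` growth is
#' rubisco-limited and insensitive to `delta` (spontaneous hydration already
#' supplies the small HCO3- demand); at high `gamma` growth is
#' bicarboxylation-limited and rises with `delta` toward a plateau where
#' `H_in/C_in` reaches the equilibrium ratio.
#'
#' @param gamma_ladder Rubisco activities (s^-1), low to high.
#' @param delta_axis CA activities to sweep (s^-1), e.g. [log_axis()].
#' @param cell Baseline [cell_params()]; `gamma`/`delta` are overridden.
#' @param env A [ci_environment()].
#' @param chem A [carbonate_params()].
#' @param q_C Biomass demand override (uM); defaults to `cell$q_C`.
#' @return A `colim_sweep` tibble: one row per (gamma, delta) with pools,
#'   fluxes and growth.
#' @examples
#' sw <- growth_vs_ca(c(1, 1000), log_axis(1e-2, 1e4, 5))
#' @export
growth_vs_ca <- function(gamma_ladder = c(1, 10, 100, 1000),
                         delta_axis = log_axis(1e-2, 1e4, 25),
                         cell = cell_params(), env = ci_environment(0.0004),
                         chem = carbonate_params(), q_C = cell$q_C) {
  if (length(gamma_ladder) < 1L || any(gamma_ladder < 0)) {
    abort("`gamma_ladder` must contain nonnegative rubisco activities.")
  }
  if (length(delta_axis) < 2L) abort("`delta_axis` is degenerate (< 2 points).")
  grid <- tidyr::expand_grid(gamma = gamma_ladder, delta = delta_axis)
  res <- purrr::pmap(grid, function(gamma, delta) {
    model_growth(update_cell(cell, gamma = gamma, delta = delta), env, chem,
                 q_C = q_C)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  new_colim_sweep(out, "growth_vs_ca")
}

#' Futile-cycle leakage over the (CA, Ci uptake) plane
#'
#' At fixed rubisco activity, sweeps CA (`delta`) and Ci uptake (`chi`) over
#' wide log ranges and reports the ratio of total Ci leakage
#' `J_L_tot = J_L_C + J_L_H` to biomass production `J_B` at every grid
#' point. Also locates, for each `delta`, the uptake activity at which
#' `J_L_tot = 0` (energized uptake exactly balanced by fixation; bisection
#' to 1e-6 relative), returned as the `"zero_contour"` attribute.
#'
#' With default permeabilities CO2 leakage dominates HCO3- leakage
#' everywhere, and at extreme coexpression the leak ratio approaches
#' `(alpha + beta * K_eq) / (gamma + phi * K_eq)`, on the order of 100.
#'
#' @param delta_axis,chi_axis Log-spaced activity axes (s^-1).
#' @param gamma Fixed rubisco activity (s^-1); default `cell$gamma`.
#' @inheritParams growth_vs_ca
#' @return A `colim_sweep` tibble with per-point fluxes and `leak_ratio`;
#'   attribute `zero_contour` is a tibble (`delta`, `chi_zero`).
#' @examples
#' hm <- leakage_heatmap(log_axis(1, 1e4, 6), log_axis(1, 1e6, 6))
#' max(hm$leak_ratio)
#' @export
leakage_heatmap <- function(delta_axis = log_axis(1e-1, 1e5, 25),
                            chi_axis = log_axis(1, 1e6, 25),
                            gamma = cell$gamma,
                            cell = cell_params(), env = ci_environment(0.0004),
                            chem = carbonate_params()) {
  if (length(delta_axis) < 2L || length(chi_axis) < 2L) {
    abort("Sweep axes must have at least 2 points.")
  }
  base <- update_cell(cell, gamma = gamma)
  grid <- tidyr::expand_grid(delta = delta_axis, chi = chi_axis)
  res <- purrr::pmap(grid, function(delta, chi) {
    fl <- ci_fluxes(steady_state(update_cell(base, delta = delta, chi = chi),
                                 env, chem))
    tibble::as_tibble(fl)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))

  leak_at <- function(delta, chi) {
    fl <- ci_fluxes(steady_state(update_cell(base, delta = delta, chi = chi),
                                 env, chem))
    fl$J_L_tot
  }
  chi_hi <- max(chi_axis)
  contour <- purrr::map_dfr(delta_axis, function(d) {
    lo <- leak_at(d, 0)
    hi <- leak_at(d, chi_hi)
    chi0 <- if (lo >= 0) 0 else if (hi <= 0) NA_real_ else {
      uniroot(function(ch) leak_at(d, ch), c(0, chi_hi),
              tol = .Machine$double.eps^0.5)$root
    }
    tibble::tibble(delta = d, chi_zero = chi0)
  })
  new_colim_sweep(out, "leakage_heatmap", zero_contour = contour,
                  gamma = gamma)
}

#' Intracellular CO2 depletion versus rubisco activity and permeability
#'
#' In the naive setting (`delta = chi = phi = 0`: CO2 balance is purely
#' membrane exchange against rubisco fixation), sweeps rubisco activity
#' and membrane CO2 permeability and records `C_in / C_out`. The
#' `"frontier"` attribute gives, per permeability, the rubisco activity at
#' which the ratio crosses 0.5; to excellent approximation this is
#' `gamma = alpha = P_C * sa_v`, i.e. only implausibly low permeability or
#' extreme rubisco activity depletes intracellular CO2 twofold.
#'
#' @param gamma_axis Rubisco activities (s^-1).
#' @param pc_axis CO2 permeabilities (cm s^-1).
#' @inheritParams growth_vs_ca
#' @return A `colim_sweep` tibble (`gamma`, `P_C`, `alpha`,
#'   `depletion_ratio`, ...); attribute `frontier` is a tibble
#'   (`P_C`, `alpha`, `gamma_half`).
#' @export
depletion_scan <- function(gamma_axis = log_axis(10, 1e5, 25),
                           pc_axis = log_axis(1e-3, 1, 25),
                           cell = cell_params(), env = ci_environment(0.0004),
                           chem = carbonate_params()) {
  if (length(gamma_axis) < 2L || length(pc_axis) < 2L) {
    abort("Sweep axes must have at least 2 points.")
  }
  base <- update_cell(cell, delta = 0, chi = 0, phi = 0)
  grid <- tidyr::expand_grid(gamma = gamma_axis, P_C = pc_axis)
  res <- purrr::pmap(grid, function(gamma, P_C) {
    cc <- update_cell(base, gamma = gamma, P_C = P_C)
    ss <- steady_state(cc, env, chem)
    tibble::tibble(alpha = cc$alpha, C_in = ss$C_in, C_out = ss$C_out,
                   depletion_ratio = ss$C_in / ss$C_out)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))

  ratio_at <- function(P_C, gamma) {
    cc <- update_cell(base, gamma = gamma, P_C = P_C)
    ss <- steady_state(cc, env, chem)
    ss$C_in / ss$C_out
  }
  frontier <- purrr::map_dfr(pc_axis, function(p) {
    a <- p * base$sa_v
    f <- function(lg) ratio_at(p, 10^lg) - 0.5
    root <- uniroot(f, log10(a) + c(-6, 6), tol = 1e-10)$root
    tibble::tibble(P_C = p, alpha = a, gamma_half = 10^root)
  })
  new_colim_sweep(out, "depletion_scan", frontier = frontier)
}

#' CO2-pump scenario: reduced membrane permeability
#'
#' Could coexpressed Ci uptake and CA act as a CO2 pump that elevates
#' `C_in` substantially above `C_out`? Starting from the measured
#' permeability (`P_C` in 0.1-1 cm/s), this sweep reduces `P_C` by a
#' log-spaced factor and records `C_in / C_out` under high CA activity and
#' an uptake capacity sized just above the demand of a twofold-elevated
#' internal pool (`chi = 2 * 1.1 * (gamma + phi * K_eq)` by default; see the
#' vignette). The `"threshold_factor"` attribute is the smallest reduction
#' factor at which `C_in / C_out >= 2` ("substantially above" is
#' operationalized as twofold), refined by root-finding between grid points.
#'
#' @param reduction_axis Fold-reductions of `P_C` to scan (>= 1).
#' @param chi Uptake activity (s^-1); default sized as above.
#' @param delta CA activity (s^-1); default the high end of the leakage
#'   sweep.
#' @inheritParams growth_vs_ca
#' @return A `colim_sweep` tibble (`reduction`, `P_C_eff`, `alpha`,
#'   `C_in`, `C_out`, `pump_ratio`); attributes `threshold_factor` (refined
#'   root), `threshold_grid` (smallest grid factor), `chi`, `delta`.
#' @export
pump_scenario <- function(reduction_axis = log_axis(1, 1e5, 101),
                          chi = NULL, delta = 1e4,
                          cell = cell_params(), env = ci_environment(0.0004),
                          chem = carbonate_params()) {
  if (length(reduction_axis) < 2L || any(reduction_axis < 1)) {
    abort("`reduction_axis` must contain factors >= 1.")
  }
  if (cell$P_C < 0.1 || cell$P_C > 1) {
    abort("Baseline `P_C` must lie in the measured range 0.1-1 cm/s.")
  }
  K_in <- equilibrium_ratio(env$pH_in, chem)
  chi <- chi %||% (2 * 1.1 * (cell$gamma + cell$phi * K_in))
  base <- update_cell(cell, delta = delta, chi = chi)
  alpha0 <- base$alpha

  ratio_at <- function(r) {
    ss <- steady_state(update_cell(base, alpha = alpha0 / r), env, chem)
    ss$C_in / ss$C_out
  }
  out <- purrr::map_dfr(sort(reduction_axis), function(r) {
    cc <- update_cell(base, alpha = alpha0 / r)
    ss <- steady_state(cc, env, chem)
    tibble::tibble(reduction = r, P_C_eff = base$P_C / r, alpha = cc$alpha,
                   C_in = ss$C_in, C_out = ss$C_out,
                   pump_ratio = ss$C_in / ss$C_out)
  })

  hit <- which(out$pump_ratio >= 2)
  threshold_grid <- if (length(hit)) out$reduction[min(hit)] else NA_real_
  threshold <- threshold_grid
  if (!is.na(threshold_grid) && min(hit) > 1) {
    i <- min(hit)
    threshold <- uniroot(function(r) ratio_at(r) - 2,
                         c(out$reduction[i - 1L], out$reduction[i]),
                         tol = 1e-8)$root
  }
  new_colim_sweep(out, "pump_scenario", threshold_factor = threshold,
                  threshold_grid = threshold_grid, chi = chi, delta = delta)
}

#' Growth across the CO2 ladder for a set of genotypes
#'
#' Evaluates each genotype's predicted growth rate at each CO2 level.
#' Growth is monotone non-decreasing in pCO2 for every genotype.
#'
#' @param genotypes A list of [genotype()] objects (a single genotype is
#'   also accepted).
#' @param pco2_levels pCO2 fractions; default the five assay conditions.
#' @param base Baseline [cell_params()] used by [evaluate_genotype()].
#' @param chem A [carbonate_params()].
#' @return A `colim_sweep` tibble: one row per genotype x pCO2.
#' @export
co2_titration <- function(genotypes,
                          pco2_levels = assay_pco2_levels(),
                          base = cell_params(mu_max = 0.25),
                          chem = carbonate_params()) {
  if (length(pco2_levels) < 1L) abort("`pco2_levels` must be nonempty.")
  if (inherits(genotypes, "ccm_genotype")) genotypes <- list(genotypes)
  out <- purrr::map_dfr(genotypes, evaluate_genotype,
                        pco2_levels = pco2_levels, base = base, chem = chem)
  new_colim_sweep(out, "co2_titration")
}
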