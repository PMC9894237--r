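#' Steady-state intracellular CO2 and HCO3- pools
#'
#' Solves the 2x2 linear system obtained by setting the two governing
#' equations to zero:
#' \deqn{dC_{in}/dt = \alpha(C_{out} - C_{in}) + (k_d + \delta/K)H_{in}
#'   - (k_h + \delta)C_{in} - \gamma C_{in}}
#' \deqn{dH_{in}/dt = \chi S_{ext} + \beta(H_{out} - H_{in})
#'   + (k_h + \delta)C_{in} - (k_d + \delta/K)H_{in} - \phi H_{in}}
#' with `K = equilibrium_ratio(pH_in)`, `k_d = k_h / K`, and `S_ext` the
#' external CO2 or HCO3- pool depending on `uptake_substrate`. Boundary
#' concentrations come from [boundary_concentrations()].
#'
#' The coefficient matrix is a (negated) M-matrix for any valid parameters,
#' so the solution is unique and nonnegative whenever it exists; a singular
#' system (all removal terms zero with nonzero input) raises a
#' degenerate-parameter error.
#'
#' @param cell A [cell_params()] object.
#' @param env A [ci_environment()].
#' @param chem A [carbonate_params()].
#' @return An object of class `ci_steady_state` with elements `C_in`,
#'   `H_in`, `C_out`, `H_out`, `S_ext` (uM) and the inputs.
#' @examples
#' ss <- steady_state(cell_params(), ci_environment(0.0004))
#' glance(ss)
#' @export
steady_state <- function(cell, env, chem = carbonate_params()) {
  stopifnot(inherits(cell, "cell_params"), inherits(env, "ci_environment"),
            inherits(chem, "carbonate_params"))
  bc <- boundary_concentrations(env, chem)
  K_in <- equilibrium_ratio(env$pH_in, chem)
  k_h <- chem$k_h
  k_d <- k_h / K_in
  S_ext <- if (cell$uptake_substrate == "CO2") bc$C_out else bc$H_out

  hyd <- k_h + cell$delta            # CO2 -> HCO3-
  deh <- k_d + cell$delta / K_in     # HCO3- -> CO2
  A <- matrix(c(cell$alpha + hyd + cell$gamma, -deh,
                -hyd, cell$beta + deh + cell$phi),
              nrow = 2, byrow = TRUE)
  b <- c(cell$alpha * bc$C_out,
         cell$chi * S_ext + cell$beta * bc$H_out)

  det_scale <- prod(sqrt(rowSums(A^2))) + .Machine$double.xmin
  if (abs(det(A)) / det_scale < 1e-14) {
    abort(paste("Degenerate parameters: the steady-state system is singular",
                "(a pool has no removal process). Add a nonzero exchange,",
                "interconversion or consumption rate."))
  }
  x <- solve(A, b)
  scale <- max(abs(b) / max(rowSums(abs(A))), 1e-300)
  if (any(x < -1e-8 * scale)) {
    abort("Internal consistency error: negative steady-state concentration.")
  }
  x <- pmax(x, 0)

  structure(
    list(C_in = x[[1]], H_in = x[[2]],
         C_out = bc$C_out, H_out = bc$H_out, S_ext = S_ext,
         K_eq_in = K_in, k_h = k_h, k_d = k_d,
         cell = cell, env = env, chem = chem),
    class = "ci_steady_state"
  )
}

#' @export
print.ci_steady_state <- function(x, ...) {
  cat("Steady state (uM):\n")
  cat(sprintf("  C_in %.6g   C_out %.6g   (C_in/C_out %.4g)\n",
              x$C_in, x$C_out, ifelse(x$C_out > 0, x$C_in / x$C_out, NA)))
  cat(sprintf("  H_in %.6g   H_out %.6g\n", x$H_in, x$H_out))
  invisible(x)
}

#' @rdname steady_state
#' @param x A `ci_steady_state` object.
#' @param ... Unused.
#' @export
tidy.ci_steady_state <- function(x, ...) {
  tibble::tibble(
    species = rep(c("CO2", "HCO3-"), 2),
    compartment = rep(c("intracellular", "extracellular"), each = 2),
    concentration_uM = c(x$C_in, x$H_in, x$C_out, x$H_out)
  )
}

#' @rdname steady_state
#' @export
glance.ci_steady_state <- function(x, ...) {
  tibble::tibble(
    C_in = x$C_in, H_in = x$H_in, C_out = x$C_out, H_out = x$H_out,
    depletion_ratio = ifelse(x$C_out > 0, x$C_in / x$C_out, NA_real_),
    H_over_C_in = ifelse(x$C_in > 0, x$H_in / x$C_in, NA_real_)
  )
}

#' Steady-state fluxes
#'
#' All fluxes in uM s^-1 per cell volume. Leakage is signed: positive means
#' net outflow across the membrane, negative means net passive influx.
#' At steady state the imported flux minus total leakage equals biomass
#' production: `J_chi - J_L_tot = J_rub + J_bic = J_B` (exact conservation
#' of the linear system).
#'
#' @param ss A [steady_state()] result.
#' @return A one-row tibble of class `ci_fluxes` with columns `J_rub`,
#'   `J_bic`, `J_B`, `J_L_C`, `J_L_H`, `J_L_tot`, `J_chi`, `leak_ratio`
#'   (= `J_L_tot / J_B`).
#' @examples
#' ci_fluxes(steady_state(cell_params(chi = 5), ci_environment(0.015)))
#' @export
ci_fluxes <- function(ss) {
  stopifnot(inherits(ss, "ci_steady_state"))
  cell <- ss$cell
  J_rub <- cell$gamma * ss$C_in
  J_bic <- cell$phi * ss$H_in
  J_B <- J_rub + J_bic
  J_L_C <- cell$alpha * (ss$C_in - ss$C_out)
  J_L_H <- cell$beta * (ss$H_in - ss$H_out)
  J_L_tot <- J_L_C + J_L_H
  J_chi <- cell$chi * ss$S_ext
  out <- tibble::tibble(
    J_rub = J_rub, J_bic = J_bic, J_B = J_B,
    J_L_C = J_L_C, J_L_H = J_L_H, J_L_tot = J_L_tot, J_chi = J_chi,
    leak_ratio = ifelse(J_B > 0, J_L_tot / J_B, NA_real_)
  )
  class(out) <- c("ci_fluxes", class(out))
  attr(out, "cell") <- cell
  out
}

#' Liebig-minimum growth prediction
#'
#' Growth is colimited by the rubisco carboxylation flux (supplying the
#' `1 - f_H` fraction of biomass carbon drawn from CO2) and the
#' bicarboxylation flux (supplying the `f_H` fraction drawn from HCO3-):
#' \deqn{\mu = \min\left(\frac{J_{rub}}{(1-f_H)q_C},
#'   \frac{J_{bic}}{f_H q_C}\right) \cdot 3600}
#' in h^-1, optionally capped at `mu_max`. The limiting regime is the
#' argmin of the two carboxylation terms; exact ties break to
#' `"rubisco_limited"`.
#'
#' @param fluxes A [ci_fluxes()] result (or any one-row data frame with
#'   `J_rub` and `J_bic` in uM s^-1).
#' @param cell A [cell_params()] object supplying `f_H` (and defaults for
#'   `q_C`, `mu_max`); taken from `fluxes` if omitted.
#' @param q_C Biomass carbon demand per unit growth rate (uM); overrides
#'   `cell$q_C`.
#' @param mu_max Growth ceiling (h^-1); overrides `cell$mu_max`.
#' @return A one-row tibble: `growth_rate` (h^-1), `limiting_regime`,
#'   `doubling_time` (h).
#' @export
growth_prediction <- function(fluxes, cell = attr(fluxes, "cell"),
                              q_C = cell$q_C, mu_max = cell$mu_max) {
  if (is.null(cell)) abort("Supply `cell` (not recoverable from `fluxes`).")
  if (!is.numeric(q_C) || length(q_C) != 1L || q_C <= 0) {
    abort("`q_C` must be a single positive number (uM per unit growth rate).")
  }
  rub_rate <- 3600 * fluxes$J_rub / ((1 - cell$f_H) * q_C)
  bic_rate <- 3600 * fluxes$J_bic / (cell$f_H * q_C)
  regime <- ifelse(rub_rate <= bic_rate, "rubisco_limited",
                   "bicarboxylation_limited")
  mu <- pmin(rub_rate, bic_rate, mu_max)
  tibble::tibble(
    growth_rate = mu,
    limiting_regime = regime,
    doubling_time = ifelse(mu > 0, log(2) / mu, Inf)
  )
}

#' Solve the full model for one cell in one environment
#'
#' Convenience chain `steady_state() |> ci_fluxes() |> growth_prediction()`
#' flattened into one tidy row; the workhorse behind the sweep engines.
#'
#' @inheritParams steady_state
#' @param q_C,mu_max Optional overrides passed to [growth_prediction()].
#' @return A one-row tibble with pools, depletion ratio, all fluxes, and the
#'   growth prediction.
#' @examples
#' model_growth(cell_params(delta = 100, chi = 5), ci_environment(0.0004))
#' @export
model_growth <- function(cell, env, chem = carbonate_params(),
                         q_C = cell$q_C, mu_max = cell$mu_max) {
  ss <- steady_state(cell, env, chem)
  fl <- ci_fluxes(ss)
  gr <- growth_prediction(fl, cell, q_C = q_C, mu_max = mu_max)
  dplyr::bind_cols(
    tibble::tibble(pCO2 = env$pCO2, C_in = ss$C_in, H_in = ss$H_in,
                   C_out = ss$C_out, H_out = ss$H_out,
                   depletion_ratio = ifelse(ss$C_out > 0,
                                            ss$C_in / ss$C_out, NA_real_)),
    tibble::as_tibble(fl)[, c("J_rub", "J_bic", "J_B", "J_L_C", "J_L_H",
                              "J_L_tot", "J_chi", "leak_ratio")],
    gr
  )
}
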