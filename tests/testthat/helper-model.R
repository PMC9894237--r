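# Shared fixtures: default parameter objects and an independent
# time-stepping oracle for the steady state.

default_chem <- carbonate_params()
ambient <- ci_environment(0.0004)

# Log-uniform random parameter sets over physiologically wide ranges.
random_cell_params <- function(n, seed = 42) {
  set.seed(seed)
  lu <- function(lo, hi) 10^runif(n, log10(lo), log10(hi))
  tibble::tibble(
    alpha = lu(1e2, 1e5),
    beta = lu(1e-4, 1e-1),
    gamma = lu(1e-1, 1e3),
    delta = lu(1e-2, 1e4),
    chi = lu(1e-2, 1e3) * sample(c(0, 1), n, replace = TRUE),
    phi = lu(1e-2, 1e1)
  )
}

cell_from_row <- function(row, ...) {
  cell_params(alpha = row$alpha, beta = row$beta, gamma = row$gamma,
              delta = row$delta, chi = row$chi, phi = row$phi, ...)
}

# Independent oracle: explicit forward integration of the two governing
# ODEs from C_in = H_in = 0, run long past the slowest relaxation rate.
ode_steady_oracle <- function(cell, env, chem = default_chem) {
  bc <- boundary_concentrations(env, chem)
  K <- equilibrium_ratio(env$pH_in, chem)
  k_h <- chem$k_h
  k_d <- k_h / K
  S <- if (cell$uptake_substrate == "CO2") bc$C_out else bc$H_out
  rhs <- function(t, y, parms) {
    C <- y[1]; H <- y[2]
    dC <- cell$alpha * (bc$C_out - C) + (k_d + cell$delta / K) * H -
      (k_h + cell$delta) * C - cell$gamma * C
    dH <- cell$chi * S + cell$beta * (bc$H_out - H) +
      (k_h + cell$delta) * C - (k_d + cell$delta / K) * H - cell$phi * H
    list(c(dC, dH))
  }
  slow <- min(cell$alpha + cell$gamma, cell$beta + cell$phi)
  t_end <- 80 / slow
  out <- deSolve::lsoda(c(0, 0), times = c(0, t_end), func = rhs,
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
  c(C_in = out[2, 2], H_in = out[2, 3])
}

expect_rel_equal <- function(actual, expected, rtol = 1e-6) {
  scale <- pmax(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected) / scale), rtol)
}
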