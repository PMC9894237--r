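test_that("with no sources or sinks the cell equilibrates with the medium", {
  cell <- cell_params(gamma = 0, delta = 0, chi = 0, phi = 0)
  ss <- steady_state(cell, ambient, default_chem)
  expect_equal(ss$C_in, ss$C_out, tolerance = 1e-12)
  expect_equal(ss$H_in, ss$H_out, tolerance = 1e-12)
  fl <- ci_fluxes(ss)
  expect_equal(unlist(fl[, c("J_rub", "J_bic", "J_B", "J_L_C", "J_L_H",
                             "J_L_tot", "J_chi")]),
               setNames(rep(0, 7), c("J_rub", "J_bic", "J_B", "J_L_C",
                                     "J_L_H", "J_L_tot", "J_chi")),
               tolerance = 1e-8)
})

test_that("extreme rubisco activity barely depletes intracellular CO2", {
  # alpha = 1e4, gamma = 1e3: C_in/C_out = alpha/(alpha+gamma) ~ 0.909
  cell <- cell_params(alpha = 1e4, gamma = 1e3, delta = 0, chi = 0, phi = 0)
  ss <- steady_state(cell, ambient, default_chem)
  expect_equal(ss$C_in / ss$C_out, 1e4 / 1.1e4, tolerance = 1e-6)
  expect_gt(ss$C_in / ss$C_out, 0.9)

  # bound holds with full default physiology for any gamma up to 1e3
  for (g in c(1, 30, 300, 1000)) {
    ss <- steady_state(cell_params(gamma = g), ambient)
    expect_gte(ss$C_in / ss$C_out, 0.9)
  }
})

test_that("linear solve matches explicit ODE integration", {
  skip_if_not_installed("deSolve")
  rows <- random_cell_params(20, seed = 7)
  for (i in seq_len(nrow(rows))) {
    cell <- cell_from_row(rows[i, ])
    ss <- steady_state(cell, ambient, default_chem)
    oracle <- ode_steady_oracle(cell, ambient, default_chem)
    expect_rel_equal(c(ss$C_in, ss$H_in), unname(oracle), rtol = 1e-6)
  }
})

test_that("imported flux minus leakage equals biomass production", {
  rows <- random_cell_params(50, seed = 11)
  for (i in seq_len(nrow(rows))) {
    fl <- ci_fluxes(steady_state(cell_from_row(rows[i, ]), ambient))
    scale <- max(abs(fl$J_chi), abs(fl$J_B), abs(fl$J_L_tot), 1e-12)
    expect_lt(abs(fl$J_chi - fl$J_L_tot - fl$J_rub - fl$J_bic) / scale, 1e-9)
  }
})

test_that("CA respects the interconversion equilibrium", {
  # with no consumption or uptake, boosting delta a millionfold must leave
  # the pools exactly where they are
  cell0 <- cell_params(gamma = 0, phi = 0, chi = 0, delta = 3)
  cell1 <- update_cell(cell0, delta = 3e6)
  env <- ci_environment(0.015, pH_out = 7.2, pH_in = 7.2)
  ss0 <- steady_state(cell0, env)
  ss1 <- steady_state(cell1, env)
  expect_equal(ss1$C_in, ss0$C_in, tolerance = 1e-9)
  expect_equal(ss1$H_in, ss0$H_in, tolerance = 1e-9)

  # in the large-delta limit the pools reach the equilibrium ratio
  cell <- cell_params(gamma = 200, phi = 2, chi = 1,
                      delta = 1e4 * max(200, 2, default_chem$k_h))
  ss <- steady_state(cell, ambient)
  K <- equilibrium_ratio(ambient$pH_in, default_chem)
  expect_equal(ss$H_in / ss$C_in, K, tolerance = 0.01)
})

test_that("growth responds monotonically to CO2, CA and uptake", {
  cell <- cell_params(delta = 50, chi = 2)
  # non-decreasing in C_out
  mu <- vapply(c(0.0004, 0.002, 0.01, 0.05, 0.1), function(p) {
    model_growth(cell, ci_environment(p))$growth_rate
  }, numeric(1))
  expect_true(all(diff(mu) >= 0))

  # non-decreasing in delta (within numerical tolerance: CA can draw down
  # C_in by at most ~phi*K/alpha relative while H_in is below equilibrium)
  for (g in c(5, 900)) {
    mu <- vapply(log_axis(1e-2, 1e4, 15), function(d) {
      model_growth(cell_params(gamma = g, delta = d), ambient)$growth_rate
    }, numeric(1))
    expect_true(all(diff(mu) >= -1e-3 * mu[-length(mu)]))
  }

  # total leakage strictly increases with uptake and changes sign
  jl <- vapply(c(0, log_axis(1e-1, 1e4, 12)), function(ch) {
    ci_fluxes(steady_state(cell_params(delta = 100, chi = ch),
                           ambient))$J_L_tot
  }, numeric(1))
  expect_true(all(diff(jl) > 0))
  expect_lt(jl[1], 0)
  expect_gt(max(jl), 0)
})

test_that("fluxes carry the documented signs", {
  # passive influx balances fixation when there is no pump
  fl <- ci_fluxes(steady_state(cell_params(gamma = 200, chi = 0), ambient))
  expect_lt(fl$J_L_C, 0)
  expect_lt(fl$J_L_tot, 0)
  expect_gt(fl$J_B, 0)
})

test_that("the Liebig growth law and its tie-break behave as specified", {
  cell <- cell_params()
  fl <- tibble::tibble(J_rub = 100, J_bic = 0)
  gp <- growth_prediction(fl, cell)
  expect_equal(gp$growth_rate, 0)
  expect_equal(gp$limiting_regime, "bicarboxylation_limited")
  expect_equal(gp$doubling_time, Inf)

  # exact tie resolves to rubisco_limited
  f_H <- cell$f_H
  fl <- tibble::tibble(J_rub = (1 - f_H) * 50, J_bic = f_H * 50)
  gp <- growth_prediction(fl, cell)
  expect_equal(gp$limiting_regime, "rubisco_limited")

  # doubling time is ln(2)/mu
  fl <- tibble::tibble(J_rub = 321, J_bic = 321)
  gp <- growth_prediction(fl, cell)
  expect_equal(gp$doubling_time, log(2) / gp$growth_rate)

  expect_error(growth_prediction(fl, cell, q_C = -1), "q_C")
})

test_that("degenerate parameter sets are rejected, not silently solved", {
  cell <- cell_params(alpha = 0, beta = 0, gamma = 0, delta = 0, chi = 0,
                      phi = 0)
  expect_error(steady_state(cell, ambient), "[Dd]egenerate")
  expect_error(cell_params(gamma = -5), "gamma")
  expect_error(cell_params(f_H = 0.7), "f_H")
})

test_that("uptake substrate flag switches the pumped pool", {
  co2cell <- cell_params(chi = 10, uptake_substrate = "CO2")
  hco3cell <- cell_params(chi = 10, uptake_substrate = "HCO3")
  s1 <- steady_state(co2cell, ambient)
  s2 <- steady_state(hco3cell, ambient)
  expect_equal(s1$S_ext, s1$C_out)
  expect_equal(s2$S_ext, s2$H_out)
  # HCO3- is the more abundant substrate at pH 7, so pumping it imports more
  expect_gt(s2$H_in, s1$H_in)
})

test_that("rubisco budget arithmetic converts protein mass to site molarity", {
  r <- max_rubisco_site_concentration(0.2, 300, 60)
  expect_equal(r$rubisco_mass_mg_per_ml, 60)
  expect_equal(r$site_concentration_mM, 1.0)
  expect_equal(max_rubisco_site_concentration(0.1, 300, 60)$site_concentration_mM,
               0.5)
  expect_equal(max_rubisco_site_concentration(0, 300, 60)$site_concentration_mM,
               0)
  expect_error(max_rubisco_site_concentration(0.2, -1, 60))
})

test_that("naive depletion ratio closed form", {
  expect_equal(naive_depletion_ratio(1e4, 1e3), 10 / 11)
  expect_gt(naive_depletion_ratio(1e4, 1e3), 0.9)
  expect_equal(naive_depletion_ratio(123, 0), 1.0)
  expect_equal(naive_depletion_ratio(1e3, 1e3), 0.5)
  expect_error(naive_depletion_ratio(0, 1), "alpha")
  expect_error(naive_depletion_ratio(1, -1), "gamma")
})

test_that("per-cell fixation rate supports fast doubling at ambient CO2", {
  # ~15 uM external CO2, extreme rubisco: ~3e10 CO2 fixed per hour
  env15 <- ci_environment(15 / (0.034 * 1e6))
  cell <- cell_params(alpha = 1e4, gamma = 1e3, volume = 1e-15)
  r <- percell_fixation_rate(cell, env15, carbon_demand = 1e10)
  expected <- 1e3 * (15 * 1e4 / 1.1e4) * 1e-6 * 1e-15 * 6.02214076e23 * 3600
  expect_equal(r$fixation_per_hour, expected, tolerance = 1e-2)
  expect_lt(r$implied_doubling_time_h, 2)

  expect_equal(percell_fixation_rate(cell_params(gamma = 0), env15)$fixation_per_hour,
               0)
  # delta and chi are zeroed for the naive calculation
  loaded <- cell_params(alpha = 1e4, gamma = 1e3, delta = 500, chi = 50)
  expect_equal(percell_fixation_rate(loaded, env15)$fixation_per_hour,
               expected, tolerance = 1e-2)
})

test_that("tidy and glance expose the steady state as tibbles", {
  ss <- steady_state(cell_params(), ambient)
  td <- tidy(ss)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  gl <- glance(ss)
  expect_equal(gl$depletion_ratio, ss$C_in / ss$C_out)
})
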