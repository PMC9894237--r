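small_delta_axis <- log_axis(1e-2, 1e4, 13)

test_that("growth is CA-insensitive at low rubisco, CA-sensitive at high", {
  sw <- growth_vs_ca(gamma_ladder = c(1, 10, 100, 1000),
                     delta_axis = small_delta_axis)
  lo <- dplyr::filter(sw, gamma == 1)
  expect_lt(diff(range(lo$growth_rate)), 0.01 * mean(lo$growth_rate))

  hi <- dplyr::filter(sw, gamma == 1000)
  # strictly increasing until within 1% of the large-delta plateau
  plateau <- hi$growth_rate[which.max(hi$delta)]
  rising <- hi$growth_rate < 0.99 * plateau
  expect_gt(sum(rising), 2)
  expect_true(all(diff(hi$growth_rate[rising]) > 0))

  # regime flip across the ladder
  expect_true(all(dplyr::filter(sw, gamma == 1)$limiting_regime ==
                    "rubisco_limited"))
  expect_true(any(dplyr::filter(sw, gamma == 1000)$limiting_regime ==
                    "bicarboxylation_limited"))
})

test_that("growth_vs_ca degenerate inputs and scale equivariance", {
  expect_error(growth_vs_ca(delta_axis = 5), "degenerate")
  expect_error(log_axis(0, 10), "positive")

  zero <- growth_vs_ca(gamma_ladder = 0, delta_axis = small_delta_axis)
  expect_true(all(zero$growth_rate == 0))

  base <- cell_params()
  s1 <- growth_vs_ca(c(10, 1000), small_delta_axis, cell = base)
  s2 <- growth_vs_ca(c(10, 1000), small_delta_axis, cell = base,
                     q_C = 2 * base$q_C)
  expect_equal(s2$growth_rate, s1$growth_rate / 2)
})

test_that("futile cycling appears only at extreme CA x uptake coexpression", {
  hm <- leakage_heatmap(log_axis(1e-1, 1e5, 13), log_axis(1, 1e6, 13))
  expect_gte(max(hm$leak_ratio, na.rm = TRUE), 100)

  # the extreme corner is the leaky one
  corner <- dplyr::filter(hm, delta == max(delta), chi == max(chi))
  expect_gte(corner$leak_ratio, 100)

  # without uptake there is no leakage to pay for, whatever the CA level
  for (d in log_axis(1e-1, 1e5, 7)) {
    fl <- ci_fluxes(steady_state(cell_params(delta = d, chi = 0), ambient))
    expect_lte(fl$J_L_tot, 0)
  }

  # CO2 leakage dominates HCO3- leakage almost everywhere
  frac_dom <- mean(abs(hm$J_L_C) > abs(hm$J_L_H))
  expect_gt(frac_dom, 0.95)
})

test_that("the zero-leakage contour moves to lower uptake as CA rises", {
  hm <- leakage_heatmap(log_axis(1e-1, 1e5, 9), log_axis(1, 1e6, 9))
  contour <- attr(hm, "zero_contour")
  expect_false(any(is.na(contour$chi_zero)))
  expect_true(all(diff(contour$chi_zero) <= 0))
  # the contour is a genuine root of J_L_tot
  mid <- contour[5, ]
  fl <- ci_fluxes(steady_state(cell_params(delta = mid$delta,
                                           chi = mid$chi_zero), ambient))
  expect_lt(abs(fl$J_L_tot) / fl$J_B, 1e-4)
})

test_that("sweeps are deterministic, pure functions of their inputs", {
  h1 <- leakage_heatmap(log_axis(1, 1e4, 5), log_axis(1, 1e5, 5))
  h2 <- leakage_heatmap(log_axis(1, 1e4, 5), log_axis(1, 1e5, 5))
  expect_identical(jsonlite::toJSON(as.data.frame(h1), digits = NA),
                   jsonlite::toJSON(as.data.frame(h2), digits = NA))
})

test_that("only extreme rubisco or implausible permeability depletes CO2", {
  ds <- depletion_scan(log_axis(10, 1e5, 9), log_axis(1e-3, 1, 9))
  # at the default permeability, any gamma <= 1e3 leaves C_in above 0.9 C_out
  meas <- dplyr::filter(ds, P_C >= 0.3, gamma <= 1e3)
  expect_gt(nrow(meas), 0)
  expect_true(all(meas$depletion_ratio > 0.9))

  # gamma = 0: no depletion at all
  ss <- steady_state(cell_params(gamma = 0, delta = 0, chi = 0, phi = 0),
                     ambient)
  expect_equal(ss$C_in / ss$C_out, 1, tolerance = 1e-12)

  # frontier matches the closed form alpha/(alpha+gamma) = 0.5 => gamma = alpha
  fr <- attr(ds, "frontier")
  expect_true(all(abs(fr$gamma_half / fr$alpha - 1) < 1e-2))
})

test_that("a CO2 pump needs a far less permeable membrane than measured", {
  ps <- pump_scenario()
  expect_gte(attr(ps, "threshold_factor"), 100)
  expect_lte(attr(ps, "threshold_factor"), 1000)
  # at the measured permeability the pump cannot elevate C_in
  expect_lt(ps$pump_ratio[ps$reduction == 1], 1.05)
  # monotone: less permeable membrane, higher C_in
  expect_true(all(diff(ps$pump_ratio) > 0))
  # the threshold is a genuine crossing of 2
  expect_true(any(ps$pump_ratio >= 2) && any(ps$pump_ratio < 2))

  # without energized uptake no reduction ever elevates C_in
  ps0 <- pump_scenario(chi = 1e-12)
  expect_true(all(ps0$pump_ratio <= 1 + 1e-9))

  expect_error(pump_scenario(cell = cell_params(P_C = 0.01)), "0.1-1")
})

test_that("growth rises with CO2 for every genotype", {
  gens <- list(genotype(), genotype(has_CA = TRUE),
               genotype(has_CA = TRUE, has_transporter = TRUE))
  tt <- co2_titration(gens)
  for (lb in unique(tt$label)) {
    g <- dplyr::arrange(dplyr::filter(tt, label == lb), pCO2)
    expect_true(all(diff(g$growth_rate) >= 0))
  }
  # rubisco alone: robust growth at 5%, near-arrest in ambient air
  ra <- dplyr::filter(tt, label == "rubisco_alone")
  expect_gt(ra$growth_rate[ra$pCO2 == 0.05],
            ra$growth_rate[ra$pCO2 == 0.0004])

  # determinism: identical genotypes give identical curves
  t2 <- co2_titration(list(genotype(), genotype()))
  half <- nrow(t2) / 2
  expect_identical(t2$growth_rate[seq_len(half)],
                   t2$growth_rate[half + seq_len(half)])

  # CA-added genotype is at least as fast everywhere
  ca <- dplyr::filter(tt, label == "rubisco+CA")
  expect_true(all(ca$growth_rate >= ra$growth_rate - 1e-12))

  expect_error(co2_titration(list(genotype()), pco2_levels = numeric(0)),
               "nonempty")
})

test_that("autoplot returns a ggplot for every sweep type", {
  expect_s3_class(autoplot(growth_vs_ca(c(1, 1000), log_axis(1, 100, 3))),
                  "ggplot")
  expect_s3_class(autoplot(leakage_heatmap(log_axis(1, 100, 3),
                                           log_axis(1, 100, 3))), "ggplot")
  expect_s3_class(autoplot(pump_scenario(reduction_axis = log_axis(1, 1e4, 9))),
                  "ggplot")
  expect_s3_class(autoplot(co2_titration(list(genotype()))), "ggplot")
})
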