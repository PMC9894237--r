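effects_tbl <- function() {
  tibble::tibble(
    gene = sprintf("g%04d", 1:10),
    condition = "low_co2",
    effect = c(-3, -2.5, -2, -2, -1.5, -1, -0.5, 0.5, 1, -2)
  )
}

test_that("a fixed seed makes the generator byte-identical", {
  sp <- library_spec(n_genes = 15, reads_per_sample = 1e4, seed = 99)
  l1 <- simulate_library(sp)
  l2 <- simulate_library(sp)
  expect_identical(l1$counts, l2$counts)
  expect_identical(l1$doublings, l2$doublings)

  l3 <- simulate_library(library_spec(n_genes = 15, reads_per_sample = 1e4,
                                      seed = 100))
  expect_false(identical(l1$counts, l3$counts))
})

test_that("library structure matches the assay design", {
  lib <- simulate_library(library_spec(n_genes = 60, reads_per_sample = 1e5,
                                       n_replicates = 2, seed = 3))
  per_gene <- lib$counts |>
    dplyr::filter(condition == "T0", replicate == "r1") |>
    dplyr::count(gene)
  expect_true(mean(per_gene$n) >= 35 && mean(per_gene$n) <= 40)
  expect_true(all(per_gene$n >= 30 & per_gene$n <= 50))
  expect_true(all(lib$doublings$doublings >= 6.5 &
                    lib$doublings$doublings <= 7.5))
  # every replicate has a T0 and read totals match the requested depth
  totals <- lib$counts |>
    dplyr::group_by(replicate, condition) |>
    dplyr::summarise(total = sum(count), .groups = "drop")
  expect_true(all(totals$total == 1e5))
  expect_setequal(unique(totals$condition), c("T0", "low_co2"))
})

test_that("a neutral library recovers fitness zero within sampling error", {
  lib <- simulate_library(library_spec(n_genes = 50, reads_per_sample = 1e6,
                                       seed = 5))
  fit <- strain_fitness(lib$counts)
  expect_lt(abs(mean(fit$fitness)), 0.05)
})

test_that("known gene effects are recovered within 0.3 log2 units", {
  lib <- simulate_library(library_spec(
    n_genes = 100, reads_per_sample = 1e6, n_replicates = 2,
    effects = effects_tbl(), seed = 17
  ))
  genes <- lib$counts |>
    strain_fitness() |>
    gene_fitness()
  est <- genes |>
    dplyr::group_by(gene) |>
    dplyr::summarise(est = mean(fitness), .groups = "drop") |>
    dplyr::left_join(lib$truth, by = "gene")
  expect_false(any(is.na(est$est)))
  # per-gene recovery, including the fourfold-drop genes at -2
  expect_lt(max(abs(est$est - est$effect)), 0.3)
  expect_lt(mean(abs(est$est - est$effect)), 0.1)

  # replicates at this depth are strongly correlated
  cc <- replicate_concordance(genes)
  expect_true(all(cc$r > 0.85))
})

test_that("generator expectations match the closed-form frequencies", {
  sp <- library_spec(n_genes = 40, reads_per_sample = 1e6,
                     effects = tibble::tibble(gene = "g0001",
                                              condition = "low_co2",
                                              effect = -2),
                     n_replicates = 1, seed = 23)
  lib <- simulate_library(sp)
  d <- lib$doublings$doublings[1]
  t0 <- dplyr::filter(lib$counts, condition == "T0")
  end <- dplyr::filter(lib$counts, condition == "low_co2")
  f0 <- t0$count / sum(t0$count)
  w <- ifelse(t0$gene == "g0001", -2 / d, 0)
  f_pred <- f0 * 2^(d * (1 + w))
  f_pred <- f_pred / sum(f_pred)
  f_obs <- end$count / sum(end$count)
  # multinomial error at 1e6 reads: a few 1e-4 in absolute frequency
  expect_lt(max(abs(f_obs - f_pred)), 5e-4)

  expect_error(library_spec(reads_per_sample = 0), "reads")
  expect_error(library_spec(doublings = c(7, 6)), "doublings")
})

test_that("growth curves are logistic in the noiseless limit", {
  gs <- growth_sim_spec(genotype(), pco2_levels = c(low = 0.005),
                        od_noise_sd = 0, n_replicates = 1, duration_h = 24,
                        seed = 1)
  curves <- simulate_growth(gs)
  mu <- curves$growth_rate[1]
  K <- 0.5; od0 <- 0.005
  expected <- K * od0 * exp(mu * curves$time_h) /
    (K + od0 * (exp(mu * curves$time_h) - 1))
  expect_equal(curves$od, expected, tolerance = 1e-12)

  # zero growth rate: flat at the inoculum
  flat <- simulate_growth(gs, rates = tibble::tibble(
    label = "dead", pCO2 = 0.005, growth_rate = 0))
  expect_true(all(abs(flat$od - od0) < 1e-12))
})

test_that("endpoint ODs reflect the CO2 dependence of rubisco-only growth", {
  gs <- growth_sim_spec(genotype(), pco2_levels = c(ambient = 0.0004,
                                                    high = 0.05),
                        od_noise_sd = 0.01, n_replicates = 3,
                        duration_h = 96, seed = 7)
  curves <- simulate_growth(gs)
  ep <- attr(curves, "endpoints") |>
    dplyr::group_by(pCO2) |>
    dplyr::summarise(od = mean(endpoint_od), .groups = "drop")
  # robust growth at 5%, failure to grow in ambient air
  expect_gt(ep$od[ep$pCO2 == 0.05], 0.4)
  expect_lt(ep$od[ep$pCO2 == 0.0004], 0.1)
})
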