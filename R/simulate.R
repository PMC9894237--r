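#' Specification of a synthetic barcoded transposon library
#'
#' Describes a pooled competition experiment: a library of barcoded
#' insertion mutants (a few dozen distinct insertions per gene), per-gene
#' condition-dependent fitness effects, competitive growth for 6.5-7.5
#' doublings, and multinomial read sampling of the T0 and endpoint pools.
#'
#' @param n_genes Number of genes.
#' @param insertions_per_gene Integer vector to draw insertions-per-gene
#'   from (default 32..44, mean 38 -- a library averaging ~35-40 distinct
#'   mutants per gene).
#' @param effects Per-gene true fitness effects in log2 units: a data frame
#'   with columns `gene`, `condition`, `effect`, or `NULL` for all-neutral.
#'   Genes not listed are neutral in that condition.
#' @param conditions Endpoint condition labels.
#' @param reads_per_sample Sequencing depth per sample (default 1e6).
#' @param doublings Range (length 2) from which each replicate's number of
#'   competitive doublings is drawn uniformly (default 6.5-7.5).
#' @param n_replicates Biological replicates per condition.
#' @param strain_sd Within-gene (per-strain) standard deviation of the true
#'   effect, log2 units (default 0: insertions in a gene are treated as
#'   replicates of the same effect).
#' @param t0_label Condition label for the reference sample.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n_genes = 100, insertions_per_gene = 32:44,
                         effects = NULL, conditions = "low_co2",
                         reads_per_sample = 1e6, doublings = c(6.5, 7.5),
                         n_replicates = 2, strain_sd = 0,
                         t0_label = "T0", seed = 1) {
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  if (reads_per_sample <= 0) abort("`reads_per_sample` must be positive.")
  if (length(doublings) != 2L || any(doublings <= 0) ||
      doublings[2] < doublings[1]) {
    abort("`doublings` must be an increasing positive range of length 2.")
  }
  if (strain_sd < 0) abort("`strain_sd` must be >= 0.")
  if (!is.null(effects)) {
    need <- c("gene", "condition", "effect")
    if (!all(need %in% names(effects))) {
      abort("`effects` needs columns gene, condition, effect.")
    }
  }
  structure(
    list(n_genes = n_genes, insertions_per_gene = insertions_per_gene,
         effects = if (is.null(effects)) NULL else tibble::as_tibble(effects),
         conditions = conditions, reads_per_sample = reads_per_sample,
         doublings = doublings, n_replicates = n_replicates,
         strain_sd = strain_sd, t0_label = t0_label, seed = seed),
    class = "library_spec"
  )
}

#' Simulate a pooled barcode competition experiment
#'
#' Strain frequencies evolve deterministically over `d` doublings of
#' competitive growth, `f_i \propto f_{i,0} 2^{d (1 + w_i)}`, where the
#' per-strain relative fitness `w_i = effect_i / d` is scaled so that the
#' recovered log2 statistic equals the specified per-gene effect (up to the
#' compositional renormalization). Reads are then drawn multinomially at
#' the specified depth for the T0 pool of each replicate and for every
#' endpoint sample.
#'
#' @param spec A [library_spec()].
#' @return A list of class `synthetic_library`:
#'   * `counts`: long tibble (`barcode`, `gene`, `replicate`, `condition`,
#'     `count`) including the T0 rows -- ready for [strain_fitness()];
#'   * `truth`: tibble of true per-gene effects per condition;
#'   * `doublings`: realized doublings per replicate;
#'   * `spec`: the input specification.
#' @examples
#' lib <- simulate_library(library_spec(n_genes = 20, reads_per_sample = 1e5))
#' head(lib$counts)
#' @export
simulate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  set.seed(spec$seed)

  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  n_ins <- sample(spec$insertions_per_gene, spec$n_genes, replace = TRUE)
  strains <- tibble::tibble(
    gene = rep(genes, n_ins),
    barcode = sprintf("bc%06d", seq_len(sum(n_ins)))
  )
  N <- nrow(strains)
  f0 <- rlnorm(N, meanlog = 0, sdlog = 0.5)
  f0 <- f0 / sum(f0)

  truth <- tidyr::expand_grid(gene = genes, condition = spec$conditions) |>
    dplyr::mutate(effect = 0)
  if (!is.null(spec$effects)) {
    truth <- truth |>
      dplyr::left_join(spec$effects, by = c("gene", "condition"),
                       suffix = c("", "_set")) |>
      dplyr::mutate(effect = dplyr::coalesce(.data$effect_set,
                                             .data$effect)) |>
      dplyr::select("gene", "condition", "effect")
  }

  reps <- sprintf("r%d", seq_len(spec$n_replicates))
  doubl <- tibble::tibble(
    replicate = reps,
    doublings = runif(spec$n_replicates, spec$doublings[1], spec$doublings[2])
  )

  rows <- purrr::map_dfr(seq_len(spec$n_replicates), function(ri) {
    rep_id <- reps[[ri]]
    d <- doubl$doublings[[ri]]
    t0_counts <- as.integer(rmultinom(1, spec$reads_per_sample, f0))
    t0 <- tibble::tibble(barcode = strains$barcode, gene = strains$gene,
                         replicate = rep_id, condition = spec$t0_label,
                         count = t0_counts)
    ends <- purrr::map_dfr(spec$conditions, function(cond) {
      eff <- truth$effect[truth$condition == cond][
        match(strains$gene, genes)]
      if (spec$strain_sd > 0) eff <- eff + rnorm(N, 0, spec$strain_sd)
      w <- eff / d
      f_end <- f0 * 2^(d * (1 + w))
      f_end <- f_end / sum(f_end)
      tibble::tibble(barcode = strains$barcode, gene = strains$gene,
                     replicate = rep_id, condition = cond,
                     count = as.integer(rmultinom(1, spec$reads_per_sample,
                                                  f_end)))
    })
    dplyr::bind_rows(t0, ends)
  })

  structure(
    list(counts = rows, truth = truth, doublings = doubl, spec = spec),
    class = "synthetic_library"
  )
}

#' Specification of synthetic growth curves
#'
#' @param genotypes A list of [genotype()] objects whose model-predicted
#'   growth rates drive the curves.
#' @param pco2_levels pCO2 fractions to simulate.
#' @param duration_h Total cultivation time (h); 96 h (4 d) suits slow
#'   rubisco-dependent strains, 48 h a chemoautotroph.
#' @param dt_h Sampling interval (h); plate readers typically read every
#'   30 min.
#' @param od0 Inoculum density (OD600); cultures are seeded at 0.005.
#' @param carrying_capacity Saturating density (OD600).
#' @param od_noise_sd Additive Gaussian OD noise (default 0.01).
#' @param n_replicates Wells per genotype x condition.
#' @param base,chem Passed to [evaluate_genotype()].
#' @param seed RNG seed.
#' @return An object of class `growth_sim_spec`.
#' @export
growth_sim_spec <- function(genotypes, pco2_levels = assay_pco2_levels(),
                            duration_h = 96, dt_h = 0.5, od0 = 0.005,
                            carrying_capacity = 0.5, od_noise_sd = 0.01,
                            n_replicates = 3,
                            base = cell_params(mu_max = 0.25),
                            chem = carbonate_params(), seed = 1) {
  if (duration_h <= 0 || dt_h <= 0) abort("Durations must be positive.")
  if (od_noise_sd < 0) abort("`od_noise_sd` must be >= 0.")
  if (od0 <= 0 || carrying_capacity <= od0) {
    abort("Need 0 < od0 < carrying_capacity.")
  }
  if (inherits(genotypes, "ccm_genotype")) genotypes <- list(genotypes)
  structure(
    list(genotypes = genotypes, pco2_levels = pco2_levels,
         duration_h = duration_h, dt_h = dt_h, od0 = od0,
         carrying_capacity = carrying_capacity, od_noise_sd = od_noise_sd,
         n_replicates = n_replicates, base = base, chem = chem, seed = seed),
    class = "growth_sim_spec"
  )
}

#' Simulate logistic growth curves from model-predicted rates
#'
#' Each genotype x CO2 level grows logistically at the rate predicted by
#' the colimitation model,
#' `OD(t) = K od0 e^{mu t} / (K + od0 (e^{mu t} - 1))`, with additive
#' Gaussian measurement noise, emulating multiday plate-reader growth
#' assays (curves plus endpoint ODs).
#'
#' @param spec A [growth_sim_spec()].
#' @param rates Optional precomputed rate table (`label`, `pCO2`,
#'   `growth_rate`); computed from the model if `NULL`.
#' @return A tibble: `label`, `pCO2`, `replicate`, `time_h`, `od`,
#'   `growth_rate`; attribute `endpoints` summarizes the final OD per well.
#' @export
simulate_growth <- function(spec, rates = NULL) {
  stopifnot(inherits(spec, "growth_sim_spec"))
  set.seed(spec$seed)
  if (is.null(rates)) {
    rates <- purrr::map_dfr(spec$genotypes, evaluate_genotype,
                            pco2_levels = spec$pco2_levels,
                            base = spec$base, chem = spec$chem) |>
      dplyr::select("label", "pCO2", "growth_rate")
  }
  times <- seq(0, spec$duration_h, by = spec$dt_h)
  K <- spec$carrying_capacity
  od0 <- spec$od0
  out <- rates |>
    tidyr::expand_grid(replicate = seq_len(spec$n_replicates)) |>
    purrr::pmap(function(label, pCO2, growth_rate, replicate) {
      mu <- growth_rate
      od <- K * od0 * exp(mu * times) / (K + od0 * (exp(mu * times) - 1))
      if (spec$od_noise_sd > 0) {
        od <- od + rnorm(length(times), 0, spec$od_noise_sd)
      }
      tibble::tibble(label = label, pCO2 = pCO2, replicate = replicate,
                     time_h = times, od = od, growth_rate = mu)
    }) |>
    dplyr::bind_rows()
  endpoints <- out |>
    dplyr::group_by(.data$label, .data$pCO2, .data$replicate) |>
    dplyr::summarise(endpoint_od = .data$od[which.max(.data$time_h)],
                     .groups = "drop")
  attr(out, "endpoints") <- endpoints
  out
}
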