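#' CCM-component genotype
#'
#' A configuration of CO2-concentrating-mechanism components layered on a
#' rubisco-bearing host: a carbonic anhydrase (sets `delta` to `delta_on`),
#' an energized Ci transporter (sets `chi` to `chi_on`), and carboxysome
#' encapsulation (annotation only; the steady-state model has no
#' compartment, so this component carries no mechanistic effect).
#'
#' `delta_on` and `chi_on` defaults sit inside the zero-leakage-feasible
#' region of [leakage_heatmap()] (leak ratio well below 1 for the complete
#' genotype), reflecting modest coexpression rather than the extreme
#' activities of the futile-cycle corner.
#'
#' @param has_CA Express a carbonic anhydrase?
#' @param has_transporter Express an energized Ci transporter?
#' @param has_carboxysome Carboxysome present? (annotation only)
#' @param rubisco_level Rubisco activity `gamma` (s^-1).
#' @param delta_on CA activity when expressed (s^-1).
#' @param chi_on Uptake activity when expressed (s^-1).
#' @param label Optional display label; derived from the flags if `NULL`.
#' @return An object of class `ccm_genotype`.
#' @examples
#' genotype(has_CA = TRUE, has_transporter = TRUE)
#' @export
genotype <- function(has_CA = FALSE, has_transporter = FALSE,
                     has_carboxysome = FALSE, rubisco_level = 90,
                     delta_on = 100, chi_on = 5, label = NULL) {
  for (fl in list(has_CA, has_transporter, has_carboxysome)) {
    if (!is.logical(fl) || length(fl) != 1L || is.na(fl)) {
      abort("Genotype flags must be TRUE or FALSE.")
    }
  }
  if (delta_on <= 0 || chi_on <= 0) abort("`delta_on` and `chi_on` must be > 0.")
  if (rubisco_level < 0) abort("`rubisco_level` must be >= 0.")
  if (is.null(label)) {
    parts <- c("CA", "transporter", "carboxysome")[
      c(has_CA, has_transporter, has_carboxysome)]
    label <- if (length(parts)) paste0("rubisco+", paste(parts, collapse = "+"))
             else "rubisco_alone"
  }
  structure(
    list(has_CA = has_CA, has_transporter = has_transporter,
         has_carboxysome = has_carboxysome, rubisco_level = rubisco_level,
         delta_on = delta_on, chi_on = chi_on, label = label),
    class = "ccm_genotype"
  )
}

#' @export
print.ccm_genotype <- function(x, ...) {
  cat(sprintf("Genotype %s: CA=%s transporter=%s carboxysome=%s gamma=%g\n",
              x$label, x$has_CA, x$has_transporter, x$has_carboxysome,
              x$rubisco_level))
  invisible(x)
}

#' Cell parameters implied by a genotype
#'
#' @param g A [genotype()].
#' @param base Baseline [cell_params()]. The default applies a growth
#'   ceiling `mu_max = 0.25 h^-1`: host physiology (energy supply, other
#'   nutrients) bounds growth once Ci supply is saturating, which is what
#'   makes the CCM dispensable at high CO2.
#' @return A `cell_params` object.
#' @export
genotype_cell <- function(g, base = cell_params(mu_max = 0.25)) {
  stopifnot(inherits(g, "ccm_genotype"))
  update_cell(base,
              gamma = g$rubisco_level,
              delta = if (g$has_CA) g$delta_on else 0,
              chi = if (g$has_transporter) g$chi_on else 0)
}

#' Predicted growth of a genotype across a CO2 ladder
#'
#' @inheritParams genotype_cell
#' @param pco2_levels pCO2 fractions (named or not); default the five assay
#'   conditions.
#' @param chem A [carbonate_params()].
#' @return A tibble: one row per pCO2 with `label`, pools, fluxes and the
#'   growth prediction. Deterministic.
#' @examples
#' evaluate_genotype(genotype(has_CA = TRUE))
#' @export
evaluate_genotype <- function(g, pco2_levels = assay_pco2_levels(),
                              base = cell_params(mu_max = 0.25),
                              chem = carbonate_params()) {
  stopifnot(inherits(g, "ccm_genotype"))
  if (length(pco2_levels) < 1L) abort("`pco2_levels` must be nonempty.")
  cell <- genotype_cell(g, base)
  rows <- purrr::map_dfr(unname(pco2_levels), function(p) {
    model_growth(cell, ci_environment(p), chem)
  })
  dplyr::bind_cols(
    tibble::tibble(label = g$label,
                   condition = if (!is.null(names(pco2_levels)))
                     names(pco2_levels) else NA_character_),
    rows
  )
}

#' Enumerate CCM acquisition trajectories under declining CO2
#'
#' All 3! = 6 orderings in which a CA, a Ci transporter and a carboxysome
#' could be acquired, scored on a declining-CO2 schedule: the ancestral
#' rubisco-only genotype is evaluated at the first (highest) CO2 level and
#' each acquisition step at the next, lower level. A trajectory is
#' "fitness positive" when growth is non-decreasing along the whole path,
#' i.e. each acquisition at least compensates the CO2 decline at which it
#' is evaluated. Carboxysome steps are mechanistically unscored
#' (`scored = FALSE`): they inherit the previous genotype's physiology.
#'
#' @param schedule Declining pCO2 evaluation ladder; must have one more
#'   level than there are components (start + 3 steps). Default
#'   5% -> 1.5% -> 0.5% -> ambient.
#' @inheritParams evaluate_genotype
#' @return A tibble with one row per trajectory step: `trajectory`,
#'   `ordering`, `step` (0 = ancestral), `component_added`, `scored`,
#'   `pCO2`, `growth_rate`, `limiting_regime`, and the per-trajectory flag
#'   `fitness_positive`.
#' @examples
#' trj <- enumerate_trajectories()
#' dplyr::distinct(trj, ordering, fitness_positive)
#' @export
enumerate_trajectories <- function(schedule = c(0.05, 0.015, 0.005, 0.0004),
                                   base = cell_params(mu_max = 0.25),
                                   chem = carbonate_params(),
                                   rubisco_level = 90,
                                   delta_on = 100, chi_on = 5) {
  components <- c("CA", "transporter", "carboxysome")
  if (length(schedule) == 0L) abort("`schedule` must be nonempty.")
  if (length(schedule) != length(components) + 1L) {
    abort(sprintf("`schedule` must have %d levels (start + one per component).",
                  length(components) + 1L))
  }
  if (any(diff(schedule) > 0)) {
    abort("`schedule` must be non-increasing in pCO2 (declining CO2).")
  }
  orderings <- list(
    c("CA", "transporter", "carboxysome"),
    c("CA", "carboxysome", "transporter"),
    c("transporter", "CA", "carboxysome"),
    c("transporter", "carboxysome", "CA"),
    c("carboxysome", "CA", "transporter"),
    c("carboxysome", "transporter", "CA")
  )
  growth_of <- function(has) {
    g <- genotype(has_CA = "CA" %in% has,
                  has_transporter = "transporter" %in% has,
                  has_carboxysome = "carboxysome" %in% has,
                  rubisco_level = rubisco_level,
                  delta_on = delta_on, chi_on = chi_on)
    function(p) {
      row <- model_growth(genotype_cell(g, base), ci_environment(p), chem)
      row[, c("growth_rate", "limiting_regime")]
    }
  }
  purrr::imap_dfr(orderings, function(ord, i) {
    have <- character(0)
    steps <- purrr::map_dfr(0:3, function(k) {
      comp <- if (k == 0) NA_character_ else ord[[k]]
      if (k > 0) have <<- c(have, comp)
      gr <- growth_of(have)(schedule[[k + 1L]])
      tibble::tibble(step = k, component_added = comp,
                     scored = is.na(comp) || comp != "carboxysome",
                     pCO2 = schedule[[k + 1L]],
                     growth_rate = gr$growth_rate,
                     limiting_regime = gr$limiting_regime)
    })
    steps$trajectory <- i
    steps$ordering <- paste(ord, collapse = " -> ")
    steps$fitness_positive <- all(diff(steps$growth_rate) >= -1e-9)
    steps[, c("trajectory", "ordering", "step", "component_added", "scored",
              "pCO2", "growth_rate", "limiting_regime", "fitness_positive")]
  })
}
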