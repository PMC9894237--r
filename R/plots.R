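#' Plot a sweep result
#'
#' Dispatches on the sweep type: growth curves versus CA activity
#' (`growth_vs_ca`), a leak-ratio heatmap with the zero-leakage contour
#' (`leakage_heatmap`), a depletion-ratio heatmap with the 0.5 frontier
#' (`depletion_scan`), the pump ratio versus permeability reduction
#' (`pump_scenario`), or growth versus pCO2 per genotype (`co2_titration`).
#'
#' @param object A `colim_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.colim_sweep <- function(object, ...) {
  type <- attr(object, "sweep_type")
  switch(
    type,
    growth_vs_ca =
      ggplot2::ggplot(object,
                      ggplot2::aes(.data$delta, .data$growth_rate,
                                   colour = factor(.data$gamma),
                                   group = factor(.data$gamma))) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "CA activity δ (1/s)",
                    y = "growth rate (1/h)",
                    colour = "rubisco γ (1/s)"),
    leakage_heatmap = {
      contour <- attr(object, "zero_contour")
      p <- ggplot2::ggplot(object,
                           ggplot2::aes(.data$delta, .data$chi,
                                        fill = asinh(.data$leak_ratio))) +
        ggplot2::geom_raster() +
        ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
        ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                      high = "firebrick") +
        ggplot2::labs(x = "CA activity δ (1/s)",
                      y = "Ci uptake χ (1/s)",
                      fill = "asinh(J_L,tot / J_B)")
      if (!is.null(contour) && any(contour$chi_zero > 0, na.rm = TRUE)) {
        p <- p + ggplot2::geom_line(
          data = dplyr::filter(contour, .data$chi_zero > 0),
          ggplot2::aes(.data$delta, .data$chi_zero),
          inherit.aes = FALSE, linetype = 2)
      }
      p
    },
    depletion_scan =
      ggplot2::ggplot(object,
                      ggplot2::aes(.data$gamma, .data$P_C,
                                   fill = .data$depletion_ratio)) +
      ggplot2::geom_raster() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::geom_line(data = attr(object, "frontier"),
                         ggplot2::aes(.data$gamma_half, .data$P_C),
                         inherit.aes = FALSE, linetype = 2) +
      ggplot2::labs(x = "rubisco γ (1/s)", y = "P_C (cm/s)",
                    fill = "C_in / C_out"),
    pump_scenario =
      ggplot2::ggplot(object,
                      ggplot2::aes(.data$reduction, .data$pump_ratio)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 2, linetype = 2) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "fold reduction of P_C", y = "C_in / C_out"),
    co2_titration =
      ggplot2::ggplot(object,
                      ggplot2::aes(.data$pCO2, .data$growth_rate,
                                   colour = .data$label,
                                   group = .data$label)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "pCO2 (fraction of 1 bar)",
                    y = "growth rate (1/h)", colour = "genotype"),
    abort(sprintf("No autoplot method for sweep type '%s'.", type))
  )
}

#' Scatter plot of gene fitness between two replicates
#'
#' @param genes Output of [gene_fitness()].
#' @param rep_a,rep_b Replicate identifiers to compare.
#' @return A ggplot object.
#' @export
plot_replicate_fitness <- function(genes, rep_a, rep_b) {
  wide <- genes |>
    dplyr::filter(.data$replicate %in% c(rep_a, rep_b),
                  !is.na(.data$fitness)) |>
    tidyr::pivot_wider(id_cols = c("gene", "condition"),
                       names_from = "replicate",
                       values_from = "fitness") |>
    dplyr::filter(!is.na(.data[[rep_a]]), !is.na(.data[[rep_b]]))
  ggplot2::ggplot(wide, ggplot2::aes(.data[[rep_a]], .data[[rep_b]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = sprintf("gene fitness, %s (log2)", rep_a),
                  y = sprintf("gene fitness, %s (log2)", rep_b))
}
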