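#' Per-strain competition fitness
#'
#' For each barcoded mutant strain, fitness is the log2 ratio of its
#' relative abundance at the endpoint of a pooled competition over its
#' relative abundance in the T0 reference: a value of -2 means a fourfold
#' drop in abundance. Abundances are within-sample frequencies
#' (`count / sample total`), so the statistic is invariant to row order
#' and (up to the pseudocount) to sequencing depth. A pseudocount of
#' `pseudocount` reads, expressed as a frequency via each sample's total,
#' regularizes zero counts:
#' `log2((f_end + eps_end) / (f_T0 + eps_T0))` with
#' `eps = pseudocount / total`.
#'
#' @param counts A data frame with columns `barcode`, `gene`, `replicate`,
#'   `condition`, `count` (long "poolcount" layout; extra columns are
#'   carried along silently). T0 reference rows are identified by
#'   `condition == t0`, and must be present for every replicate.
#' @param t0 Condition label of the T0 reference samples.
#' @param pseudocount Pseudocount in reads (default 0.5).
#' @return A tibble with one row per barcode x replicate x endpoint
#'   condition: `barcode`, `gene`, `replicate`, `condition`, `n_t0`,
#'   `n_end`, `fitness` (log2 units).
#' @examples
#' counts <- tibble::tibble(
#'   barcode = rep(c("b1", "b2"), 2), gene = rep(c("g1", "g2"), 2),
#'   replicate = "r1", condition = rep(c("T0", "low"), each = 2),
#'   count = c(100, 100, 25, 175)
#' )
#' strain_fitness(counts)
#' @export
strain_fitness <- function(counts, t0 = "T0", pseudocount = 0.5) {
  counts <- tibble::as_tibble(counts)
  need <- c("barcode", "gene", "replicate", "condition", "count")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort(sprintf("`counts` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    abort("`count` must contain nonnegative integers.")
  }
  multi <- counts |>
    dplyr::distinct(.data$barcode, .data$gene) |>
    dplyr::count(.data$barcode) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(sprintf("Barcode(s) map to more than one gene: %s",
                  paste(utils::head(multi$barcode, 3), collapse = ", ")))
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")

  totals <- counts |>
    dplyr::group_by(.data$replicate, .data$condition) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  if (all(totals$total == 0)) abort("All sample totals are zero.")

  t0_reps <- totals$replicate[totals$condition == t0]
  missing_t0 <- setdiff(unique(counts$replicate), t0_reps)
  if (length(missing_t0)) {
    abort(sprintf("No '%s' reference sample for replicate(s): %s", t0,
                  paste(missing_t0, collapse = ", ")))
  }

  freq <- counts |>
    dplyr::left_join(totals, by = c("replicate", "condition")) |>
    dplyr::mutate(f = ifelse(.data$total > 0, .data$count / .data$total, 0),
                  eps = ifelse(.data$total > 0, pseudocount / .data$total, 0))

  ref <- freq |>
    dplyr::filter(.data$condition == t0) |>
    dplyr::select("barcode", "gene", "replicate",
                  n_t0 = "count", f_t0 = "f", eps_t0 = "eps",
                  total_t0 = "total")
  end <- freq |>
    dplyr::filter(.data$condition != t0) |>
    dplyr::select("barcode", "gene", "replicate", "condition",
                  n_end = "count", f_end = "f", eps_end = "eps",
                  total_end = "total")

  joined <- dplyr::inner_join(end, ref,
                              by = c("barcode", "gene", "replicate"))
  bad <- joined$total_t0 == 0 & joined$total_end == 0
  if (any(bad)) abort("Both T0 and endpoint totals are zero for some samples.")

  joined |>
    dplyr::mutate(fitness = log2((.data$f_end + .data$eps_end) /
                                 (.data$f_t0 + .data$eps_t0))) |>
    dplyr::select("barcode", "gene", "replicate", "condition",
                  "n_t0", "n_end", "fitness") |>
    dplyr::arrange(.data$condition, .data$replicate, .data$gene,
                   .data$barcode)
}

#' Gene-level fitness
#'
#' Aggregates strain fitness to genes: for each gene x replicate x
#' condition, the (by default unweighted) mean over the insertion strains
#' passing the T0 read filter. Genes whose strains all fail the filter are
#' flagged (`flagged = TRUE`, `fitness = NA`) rather than dropped.
#'
#' @param strains Output of [strain_fitness()].
#' @param min_t0_reads Strains with fewer T0 reads are excluded (default 3).
#' @param weighted If `TRUE`, weight strains by their T0 read count instead
#'   of averaging equally.
#' @return A tibble: `gene`, `replicate`, `condition`, `fitness`,
#'   `n_strains` (passing), `flagged`.
#' @export
gene_fitness <- function(strains, min_t0_reads = 3, weighted = FALSE) {
  need <- c("gene", "replicate", "condition", "n_t0", "fitness")
  missing_cols <- setdiff(need, names(strains))
  if (length(missing_cols)) {
    abort(sprintf("`strains` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  strains |>
    dplyr::group_by(.data$gene, .data$replicate, .data$condition) |>
    dplyr::summarise(
      n_strains = sum(.data$n_t0 >= min_t0_reads),
      fitness = {
        ok <- .data$n_t0 >= min_t0_reads
        if (!any(ok)) NA_real_
        else if (weighted) {
          stats::weighted.mean(.data$fitness[ok], w = .data$n_t0[ok])
        } else mean(.data$fitness[ok])
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n_strains == 0L) |>
    dplyr::select("gene", "replicate", "condition", "fitness",
                  "n_strains", "flagged")
}

#' Between-replicate concordance of gene fitness
#'
#' Pearson correlation of gene-level fitness between every pair of
#' replicates, per condition, over the genes measured (non-flagged) in
#' both. At realistic depth replicate assays are strongly correlated
#' (R well above 0.85).
#'
#' @param genes Output of [gene_fitness()].
#' @param condition Optional condition filter (default: all endpoint
#'   conditions present).
#' @return A tibble: `condition`, `rep_a`, `rep_b`, `r`, `n_genes`.
#' @export
replicate_concordance <- function(genes, condition = NULL) {
  need <- c("gene", "replicate", "condition", "fitness")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols)) {
    abort(sprintf("`genes` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(condition)) {
    genes <- dplyr::filter(genes, .data$condition %in% !!condition)
  }
  out <- genes |>
    dplyr::filter(!is.na(.data$fitness)) |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      reps <- sort(unique(df$replicate))
      if (length(reps) < 2L) {
        abort("Need at least two replicates per condition.")
      }
      pairs <- utils::combn(reps, 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(pr) {
        a <- df[df$replicate == pr[[1]], c("gene", "fitness")]
        b <- df[df$replicate == pr[[2]], c("gene", "fitness")]
        shared <- dplyr::inner_join(a, b, by = "gene",
                                    suffix = c("_a", "_b"))
        if (nrow(shared) < 3L) {
          abort("Fewer than 3 shared genes between replicates.")
        }
        tibble::tibble(rep_a = pr[[1]], rep_b = pr[[2]],
                       r = cor(shared$fitness_a, shared$fitness_b),
                       n_genes = nrow(shared))
      })
    }) |>
    dplyr::ungroup()
  out
}

#' Distribution summary of fitness values
#'
#' @param x A tibble with a `fitness` column ([strain_fitness()] or
#'   [gene_fitness()] output).
#' @return A one-row tibble: `n`, `median`, `iqr_lo`, `iqr_hi` (25th/75th
#'   percentiles).
#' @export
fitness_summary <- function(x) {
  v <- x$fitness[!is.na(x$fitness)]
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  tibble::tibble(n = length(v), median = median(v),
                 iqr_lo = q[[1]], iqr_hi = q[[2]])
}

#' Read a poolcount-style TSV of barcode counts
#'
#' Expected columns: `barcode`, `gene`, `replicate`, `condition`, `count`
#' (extra columns such as `scaffold`/`pos` are kept).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble suitable for [strain_fitness()].
#' @export
read_poolcount <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("barcode", "gene", "replicate", "condition", "count")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols)) {
    abort(sprintf("'%s' lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  out
}
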