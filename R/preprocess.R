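#' Subset an expression matrix to one condition and an optional dose range
#'
#' Selects the samples of a condition, optionally restricted to doses strictly
#' below a cutoff (in molar units), preserving the matrix's sample order.
#' Restricting an exposure series to doses below 12.5e-6 M, for example,
#' isolates the low-dose part of a dose-response curve.
#'
#' @param expr genes x samples matrix.
#' @param meta sample metadata tibble (`sample_id`, `condition`, `dose_molar`).
#' @param condition condition label to keep.
#' @param max_dose_exclusive optional molar cutoff; samples with
#'   `dose_molar < max_dose_exclusive` are kept. `NULL` keeps all doses.
#' @return the expression matrix restricted to the selected samples.
#' @export
subset_condition <- function(expr, meta, condition, max_dose_exclusive = NULL) {
  validate_expression(expr)
  validate_metadata(meta, expr)
  if (!condition %in% meta$condition) {
    abort(paste0("condition not present in metadata: ", condition),
          class = "dosenet_validation_error")
  }
  keep <- meta$condition == condition
  if (!is.null(max_dose_exclusive)) {
    keep <- keep & meta$dose_molar < max_dose_exclusive
  }
  ids <- intersect(colnames(expr), meta$sample_id[keep])
  if (length(ids) == 0) {
    abort(sprintf(
      "no samples left for condition '%s'%s", condition,
      if (is.null(max_dose_exclusive)) "" else
        sprintf(" with dose < %g M", max_dose_exclusive)),
      class = "dosenet_validation_error")
  }
  expr[, ids, drop = FALSE]
}

#' Keep the most highly expressed genes by rank-means
#'
#' Within each sample, genes are ranked ascending by expression (midranks for
#' ties); genes are then ordered by their mean rank across samples,
#' descending, and the top `top_n` retained. Ties on mean rank are broken
#' lexicographically by gene id, so the filter is deterministic. Because it
#' is rank-based, the selection is invariant to any strictly monotone
#' per-sample transform of the data.
#'
#' @param expr genes x samples matrix.
#' @param top_n number of genes to keep (>= 2).
#' @return the matrix restricted to the selected genes, original row order
#'   preserved.
#' @export
rank_mean_filter <- function(expr, top_n) {
  validate_expression(expr)
  if (top_n < 2) {
    abort("top_n must be >= 2", class = "dosenet_validation_error")
  }
  ranks <- apply(expr, 2, rank)          # within-sample, midranks for ties
  mean_rank <- rowMeans(ranks)
  ord <- order(-mean_rank, rownames(expr))
  keep <- sort(ord[seq_len(min(top_n, nrow(expr)))])
  expr[keep, , drop = FALSE]
}
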