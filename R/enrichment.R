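#' Gene-set over-representation in a module by Fisher's exact test
#'
#' Tests each set of a library (typically transcription-factor target sets)
#' for over-representation in a module's genes against a gene universe,
#' using the one-sided (enrichment) Fisher exact test — the hypergeometric
#' upper tail `P(X >= overlap)` of the 2x2 table (overlap, module-only,
#' set-only, rest). Sets are intersected with the universe first; sets with
#' an empty intersection are skipped (logged). P-values are
#' Benjamini-Hochberg-adjusted within the result (one module x one library
#' family).
#'
#' @param module_genes character vector of module gene ids (subset of
#'   `universe`).
#' @param library a `gene_set_library` from [read_gmt()] or a named list of
#'   character vectors.
#' @param universe background gene ids, normally the network's analyzed
#'   (filtered) genes.
#' @param module optional module label recorded in the table.
#' @return tibble (`module`, `set_name`, `overlap`, `module_size`,
#'   `set_size`, `universe`, `p`, `adj_p`) ordered by `adj_p`.
#' @export
fisher_enrichment <- function(module_genes, library, universe,
                              module = NA_character_) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    abort("empty universe", class = "dosenet_validation_error")
  }
  module_genes <- unique(module_genes)
  outside <- setdiff(module_genes, universe)
  if (length(outside) > 0) {
    abort(paste0("module genes outside the universe: ",
                 paste(head(outside, 10), collapse = ", ")),
          class = "dosenet_validation_error")
  }
  n_univ <- length(universe)
  n_mod <- length(module_genes)
  rows <- purrr::imap(unclass(library), function(set, nm) {
    set <- intersect(unique(set), universe)
    if (length(set) == 0) return(NULL)
    k <- length(intersect(module_genes, set))
    # hypergeometric upper tail P(X >= k)
    p <- phyper(k - 1, length(set), n_univ - length(set), n_mod,
                lower.tail = FALSE)
    tibble(module = module, set_name = nm, overlap = k,
           module_size = n_mod, set_size = length(set),
           universe = n_univ, p = min(p, 1))
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    inform(sprintf("%d set(s) with empty universe intersection skipped", skipped))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out |>
    mutate(adj_p = bh_adjust(.data$p)) |>
    arrange(.data$adj_p, .data$p, .data$set_name)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`:
#' `adj_p_(i) = min_{j >= i} (m p_(j) / j)`, capped at 1, mapped back to the
#' input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "dosenet_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Genes private to one network's significant modules
#'
#' The union of genes in one condition's significant modules minus the gene
#' universe of a comparison network — e.g. the genes driving a low-dose
#' response that the reference exposure's network never even analyzed.
#'
#' @param significant_partition tibble (`gene_id`, `module`) restricted to
#'   the significant modules of condition A.
#' @param universe_b gene ids of the comparison network.
#' @return character vector of gene ids.
#' @export
network_unique_genes <- function(significant_partition, universe_b) {
  setdiff(unique(significant_partition$gene_id), universe_b)
}
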