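#' Degrees of module genes in the module-induced interaction subgraph
#'
#' Restricts an external (protein-protein style) edge list to edges with
#' both ends in the module and counts per-gene degrees. The module's average
#' node degree is `2 E_within / |module|`; genes without edges count with
#' degree 0.
#'
#' @param module_genes character vector of module gene ids.
#' @param edges tibble (`gene_a`, `gene_b`, optional `score`).
#' @return list with `degrees` (tibble `gene_id`, `degree`) and
#'   `average_degree`.
#' @export
module_degree <- function(module_genes, edges) {
  module_genes <- unique(module_genes)
  within <- edges$gene_a %in% module_genes & edges$gene_b %in% module_genes
  sub <- edges[within, , drop = FALSE]
  if (nrow(sub) > 0) {
    g <- igraph::graph_from_data_frame(sub[, c("gene_a", "gene_b")],
                                       directed = FALSE,
                                       vertices = module_genes)
    deg <- igraph::degree(g)[module_genes]
  } else {
    deg <- setNames(rep(0, length(module_genes)), module_genes)
  }
  list(
    degrees = tibble(gene_id = module_genes, degree = as.integer(deg)),
    average_degree = 2 * nrow(sub) / length(module_genes)
  )
}

#' Hub genes: high intramodular kME and high interaction degree
#'
#' Per module, hub candidates are the genes in the top fraction both by
#' own-module kME and by degree in the module-induced subgraph of an
#' external interaction network; the intersection is returned ranked by kME.
#' Rank cutoffs use `ceiling(top_fraction * module size)` with ties at the
#' boundary included, so shrinking `top_fraction` can only shrink the list.
#'
#' @param kme_mat genes x modules kME matrix from [kme()].
#' @param partition tibble (`gene_id`, `module`).
#' @param edges interaction edge list tibble.
#' @param top_fraction fraction defining "high-ranking" (default 0.1).
#' @return tibble (`module`, `gene_id`, `kme`, `degree`), hubs only.
#' @export
hub_candidates <- function(kme_mat, partition, edges, top_fraction = 0.1) {
  mods <- setdiff(unique(partition$module), "grey")
  missing_m <- setdiff(mods, colnames(kme_mat))
  if (length(missing_m) > 0) {
    abort(paste0("module(s) absent from kME matrix: ",
                 paste(missing_m, collapse = ", ")),
          class = "dosenet_validation_error")
  }
  rows <- lapply(mods, function(mod) {
    genes <- partition$gene_id[partition$module == mod]
    kv <- kme_mat[genes, mod]
    dv <- module_degree(genes, edges)$degrees
    deg <- setNames(dv$degree, dv$gene_id)[genes]
    n_top <- ceiling(top_fraction * length(genes))
    if (n_top < 1) return(NULL)
    k_cut <- sort(kv, decreasing = TRUE)[n_top]
    d_cut <- sort(deg, decreasing = TRUE)[n_top]
    hubs <- genes[kv >= k_cut & deg >= d_cut]
    if (length(hubs) == 0) return(NULL)
    tibble(module = mod, gene_id = hubs,
           kme = unname(kv[hubs]), degree = unname(deg[hubs])) |>
      arrange(desc(.data$kme))
  })
  bind_rows(rows)
}
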