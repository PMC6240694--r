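#' Run the full single-condition network analysis
#'
#' Orchestrates the pipeline for one exposure series: subset samples to the
#' condition (optionally below a dose cutoff), keep the top genes by
#' rank-means, build the signed soft-thresholded Spearman network and its
#' topological overlap, cluster with average linkage, cut modules
#' adaptively, merge similar modules, reassign poorly placed genes, and
#' correlate module eigengenes with dose. Optional gene-set and interaction
#' inputs add enrichment of the significant modules and hub identification.
#'
#' @param expr genes x samples matrix.
#' @param meta sample metadata tibble.
#' @param condition condition label to analyze.
#' @param max_dose_exclusive optional molar dose cutoff (strict).
#' @param top_n genes kept by the rank-means filter (default 10000).
#' @param beta soft power (default 10).
#' @param deep_split tree-cut sensitivity 0-4 (default 2).
#' @param min_module_size smallest module (default 30).
#' @param merge_cut_height eigengene merge height (default 0.25).
#' @param reassign_threshold p-value ratio for reassignment (default 0.2).
#' @param alpha module-trait significance threshold (default 0.01).
#' @param min_kme_to_stay genes with own-module kME below this are demoted
#'   to grey (default 0.3; see [prune_low_kme()]).
#' @param trait_transform dose encoding, see [dose_trait()].
#' @param gene_sets optional `gene_set_library` for enrichment of
#'   significant modules.
#' @param edges optional interaction edge list for hub detection.
#' @param hub_top_fraction top fraction for both hub criteria (default 0.1).
#' @param max_block_size refuse networks larger than this many genes
#'   (default 10000); filter harder instead.
#' @return an object of class `network_fit`.
#' @export
run_condition_network <- function(expr, meta, condition,
                                  max_dose_exclusive = NULL,
                                  top_n = 10000, beta = 10, deep_split = 2,
                                  min_module_size = 30,
                                  merge_cut_height = 0.25,
                                  reassign_threshold = 0.2, alpha = 0.01,
                                  min_kme_to_stay = 0.3,
                                  trait_transform = "ordinal",
                                  gene_sets = NULL, edges = NULL,
                                  hub_top_fraction = 0.1,
                                  max_block_size = 10000) {
  sub <- subset_condition(expr, meta, condition, max_dose_exclusive)
  sub <- rank_mean_filter(sub, top_n)
  if (nrow(sub) > max_block_size) {
    abort(sprintf(
      "network of %d genes exceeds max_block_size = %d; use a stronger top_n filter",
      nrow(sub), max_block_size), class = "dosenet_validation_error")
  }
  tom <- topological_overlap(signed_adjacency(spearman_correlation(sub), beta))
  dendro <- average_linkage(1 - tom)
  partition <- dynamic_tree_cut(dendro, 1 - tom, deep_split, min_module_size)
  if (all(partition$module == "grey")) {
    abort("no modules detected", class = "dosenet_computation_error")
  }
  merged <- merge_close_modules(sub, partition, merge_cut_height)
  res <- reassign_genes(sub, merged$partition, merged$eigengenes,
                        reassign_threshold)
  res <- prune_low_kme(sub, res$partition, min_kme_to_stay)
  trait <- dose_trait(meta, colnames(sub), trait_transform)
  trait_table <- eigengene_trait_correlation(res$eigengenes, trait,
                                             condition = condition)
  significant <- select_significant(trait_table, alpha)
  kme_mat <- kme(sub, res$eigengenes)
  own_kme <- vapply(seq_len(nrow(res$partition)), function(i) {
    mod <- res$partition$module[i]
    if (mod == "grey") NA_real_ else kme_mat[res$partition$gene_id[i], mod]
  }, numeric(1))
  partition_tbl <- res$partition |> mutate(kme_own = own_kme)

  enrichment <- NULL
  if (!is.null(gene_sets) && nrow(significant) > 0) {
    universe <- rownames(sub)
    enrichment <- bind_rows(lapply(significant$module, function(mod) {
      fisher_enrichment(
        partition_tbl$gene_id[partition_tbl$module == mod],
        gene_sets, universe, module = mod)
    }))
  }
  hubs <- NULL
  if (!is.null(edges)) {
    sig_part <- partition_tbl |> filter(.data$module %in% significant$module)
    hubs <- hub_candidates(kme_mat, sig_part, edges, hub_top_fraction)
  }
  structure(list(
    condition = condition, expression = sub,
    parameters = list(
      condition = condition, max_dose_exclusive = max_dose_exclusive,
      top_n = top_n, beta = beta, deep_split = deep_split,
      min_module_size = min_module_size,
      merge_cut_height = merge_cut_height,
      reassign_threshold = reassign_threshold, alpha = alpha,
      min_kme_to_stay = min_kme_to_stay,
      trait_transform = trait_transform,
      hub_top_fraction = hub_top_fraction),
    dendrogram = dendro, partition = partition_tbl,
    eigengenes = res$eigengenes, kme = kme_mat,
    trait = trait, trait_table = trait_table, significant = significant,
    enrichment = enrichment, hubs = hubs
  ), class = "network_fit")
}

#' Run the consensus network analysis across two or more conditions
#'
#' Builds one network per condition on the shared gene universe (the
#' intersection of the per-condition rank-means top lists, logged),
#' calibrates the per-condition TOMs to a common scale, takes their
#' entrywise minimum as the consensus TOM, detects consensus modules
#' (minimum size 100 by convention), and summarizes the per-condition
#' eigengene-dose correlations into the conservative consensus
#' relationship.
#'
#' @inheritParams run_condition_network
#' @param conditions character vector of >= 2 condition labels.
#' @param min_module_size smallest consensus module (default 100).
#' @param alpha consensus significance threshold (default 0.05).
#' @param calibrate calibrate TOMs before the minimum (default TRUE).
#' @param calibration_quantile quantile used by [calibrate_toms()].
#' @return an object of class `consensus_fit`.
#' @export
run_consensus_network <- function(expr, meta, conditions,
                                  top_n = 10000, beta = 10, deep_split = 2,
                                  min_module_size = 100,
                                  merge_cut_height = 0.25, alpha = 0.05,
                                  min_kme_to_stay = 0.3,
                                  trait_transform = "ordinal",
                                  calibrate = TRUE,
                                  calibration_quantile = 0.95,
                                  max_block_size = 10000) {
  if (length(conditions) < 2) {
    abort("consensus needs >= 2 conditions", class = "dosenet_validation_error")
  }
  subsets <- lapply(conditions, function(cc) {
    rank_mean_filter(subset_condition(expr, meta, cc), top_n)
  })
  names(subsets) <- conditions
  universe <- Reduce(intersect, lapply(subsets, rownames))
  inform(sprintf("consensus gene universe: %d gene(s) (intersection of top-%d lists)",
                 length(universe), top_n))
  if (length(universe) < min_module_size) {
    abort("consensus gene universe smaller than min_module_size",
          class = "dosenet_validation_error")
  }
  subsets <- lapply(subsets, function(s) s[universe, , drop = FALSE])
  if (length(universe) > max_block_size) {
    abort("consensus network exceeds max_block_size",
          class = "dosenet_validation_error")
  }
  toms <- lapply(subsets, function(s) {
    topological_overlap(signed_adjacency(spearman_correlation(s), beta))
  })
  calibrated <- if (calibrate) calibrate_toms(toms, calibration_quantile) else toms
  cons <- consensus_tom(calibrated)
  dendro <- average_linkage(1 - cons)
  partition <- dynamic_tree_cut(dendro, 1 - cons, deep_split, min_module_size)
  if (all(partition$module == "grey")) {
    abort("no consensus modules detected", class = "dosenet_computation_error")
  }
  # merge on the eigengenes of the pooled conditions so the partition stays
  # one object across conditions
  pooled <- do.call(cbind, subsets)
  merged <- merge_close_modules(pooled, partition, merge_cut_height)
  partition <- prune_low_kme(subsets, merged$partition,
                             min_kme_to_stay)$partition

  per_condition <- lapply(conditions, function(cc) {
    eig <- module_eigengene(subsets[[cc]], partition)
    trait <- dose_trait(meta, colnames(subsets[[cc]]), trait_transform)
    eigengene_trait_correlation(eig, trait, condition = cc)
  })
  names(per_condition) <- conditions
  consensus_table <- consensus_trait_relationship(per_condition)
  significant <- consensus_table |>
    filter(!is.na(.data$consensus_p), .data$consensus_p < alpha) |>
    arrange(desc(.data$consensus_r))
  structure(list(
    conditions = conditions, universe = universe,
    parameters = list(top_n = top_n, beta = beta, deep_split = deep_split,
                      min_module_size = min_module_size,
                      merge_cut_height = merge_cut_height, alpha = alpha,
                      min_kme_to_stay = min_kme_to_stay,
                      trait_transform = trait_transform,
                      calibrate = calibrate,
                      calibration_quantile = calibration_quantile,
                      scale_factors = if (calibrate)
                        vapply(calibrated, attr, numeric(1), "scale_factor")
                      else NULL),
    dendrogram = dendro, partition = partition,
    per_condition = per_condition, consensus_table = consensus_table,
    significant = significant
  ), class = "consensus_fit")
}

#' Write the result tables and run report of a fit to a directory
#'
#' Emits TSV tables (module assignments with own-module kME, eigengenes,
#' module-trait statistics, enrichment, hubs — whichever the fit contains)
#' and a machine-readable JSON run report with all effective parameters and
#' package version.
#'
#' @param fit a `network_fit` or `consensus_fit`.
#' @param dir output directory, created if needed.
#' @param seed optional seed recorded in the run report.
#' @return `dir`, invisibly.
#' @export
write_network_results <- function(fit, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f))
  w(fit$partition, "modules.tsv")
  if (!is.null(fit$eigengenes)) {
    eig <- as_tibble(t(fit$eigengenes$profiles), rownames = "module")
    w(eig, "eigengenes.tsv")
  }
  if (!is.null(fit$trait_table)) w(fit$trait_table, "module_trait.tsv")
  if (!is.null(fit$consensus_table)) {
    w(fit$consensus_table, "consensus_trait.tsv")
    w(bind_rows(fit$per_condition), "module_trait_per_condition.tsv")
  }
  if (!is.null(fit$significant)) w(fit$significant, "significant_modules.tsv")
  if (!is.null(fit$enrichment) && nrow(fit$enrichment %||% tibble()) > 0) {
    w(fit$enrichment, "enrichment.tsv")
  }
  if (!is.null(fit$hubs) && nrow(fit$hubs %||% tibble()) > 0) {
    w(fit$hubs, "hubs.tsv")
  }
  report <- list(
    class = class(fit)[1],
    condition = fit$condition %||% fit$conditions,
    parameters = fit$parameters,
    n_genes = if (!is.null(fit$expression)) nrow(fit$expression)
              else length(fit$universe),
    n_modules = length(setdiff(unique(fit$partition$module), "grey")),
    seed = seed,
    package_version = as.character(utils::packageVersion("dosenet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
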