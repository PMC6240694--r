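#' Average-linkage (UPGMA) clustering of a TOM dissimilarity
#'
#' @param dissim symmetric dissimilarity matrix, typically `1 - TOM`.
#' @return an [stats::hclust] tree over the genes.
#' @export
average_linkage <- function(dissim) {
  if (!isSymmetric(unname(dissim), tol = 1e-8)) {
    abort("dissimilarity must be symmetric", class = "dosenet_validation_error")
  }
  hclust(as.dist(dissim), method = "average")
}

# deep-split sensitivity -> (max core scatter, min branch gap), both as
# fractions of the height range between the cut height and the 5th
# percentile of merge heights
deep_split_map <- list(
  `0` = c(0.64, 0.27),
  `1` = c(0.73, 0.2025),
  `2` = c(0.82, 0.135),
  `3` = c(0.91, 0.0675),
  `4` = c(0.95, 0.0375)
)

module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna",
  "yellowgreen", "lightcyan1", "plum", "ivory", "orangered"
)

#' Relabel modules by decreasing size using the conventional color sequence
#'
#' Labels carry no semantics; color names are used only for human
#' comparability with the usual co-expression reporting convention. Ties in
#' size are broken by the smallest member gene id, so relabeling is
#' deterministic. The reserved label `"grey"` (unassigned) is kept as is.
#'
#' @param partition tibble with columns `gene_id`, `module`.
#' @return relabeled partition tibble.
#' @export
relabel_partition <- function(partition) {
  mods <- partition |>
    filter(.data$module != "grey") |>
    group_by(.data$module) |>
    summarise(size = n(), first_gene = min(.data$gene_id), .groups = "drop") |>
    arrange(desc(.data$size), .data$first_gene)
  if (nrow(mods) > length(module_colors)) {
    new <- c(module_colors,
             sprintf("module%03d", seq_len(nrow(mods) - length(module_colors))))
  } else {
    new <- module_colors
  }
  lut <- setNames(new[seq_len(nrow(mods))], mods$module)
  lut <- c(lut, grey = "grey")
  partition |> mutate(module = unname(lut[.data$module]))
}

#' Adaptive dendrogram cut into co-expression modules
#'
#' Cuts an average-linkage tree of TOM dissimilarities into modules by
#' recursive branch acceptance. A static cut at 0.99 x the top merge height
#' defines candidate branches; a branch is accepted as a module when it has
#' at least `min_module_size` genes, its core scatter (mean pairwise
#' dissimilarity among its members) is small, and it is separated from its
#' surroundings by a sufficient gap between the height at which it attaches
#' to the rest of the tree and its core scatter. Scatter and gap are
#' assessed relative to the range between the cut height and the 5th
#' percentile of merge heights; the thresholds are set by `deep_split`
#' (0 = conservative, 4 = aggressive). An accepted branch is split further
#' only where its subtree decomposes into two or more acceptable
#' sub-branches; with at most one, the branch stays whole, so loosely
#' attached genes ride along with their module instead of fragmenting it.
#' Genes in no accepted branch get the reserved label `"grey"`.
#'
#' @param dendro an [stats::hclust] tree from [average_linkage()].
#' @param dissim the dissimilarity matrix the tree was built from
#'   (`1 - TOM`), gene order matching `dendro$labels`.
#' @param deep_split integer 0-4 controlling split sensitivity (default 2).
#' @param min_module_size smallest allowed module (default 30).
#' @return tibble with columns `gene_id`, `module` (color labels ordered by
#'   decreasing module size; `"grey"` = unassigned).
#' @export
dynamic_tree_cut <- function(dendro, dissim, deep_split = 2,
                             min_module_size = 30) {
  if (!as.character(deep_split) %in% names(deep_split_map)) {
    abort("deep_split must be an integer in 0..4",
          class = "dosenet_validation_error")
  }
  thr <- deep_split_map[[as.character(deep_split)]]
  max_core_scatter <- thr[1]
  min_gap <- thr[2]

  genes <- dendro$labels
  n <- length(genes)
  if (min_module_size > n) {
    warn("min_module_size exceeds the number of genes; all genes unassigned")
    return(tibble(gene_id = genes, module = "grey"))
  }
  if (!identical(rownames(dissim), genes) && !is.null(rownames(dissim))) {
    abort("dissimilarity gene order must match the dendrogram",
          class = "dosenet_validation_error")
  }
  h <- dendro$height
  m <- dendro$merge
  cut_height <- 0.99 * max(h)
  q5 <- quantile(h, 0.05, names = FALSE)
  denom <- max(cut_height - q5, .Machine$double.eps)

  # per internal node: member leaves and the sum of pairwise dissimilarities
  # among them (built incrementally: within-left + within-right + cross)
  members <- vector("list", nrow(m))
  pair_sum <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    pick <- function(j) if (j < 0) -j else members[[j]]
    a <- pick(m[i, 1])
    b <- pick(m[i, 2])
    members[[i]] <- c(a, b)
    sub <- function(j) if (j < 0) 0 else pair_sum[j]
    pair_sum[i] <- sub(m[i, 1]) + sub(m[i, 2]) +
      sum(dissim[a, b, drop = FALSE])
  }
  node_size <- function(j) if (j < 0) 1L else length(members[[j]])
  # core scatter: mean pairwise dissimilarity among the branch's members
  node_scatter <- function(j) {
    if (j < 0) return(q5)
    s <- length(members[[j]])
    pair_sum[j] / (s * (s - 1) / 2)
  }

  qualifies <- function(j, attach_h) {
    if (node_size(j) < min_module_size) return(FALSE)
    raw <- node_scatter(j)
    scatter <- (raw - q5) / denom
    gap <- (attach_h - raw) / denom
    scatter <= max_core_scatter && gap >= min_gap
  }
  # maximal acceptable branches under `j`: an acceptable branch is split
  # only when its subtree decomposes into >= 2 acceptable sub-branches;
  # with <= 1 the branch stays whole, so loosely attached genes ride along
  # with their module instead of fragmenting it
  collect <- function(j, attach_h) {
    if (j < 0) return(list())
    below <- c(collect(m[j, 1], h[j]), collect(m[j, 2], h[j]))
    if (!qualifies(j, attach_h)) return(below)
    if (length(below) >= 2) below else list(members[[j]])
  }

  # static cut defines the top-level branches
  top <- cutree_nodes(m, h, cut_height)
  found <- list()
  for (j in top) {
    found <- c(found, collect(j, Inf))
  }
  labels <- rep("grey", n)
  for (i in seq_along(found)) {
    labels[found[[i]]] <- sprintf("M%04d", i)
  }
  relabel_partition(tibble(gene_id = genes, module = labels))
}

# root nodes of the branches obtained by cutting the tree at `cut_height`;
# encoded as hclust does: negative = single leaf, positive = merge row
cutree_nodes <- function(merge, height, cut_height) {
  n_merges <- nrow(merge)
  absorbed <- rep(FALSE, n_merges)      # node became part of a larger branch
  roots <- integer(0)
  leaves_taken <- rep(FALSE, n_merges + 1)
  for (i in seq_len(n_merges)) {
    if (height[i] <= cut_height) {
      for (child in merge[i, ]) {
        if (child > 0) absorbed[child] <- TRUE else leaves_taken[-child] <- TRUE
      }
    }
  }
  for (i in seq_len(n_merges)) {
    if (height[i] <= cut_height && !absorbed[i]) roots <- c(roots, i)
  }
  # leaves never merged below the cut are their own (singleton) branches
  singletons <- which(!leaves_taken)
  c(roots, -singletons)
}
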