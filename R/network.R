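#' Pairwise Spearman correlation between genes
#'
#' Spearman correlation (Pearson on midranks) between all gene pairs of an
#' expression matrix. Genes with zero rank variance (constant across samples)
#' get correlation 0 with every other gene, and the event is logged; the
#' diagonal is always 1.
#'
#' @param expr genes x samples matrix with >= 4 samples and complete data.
#' @return symmetric genes x genes correlation matrix in `[-1, 1]`.
#' @export
spearman_correlation <- function(expr) {
  validate_expression(expr, network = TRUE)
  r <- suppressWarnings(cor(t(expr), method = "spearman"))
  if (anyNA(r)) {
    const <- which(apply(expr, 1, function(x) length(unique(x)) == 1))
    inform(sprintf(
      "%d constant gene(s) have zero rank variance; correlations set to 0",
      length(const)))
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r
}

#' Signed soft-thresholded adjacency
#'
#' Maps correlations into `[0, 1]` with the signed transform
#' `a_ij = ((1 + r_ij) / 2)^beta`, so perfectly anti-correlated genes get
#' adjacency 0 rather than 1, and raises to the soft power `beta` to suppress
#' weak correlations continuously. The diagonal is 1.
#'
#' @param cor_mat symmetric correlation matrix.
#' @param beta soft-thresholding power (>= 1); 10 is the default used for
#'   signed dose-response networks here.
#' @return adjacency matrix in `[0, 1]` with attribute `beta`.
#' @export
signed_adjacency <- function(cor_mat, beta = 10) {
  if (beta < 1) abort("beta must be >= 1", class = "dosenet_validation_error")
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' The topological overlap of genes i and j combines their direct adjacency
#' with the agreement of their neighborhoods:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_u a_iu a_uj` over u != i, j and `k_i` is the connectivity
#' `sum_u a_iu` (u != i). The diagonal is 1, and `1 - TOM` is the clustering
#' dissimilarity. Computed with one matrix product so it scales to 10^4
#' genes.
#'
#' @param adj adjacency matrix from [signed_adjacency()].
#' @return symmetric TOM in `[0, 1]`.
#' @export
topological_overlap <- function(adj) {
  a0 <- adj
  diag(a0) <- 0
  k <- rowSums(a0)
  L <- a0 %*% a0                        # u = i, j terms vanish: diag(a0) = 0
  kmin <- outer(k, k, pmin)
  denom <- pmax(kmin + 1 - a0, 1e-12)
  tom <- (L + a0) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2             # symmetrize away FP asymmetry
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adj)
  attr(tom, "is_consensus") <- FALSE
  tom
}

#' Calibrate TOMs to a common scale before consensus
#'
#' Different conditions yield TOMs on slightly different overall scales; the
#' entrywise-minimum consensus would otherwise be dominated by the condition
#' with the smallest values. Each TOM is rescaled by
#' `s_k = Q_ref / Q_k`, where `Q_k` is its off-diagonal quantile (default
#' 0.95) and `Q_ref` the median of the `Q_k`; values are clipped to
#' `[0, 1]`.
#'
#' @param toms list of TOM matrices over the identical gene set and order.
#' @param probs quantile used for calibration (default 0.95).
#' @return list of calibrated TOMs; each carries attributes `scale_factor`
#'   and `reference_quantile`.
#' @export
calibrate_toms <- function(toms, probs = 0.95) {
  if (length(toms) < 2) {
    abort("calibration needs >= 2 TOMs", class = "dosenet_validation_error")
  }
  genes <- rownames(toms[[1]])
  for (tm in toms[-1]) {
    if (!identical(rownames(tm), genes)) {
      d <- union(setdiff(rownames(tm), genes), setdiff(genes, rownames(tm)))
      abort(paste0("TOM gene sets differ: ",
                   paste(head(d, 10), collapse = ", ")),
            class = "dosenet_validation_error")
    }
  }
  off <- upper.tri(toms[[1]])
  q <- vapply(toms, function(tm) quantile(tm[off], probs, names = FALSE),
              numeric(1))
  q_ref <- median(q)
  purrr::map2(toms, q, function(tm, qk) {
    s <- q_ref / qk
    out <- tm * s
    diag(out) <- 1
    out[out > 1] <- 1
    attr(out, "scale_factor") <- s
    attr(out, "reference_quantile") <- q_ref
    attr(out, "is_consensus") <- FALSE
    out
  })
}

#' Consensus TOM across conditions
#'
#' The entrywise minimum of calibrated TOMs: a gene pair's consensus overlap
#' is only as strong as its weakest condition, so consensus modules reflect
#' co-expression present in every condition.
#'
#' @param calibrated list of calibrated TOMs (see [calibrate_toms()]) over
#'   identical gene order.
#' @return consensus TOM with attribute `is_consensus = TRUE`.
#' @export
consensus_tom <- function(calibrated) {
  genes <- rownames(calibrated[[1]])
  out <- calibrated[[1]]
  for (tm in calibrated[-1]) {
    if (!identical(rownames(tm), genes)) {
      abort("consensus inputs must share gene order",
            class = "dosenet_validation_error")
    }
    out <- pmin(out, tm)
  }
  diag(out) <- 1
  dimnames(out) <- dimnames(calibrated[[1]])
  attr(out, "is_consensus") <- TRUE
  out
}
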