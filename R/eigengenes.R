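#' Module eigengenes: the first principal component of each module
#'
#' Each member gene is z-scored across samples; the module eigengene is the
#' first right-singular vector of the member x sample matrix (unit Euclidean
#' norm), i.e. the sample profile explaining the most member variance. Its
#' sign is fixed so the mean correlation with member gene profiles is
#' non-negative (first nonzero loading positive in the degenerate zero-mean
#' case). Variance explained is the first squared singular value over the
#' total. A 1-gene module's eigengene is its normalized z-profile; constant
#' genes contribute a zero profile.
#'
#' @param expr genes x samples matrix.
#' @param partition tibble with `gene_id`, `module`; `"grey"` is skipped.
#' @return an object of class `eigengene_set`: list with `profiles`
#'   (samples x modules matrix, unit-norm columns) and `var_explained`
#'   (named numeric in (0, 1]).
#' @export
module_eigengene <- function(expr, partition) {
  validate_expression(expr)
  mods <- setdiff(unique(partition$module), "grey")
  if (length(mods) == 0) {
    abort("partition contains no assigned module", class = "dosenet_validation_error")
  }
  ns <- ncol(expr)
  profiles <- matrix(0, nrow = ns, ncol = length(mods),
                     dimnames = list(colnames(expr), mods))
  ve <- setNames(numeric(length(mods)), mods)
  for (mod in mods) {
    g <- partition$gene_id[partition$module == mod]
    z <- z_score_rows(expr[g, , drop = FALSE])
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    # sign convention
    r_mean <- mean(z %*% e)             # mean inner product with members
    if (r_mean < 0) {
      e <- -e
    } else if (r_mean == 0) {
      nz <- which(e != 0)
      if (length(nz) > 0 && e[nz[1]] < 0) e <- -e
    }
    profiles[, mod] <- e
    tot <- sum(sv$d^2)
    ve[mod] <- if (tot > 0) sv$d[1]^2 / tot else 1
  }
  structure(list(profiles = profiles, var_explained = ve),
            class = "eigengene_set")
}

# z-score each row over columns; constant rows become all-zero (logged)
z_score_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  const <- s == 0
  if (any(const)) {
    inform(sprintf("%d constant gene(s) z-scored to zero", sum(const)))
    s[const] <- 1
  }
  (x - mu) / s
}

#' Intramodular membership (kME)
#'
#' Pearson correlation of every gene's expression profile with every module
#' eigengene. A gene's kME with its own module ranks its intramodular
#' connectivity; constant genes get kME 0 (logged).
#'
#' @param expr genes x samples matrix.
#' @param eigengenes an `eigengene_set` from [module_eigengene()].
#' @return genes x modules matrix of correlations in `[-1, 1]`.
#' @export
kme <- function(expr, eigengenes) {
  k <- suppressWarnings(cor(t(expr), eigengenes$profiles))
  if (anyNA(k)) {
    inform(sprintf("%d constant gene(s) assigned kME 0",
                   sum(rowSums(is.na(k)) > 0)))
    k[is.na(k)] <- 0
  }
  k
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengenes are highly correlated describe the same
#' co-expression signal split by the tree cut. Eigengenes are clustered by
#' average linkage on dissimilarity `1 - cor(ME_i, ME_j)`; module groups
#' joined below `merge_cut_height` are unioned and eigengenes recomputed,
#' iterating to a fixed point. `"grey"` never merges.
#'
#' @param expr genes x samples matrix.
#' @param partition tibble with `gene_id`, `module`.
#' @param merge_cut_height eigengene dissimilarity below which modules fuse
#'   (default 0.25, i.e. correlation above 0.75).
#' @return list with relabeled `partition` and recomputed `eigengenes`.
#' @export
merge_close_modules <- function(expr, partition, merge_cut_height = 0.25) {
  partition <- relabel_partition(partition)
  repeat {
    eig <- module_eigengene(expr, partition)
    mods <- colnames(eig$profiles)
    if (length(mods) < 2) break
    d <- 1 - cor(eig$profiles)
    tree <- hclust(as.dist(d), method = "average")
    grp <- cutree(tree, h = merge_cut_height)
    if (max(grp) == length(mods)) break  # nothing below the cut
    lut <- setNames(sprintf("G%04d", grp[mods]), mods)
    partition <- partition |>
      mutate(module = ifelse(.data$module == "grey", "grey",
                             unname(lut[.data$module]))) |>
      relabel_partition()
  }
  list(partition = partition, eigengenes = eig)
}

#' Reassign genes that fit another module's eigengene better
#'
#' For each assigned gene, the correlation with every module eigengene is
#' tested (Student t p-value); the gene moves to module m' when
#' `p_m' < reassign_threshold * p_own` and its kME with m' exceeds its own
#' kME. A single pass over genes (decisions taken against the incoming
#' eigengenes) guarantees termination; eigengenes are recomputed once after
#' the pass.
#'
#' @param expr genes x samples matrix.
#' @param partition tibble with `gene_id`, `module`.
#' @param eigengenes an `eigengene_set` consistent with `partition`.
#' @param reassign_threshold p-value ratio below which a gene is moved
#'   (default 0.2); 0 disables reassignment.
#' @return list with updated `partition` and recomputed `eigengenes`.
#' @export
reassign_genes <- function(expr, partition, eigengenes,
                           reassign_threshold = 0.2) {
  k <- kme(expr, eigengenes)
  n <- ncol(expr)
  p <- correlation_p(k, n)
  mods <- colnames(k)
  module <- partition$module
  names(module) <- partition$gene_id
  moved <- 0L
  for (g in partition$gene_id[partition$module != "grey"]) {
    own <- module[[g]]
    if (!own %in% mods) next
    better <- mods[p[g, ] < reassign_threshold * p[g, own] &
                     k[g, ] > k[g, own]]
    if (length(better) > 0) {
      module[[g]] <- better[which.max(k[g, better])]
      moved <- moved + 1L
    }
  }
  if (moved > 0) inform(sprintf("reassigned %d gene(s)", moved))
  partition <- relabel_partition(tibble(gene_id = partition$gene_id,
                                        module = unname(module[partition$gene_id])))
  list(partition = partition, eigengenes = module_eigengene(expr, partition))
}

#' Prune weakly connected module members
#'
#' Genes whose correlation with their own module eigengene falls below
#' `min_kme` are background riders picked up by the tree cut; they are
#' demoted to `"grey"` and eigengenes recomputed. With several expression
#' matrices (consensus analysis) a gene must clear the threshold in every
#' condition to stay.
#'
#' @param exprs one genes x samples matrix, or a list of them sharing genes.
#' @param partition tibble with `gene_id`, `module`.
#' @param min_kme smallest own-module kME to stay (default 0.3).
#' @return list with pruned, relabeled `partition` and `eigengenes`
#'   (recomputed on the first/only matrix).
#' @export
prune_low_kme <- function(exprs, partition, min_kme = 0.3) {
  if (is.matrix(exprs)) exprs <- list(exprs)
  own <- rep(Inf, nrow(partition))
  for (x in exprs) {
    eig <- module_eigengene(x, partition)
    k <- kme(x, eig)
    ko <- vapply(seq_len(nrow(partition)), function(i) {
      mod <- partition$module[i]
      if (mod == "grey") Inf else k[partition$gene_id[i], mod]
    }, numeric(1))
    own <- pmin(own, ko)
  }
  drop <- own < min_kme
  if (any(drop)) {
    inform(sprintf("pruned %d weakly connected gene(s) (own kME < %g)",
                   sum(drop), min_kme))
    partition$module[drop] <- "grey"
  }
  partition <- relabel_partition(partition)
  list(partition = partition,
       eigengenes = module_eigengene(exprs[[1]], partition))
}

# two-sided Student-t p-value for a correlation at sample size n
correlation_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0, {
    t_stat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
    2 * pt(t_stat, df = n - 2, lower.tail = FALSE)
  })
  p
}
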