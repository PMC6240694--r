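test_that("average linkage reproduces hand and textbook UPGMA merges", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  tree <- average_linkage(d)
  expect_equal(tree$height, c(0.1, 0.9))

  set.seed(21)
  for (i in 1:5) {
    dm <- as.matrix(dist(matrix(rnorm(20 * 4), 20)))
    dimnames(dm) <- list(paste0("g", 1:20), paste0("g", 1:20))
    tree <- average_linkage(dm)
    expect_equal(sort(tree$height), upgma_heights(dm), tolerance = 1e-12)
  }
})

test_that("two planted blocks are cut into exactly two complete modules", {
  n <- 50
  d <- matrix(0.9, 2 * n, 2 * n)
  d[1:n, 1:n] <- 0.1
  d[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:(2 * n)), paste0("g", 1:(2 * n)))
  part <- dynamic_tree_cut(average_linkage(d), d, deep_split = 2,
                           min_module_size = 30)
  expect_equal(sum(part$module == "grey"), 0)
  expect_equal(length(unique(part$module)), 2)
  # blocks map one-to-one onto modules
  expect_equal(length(unique(part$module[1:n])), 1)
  expect_equal(length(unique(part$module[(n + 1):(2 * n)])), 1)
  expect_false(part$module[1] == part$module[n + 1])
})

test_that("an unreachable minimum module size leaves everything grey", {
  d <- as.matrix(dist(matrix(rnorm(40), 10)))
  dimnames(d) <- list(paste0("g", 1:10), paste0("g", 1:10))
  expect_warning(
    part <- dynamic_tree_cut(average_linkage(d), d, min_module_size = 11),
    "unassigned")
  expect_true(all(part$module == "grey"))
})

test_that("planted co-expression modules are recovered from expression", {
  set.seed(31)
  expr <- planted_blocks(n_per_block = 40, n_samples = 24, n_noise = 60)
  tom <- topological_overlap(signed_adjacency(spearman_correlation(expr), 10))
  part <- dynamic_tree_cut(average_linkage(1 - tom), 1 - tom,
                           min_module_size = 20)
  truth <- ifelse(startsWith(part$gene_id, "a"), "A",
                  ifelse(startsWith(part$gene_id, "b"), "B", "noise"))
  planted <- truth != "noise"
  ari <- mclust::adjustedRandIndex(truth[planted], part$module[planted])
  expect_gte(ari, 0.9)
})

test_that("module eigengene matches its definition in degenerate and random cases", {
  # k copies of one profile: eigengene is the z-profile, unit norm, VE = 1
  prof <- c(1, 3, 2, 5, 4, 6)
  expr <- make_expr(rbind(prof, prof, prof), genes = c("g1", "g2", "g3"))
  part <- tibble::tibble(gene_id = rownames(expr), module = "m1")
  eig <- module_eigengene(expr, part)
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(eig$profiles[, "m1"]), z / sqrt(sum(z^2)),
               tolerance = 1e-12)
  expect_equal(unname(eig$var_explained["m1"]), 1)
  expect_equal(sqrt(sum(eig$profiles[, "m1"]^2)), 1)

  # sign convention survives negating all members
  eig_neg <- module_eigengene(-expr, part)
  expect_gte(mean(cor(t(-expr), eig_neg$profiles[, "m1"])), 0)

  # single-gene module: normalized z-profile
  single <- module_eigengene(expr[1, , drop = FALSE],
                             tibble::tibble(gene_id = "g1", module = "solo"))
  expect_equal(unname(single$profiles[, "solo"]), z / sqrt(sum(z^2)),
               tolerance = 1e-12)
})

test_that("variance explained matches a full eigendecomposition oracle", {
  set.seed(13)
  for (i in 1:10) {
    expr <- make_expr(matrix(rnorm(30 * 12), 30))
    part <- tibble::tibble(gene_id = rownames(expr), module = "m")
    eig <- module_eigengene(expr, part)
    z <- t(scale(t(expr)))
    ev <- eigen(crossprod(z), symmetric = TRUE)   # independent oracle
    expect_equal(unname(eig$var_explained["m"]),
                 ev$values[1] / sum(ev$values), tolerance = 1e-8)
    v1 <- ev$vectors[, 1]
    expect_lt(min(sum((eig$profiles[, "m"] - v1)^2),
                  sum((eig$profiles[, "m"] + v1)^2)), 1e-8)
  }
})

test_that("modules with correlated eigengenes merge; distinct ones do not", {
  set.seed(17)
  n_samp <- 40
  lat <- rnorm(n_samp)
  # two halves of one signal (eigengene correlation ~0.9), plus an
  # independent module
  mk <- function(lat, k, prefix, loading) {
    x <- t(vapply(seq_len(k), function(i)
      loading * lat + sqrt(1 - loading^2) * rnorm(n_samp), numeric(n_samp)))
    rownames(x) <- paste0(prefix, seq_len(k))
    x
  }
  expr <- rbind(mk(lat, 30, "a", 0.95), mk(lat, 30, "b", 0.95),
                mk(rnorm(n_samp), 30, "c", 0.95))
  colnames(expr) <- paste0("s", seq_len(n_samp))
  part <- tibble::tibble(
    gene_id = rownames(expr),
    module = substr(rownames(expr), 1, 1))
  eig <- module_eigengene(expr, part)
  expect_gt(cor(eig$profiles[, "a"], eig$profiles[, "b"]), 0.75)

  merged <- suppressMessages(merge_close_modules(expr, part, 0.25))
  mods <- merged$partition$module
  expect_equal(length(unique(mods)), 2)
  expect_equal(mods[1], mods[31])       # a and b fused
  expect_false(mods[1] == mods[61])     # c untouched

  # idempotence: a second call is a no-op
  again <- suppressMessages(merge_close_modules(expr, merged$partition, 0.25))
  expect_identical(again$partition, merged$partition)

  # after merging, no eigengene pair sits below the cut height
  d <- 1 - cor(merged$eigengenes$profiles)
  expect_true(all(d[upper.tri(d)] >= 0.25))
})

test_that("misplaced genes are reassigned to the better module", {
  set.seed(23)
  expr <- planted_blocks(n_per_block = 30, n_samples = 30)
  part <- block_partition(expr)
  part$module[1] <- "beta"              # a-gene mislabeled into beta
  eig <- module_eigengene(expr, part)
  res <- suppressMessages(reassign_genes(expr, part, eig, 0.2))
  moved <- res$partition$module[res$partition$gene_id == "a1"]
  others_a <- res$partition$module[res$partition$gene_id == "a2"]
  expect_equal(moved, others_a)

  # threshold 0: nothing can move
  eig0 <- module_eigengene(expr, part)
  res0 <- reassign_genes(expr, part, eig0, 0)
  expect_equal(sort(table(res0$partition$module)),
               sort(table(relabel_partition(part)$module)))

  # perfectly placed genes stay put
  clean <- block_partition(expr)
  eig_c <- module_eigengene(expr, clean)
  res_c <- reassign_genes(expr, clean, eig_c, 0.2)
  expect_equal(unname(table(res_c$partition$module)),
               unname(table(relabel_partition(clean)$module)))
})

test_that("kME separates members from background", {
  set.seed(29)
  expr <- planted_blocks(n_per_block = 40, n_samples = 36, n_noise = 40)
  part <- block_partition(expr)
  eig <- module_eigengene(expr, part)
  k <- kme(expr, eig)
  # a gene equal to the eigengene profile has kME 1
  e_gene <- matrix(eig$profiles[, "alpha"], nrow = 1,
                   dimnames = list("probe", colnames(expr)))
  expect_equal(unname(kme(e_gene, eig)[1, "alpha"]), 1, tolerance = 1e-12)

  members <- startsWith(rownames(expr), "a")
  noise <- startsWith(rownames(expr), "n")
  expect_gt(mean(k[members, "alpha"]), mean(k[noise, "alpha"]))
  expect_gt(mean(k[members, "alpha"]), 0.7)
  expect_lt(max(abs(k[noise, c("alpha", "beta")])), 0.75)
})

test_that("kME pruning demotes weakly connected riders to grey", {
  set.seed(37)
  expr <- planted_blocks(n_per_block = 30, n_samples = 30, n_noise = 6)
  part <- block_partition(expr)
  part$module[startsWith(part$gene_id, "n")] <- "alpha"  # riders
  pruned <- suppressMessages(prune_low_kme(expr, part, min_kme = 0.3))
  lut <- setNames(pruned$partition$module, pruned$partition$gene_id)
  expect_true(all(lut[paste0("n", 1:6)] == "grey"))
  expect_true(all(lut[paste0("a", 1:30)] != "grey"))
})
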