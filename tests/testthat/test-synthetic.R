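test_that("generation is fully deterministic given the seed", {
  cfg <- synthetic_config(seed = 61, background_genes = 100L,
                          modules = tibble::tibble(
                            size = 40L, loading = 0.8, dose_effect = 0.7,
                            shape = "monotonic", shared = TRUE))
  a <- simulate_expression_data(cfg)
  b <- simulate_expression_data(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$metadata, b$metadata)
  expect_identical(unclass(a$gene_sets), unclass(b$gene_sets))
  expect_identical(a$edges, b$edges)

  c2 <- simulate_expression_data(synthetic_config(seed = 62,
                                                  background_genes = 100L,
                                                  modules = cfg$modules))
  expect_false(identical(a$expression, c2$expression))
})

test_that("module loading controls within-module correlation", {
  mods <- function(lam) tibble::tibble(size = 50L, loading = lam,
                                       dose_effect = 0, shape = "null",
                                       shared = TRUE)
  # lambda = 0: members uncorrelated in expectation
  sim0 <- simulate_expression_data(synthetic_config(
    seed = 67, modules = mods(0), background_genes = 10L))
  x <- sim0$expression[[1]][1:50, ]
  r <- cor(t(x), method = "spearman")
  expect_lt(mean(abs(r[upper.tri(r)])), 0.15)

  # lambda = 1: members are identical up to their offsets
  sim1 <- simulate_expression_data(synthetic_config(
    seed = 67, modules = mods(1), background_genes = 10L))
  x1 <- sim1$expression[[1]][1:50, ]
  r1 <- cor(t(x1), method = "spearman")
  expect_true(all(abs(r1[upper.tri(r1)] - 1) < 1e-12))
})

test_that("planted dose effects surface in the module eigengene", {
  # alpha = 0.7 monotone: eigengene-ordinal-dose correlation ~ 0.7
  rs <- vapply(1:10, function(s) {
    sim <- simulate_expression_data(synthetic_config(
      seed = 70 + s, background_genes = 20L,
      modules = tibble::tibble(size = 80L, loading = 0.8, dose_effect = 0.7,
                               shape = "monotonic", shared = TRUE)))
    expr <- sim$expression[[1]]
    part <- sim$truth$gene_module |>
      dplyr::mutate(module = ifelse(module == "background", "grey", module))
    eig <- module_eigengene(expr, part)
    trait <- dose_trait(sim$metadata, colnames(expr), "ordinal")
    cor(eig$profiles[, 1], trait)
  }, numeric(1))
  expect_lt(abs(median(rs) - 0.7), 0.15)
})

test_that("planted TF sets cover their module and the edge model is honored", {
  sim <- simulate_expression_data(synthetic_config(seed = 73,
                                                   background_genes = 300L))
  tf <- sim$gene_sets[["TF_planted_01"]]
  members <- sim$truth$gene_module$gene_id[
    sim$truth$gene_module$module == "planted_01"]
  expect_equal(sum(tf %in% members), 60)     # coverage 0.6 of 100
  expect_equal(sum(!tf %in% members), 40)    # decoys
  # within-module edge density far above background
  ed <- sim$edges
  within01 <- ed$gene_a %in% members & ed$gene_b %in% members
  dens_within <- sum(within01) / choose(length(members), 2)
  expect_gt(dens_within, 0.1)
  expect_false(any(ed$gene_a == ed$gene_b))
})

test_that("recovery scoring behaves at its fixed points", {
  truth <- structure(list(
    gene_module = tibble::tibble(
      gene_id = paste0("g", 1:60),
      module = rep(c("planted_01", "planted_02", "background"), each = 20)),
    modules = tibble::tibble(module = c("planted_01", "planted_02"),
                             dose_effect = c(0.7, -0.7))),
    class = "ground_truth")
  perfect <- tibble::tibble(
    gene_id = paste0("g", 1:60),
    module = rep(c("blue", "brown", "grey"), each = 20))
  sc <- score_recovery(perfect, truth)
  expect_equal(sc$ari, 1)
  expect_true(all(sc$jaccard$jaccard == 1))

  # random labels: ARI near zero
  set.seed(79)
  aris <- vapply(1:20, function(i) {
    rnd <- perfect
    rnd$module <- sample(c("blue", "brown", "green", "grey"), 60, replace = TRUE)
    score_recovery(rnd, truth)$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)

  # all-background truth: ARI undefined -> NA
  truth_bg <- truth
  truth_bg$gene_module$module <- "background"
  expect_true(is.na(score_recovery(perfect, truth_bg)$ari))

  # sign agreement against a trait table
  tt <- tibble::tibble(module = c("blue", "brown"), r = c(0.6, -0.5))
  sc2 <- score_recovery(perfect, truth, tt)
  expect_true(all(sc2$sign_agreement$agrees))
})
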