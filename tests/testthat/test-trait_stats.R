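meta_for <- function(doses, ids = paste0("s", seq_along(doses))) {
  tibble::tibble(sample_id = ids, condition = "x", dose_molar = doses)
}

eig_from <- function(profiles) {
  structure(list(profiles = profiles,
                 var_explained = setNames(rep(1, ncol(profiles)),
                                          colnames(profiles))),
            class = "eigengene_set")
}

test_that("dose encodings follow their declared rules", {
  m <- meta_for(c(1e-9, 1e-8, 1e-7))
  expect_equal(unname(dose_trait(m, m$sample_id, "ordinal")), c(1, 2, 3))

  m2 <- meta_for(c(1e-9, 1e-9, 1e-7))
  expect_equal(unname(dose_trait(m2, m2$sample_id, "ordinal")), c(1, 1, 2))

  m3 <- meta_for(c(0, 1e-9, 1e-6))
  expect_equal(unname(dose_trait(m3, m3$sample_id, "log10")), c(-10, -9, -6))
  expect_equal(unname(dose_trait(m3, m3$sample_id, "linear")),
               c(0, 1e-9, 1e-6))

  m4 <- meta_for(c(0, 0, 0))
  expect_error(dose_trait(m4, m4$sample_id, "log10"), "positive",
               class = "dosenet_validation_error")
  # trait comes back in the requested sample order
  expect_equal(unname(dose_trait(m, rev(m$sample_id), "ordinal")), c(3, 2, 1))
})

test_that("eigengene-trait correlation carries the Student-t p-value", {
  trait <- c(1, 2, 3, 4, 5, 6)
  z <- (trait - mean(trait)) / sd(trait)
  e1 <- z / sqrt(sum(z^2))
  orth <- c(1, -2, 1, 1, -2, 1)         # exactly uncorrelated with trait
  e2 <- orth / sqrt(sum(orth^2))
  eig <- eig_from(cbind(perfect = e1, null = e2))
  rownames(eig$profiles) <- paste0("s", 1:6)
  tt <- eigengene_trait_correlation(eig, trait)
  expect_equal(tt$r[tt$module == "perfect"], 1)
  expect_equal(tt$p[tt$module == "perfect"], 0)
  expect_equal(tt$r[tt$module == "null"], 0, tolerance = 1e-12)
  expect_equal(tt$p[tt$module == "null"], 1)

  expect_error(eigengene_trait_correlation(eig, rep(1, 6)), "variance",
               class = "dosenet_validation_error")
})

test_that("the p-value formula matches an independent t-tail oracle", {
  # r = 0.5, n = 20; oracle integrates the t density directly
  r <- 0.5; n <- 20
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  dens <- function(x) {
    df <- n - 2
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail_p <- 2 * stats::integrate(dens, t_stat, Inf, rel.tol = 1e-12)$value

  set.seed(41)
  trait <- rnorm(n)
  # build an eigengene with exactly correlation 0.5 to the trait
  e_raw <- r * scale(trait)[, 1] +
    sqrt(1 - r^2) * scale(residuals(lm(rnorm(n) ~ trait)))[, 1]
  eig <- eig_from(matrix(e_raw / sqrt(sum(e_raw^2)), ncol = 1,
                         dimnames = list(paste0("s", 1:n), "m")))
  tt <- eigengene_trait_correlation(eig, trait)
  expect_equal(tt$r, 0.5, tolerance = 1e-12)
  expect_equal(tt$p, tail_p, tolerance = 1e-10)
})

test_that("p decreases in |r| at fixed n and in n at fixed r", {
  p_of <- function(r, n) {
    t_stat <- abs(r) * sqrt((n - 2) / (1 - r^2))
    2 * pt(t_stat, n - 2, lower.tail = FALSE)
  }
  rs <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(rs, p_of, numeric(1), n = 20)
  expect_true(all(diff(ps) < 0))
  ns <- seq(5, 100, by = 5)
  ps_n <- vapply(ns, function(n) p_of(0.4, n), numeric(1))
  expect_true(all(diff(ps_n) < 0))
})

test_that("significance selection is strict and ordered by correlation", {
  tt <- tibble::tibble(
    module = c("a", "b", "c", "d"), condition = "x",
    r = c(0.5, -0.9, 0.8, -0.2), p = c(0.01, 0.001, 0.002, 0.5), n = 36)
  sel <- select_significant(tt, alpha = 0.01)
  expect_equal(sel$module, c("c", "b"))   # p = alpha excluded, descending r
  expect_equal(nrow(select_significant(tt, alpha = 1e-6)), 0)
})

test_that("consensus relationship keeps the weakest same-sign correlation", {
  t1 <- tibble::tibble(module = c("m1", "m2", "m3"), condition = "a",
                       r = c(0.30, 0.5, -0.4), p = c(0.02, 0.001, 0.01), n = 36)
  t2 <- tibble::tibble(module = c("m1", "m2", "m3"), condition = "b",
                       r = c(0.24, -0.3, -0.2), p = c(0.03, 0.001, 0.2), n = 44)
  cons <- consensus_trait_relationship(list(t1, t2))
  m1 <- cons[cons$module == "m1", ]
  expect_equal(m1$consensus_r, 0.24)
  expect_equal(m1$consensus_p, 0.03)
  expect_true(is.na(cons$consensus_r[cons$module == "m2"]))  # sign clash
  m3 <- cons[cons$module == "m3", ]
  expect_equal(m3$consensus_r, -0.2)
  expect_equal(m3$consensus_p, 0.2)

  # missing module in one condition -> NA, logged
  expect_message(
    cons2 <- consensus_trait_relationship(
      list(t1, t2[t2$module != "m1", ])), "absent")
  expect_true(is.na(cons2$consensus_r[cons2$module == "m1"]))

  # magnitude / p-value conservatism over random tables
  set.seed(43)
  for (i in 1:20) {
    r1 <- runif(1, -1, 1); r2 <- runif(1, -1, 1)
    p1 <- runif(1); p2 <- runif(1)
    cc <- consensus_trait_relationship(list(
      tibble::tibble(module = "m", condition = "a", r = r1, p = p1, n = 10),
      tibble::tibble(module = "m", condition = "b", r = r2, p = p2, n = 10)))
    if (!is.na(cc$consensus_r)) {
      expect_lte(abs(cc$consensus_r), min(abs(r1), abs(r2)))
      expect_gte(cc$consensus_p, max(p1, p2))
      expect_equal(sign(cc$consensus_r), sign(r1))
    } else {
      expect_true(sign(r1) != sign(r2))
    }
  }
})
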