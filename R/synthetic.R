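#' Configuration for the synthetic dose-response generator
#'
#' Defaults emulate a multi-condition estrogenicity screen: one exposure
#' series of 36 samples over 18 half-log dose levels from 1e-12 to
#' 10^-3.5 M (picomolar to above the 12.5 uM low-dose cutoff), 5 planted
#' modules of 100 genes at loading 0.8 on 1,500 background genes, three of
#' them with monotone dose effects of magnitude 0.7, one with a low-dose
#' activity peak, one dose-null.
#'
#' @param seed integer seed; every random draw flows from it.
#' @param conditions tibble (`name`, `replicates`) or list of condition
#'   names; each condition uses `dose_levels` with `replicates` per level.
#' @param dose_levels molar dose grid (shared across conditions).
#' @param replicates samples per dose level.
#' @param modules tibble with columns `size`, `loading` (lambda in `[0,1]`),
#'   `dose_effect` (alpha in `[-1,1]`), `shape`
#'   (`monotonic`/`low_dose_peak`/`null`), `shared` (present in all
#'   conditions; private modules behave as background elsewhere), and an
#'   optional `condition` column naming a private module's host condition
#'   (default: the first condition).
#' @param background_genes count of unstructured genes.
#' @param noise_sd standard deviation of gene- and sample-level noise.
#' @param tf_coverage fraction of each module sampled into its planted
#'   regulator target set.
#' @param tf_decoys decoy genes added to each target set from outside the
#'   module.
#' @param edge_p_within,edge_p_background Bernoulli edge probabilities for
#'   the planted interaction network.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1,
    conditions = "estrogen",
    dose_levels = 10^seq(-12, -3.5, by = 0.5),
    replicates = 2,
    modules = tibble(
      size = rep(100L, 5),
      loading = rep(0.8, 5),
      dose_effect = c(0.7, -0.7, 0.7, 0.5, 0),
      shape = c("monotonic", "monotonic", "monotonic", "low_dose_peak", "null"),
      shared = TRUE
    ),
    background_genes = 1500L,
    noise_sd = 1,
    tf_coverage = 0.6,
    tf_decoys = 40L,
    edge_p_within = 0.2,
    edge_p_background = 0.005) {
  if (length(dose_levels) < 3) {
    abort("need >= 3 dose levels per condition", class = "dosenet_validation_error")
  }
  stopifnot(all(modules$loading >= 0 & modules$loading <= 1),
            all(abs(modules$dose_effect) <= 1),
            all(modules$shape %in% c("monotonic", "low_dose_peak", "null")),
            noise_sd > 0, tf_coverage >= 0, tf_coverage <= 1)
  structure(list(
    seed = as.integer(seed), conditions = conditions,
    dose_levels = dose_levels, replicates = replicates,
    modules = modules, background_genes = as.integer(background_genes),
    noise_sd = noise_sd, tf_coverage = tf_coverage,
    tf_decoys = as.integer(tf_decoys),
    edge_p_within = edge_p_within, edge_p_background = edge_p_background
  ), class = "synthetic_config")
}

#' Generate a synthetic dose-response dataset with planted modules
#'
#' Per condition and module, a latent module profile over samples is
#' `m(s) = alpha f(dose_s) + sqrt(1 - alpha^2) eta_s`, where `f` is a
#' standardized dose-response shape (z-scored ordinal dose for `monotonic`;
#' a z-scored unimodal bump centered on a low dose level for
#' `low_dose_peak`, emulating weak transcriptional activation at very low
#' exposure; 0 for `null`) and `eta` is standard normal noise. A member
#' gene's expression is `x = lambda m(s) + sqrt(1 - lambda^2) eps + offset`;
#' background genes are offset plus noise. Planted regulator target sets
#' sample `tf_coverage x size` genes from their module plus decoys;
#' interaction edges are drawn with the within-module vs background
#' probabilities. All draws come from the seeded generator, so outputs are
#' fully reproducible.
#'
#' @param config a [synthetic_config()].
#' @return list with `expression` (named list of genes x samples matrices,
#'   one per condition), `metadata` tibble, `gene_sets`
#'   (`gene_set_library`), `edges` tibble, and `truth` (a `ground_truth`
#'   list: `gene_module` tibble, `modules` config tibble, latent module
#'   profiles per condition, planted TF memberships and edges).
#' @export
simulate_expression_data <- function(config = synthetic_config()) {
  set.seed(config$seed)
  cond_names <- if (is.character(config$conditions)) config$conditions
                else config$conditions$name
  mods <- config$modules
  n_mod <- nrow(mods)
  mod_names <- sprintf("planted_%02d", seq_len(n_mod))
  gene_ids <- character(0)
  gene_module <- character(0)
  for (i in seq_len(n_mod)) {
    ids <- sprintf("%s_g%03d", mod_names[i], seq_len(mods$size[i]))
    gene_ids <- c(gene_ids, ids)
    gene_module <- c(gene_module, rep(mod_names[i], mods$size[i]))
  }
  bg_ids <- sprintf("background_g%04d", seq_len(config$background_genes))
  gene_ids <- c(gene_ids, bg_ids)
  gene_module <- c(gene_module, rep("background", config$background_genes))
  n_genes <- length(gene_ids)
  offsets <- rnorm(n_genes, mean = 8, sd = 2)   # gene-specific baseline

  doses <- rep(config$dose_levels, each = config$replicates)
  n_samp <- length(doses)
  shapes <- dose_shapes(doses)

  shared <- if ("shared" %in% names(mods)) mods$shared else rep(TRUE, n_mod)
  # a private module may name its host condition; default = first condition
  host <- if ("condition" %in% names(mods)) mods$condition
          else rep(cond_names[1], n_mod)
  host[is.na(host)] <- cond_names[1]
  expression <- list()
  metadata <- list()
  latent <- list()
  for (cond in cond_names) {
    sample_ids <- sprintf("%s_s%02d", cond, seq_len(n_samp))
    m_prof <- matrix(0, nrow = n_samp, ncol = n_mod,
                     dimnames = list(sample_ids, mod_names))
    x <- matrix(rnorm(n_genes * n_samp, sd = config$noise_sd),
                nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    for (i in seq_len(n_mod)) {
      f <- switch(mods$shape[i],
                  monotonic = shapes$monotonic,
                  low_dose_peak = shapes$low_dose_peak,
                  null = rep(0, n_samp))
      a <- mods$dose_effect[i]
      eta <- rnorm(n_samp, sd = config$noise_sd)
      m <- a * f + sqrt(1 - a^2) * eta
      m_prof[, i] <- m
      active <- shared[i] || cond == host[i]
      if (!active) next                 # private module: background elsewhere
      members <- which(gene_module == mod_names[i])
      lam <- mods$loading[i]
      x[members, ] <- lam * matrix(m, nrow = length(members),
                                   ncol = n_samp, byrow = TRUE) +
        sqrt(1 - lam^2) * x[members, ]
    }
    x <- x + offsets
    expression[[cond]] <- x
    latent[[cond]] <- m_prof
    metadata[[cond]] <- tibble(
      sample_id = sample_ids, condition = cond, dose_molar = doses,
      replicate = rep(seq_len(config$replicates), times = length(config$dose_levels)))
  }

  # planted regulator target sets: coverage of the module plus decoys
  tf_sets <- list()
  for (i in seq_len(n_mod)) {
    members <- gene_ids[gene_module == mod_names[i]]
    n_cov <- round(config$tf_coverage * length(members))
    decoy_pool <- gene_ids[gene_module != mod_names[i]]
    tf_sets[[sprintf("TF_%s", mod_names[i])]] <-
      c(sample(members, n_cov),
        sample(decoy_pool, min(config$tf_decoys, length(decoy_pool))))
  }
  gene_sets <- structure(tf_sets, class = "gene_set_library",
                         library_name = "planted_tf_targets")

  edges <- simulate_edges(gene_ids, gene_module, mod_names,
                          config$edge_p_within, config$edge_p_background)

  truth <- structure(list(
    gene_module = tibble(gene_id = gene_ids, module = gene_module),
    modules = mutate(mods, module = mod_names),
    latent = latent,
    tf_sets = tf_sets,
    edges = edges
  ), class = "ground_truth")

  list(expression = expression, metadata = bind_rows(metadata),
       gene_sets = gene_sets, edges = edges, truth = truth)
}

# standardized dose-response shapes over the sample dose vector
dose_shapes <- function(doses) {
  lev <- sort(unique(doses))
  ord <- match(doses, lev)
  z <- function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
  # unimodal bump centered on a low dose level (~1/4 of the way up the grid)
  center <- max(2, round(length(lev) / 4))
  bump <- exp(-((ord - center)^2) / (2 * (length(lev) / 8)^2))
  list(monotonic = z(ord), low_dose_peak = z(bump))
}

simulate_edges <- function(gene_ids, gene_module, mod_names,
                           p_within, p_background) {
  rows <- list()
  # dense sampling within modules only; sparse background pairs by count
  for (mod in mod_names) {
    members <- gene_ids[gene_module == mod]
    pairs <- which(upper.tri(diag(length(members))), arr.ind = TRUE)
    hit <- runif(nrow(pairs)) < p_within
    if (any(hit)) {
      rows[[mod]] <- tibble(gene_a = members[pairs[hit, 1]],
                            gene_b = members[pairs[hit, 2]], score = 0.9)
    }
  }
  # background edges: sample the binomial count of random pairs rather than
  # enumerating all ~n^2/2 candidates
  n <- length(gene_ids)
  total_pairs <- n * (n - 1) / 2
  n_bg <- stats::rbinom(1, size = as.integer(min(total_pairs, 2^30)),
                        prob = p_background)
  if (n_bg > 0) {
    a <- sample(gene_ids, n_bg, replace = TRUE)
    b <- sample(gene_ids, n_bg, replace = TRUE)
    rows[["background"]] <- tibble(gene_a = a, gene_b = b, score = 0.4)
  }
  suppressMessages(normalize_edges(bind_rows(rows)))
}

#' Score recovery of planted modules
#'
#' Compares a detected partition with the generator's ground truth:
#' adjusted Rand index over the planted (non-background) genes, best-match
#' Jaccard per planted module, and the sign agreement between each planted
#' dose effect and the detected module-trait correlation of its best-match
#' module.
#'
#' @param partition detected tibble (`gene_id`, `module`).
#' @param truth `ground_truth` from [simulate_expression_data()].
#' @param trait_table optional module-trait tibble used for sign agreement.
#' @return list with `ari`, `jaccard` tibble (`module`, `best_match`,
#'   `jaccard`) and, when `trait_table` is given, `sign_agreement` tibble.
#' @export
score_recovery <- function(partition, truth, trait_table = NULL) {
  tm <- truth$gene_module
  planted <- tm[tm$module != "background", ]
  if (nrow(planted) == 0) {
    return(list(ari = NA_real_, jaccard = tibble(), sign_agreement = NULL))
  }
  det <- setNames(partition$module, partition$gene_id)[planted$gene_id]
  ari <- mclust::adjustedRandIndex(planted$module, det)

  jac <- planted |>
    group_by(truth_module = .data$module) |>
    summarise(best = {
      mine <- .data$gene_id
      cand <- setdiff(unique(partition$module), "grey")
      j <- vapply(cand, function(mod) {
        theirs <- partition$gene_id[partition$module == mod]
        length(intersect(mine, theirs)) / length(union(mine, theirs))
      }, numeric(1))
      if (length(j) == 0) list(tibble(best_match = NA_character_, jaccard = 0))
      else list(tibble(best_match = names(j)[which.max(j)], jaccard = max(j)))
    }, .groups = "drop") |>
    tidyr::unnest("best")

  sign_agree <- NULL
  if (!is.null(trait_table)) {
    sign_agree <- jac |>
      left_join(truth$modules |> select(truth_module = "module", "dose_effect"),
                by = "truth_module") |>
      left_join(trait_table |> select(best_match = "module", "r"),
                by = "best_match") |>
      mutate(agrees = sign(.data$dose_effect) == sign(.data$r))
  }
  list(ari = ari, jaccard = jac, sign_agreement = sign_agree)
}
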