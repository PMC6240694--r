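#' Encode sample doses as a trait vector
#'
#' Dose-response designs span many orders of magnitude (picomolar to
#' micromolar), so raw molar values would be dominated by the top doses.
#' The default ordinal encoding maps the unique doses, sorted ascending, to
#' ranks 1..L (duplicated doses share a level) and is invariant to any
#' monotone re-expression of concentration. `log10` uses log10(dose) with
#' zero doses mapped one decade below the smallest positive dose; `linear`
#' uses raw molar values.
#'
#' @param meta metadata tibble (`sample_id`, `dose_molar`).
#' @param samples ordered sample ids the trait must align with.
#' @param transform `"ordinal"` (default), `"log10"` or `"linear"`.
#' @return named numeric vector in the order of `samples`.
#' @export
dose_trait <- function(meta, samples, transform = c("ordinal", "log10", "linear")) {
  transform <- match.arg(transform)
  missing_s <- setdiff(samples, meta$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("samples without metadata: ", paste(missing_s, collapse = ", ")),
          class = "dosenet_validation_error")
  }
  dose <- meta$dose_molar[match(samples, meta$sample_id)]
  out <- switch(transform,
    ordinal = {
      lev <- sort(unique(dose))
      match(dose, lev)
    },
    log10 = {
      pos <- dose[dose > 0]
      if (length(pos) == 0) {
        abort("log10 transform needs at least one positive dose",
              class = "dosenet_validation_error")
      }
      ifelse(dose > 0, log10(dose), log10(min(pos)) - 1)
    },
    linear = dose)
  setNames(as.numeric(out), samples)
}

#' Correlate module eigengenes with a trait
#'
#' Per-module correlation of the eigengene sample profile with the trait
#' (dose), with the two-sided Student-t p-value
#' `p = 2 P(T_{n-2} >= |r| sqrt((n-2)/(1-r^2)))`; `|r| = 1` gives p = 0.
#'
#' @param eigengenes an `eigengene_set`.
#' @param trait numeric vector aligned with the eigengene samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param condition optional condition label recorded in the table.
#' @return tibble (`module`, `condition`, `r`, `p`, `n`), one row per module.
#' @export
eigengene_trait_correlation <- function(eigengenes, trait,
                                        method = c("pearson", "spearman"),
                                        condition = NA_character_) {
  method <- match.arg(method)
  E <- eigengenes$profiles
  n <- nrow(E)
  if (length(trait) != n) {
    abort("trait length must equal the number of samples",
          class = "dosenet_validation_error")
  }
  if (n < 4) {
    abort("trait correlation needs >= 4 samples",
          class = "dosenet_validation_error")
  }
  if (sd(trait) == 0) {
    abort("trait has zero variance", class = "dosenet_validation_error")
  }
  r <- drop(cor(E, trait, method = method))
  tibble(
    module = colnames(E),
    condition = condition,
    r = unname(r),
    p = unname(correlation_p(r, n)),
    n = n
  )
}

#' Select modules significantly correlated with the trait
#'
#' Keeps rows with `p < alpha` (strict), ordered the way dose-response
#' module tables are usually printed: correlations descending, so the
#' positive block comes first and the negative block runs from weakest to
#' strongest negative.
#'
#' @param table module-trait tibble from [eigengene_trait_correlation()].
#' @param alpha significance threshold (0.01 for single-condition networks,
#'   0.05 for consensus tables, conventionally).
#' @return filtered, re-ordered tibble.
#' @export
select_significant <- function(table, alpha = 0.01) {
  table |>
    filter(.data$p < alpha) |>
    arrange(desc(.data$r))
}

#' Consensus module-trait relationship across conditions
#'
#' A module's association is conserved only when every condition agrees on
#' the sign; the consensus correlation is then the per-condition correlation
#' of smallest magnitude and the consensus p-value the largest per-condition
#' p-value (the most conservative summary). Sign disagreement, or a module
#' missing from a condition, yields `NA` (logged).
#'
#' @param per_condition list of module-trait tibbles covering the same
#'   modules, one per condition.
#' @return tibble (`module`, `consensus_r`, `consensus_p`).
#' @export
consensus_trait_relationship <- function(per_condition) {
  if (length(per_condition) < 2) {
    abort("need >= 2 per-condition tables", class = "dosenet_validation_error")
  }
  modules <- unique(unlist(lapply(per_condition, function(t) t$module)))
  rows <- lapply(modules, function(mod) {
    rs <- vapply(per_condition, function(t) {
      i <- which(t$module == mod)
      if (length(i) == 1) t$r[i] else NA_real_
    }, numeric(1))
    ps <- vapply(per_condition, function(t) {
      i <- which(t$module == mod)
      if (length(i) == 1) t$p[i] else NA_real_
    }, numeric(1))
    if (anyNA(rs)) {
      inform(paste0("module absent from a condition: ", mod))
      return(tibble(module = mod, consensus_r = NA_real_, consensus_p = NA_real_))
    }
    same_sign <- all(rs > 0) || all(rs < 0)
    if (!same_sign) {
      return(tibble(module = mod, consensus_r = NA_real_, consensus_p = NA_real_))
    }
    i_min <- which.min(abs(rs))
    tibble(module = mod, consensus_r = unname(rs[i_min]),
           consensus_p = max(ps))
  })
  bind_rows(rows)
}
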