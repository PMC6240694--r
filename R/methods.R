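#' @export
print.network_fit <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$partition$module), "grey"))
  cat(sprintf(
    "<network_fit> condition '%s': %d genes x %d samples, %d modules (%d grey), %d dose-significant\n",
    x$condition, nrow(x$expression), ncol(x$expression), n_mod,
    sum(x$partition$module == "grey"), nrow(x$significant)))
  invisible(x)
}

#' @export
print.consensus_fit <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$partition$module), "grey"))
  cat(sprintf(
    "<consensus_fit> conditions %s: %d shared genes, %d consensus modules, %d significant\n",
    paste(x$conditions, collapse = "+"), length(x$universe), n_mod,
    nrow(x$significant)))
  invisible(x)
}

#' Tidy module-trait statistics of a network fit
#'
#' One row per module with the eigengene-dose correlation, its Student-t
#' p-value, sample size and variance explained by the eigengene.
#'
#' @param x a `network_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.network_fit <- function(x, ...) {
  x$trait_table |>
    mutate(var_explained = unname(x$eigengenes$var_explained[.data$module]),
           size = vapply(.data$module, function(mod)
             sum(x$partition$module == mod), integer(1)),
           significant = .data$p < x$parameters$alpha)
}

#' @rdname tidy.network_fit
#' @export
tidy.consensus_fit <- function(x, ...) {
  sizes <- x$partition |> group_by(.data$module) |>
    summarise(size = n(), .groups = "drop")
  x$consensus_table |>
    left_join(sizes, by = "module") |>
    mutate(significant = !is.na(.data$consensus_p) &
             .data$consensus_p < x$parameters$alpha)
}

#' One-row summary of a network fit
#'
#' @param x a `network_fit` or `consensus_fit`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.network_fit <- function(x, ...) {
  tibble(
    condition = x$condition,
    n_genes = nrow(x$expression),
    n_samples = ncol(x$expression),
    n_modules = length(setdiff(unique(x$partition$module), "grey")),
    n_grey = sum(x$partition$module == "grey"),
    n_significant = nrow(x$significant),
    beta = x$parameters$beta,
    alpha = x$parameters$alpha
  )
}

#' @rdname glance.network_fit
#' @export
glance.consensus_fit <- function(x, ...) {
  tibble(
    conditions = paste(x$conditions, collapse = "+"),
    n_genes = length(x$universe),
    n_modules = length(setdiff(unique(x$partition$module), "grey")),
    n_grey = sum(x$partition$module == "grey"),
    n_significant = nrow(x$significant),
    alpha = x$parameters$alpha
  )
}

#' Plot module-dose correlations of a fit
#'
#' Horizontal bar chart of per-module eigengene-dose correlations, filled by
#' correlation and annotated with p-values — a lightweight version of the
#' usual module-trait heatmap row.
#'
#' @param object a `network_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.network_fit <- function(object, ...) {
  d <- object$trait_table |> arrange(.data$r) |>
    mutate(module = factor(.data$module, levels = .data$module))
  ggplot(d, aes(x = .data$module, y = .data$r, fill = .data$r)) +
    geom_col() +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = c(-1, 1)) +
    coord_flip() +
    labs(x = NULL, y = "eigengene-dose correlation",
         title = sprintf("Module-dose correlation (%s)", object$condition),
         fill = "r") +
    theme_minimal()
}

#' @rdname autoplot.network_fit
#' @export
autoplot.consensus_fit <- function(object, ...) {
  d <- bind_rows(object$per_condition)
  ggplot(d, aes(x = .data$condition, y = .data$module, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f\n(%.1g)", .data$r, .data$p)),
              size = 2.8) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r",
         title = "Per-condition module-dose correlation") +
    theme_minimal()
}
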