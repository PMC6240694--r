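#' Validate an expression matrix
#'
#' An expression matrix is a numeric genes x samples matrix with unique,
#' non-empty row (gene) and column (sample) names and finite values.
#' Network operations additionally require at least 2 genes and 4 samples;
#' set `network = TRUE` to enforce that.
#'
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @param network logical; also require >= 2 genes and >= 4 samples.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr, network = FALSE) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("expression must be a numeric matrix (genes x samples)",
          class = "dosenet_validation_error")
  }
  gid <- rownames(expr)
  sid <- colnames(expr)
  if (is.null(gid) || is.null(sid) || any(!nzchar(gid)) || any(!nzchar(sid))) {
    abort("expression matrix needs non-empty gene rownames and sample colnames",
          class = "dosenet_validation_error")
  }
  if (anyDuplicated(gid)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(gid[duplicated(gid)]), collapse = ", ")),
          class = "dosenet_validation_error")
  }
  if (anyDuplicated(sid)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")),
          class = "dosenet_validation_error")
  }
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite expression value at gene '%s', sample '%s'",
                  gid[bad[1]], sid[bad[2]]),
          class = "dosenet_validation_error")
  }
  if (network && (nrow(expr) < 2 || ncol(expr) < 4)) {
    abort("network operations require at least 2 genes and 4 samples",
          class = "dosenet_validation_error")
  }
  invisible(expr)
}

#' Read a normalized expression matrix from TSV
#'
#' Expects genes in rows: first column gene id, header row of sample ids.
#' Orientation is never guessed. Duplicate gene ids are collapsed by keeping
#' the row with the highest mean expression (logged). Missing values are
#' rejected unless `impute_missing = TRUE`, in which case they are replaced
#' by the gene's mean over observed samples (logged).
#'
#' @param path path to a tab-separated file.
#' @param impute_missing replace NA by the per-gene mean instead of failing.
#' @return a validated numeric matrix, genes x samples.
#' @export
read_expression <- function(path, impute_missing = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dosenet_validation_error")
  }
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header)) {
    abort(paste0("duplicate sample id in header: ",
                 paste(unique(header[duplicated(header)]), collapse = ", ")),
          class = "dosenet_validation_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(raw) < 2) {
    abort("expression file needs a gene id column plus >= 1 sample column",
          class = "dosenet_parse_error")
  }
  sid <- names(raw)[-1]
  gid <- raw[[1]]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, sid))
  na_in <- is.na(vals) & !(is.na(raw[-1]) | raw[-1] == "NA")
  if (any(na_in)) {
    bad <- which(as.matrix(na_in), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                  raw[[1 + bad[2]]][bad[1]], gid[bad[1]], sid[bad[2]]),
          class = "dosenet_parse_error")
  }
  if (anyDuplicated(gid)) {
    means <- rowMeans(vals, na.rm = TRUE)
    # keep, per gene id, the row with the highest mean
    ord <- order(gid, -means)
    keep <- ord[!duplicated(gid[ord])]
    n_drop <- nrow(vals) - length(keep)
    inform(sprintf(
      "collapsed %d duplicate gene row(s), keeping the highest-mean row",
      n_drop))
    keep <- sort(keep)
    vals <- vals[keep, , drop = FALSE]
    gid <- gid[keep]
  }
  rownames(vals) <- gid
  if (anyNA(vals)) {
    if (!impute_missing) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "missing value at gene '%s', sample '%s' (set impute_missing = TRUE to mean-impute)",
        gid[bad[1]], sid[bad[2]]), class = "dosenet_validation_error")
    }
    n_na <- sum(is.na(vals))
    gm <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- gm[idx[, 1]]
    inform(sprintf("mean-imputed %d missing value(s) across %d gene(s)",
                   n_na, length(unique(idx[, 1]))))
  }
  validate_expression(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample, full numeric precision.
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns: `sample_id`, `condition`, `dose_molar` (non-negative molar
#' concentration, scientific notation accepted), optional `replicate`.
#'
#' @param path path to a tab-separated file.
#' @return a tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dosenet_validation_error")
  }
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    condition = readr::col_character(),
    dose_molar = readr::col_double(),
    .default = readr::col_guess()))
  validate_metadata(meta)
  meta
}

#' Validate sample metadata, optionally against an expression matrix
#'
#' @param meta metadata tibble (`sample_id`, `condition`, `dose_molar`).
#' @param expr optional expression matrix whose samples must all appear
#'   exactly once in `meta`.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta, expr = NULL) {
  need <- c("sample_id", "condition", "dose_molar")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")),
          class = "dosenet_validation_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicate sample_id in metadata: ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                       collapse = ", ")),
          class = "dosenet_validation_error")
  }
  if (any(!is.finite(meta$dose_molar)) || any(meta$dose_molar < 0)) {
    abort("doses must be finite and non-negative (molar units)",
          class = "dosenet_validation_error")
  }
  if (!is.null(expr)) {
    missing_samples <- setdiff(colnames(expr), meta$sample_id)
    if (length(missing_samples) > 0) {
      abort(paste0("samples absent from metadata: ",
                   paste(missing_samples, collapse = ", ")),
            class = "dosenet_validation_error")
    }
  }
  invisible(meta)
}

#' Read a gene-set library in GMT format
#'
#' One set per line: `set_name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Duplicate gene ids within a set are collapsed; set order is preserved.
#'
#' @param path path to a GMT file.
#' @param library_name optional label; defaults to the file name.
#' @return a named list of character vectors of class `gene_set_library`,
#'   with a `library_name` attribute.
#' @export
read_gmt <- function(path, library_name = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dosenet_validation_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("no sets: GMT file is empty", class = "dosenet_parse_error")
  }
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields", i),
            class = "dosenet_parse_error")
    }
    nm[i] <- f[1]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate set names in GMT: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
          class = "dosenet_validation_error")
  }
  names(sets) <- nm
  structure(sets, class = "gene_set_library",
            library_name = library_name %||% basename(path))
}

#' Write a gene-set library to GMT
#'
#' @param sets named list of character vectors (or a `gene_set_library`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction edge list from TSV
#'
#' Columns `gene_a`, `gene_b` and optional `score` in `[0, 1]`. Self-loops
#' are dropped (logged) and each unordered pair is stored once, keeping the
#' highest score among duplicates.
#'
#' @param path path to a tab-separated file.
#' @return a tibble with columns `gene_a`, `gene_b`, `score`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dosenet_validation_error")
  }
  edges <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    .default = readr::col_double()))
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort("edge list needs columns gene_a and gene_b",
          class = "dosenet_parse_error")
  }
  if (!"score" %in% names(edges)) edges$score <- 1
  if (any(edges$score < 0 | edges$score > 1, na.rm = TRUE)) {
    abort("edge scores must lie in [0, 1]", class = "dosenet_validation_error")
  }
  normalize_edges(edges)
}

#' @keywords internal
normalize_edges <- function(edges) {
  self <- edges$gene_a == edges$gene_b
  if (any(self)) {
    inform(sprintf("dropped %d self-loop(s)", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  out <- tibble(gene_a = a, gene_b = b, score = edges$score)
  n0 <- nrow(out)
  out <- out |>
    arrange(.data$gene_a, .data$gene_b, desc(.data$score)) |>
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)
  if (nrow(out) < n0) {
    inform(sprintf("collapsed %d duplicate undirected edge(s)", n0 - nrow(out)))
  }
  out
}

#' Write an edge list to TSV
#'
#' @param edges tibble with `gene_a`, `gene_b`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}
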