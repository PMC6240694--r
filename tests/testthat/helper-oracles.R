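# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (triple loops, exact tail sums, textbook
# agglomeration) and never share code with the implementation they check.

# small expression matrix with named dims
make_expr <- function(values, genes = NULL, samples = NULL) {
  nr <- if (is.null(genes)) nrow(values) else length(genes)
  m <- matrix(values, nrow = nr)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random valid signed adjacency (symmetric, [0,1], unit diagonal)
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

# O(n^3) topological overlap, straight from the definition
tom_brute_force <- function(adj) {
  n <- nrow(adj)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
      }
      ki <- sum(adj[i, -i])
      kj <- sum(adj[j, -j])
      out[i, j] <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
    }
  }
  dimnames(out) <- dimnames(adj)
  out
}

# textbook UPGMA: merge the closest pair, average distances weighted by size
upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    dd <- d[active, active]
    diag(dd) <- Inf
    idx <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- active[idx[1]]; j <- active[idx[2]]
    heights <- c(heights, d[i, j])
    # weighted average of distances to the merged cluster
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# exact hypergeometric upper tail P(X >= k) via log-binomials
hyper_tail_oracle <- function(k, set_size, module_size, universe) {
  kmax <- min(set_size, module_size)
  if (k <= 0) return(1)
  if (k > kmax) return(0)
  terms <- vapply(k:kmax, function(x) {
    exp(lchoose(set_size, x) + lchoose(universe - set_size, module_size - x) -
          lchoose(universe, module_size))
  }, numeric(1))
  sum(terms)
}

# expression with two planted blocks and optional noise genes; block members
# are scaled copies of a latent profile plus noise
planted_blocks <- function(n_per_block = 50, n_samples = 20, n_noise = 0,
                           loading = 0.95) {
  lat1 <- rnorm(n_samples)
  lat2 <- rnorm(n_samples)
  mk <- function(lat, k, prefix) {
    x <- t(vapply(seq_len(k), function(i) {
      loading * lat + sqrt(1 - loading^2) * rnorm(n_samples)
    }, numeric(n_samples)))
    rownames(x) <- paste0(prefix, seq_len(k))
    x
  }
  x <- rbind(mk(lat1, n_per_block, "a"), mk(lat2, n_per_block, "b"))
  if (n_noise > 0) {
    noise <- matrix(rnorm(n_noise * n_samples), n_noise)
    rownames(noise) <- paste0("n", seq_len(n_noise))
    x <- rbind(x, noise)
  }
  colnames(x) <- paste0("s", seq_len(n_samples))
  x
}

# two-module partition fixture over an expression matrix
block_partition <- function(expr) {
  tibble::tibble(
    gene_id = rownames(expr),
    module = ifelse(startsWith(rownames(expr), "a"), "alpha",
                    ifelse(startsWith(rownames(expr), "b"), "beta", "grey")))
}
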