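# Independent oracles used across tests. These deliberately use naive
# enumeration / brute force so they cannot share a bug with the package's
# vectorised implementations.

# Triple-sum TOM definition, looped verbatim.
tom_bruteforce <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# AUC by explicit positive-negative pair counting.
auc_bruteforce <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# P(overlap >= k) for a query of size q drawn from a universe of size N
# containing a set of size s, by exhaustive enumeration of all draws.
hyper_enum_tail <- function(k, s, N, q) {
  combos <- utils::combn(N, q)
  mean(apply(combos, 2, function(draw) sum(draw <= s) >= k))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Standard planted-module configuration used by several tests.
planted_modules_config <- function(seed, n_genes = 500, n_cells = 200,
                                   sizes = rep(40, 5), noise_sd = 0.3) {
  synthetic_config(n_genes, n_cells,
                   modules = lapply(sizes, function(s) list(size = s)),
                   noise_sd = noise_sd, seed = seed)
}

# log -> correlation -> signed adjacency -> TOM -> modules, at a fixed
# conventional power.
detect_from_expr <- function(expr, beta = 6, min_size = 30) {
  lx <- log_transform(expr)
  if (inherits(lx, "sc_expr")) lx <- lx$values
  tom <- topological_overlap(signed_adjacency(gene_correlation(lx), beta))
  list(modules = detect_modules(tom, min_size = min_size, expr = lx),
       log_values = lx)
}

trajectory_config <- function(seed, n_lineages, noise_sd = 0.2) {
  synthetic_config(
    150, 250,
    modules = list(list(size = 40), list(size = 40), list(size = 40)),
    trajectory = list(n_lineages = n_lineages, modules_up = c(1, 2),
                      modules_down = 3, scale = 3),
    noise_sd = noise_sd, seed = seed)
}

# embed (5D for robust geometry) -> SNN cluster -> root -> lineages
run_trajectory <- function(d, k = 20, n_dim = 5) {
  lx <- log_transform(d$expr)
  coords <- embed_cells(lx, n_dim = n_dim)
  labels <- cluster_snn(coords, k = k)
  root <- select_root_cluster(labels, d$expr$cell_meta)
  lineages <- infer_lineages(coords, labels, root)
  list(coords = coords, labels = labels, root = root, lineages = lineages)
}
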