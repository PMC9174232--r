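# Trajectory analysis: 2D embedding, shared-nearest-neighbour clustering,
# centroid-MST lineage inference, centroid-path pseudotime, and module
# eigengene dynamics along pseudotime.

#' Embed cells in two dimensions
#'
#' Deterministic 2D embedding of cells by classical metric multidimensional
#' scaling on Euclidean distances (`method = "mds"`, the default) or the
#' first two principal components (`method = "pca"`). The backend is kept
#' pluggable but deliberately deterministic, so downstream lineage and
#' pseudotime results are reproducible without a stochastic embedder.
#'
#' @inheritParams gene_correlation
#' @param n_neighbors neighbourhood size contract carried by the interface;
#'   must be smaller than the number of cells.
#' @param method "mds" or "pca".
#' @param n_dim number of dimensions (default 2 for display; lineage
#'   geometry is more robust in a handful of dimensions, e.g. 5).
#' @param seed integer; retained for interface stability (both backends are
#'   deterministic).
#' @return cell x `n_dim` coordinate matrix (columns `dim1`, `dim2`, ...).
#' @export
embed_cells <- function(x, n_neighbors = 15, method = c("mds", "pca"),
                        n_dim = 2, seed = 1) {
  v <- expr_values(x)
  method <- match.arg(method)
  n <- ncol(v)
  if (n < 2) stop("cannot embed a single cell")
  if (n_neighbors >= n) stop("'n_neighbors' must be < number of cells")
  if (n_dim < 1) stop("'n_dim' must be >= 1")
  set.seed(seed)
  m <- t(v)  # cells x genes
  coords <- switch(method,
    mds = stats::cmdscale(stats::dist(m), k = n_dim),
    pca = {
      keep <- apply(m, 2L, stats::sd) > 0
      p <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE,
                         scale. = FALSE)
      p$x[, seq_len(min(n_dim, ncol(p$x))), drop = FALSE]
    })
  if (ncol(coords) < n_dim)  # degenerate geometry: pad with zeros
    coords <- cbind(coords, matrix(0, nrow(coords), n_dim - ncol(coords)))
  dimnames(coords) <- list(colnames(v), paste0("dim", seq_len(n_dim)))
  coords
}

#' Shared-nearest-neighbour graph clustering
#'
#' Builds a k-nearest-neighbour graph (Euclidean distances in the supplied
#' space), connects every pair of cells that are mutual or one-way kNN
#' neighbours with weight `shared / (2k - shared)` where `shared` is the
#' number of common k-nearest neighbours, drops zero-weight edges, and
#' maximises modularity by deterministic greedy agglomeration. Cluster
#' labels are integers 1, 2, ... ordered by decreasing cluster size.
#'
#' @param x cell x feature matrix (e.g. coordinates from [embed_cells()]),
#'   or an `sc_expr`, in which case cells are taken from its columns.
#' @param k neighbourhood size (>= 1, smaller than the number of cells).
#' @param seed integer; the agglomeration is deterministic, the seed is
#'   kept for interface stability.
#' @return named integer vector: cell -> cluster label.
#' @export
cluster_snn <- function(x, k = 10, seed = 1) {
  m <- cells_by_features(x)
  n <- nrow(m)
  if (k < 1) stop("'k' must be >= 1")
  if (k >= n) stop("'k' must be < number of cells")
  set.seed(seed)
  d <- as.matrix(stats::dist(m))
  if (all(d == 0))  # degenerate geometry: one cluster
    return(stats::setNames(rep(1L, n), rownames(m)))
  # k nearest neighbours of each cell (excluding itself; ties by index)
  nn <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  nn_sets <- lapply(seq_len(n), function(i) nn[i, ])
  edges <- list()
  w <- numeric(0)
  ei <- 0L
  for (i in seq_len(n)) {
    cand <- unique(c(nn_sets[[i]], which(vapply(nn_sets, function(s)
      i %in% s, TRUE))))
    cand <- cand[cand > i]
    for (j in cand) {
      shared <- length(intersect(nn_sets[[i]], nn_sets[[j]]))
      if (shared == 0) next
      ei <- ei + 1L
      edges[[ei]] <- c(i, j)
      w[ei] <- shared / (2 * k - shared)
    }
  }
  if (!ei) return(stats::setNames(seq_len(n) * 0L + 1L, rownames(m)))
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  memb <- igraph::membership(igraph::cluster_fast_greedy(g))
  relabel_by_size(stats::setNames(as.integer(memb), rownames(m)))
}

cells_by_features <- function(x) {
  if (inherits(x, "sc_expr")) return(t(x$values))
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an 'sc_expr' or a cells-by-features numeric matrix")
}

relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  stats::setNames(as.integer(map[as.character(labels)]), names(labels))
}

#' Infer lineages from cluster centroids
#'
#' Builds the minimum spanning tree over cluster centroids (Euclidean
#' distance) and returns every root-to-leaf path as an ordered cluster
#' sequence. A single cluster yields one trivial lineage containing only
#' the root. Deterministic; ties break by cluster label order.
#'
#' @param coords cell x 2 coordinate matrix.
#' @param labels named cluster labels from [cluster_snn()] (same cells).
#' @param root cluster label of the root (e.g. the control-dominated
#'   cluster); see [select_root_cluster()].
#' @return list of character vectors, each an ordered cluster sequence
#'   starting at the root.
#' @export
infer_lineages <- function(coords, labels, root) {
  labs <- sort(unique(as.character(labels)))
  root <- as.character(root)
  if (!root %in% labs) stop("root cluster '", root, "' not in labels")
  if (length(labs) == 1) return(list(labs))
  cent <- do.call(rbind, lapply(labs, function(l)
    colMeans(coords[as.character(labels) == l, , drop = FALSE])))
  rownames(cent) <- labs
  dm <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g)
  deg <- igraph::degree(mst)
  leaves <- names(deg)[deg == 1 & names(deg) != root]
  if (!length(leaves)) leaves <- setdiff(names(deg), root)
  lineages <- lapply(sort(leaves), function(lf) {
    p <- igraph::shortest_paths(mst, from = root, to = lf)$vpath[[1]]
    igraph::V(mst)$name[as.integer(p)]
  })
  lineages
}

#' Default root: the control-dominated cluster
#'
#' Picks the cluster with the highest fraction of cells labelled with
#' `control_value` in the metadata column `condition_col`; ties break by
#' cluster label.
#'
#' @param labels named cluster labels.
#' @param cell_meta data.frame with cell metadata (rownames = cell ids).
#' @param condition_col metadata column holding the condition.
#' @param control_value label identifying control cells.
#' @return the root cluster label (character).
#' @export
select_root_cluster <- function(labels, cell_meta,
                                condition_col = "condition",
                                control_value = "control") {
  if (is.null(cell_meta) || !condition_col %in% colnames(cell_meta))
    stop("no '", condition_col, "' metadata; specify the root explicitly")
  cond <- cell_meta[names(labels), condition_col]
  frac <- tapply(cond == control_value, as.character(labels), mean)
  names(sort(frac, decreasing = TRUE))[1L]
}

#' Pseudotime along a lineage's centroid path
#'
#' Projects each cell of the lineage's clusters orthogonally onto the
#' piecewise-linear path through the lineage's cluster centroids; the
#' pseudotime is the arc length from the root end to the projection, scaled
#' to \[0, 1\] by the total path length. Cells projecting beyond an endpoint
#' clamp to 0 or 1. Cells outside the lineage get NA.
#'
#' @inheritParams infer_lineages
#' @param lineage ordered cluster sequence (one element of
#'   [infer_lineages()]).
#' @return named numeric vector over all cells; NA off-lineage.
#' @export
compute_pseudotime <- function(coords, lineage, labels) {
  if (!length(lineage)) stop("empty lineage")
  labs <- as.character(labels)
  unknown <- setdiff(lineage, unique(labs))
  if (length(unknown))
    stop("lineage references unknown cluster(s): ",
         paste(unknown, collapse = ", "))
  pt <- stats::setNames(rep(NA_real_, nrow(coords)), rownames(coords))
  on_lineage <- labs %in% lineage
  if (length(lineage) == 1) {
    pt[on_lineage] <- 0
    return(pt)
  }
  cent <- do.call(rbind, lapply(lineage, function(l)
    colMeans(coords[labs == l, , drop = FALSE])))
  seg_len <- sqrt(rowSums((cent[-1, , drop = FALSE] -
                           cent[-nrow(cent), , drop = FALSE])^2))
  cum_len <- c(0, cumsum(seg_len))
  total <- cum_len[length(cum_len)]
  for (ci in which(on_lineage)) {
    p <- coords[ci, ]
    best_d <- Inf
    best_t <- 0
    for (s in seq_along(seg_len)) {
      a <- cent[s, ]
      b <- cent[s + 1L, ]
      ab <- b - a
      u <- if (seg_len[s] > 0) sum((p - a) * ab) / sum(ab^2) else 0
      u <- min(max(u, 0), 1)
      proj <- a + u * ab
      dd <- sum((p - proj)^2)
      if (dd < best_d) {
        best_d <- dd
        best_t <- cum_len[s] + u * seg_len[s]
      }
    }
    pt[ci] <- if (total > 0) best_t / total else 0
  }
  pt
}

#' Module eigengene dynamics along pseudotime
#'
#' Smooths a module eigengene against pseudotime with a sliding local mean
#' (each window holds `span * n` cells nearest in pseudotime), evaluated on
#' a regular 100-point grid. The direction call compares the smoothed
#' endpoint difference with a permutation null (shuffling the eigengene
#' against pseudotime): "increasing" above the upper tail, "decreasing"
#' below the lower tail, "non-monotone" otherwise. `trend` is the endpoint
#' difference standardised by the curve's range, so a perfectly monotone
#' increasing curve has trend 1.
#'
#' @param eigengenes module x cell matrix from [module_eigengenes()].
#' @param pseudotime named per-cell pseudotime (NA allowed off-lineage).
#' @param module module id (row of `eigengenes`).
#' @param span fraction of cells per smoothing window, in (0, 1].
#' @param n_grid grid resolution.
#' @param n_perm permutation-null size for the direction call.
#' @param alpha two-sided tail probability for the direction call.
#' @param seed integer seed for the permutation null.
#' @return object of class `module_dynamics`: list with `grid`, `curve`,
#'   `direction`, `trend`, `endpoint_diff`, `span`.
#' @export
module_dynamics <- function(eigengenes, pseudotime, module, span = 0.3,
                            n_grid = 100, n_perm = 1000, alpha = 0.05,
                            seed = 1) {
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  if (!module %in% rownames(eigengenes)) stop("unknown module: ", module)
  cells <- intersect(colnames(eigengenes), names(pseudotime))
  pt <- pseudotime[cells]
  keep <- !is.na(pt)
  pt <- pt[keep]
  me <- eigengenes[module, cells][keep]
  if (length(pt) < 5) stop("need at least 5 cells on the lineage")
  set.seed(seed)
  w <- max(2L, ceiling(span * length(pt)))
  grid <- seq(min(pt), max(pt), length.out = n_grid)
  smooth_curve <- function(values) {
    vapply(grid, function(g) {
      idx <- order(abs(pt - g))[seq_len(w)]
      mean(values[idx])
    }, numeric(1))
  }
  curve <- smooth_curve(me)
  endpoint_diff <- curve[n_grid] - curve[1L]
  null_diff <- vapply(seq_len(n_perm), function(i) {
    cs <- smooth_curve(sample(me))
    cs[n_grid] - cs[1L]
  }, numeric(1))
  lo <- stats::quantile(null_diff, alpha / 2)
  hi <- stats::quantile(null_diff, 1 - alpha / 2)
  direction <- if (endpoint_diff > hi) "increasing"
               else if (endpoint_diff < lo) "decreasing"
               else "non-monotone"
  rng <- max(curve) - min(curve)
  structure(list(grid = grid, curve = curve, direction = direction,
                 trend = if (rng > 0) endpoint_diff / rng else 0,
                 endpoint_diff = endpoint_diff, span = span),
            class = "module_dynamics")
}

#' @export
print.module_dynamics <- function(x, ...) {
  cat("module_dynamics: direction ", x$direction,
      sprintf(" (trend %.3f, endpoint diff %.3f, span %.2f)\n",
              x$trend, x$endpoint_diff, x$span), sep = "")
  invisible(x)
}

#' Mutual exclusivity of two module eigengenes
#'
#' Pearson correlation of two module eigengenes across cells; the pair is
#' flagged mutually exclusive when the correlation is at or below
#' `threshold` (default -0.3), the signature of two gene programs that are
#' active in disjoint cell states.
#'
#' @inheritParams module_dynamics
#' @param module_a,module_b module ids (rows of `eigengenes`).
#' @param threshold correlation at or below which the pair is flagged.
#' @return list with `correlation` and `mutually_exclusive`.
#' @export
module_exclusivity <- function(eigengenes, module_a, module_b,
                               threshold = -0.3) {
  for (m in c(module_a, module_b))
    if (!m %in% rownames(eigengenes)) stop("unknown module: ", m)
  r <- stats::cor(eigengenes[module_a, ], eigengenes[module_b, ])
  list(correlation = r, mutually_exclusive = r <= threshold)
}
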