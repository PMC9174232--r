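# Signed weighted co-expression networks: soft-threshold selection,
# adjacency, topological overlap, module detection with a minimum-size merge
# rule, module eigengenes and module membership.

#' Pearson gene-gene correlation with constant-gene handling
#'
#' Correlation across cells between all gene pairs. Genes with zero variance
#' get correlation 0 with every other gene (flagged in the `constant`
#' attribute) rather than NaN, so they fall out of the network instead of
#' poisoning it.
#'
#' @param x `sc_expr` or genes-by-cells matrix (typically log-transformed).
#' @return symmetric gene x gene correlation matrix with unit diagonal and
#'   attribute `constant` (character vector of zero-variance genes).
#' @export
gene_correlation <- function(x) {
  v <- expr_values(x)
  sds <- apply(v, 1L, stats::sd)
  const <- rownames(v)[sds == 0 | is.na(sds)]
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  attr(cc, "constant") <- const
  cc
}

#' Signed adjacency from correlations
#'
#' The signed weighted-network convention `a_ij = ((1 + cor_ij) / 2)^beta`:
#' perfectly anti-correlated genes get adjacency 0, uncorrelated genes get
#' `(1/2)^beta`, perfectly correlated genes get 1.
#'
#' @param cor_mat symmetric correlation matrix, entries in \[-1, 1\], unit
#'   diagonal.
#' @param beta soft-threshold power, positive integer.
#' @return adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
signed_adjacency <- function(cor_mat, beta) {
  if (beta < 1) stop("'beta' must be >= 1")
  if (max(abs(cor_mat)) > 1 + 1e-12) stop("correlations must lie in [-1, 1]")
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  a
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivity `k_i = sum_{j != i} a_ij`, bins `k`, and regresses
#' `log10 p(k)` on `log10 k` across bins. The signed fit index is
#' `R^2 x sign(-slope)` so that only decreasing degree distributions count
#' as scale-free. Returns the smallest power reaching `r2_target`
#' (convention: 0.85), or the power maximising the fit with
#' `reached_target = FALSE` when none does.
#'
#' @inheritParams gene_correlation
#' @param powers ascending integer grid of candidate powers.
#' @param r2_target required signed scale-free fit index.
#' @param n_breaks number of equal-width connectivity bins.
#' @return list with `beta`, `reached_target`, and `fit` (data.frame with
#'   `power`, `r2_signed`, `slope`, `mean_k`).
#' @export
pick_soft_threshold <- function(x, powers = 1:20, r2_target = 0.85,
                                n_breaks = 10) {
  v <- expr_values(x)
  if (nrow(v) < 3) stop("need at least 3 genes")
  if (!length(powers) || is.unsorted(powers))
    stop("'powers' must be a non-empty ascending grid")
  cc <- gene_correlation(v)
  fit <- do.call(rbind, lapply(powers, function(b) {
    a <- signed_adjacency(cc, b)
    k <- rowSums(a) - 1
    sf <- scale_free_fit(k, n_breaks)
    data.frame(power = b, r2_signed = sf$r2_signed, slope = sf$slope,
               mean_k = mean(k))
  }))
  hit <- which(fit$r2_signed >= r2_target)
  if (length(hit)) {
    beta <- fit$power[hit[1L]]
    reached <- TRUE
  } else {
    beta <- fit$power[which.max(fit$r2_signed)]
    reached <- FALSE
    warning("no power reached the scale-free fit target ", r2_target,
            "; using the best power ", beta)
  }
  list(beta = beta, reached_target = reached, fit = fit)
}

scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  cut_k <- cut(k, n_breaks)
  dk <- tapply(k, cut_k, mean)
  pk <- tapply(k, cut_k, length) / length(k)
  keep <- !is.na(dk) & dk > 0
  if (sum(keep) < 2) stop("fewer than 2 non-empty connectivity bins")
  lx <- log10(dk[keep])
  ly <- log10(pk[keep])
  f <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(f)[2L])
  r2 <- summary(f)$r.squared
  list(r2_signed = -sign(slope) * r2, slope = slope)
}

#' Topological overlap matrix
#'
#' For `i != j`,
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `tom_ii = 1`. High TOM means two genes are directly connected and share
#' neighbours; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency symmetric matrix in \[0, 1\] with unit diagonal.
#' @return symmetric TOM in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("'adjacency' must be symmetric")
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`. The dendrogram is
#' cut at the midpoint of the largest gap in the sorted merge heights
#' (co-expression blocks merge at low heights, background genes near 1, so
#' the gap separates module formation from background agglomeration); a
#' fixed `cut_height` may be supplied instead. A branch is kept as a stable
#' candidate module only if its mean within-branch TOM exceeds
#' `stability_ratio` times its mean TOM to non-members (pure-noise genes
#' fail this and end up unassigned). Stable modules smaller than `min_size`
#' are then merged into the closest larger module (closeness by correlation
#' of module eigengenes when `expr` is supplied, else of TOM centroid
#' profiles) -- the "modules with fewer than `min_size` genes are merged
#' with their closest larger neighbouring module" rule, default 30. Pairs
#' of modules whose representatives correlate above `merge_cor` are also
#' merged. Remaining genes attach to their best module only if their mean
#' TOM to it exceeds the 95th percentile of their TOM to all genes;
#' otherwise they stay "unassigned". Modules are named M1, M2, ... by
#' decreasing size.
#'
#' @param tom topological overlap matrix from [topological_overlap()].
#' @param min_size minimum module size (default 30).
#' @param merge_cor correlation above which two modules are merged
#'   (default 0.75, mirroring a merge height of 0.25).
#' @param expr optional genes-by-cells matrix (same genes, same order as
#'   `tom` rows) used to compute eigengenes for the merge steps.
#' @param cut_height optional fixed dissimilarity at which to cut the
#'   dendrogram; by default the midpoint of the largest merge-height gap.
#' @param stability_ratio required ratio of within-branch to out-of-branch
#'   mean TOM for a branch to count as a module.
#' @return object of class `module_set`: list with `assignment` (named
#'   character vector, gene -> "M1"... or "unassigned") and `modules`
#'   (named list of gene id vectors).
#' @export
detect_modules <- function(tom, min_size = 30, merge_cor = 0.75,
                           expr = NULL, cut_height = NULL,
                           stability_ratio = 2) {
  if (min_size < 2) stop("'min_size' must be >= 2")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  n <- nrow(tom)
  d <- 1 - tom
  h <- stats::hclust(stats::as.dist(d), method = "average")
  if (is.null(cut_height)) {
    ht <- sort(h$height)
    if (length(ht) > 1) {
      i <- which.max(diff(ht))
      cut_height <- (ht[i] + ht[i + 1L]) / 2
    } else cut_height <- h$height / 2
  }
  cl <- stats::cutree(h, h = cut_height)
  branches <- split(seq_len(n), cl)
  branches <- branches[lengths(branches) >= 2]

  stable <- Filter(function(idx) {
    within <- mean(tom[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
    out <- if (length(idx) < n) mean(tom[idx, -idx, drop = FALSE]) else 0
    within > stability_ratio * out
  }, branches)

  if (!length(stable)) {
    warning("no stable modules found; all genes unassigned")
    assignment <- stats::setNames(rep("unassigned", n), genes)
    return(structure(list(assignment = assignment, modules = list()),
                     class = "module_set"))
  }
  modules <- unname(stable)

  representative <- function(idx) {
    if (!is.null(expr)) {
      sub <- expr[idx, , drop = FALSE]
      module_pc1(sub)
    } else colMeans(tom[idx, , drop = FALSE])
  }

  # merge undersized modules into the closest larger module; a small module
  # with no larger neighbour cannot satisfy the size invariant and is
  # dissolved to unassigned
  repeat {
    sizes <- lengths(modules)
    small <- which(sizes < min_size)
    if (!length(small)) break
    s <- small[which.min(sizes[small])]
    larger <- which(sizes > sizes[s])
    if (!length(larger)) {
      modules <- modules[-small]
      break
    }
    reps <- lapply(modules, representative)
    cors <- vapply(larger, function(j)
      stats::cor(reps[[s]], reps[[j]]), numeric(1))
    tgt <- larger[which.max(cors)]
    modules[[tgt]] <- c(modules[[tgt]], modules[[s]])
    modules[[s]] <- NULL
  }
  if (!length(modules)) {
    warning("no module survived size filtering; all genes unassigned")
    assignment <- stats::setNames(rep("unassigned", n), genes)
    return(structure(list(assignment = assignment, modules = list()),
                     class = "module_set"))
  }

  # merge highly correlated module pairs
  repeat {
    if (length(modules) < 2) break
    reps <- do.call(cbind, lapply(modules, representative))
    rc <- stats::cor(reps)
    diag(rc) <- -Inf
    mx <- which(rc == max(rc), arr.ind = TRUE)[1L, ]
    if (rc[mx[1L], mx[2L]] <= merge_cor) break
    i <- min(mx); j <- max(mx)
    modules[[i]] <- c(modules[[i]], modules[[j]])
    modules[[j]] <- NULL
  }

  # attach leftover genes only when clearly closer to a module than to
  # the background
  assigned <- unlist(modules)
  leftover <- setdiff(seq_len(n), assigned)
  if (length(leftover) && length(modules)) {
    for (g in leftover) {
      mean_tom <- vapply(modules, function(idx) mean(tom[g, idx]), numeric(1))
      best <- which.max(mean_tom)
      null_q <- stats::quantile(tom[g, -g], 0.95)
      if (mean_tom[best] > null_q)
        modules[[best]] <- c(modules[[best]], g)
    }
  }

  modules <- modules[order(-lengths(modules),
                           vapply(modules, min, 0L))]
  names(modules) <- paste0("M", seq_along(modules))
  assignment <- stats::setNames(rep("unassigned", n), genes)
  for (m in names(modules)) assignment[modules[[m]]] <- m
  modules <- lapply(modules, function(idx) genes[sort(idx)])
  structure(list(assignment = assignment, modules = modules),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat("module_set: ", length(x$modules), " modules over ",
      length(x$assignment), " genes (",
      sum(x$assignment == "unassigned"), " unassigned)\n", sep = "")
  if (length(sizes))
    print(sizes)
  invisible(x)
}

# First principal component of a genes-by-cells block after per-gene
# standardisation; returns the per-cell score vector.
module_pc1 <- function(sub) {
  s <- t(scale(t(sub)))
  sv <- svd(s, nu = 0, nv = 1)
  drop(sv$v[, 1L])
}

#' Module eigengenes
#'
#' Per-cell module eigengene (ME): first principal component of the module's
#' per-gene standardised expression, scaled to unit variance and oriented so
#' that the mean correlation with the module's member genes is nonnegative
#' (ties resolved so the first member gene correlates positively).
#'
#' @inheritParams gene_correlation
#' @param assignment a `module_set` from [detect_modules()], or a named
#'   character vector gene -> module id / "unassigned".
#' @return matrix module x cell; attribute `var_explained` gives the
#'   fraction of standardised variance captured per module.
#' @export
module_eigengenes <- function(x, assignment) {
  v <- expr_values(x)
  asg <- if (inherits(assignment, "module_set")) assignment$assignment
         else assignment
  mods <- sort(unique(asg[asg != "unassigned"]))
  mods <- mods[order(as_module_rank(mods))]
  if (!length(mods)) stop("no named modules in assignment")
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(v),
               dimnames = list(mods, colnames(v)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(asg)[asg == m]
    genes <- intersect(genes, rownames(v))
    if (length(genes) < 2)
      stop("module ", m, " has fewer than 2 genes in the matrix")
    sub <- v[genes, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0))
      stop("module ", m, " contains constant gene(s): ",
           paste(utils::head(genes[sds == 0], 3), collapse = ", "))
    s <- t(scale(t(sub)))
    sv <- svd(s, nu = 0, nv = 1)
    e <- drop(sv$v[, 1L])
    e <- e / stats::sd(e)
    mc <- mean(stats::cor(t(sub), e))
    if (mc < 0 || (mc == 0 && stats::cor(sub[1L, ], e) < 0)) e <- -e
    me[m, ] <- e
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  attr(me, "var_explained") <- ve
  me
}

as_module_rank <- function(ids) {
  num <- suppressWarnings(as.numeric(sub("^M", "", ids)))
  ifelse(is.na(num), Inf, num)
}

#' Module membership (gene-eigengene correlation)
#'
#' Pearson correlation of every gene with every module eigengene. Constant
#' genes get correlation 0 and are flagged in the `constant` attribute.
#'
#' @inheritParams gene_correlation
#' @param eigengenes module x cell matrix from [module_eigengenes()].
#' @return gene x module correlation matrix with attribute `constant`.
#' @export
module_membership <- function(x, eigengenes) {
  v <- expr_values(x)
  if (!identical(colnames(v), colnames(eigengenes)))
    stop("expression and eigengenes must cover the same cells in order")
  sds <- apply(v, 1L, stats::sd)
  const <- rownames(v)[sds == 0]
  mem <- suppressWarnings(stats::cor(t(v), t(eigengenes)))
  mem[is.na(mem)] <- 0
  attr(mem, "constant") <- const
  mem
}

#' Top genes most correlated with a module eigengene
#'
#' The classic hub-gene ranking: the `k` genes with the highest membership
#' correlation to a named module, descending, ties broken lexicographically
#' by gene id. Requesting more genes than exist returns all of them.
#'
#' @param membership gene x module matrix from [module_membership()].
#' @param module module id (column of `membership`).
#' @param k number of genes to return (default 10).
#' @return data.frame with `gene` and `correlation`, ordered.
#' @export
top_module_genes <- function(membership, module, k = 10) {
  if (!module %in% colnames(membership))
    stop("unknown module: ", module)
  cors <- membership[, module]
  ord <- order(-cors, rownames(membership))
  ord <- utils::head(ord, k)
  data.frame(gene = rownames(membership)[ord],
             correlation = unname(cors[ord]),
             stringsAsFactors = FALSE)
}
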