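# Random-forest permutation importance for module/biomarker ranking, and
# cross-species module overlap by hypergeometric test.

#' Rank features by random-forest permutation importance
#'
#' Trains a random forest on a sample-by-feature matrix and class labels and
#' ranks features by mean decrease in accuracy: the average over trees of
#' the drop in out-of-bag accuracy when the feature is permuted within the
#' out-of-bag samples (raw, unscaled importance). A constant feature has
#' importance exactly 0. Deterministic given the seed.
#'
#' @param features numeric sample x feature matrix.
#' @param labels class label per sample; at least 2 classes with >= 2
#'   samples each.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @return object of class `importance_result`: list with `importance`
#'   (data.frame `feature`, `mean_decrease_accuracy`, `rank`),
#'   `oob_accuracy`, `n_trees`, `seed`.
#' @export
rank_feature_importance <- function(features, labels, n_trees = 500,
                                    seed = 1) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("labels contain a single class")
  if (any(table(y) < 2)) stop("every class needs >= 2 samples")
  if (nrow(features) != length(y))
    stop("features and labels disagree on sample count")
  set.seed(seed)
  rf <- randomForest::randomForest(x = features, y = y, ntree = n_trees,
                                   importance = TRUE)
  mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  ord <- order(-mda, names(mda))
  imp <- data.frame(feature = names(mda)[ord],
                    mean_decrease_accuracy = unname(mda[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  oob <- 1 - rf$err.rate[n_trees, "OOB"]
  structure(list(importance = imp, oob_accuracy = unname(oob),
                 n_trees = n_trees, seed = seed),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("importance_result: ", nrow(x$importance), " features, OOB accuracy ",
      sprintf("%.3f", x$oob_accuracy), " (", x$n_trees, " trees)\n", sep = "")
  print(utils::head(x$importance, 10))
  invisible(x)
}

#' Features significantly involved in classification
#'
#' Operationalises "significantly involved in classification" as: observed
#' mean decrease in accuracy above the `1 - alpha/2` quantile of a
#' label-permutation null (labels shuffled, forest refit, maximum feature
#' importance recorded per permutation).
#'
#' @inheritParams rank_feature_importance
#' @param n_perm number of label permutations (default 100).
#' @param alpha two-sided tail probability (default 0.05, i.e. the 97.5th
#'   null percentile).
#' @return list with `significant` (character vector of features),
#'   `null_cutoff`, `observed` (the `importance_result`).
#' @export
importance_significance <- function(features, labels, n_trees = 500,
                                    n_perm = 100, alpha = 0.05, seed = 1) {
  obs <- rank_feature_importance(features, labels, n_trees = n_trees,
                                 seed = seed)
  set.seed(seed + 1L)
  null_max <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(labels)
    rf <- randomForest::randomForest(x = as.matrix(features),
                                     y = factor(perm), ntree = n_trees,
                                     importance = TRUE)
    max(randomForest::importance(rf, type = 1, scale = FALSE)[, 1L])
  }, numeric(1))
  cutoff <- stats::quantile(null_max, 1 - alpha / 2)
  sig <- obs$importance$feature[obs$importance$mean_decrease_accuracy > cutoff]
  list(significant = sig, null_cutoff = unname(cutoff), observed = obs)
}

#' Cross-species module overlap
#'
#' Maps the modules of dataset A through an ortholog map, then tests every
#' (module A, module B) pair for gene overlap with a one-sided
#' hypergeometric upper-tail test over the shared mapped universe, BH-
#' adjusted across all pairs. `best_match` pairs each A module with the B
#' module minimising the adjusted p (ties by larger overlap, then by module
#' name); pairs with adjusted p >= `alpha` yield no match.
#'
#' @param modules_a,modules_b named lists: module -> gene set (A genes in
#'   the source namespace, B genes in the target namespace).
#' @param ortholog_map named character vector geneA -> geneB (injective);
#'   NULL for identity mapping.
#' @param universe character vector, the mapped shared gene space.
#' @param alpha adjusted-p cutoff for declaring a match.
#' @return object of class `module_overlap_result`: list with `pairs`
#'   (data.frame `module_a`, `module_b`, `size_a`, `size_b`, `overlap`,
#'   `p`, `adjusted_p`) and `best_match` (named character vector, NA where
#'   unmatched).
#' @export
module_overlap <- function(modules_a, modules_b, ortholog_map = NULL,
                           universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!is.null(ortholog_map)) {
    if (anyDuplicated(ortholog_map[!is.na(ortholog_map)]))
      stop("'ortholog_map' must be injective")
    modules_a <- lapply(modules_a, function(g) {
      mapped <- ortholog_map[intersect(g, names(ortholog_map))]
      unname(mapped[!is.na(mapped)])
    })
  }
  modules_a <- lapply(modules_a, function(g) intersect(unique(g), universe))
  modules_b <- lapply(modules_b, function(g) intersect(unique(g), universe))
  n <- length(universe)
  pairs <- do.call(rbind, lapply(names(modules_a), function(ma) {
    do.call(rbind, lapply(names(modules_b), function(mb) {
      a <- modules_a[[ma]]
      b <- modules_b[[mb]]
      k <- length(intersect(a, b))
      p <- stats::phyper(k - 1, length(a), n - length(a), length(b),
                         lower.tail = FALSE)
      data.frame(module_a = ma, module_b = mb, size_a = length(a),
                 size_b = length(b), overlap = k, p = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs$adjusted_p <- stats::p.adjust(pairs$p, method = "BH")
  best <- stats::setNames(rep(NA_character_, length(modules_a)),
                          names(modules_a))
  for (ma in names(modules_a)) {
    sub <- pairs[pairs$module_a == ma, ]
    sub <- sub[order(sub$adjusted_p, -sub$overlap, sub$module_b), ]
    if (nrow(sub) && sub$adjusted_p[1L] < alpha)
      best[ma] <- sub$module_b[1L]
  }
  structure(list(pairs = pairs, best_match = best),
            class = "module_overlap_result")
}

#' @export
print.module_overlap_result <- function(x, ...) {
  matched <- !is.na(x$best_match)
  cat("module_overlap_result: ", sum(matched), "/", length(x$best_match),
      " modules matched\n", sep = "")
  if (any(matched))
    for (m in names(x$best_match)[matched])
      cat("  ", m, " -> ", x$best_match[m], "\n", sep = "")
  invisible(x)
}
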