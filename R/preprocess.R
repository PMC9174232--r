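#' Filter cells by number of detected genes
#'
#' Retains cells whose number of detected genes (entries strictly greater
#' than zero) is strictly greater than `min_genes`. The strict inequality
#' follows the usual "cells with >N expressed genes were retained" QC
#' convention; typical cutoffs are 300 for droplet data, 500 for public
#' human data and 2000 for deep full-length protocols.
#'
#' @param x `sc_expr` or genes-by-cells matrix.
#' @param min_genes nonnegative integer; a cell is kept iff it detects more
#'   than this many genes.
#' @return the filtered object, same class as the input; genes unchanged.
#' @export
filter_cells_by_detected_genes <- function(x, min_genes = 300) {
  v <- expr_values(x)
  if (min_genes < 0) stop("'min_genes' must be >= 0")
  detected <- colSums(v > 0)
  keep <- detected > min_genes
  if (!any(keep))
    stop("no cells detect more than ", min_genes, " genes; empty result")
  expr_like(x, v[, keep, drop = FALSE])
}

#' Filter genes by minimum expression
#'
#' Keeps genes expressed at or above `min_value` in at least `min_cells`
#' cells. With the defaults (`min_value = 10`, `min_cells = 1`) this is the
#' classic "FPKM >= 10 in at least one sample" gate applied before building
#' a co-expression network.
#'
#' @inheritParams filter_cells_by_detected_genes
#' @param min_value nonnegative expression threshold (inclusive).
#' @param min_cells minimum number of cells (>= 1) reaching `min_value`.
#' @return the filtered object; cells unchanged.
#' @export
filter_genes_by_expression <- function(x, min_value = 10, min_cells = 1) {
  v <- expr_values(x)
  if (min_value < 0) stop("'min_value' must be >= 0")
  if (min_cells < 1) stop("'min_cells' must be >= 1")
  keep <- rowSums(v >= min_value) >= min_cells
  if (!any(keep))
    stop("no genes reach ", min_value, " in ", min_cells,
         " cell(s); empty result")
  expr_like(x, v[keep, , drop = FALSE])
}

#' Log-transform expression values
#'
#' Elementwise `log2(x + 1)`; monotone and zero-preserving. Applied before
#' any correlation-based step to stabilise the heavy right tail of
#' FPKM-scale values.
#'
#' @inheritParams filter_cells_by_detected_genes
#' @return transformed object, same class as the input.
#' @export
log_transform <- function(x) {
  v <- expr_values(x)
  if (any(v < 0)) stop("log_transform requires nonnegative values")
  expr_like(x, log2(v + 1))
}

#' Two-group differential expression (Wilcoxon rank-sum)
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two disjoint cell
#' groups with Benjamini-Hochberg adjustment. Fold change is
#' `log2((mean_A + eps) / (mean_B + eps))` with `eps = 1e-9`. A gene is
#' flagged significant iff `adjusted_p < alpha` and
#' `|log2_fold_change| > lfc_threshold` (defaults 0.05 and 0.25, the usual
#' marker-detection cutoffs).
#'
#' The exact rank-sum distribution is used when both groups have at most 10
#' cells and the gene has no tied values; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @inheritParams filter_cells_by_detected_genes
#' @param group_a,group_b character vectors of cell ids (or logical masks
#'   over columns); must be disjoint, each of size >= 2.
#' @param lfc_threshold minimum absolute log2 fold change for significance.
#' @param alpha adjusted-p cutoff for significance.
#' @return data.frame of class `de_table` with columns `gene`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `mean_A`, `mean_B`,
#'   `significant`, ordered by `p_value`.
#' @export
differential_expression <- function(x, group_a, group_b,
                                    lfc_threshold = 0.25, alpha = 0.05) {
  v <- expr_values(x)
  a <- resolve_cells(v, group_a)
  b <- resolve_cells(v, group_b)
  if (length(intersect(a, b)))
    stop("groups must be disjoint")
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 cells")
  eps <- 1e-9
  va <- v[, a, drop = FALSE]
  vb <- v[, b, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  lfc <- log2((mean_a + eps) / (mean_b + eps))
  small <- length(a) <= 10 && length(b) <= 10
  p <- vapply(seq_len(nrow(v)), function(i) {
    xa <- va[i, ]
    xb <- vb[i, ]
    exact <- small && !anyDuplicated(c(xa, xb))
    suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # constant gene across both groups
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene = rownames(v),
    log2_fold_change = lfc,
    p_value = p,
    adjusted_p = padj,
    mean_A = mean_a,
    mean_B = mean_b,
    significant = padj < alpha & abs(lfc) > lfc_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

resolve_cells <- function(values, cells) {
  if (is.logical(cells)) {
    if (length(cells) != ncol(values))
      stop("logical cell selector has wrong length")
    return(colnames(values)[cells])
  }
  cells <- as.character(cells)
  missing <- setdiff(cells, colnames(values))
  if (length(missing))
    stop("unknown cell id(s): ", paste(utils::head(missing, 3), collapse = ", "))
  if (!length(cells)) stop("empty cell group")
  cells
}
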