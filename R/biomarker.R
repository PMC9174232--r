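# ROC/AUC biomarker analysis: Mann-Whitney AUC, ROC curves, the paired
# DeLong test (with a stratified-bootstrap alternative), and the
# diagnosis-versus-severity screen.

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `AUC = (#\{pos > neg\} + 0.5 #\{ties\}) / (n_pos * n_neg)`: the
#' probability that a random positive sample scores above a random negative
#' one, with half credit for ties. Computed via midranks, so it is exact
#' and O(n log n).
#'
#' @param scores numeric vector.
#' @param labels binary labels (logical, 0/1, or a factor whose second
#'   level is the positive class).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y))
    stop("scores and labels differ in length")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos < 1 || n_neg < 1)
    stop("need at least one positive and one negative sample")
  r <- rank(scores)  # midranks handle ties with 0.5 credit
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
    return(labels == levels(labels)[2L])
  }
  u <- sort(unique(labels))
  if (length(u) != 2) stop("labels must be binary")
  labels == u[2L]
}

#' ROC curve
#'
#' Thresholds at each unique score value, descending ("score >= threshold"
#' calls positive), giving a step curve from (0, 0) to (1, 1) with both
#' coordinates non-decreasing. The trapezoidal area equals the
#' Mann-Whitney [auc()] estimator to numerical precision.
#'
#' @inheritParams auc
#' @return object of class `roc_result`: list with `curve` (data.frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y))
    stop("scores and labels differ in length")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos < 1 || n_neg < 1)
    stop("need at least one positive and one negative sample")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[y] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!y] >= t) / n_neg, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  area <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  structure(list(curve = curve, auc = area, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties half credit), and symmetrically for negatives.
placement_values <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  v10 <- vapply(pos, function(s)
    (sum(s > neg) + 0.5 * sum(s == neg)) / length(neg), numeric(1))
  v01 <- vapply(neg, function(s)
    (sum(pos > s) + 0.5 * sum(pos == s)) / length(pos), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Compare two paired AUCs
#'
#' Tests whether two markers measured on the same samples discriminate the
#' same binary outcome equally well. The primary method is the paired
#' DeLong test: the difference of the two Mann-Whitney AUCs is standardised
#' by a variance estimated from the covariance of per-sample placement
#' values, and referred to a two-sided standard normal. The alternative is
#' a stratified bootstrap (resampling positives and negatives separately):
#' `z = delta / sd(bootstrap deltas)` against a standard normal.
#'
#' @param scores_1,scores_2 two score vectors over the same samples.
#' @inheritParams auc
#' @param method "delong" (default) or "bootstrap".
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed (bootstrap only).
#' @return object of class `auc_comparison`: list with `auc_1`, `auc_2`,
#'   `delta`, `p_value`, `method`.
#' @export
compare_auc_paired <- function(scores_1, scores_2, labels,
                               method = c("delong", "bootstrap"),
                               n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  y <- as_binary_labels(labels)
  if (length(scores_1) != length(y) || length(scores_2) != length(y))
    stop("scores and labels differ in length")
  a1 <- auc(scores_1, y)
  a2 <- auc(scores_2, y)
  delta <- a1 - a2
  if (method == "delong") {
    p1 <- placement_values(scores_1, y)
    p2 <- placement_values(scores_2, y)
    m <- length(p1$v10)
    n <- length(p1$v01)
    s10 <- stats::cov(cbind(p1$v10, p2$v10))
    s01 <- stats::cov(cbind(p1$v01, p2$v01))
    var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
                 (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
    p <- if (var_delta <= 0) {
      if (delta == 0) 1 else 0
    } else 2 * stats::pnorm(-abs(delta) / sqrt(var_delta))
  } else {
    set.seed(seed)
    ip <- which(y)
    im <- which(!y)
    deltas <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
      auc(scores_1[idx], y[idx]) - auc(scores_2[idx], y[idx])
    }, numeric(1))
    s <- stats::sd(deltas)
    p <- if (s == 0) {
      if (delta == 0) 1 else 0
    } else 2 * stats::pnorm(-abs(delta) / s)
  }
  structure(list(auc_1 = a1, auc_2 = a2, delta = delta,
                 p_value = min(p, 1), method = method),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "auc_comparison (%s): AUC1 %.4f vs AUC2 %.4f, delta %.4f, p = %.4g\n",
    x$method, x$auc_1, x$auc_2, x$delta, x$p_value))
  invisible(x)
}

#' Diagnosis-versus-severity biomarker screen
#'
#' For every protein in a multi-group proteome table, computes two AUCs:
#' one for the diagnosis task (e.g. control vs any heart failure) and one
#' for the severity task (e.g. non-advanced vs advanced disease). Markers
#' like NT-proBNP excel at diagnosis; markers like IGFBP7 at severity; the
#' two ranked tables expose the dissociation.
#'
#' @param proteome `proteome_table` (list with `values` protein x sample
#'   and `sample_group`), e.g. from [generate_proteome()].
#' @param diagnosis_split,severity_split lists with `negative` and
#'   `positive` character vectors of group names; each split must select a
#'   non-empty set of samples on both sides (samples in neither side are
#'   ignored for that task).
#' @return data.frame with `protein`, `auc_diagnosis`, `auc_severity`,
#'   `rank_diagnosis`, `rank_severity`.
#' @export
severity_vs_diagnosis_screen <- function(proteome, diagnosis_split,
                                         severity_split) {
  v <- proteome$values
  grp <- as.character(proteome$sample_group)
  task_auc <- function(split) {
    for (side in c("negative", "positive")) {
      missing <- setdiff(split[[side]], unique(grp))
      if (length(missing))
        stop("split references unknown group(s): ",
             paste(missing, collapse = ", "))
    }
    sel <- grp %in% c(split$negative, split$positive)
    if (!any(grp %in% split$negative) || !any(grp %in% split$positive))
      stop("split selects an empty class")
    y <- grp[sel] %in% split$positive
    apply(v[, sel, drop = FALSE], 1L, auc, labels = y)
  }
  a_dx <- task_auc(diagnosis_split)
  a_sev <- task_auc(severity_split)
  out <- data.frame(protein = rownames(v),
                    auc_diagnosis = unname(a_dx),
                    auc_severity = unname(a_sev),
                    stringsAsFactors = FALSE)
  out$rank_diagnosis <- rank(-out$auc_diagnosis, ties.method = "min")
  out$rank_severity <- rank(-out$auc_severity, ties.method = "min")
  out[order(out$rank_diagnosis, out$protein), ]
}
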