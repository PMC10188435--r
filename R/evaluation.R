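#' ROC and precision-recall analysis of HRD scores
#'
#' AUC uses the Mann-Whitney formulation (a randomly chosen positive
#' out-scores a randomly chosen negative; ties credit 1/2), so it is
#' invariant under strictly monotone score transforms. PR-AUC integrates
#' the right-continuous step precision-recall curve over recall.
#'
#' @param scores Numeric scores (higher = more HRD-like).
#' @param labels Class labels; `positive` marks the positive class.
#' @param positive The positive-class label (default `"HRD"`).
#' @return An object of class `"hrd_roc"`: a list with `auc`, `pr_auc`,
#'   `curve` (tibble of `threshold`, `sensitivity`, `specificity`,
#'   `precision`, `recall`), `n_pos`, `n_neg`.
#' @examples
#' r <- eval_roc(c(0.1, 0.4, 0.35, 0.8), c("HRP", "HRP", "HRD", "HRD"))
#' r$auc   # 0.75
#' @export
eval_roc <- function(scores, labels, positive = "HRD") {
  y <- as.integer(as.character(labels) == positive)
  if (length(y) != length(scores)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  # Mann-Whitney AUC via midranks (ties get half credit)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # sweep thresholds from high to low: one point per distinct score
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & y == 0), numeric(1))
  curve <- tibble::tibble(
    threshold = thr,
    sensitivity = tp / n_pos,
    specificity = 1 - fp / n_neg,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), 1),
    recall = tp / n_pos
  )
  # right-continuous step PR curve: precision held across each recall step
  d_recall <- diff(c(0, curve$recall))
  pr_auc <- sum(d_recall * curve$precision)

  structure(list(auc = auc, pr_auc = pr_auc, curve = curve,
                 n_pos = n_pos, n_neg = n_neg), class = "hrd_roc")
}

#' @export
print.hrd_roc <- function(x, ...) {
  cat(sprintf("<hrd_roc>  AUC %.4f  PR-AUC %.4f  (%d pos / %d neg)\n",
              x$auc, x$pr_auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname tidy.hrd_model
#' @export
glance.hrd_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, pr_auc = x$pr_auc,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname tidy.hrd_model
#' @export
tidy.hrd_roc <- function(x, ...) x$curve

#' Confusion matrix and derived metrics at a fixed cutoff
#'
#' @inheritParams eval_roc
#' @param cutoff Call threshold; predicted positive iff `score >= cutoff`
#'   (default 0.2).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff = 0.2,
                                positive = "HRD") {
  y <- as.integer(as.character(labels) == positive)
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1)
}

#' Cutoff maximizing the Youden index
#'
#' Candidate cutoffs are midpoints between adjacent distinct scores (plus
#' the extremes); the cutoff with maximal J = sensitivity + specificity - 1
#' is returned, the lowest such cutoff on ties.
#'
#' @inheritParams eval_roc
#' @return A list: `cutoff` and `j` (the Youden index attained).
#' @export
youden_cutoff <- function(scores, labels, positive = "HRD") {
  y <- as.integer(as.character(labels) == positive)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  j <- vapply(cand, function(t) {
    sum(scores >= t & y == 1) / n_pos + sum(scores < t & y == 0) / n_neg - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]   # lowest cutoff on ties
  list(cutoff = cand[best], j = j[best])
}

#' ROC analysis of a single component count as a biomarker
#'
#' Uses the raw component count (e.g. `BP10MB[1]` or `SS[>7 & <=8]`) as the
#' classification score.
#'
#' @param features A feature-matrix tibble.
#' @param component A component label present in the matrix.
#' @inheritParams eval_roc
#' @param labels Labels tibble (`sample_id`, `label`) or aligned vector.
#' @return An `"hrd_roc"` object.
#' @export
biomarker_roc <- function(features, component, labels, positive = "HRD") {
  if (!component %in% names(features)) {
    stop("component '", component, "' not found in the feature matrix",
         call. = FALSE)
  }
  y <- align_labels(features, labels)
  eval_roc(features[[component]], ifelse(y == 1, "HRD", "HRP"), positive)
}
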