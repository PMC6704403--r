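#' Evaluate classifier scores against labels
#'
#' Computes the confusion matrix at a decision threshold (lncRNA = positive
#' class), the derived rates, and threshold-free ranking metrics. AUROC is
#' the Wilcoxon rank statistic: the fraction of (positive, negative) pairs
#' ordered correctly, with 0.5 credit for score ties. AUPRC is the
#' rectangular step integral of the precision-recall curve evaluated at
#' every distinct score (not trapezoidal; the choice shifts the third
#' decimal and is fixed here for reproducibility).
#'
#' @param labels Vector over `{"coding", "lncRNA"}` (or logical, `TRUE` =
#'   lncRNA).
#' @param scores Numeric lncRNA probabilities, same length as `labels`.
#' @param threshold Scores `>= threshold` are called lncRNA.
#' @return An object of class `evaluation_report`: a list with `TP`, `FP`,
#'   `TN`, `FN`, `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `auroc`, `auprc`, `threshold` and `n`. With single-class labels the
#'   confusion counts are reported but `auroc`/`auprc` are `NA` (flagged by
#'   a warning).
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  if (is.logical(labels)) labels <- ifelse(labels, "lncRNA", "coding")
  labels <- as.character(labels)
  stopifnot(
    length(labels) == length(scores),
    all(labels %in% CLASS_LEVELS),
    all(is.finite(scores))
  )
  pos <- labels == "lncRNA"
  call_pos <- scores >= threshold
  tp <- sum(pos & call_pos)
  fp <- sum(!pos & call_pos)
  tn <- sum(!pos & !call_pos)
  fn <- sum(pos & !call_pos)
  n <- length(labels)

  if (all(pos) || all(!pos)) {
    warning("labels contain a single class; AUROC/AUPRC undefined")
    auroc <- NA_real_
    auprc <- NA_real_
  } else {
    auroc <- auroc_rank(pos, scores)
    auprc <- auprc_step(pos, scores)
  }
  structure(
    list(
      TP = tp, FP = fp, TN = tn, FN = fn,
      accuracy = (tp + tn) / n,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      auroc = auroc, auprc = auprc,
      threshold = threshold, n = n
    ),
    class = "evaluation_report"
  )
}

# Wilcoxon rank form of AUROC; average ranks give exactly 0.5 per tied pair.
auroc_rank <- function(pos, scores) {
  r <- rank(scores)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Rectangular step integration of the PR curve at every distinct score.
auprc_step <- function(pos, scores) {
  o <- order(scores, decreasing = TRUE)
  y <- pos[o]
  s <- scores[o]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(!y)
  last_of_score <- !duplicated(s, fromLast = TRUE)
  tp <- cum_tp[last_of_score]
  fp <- cum_fp[last_of_score]
  prec <- tp / (tp + fp)
  rec <- tp / sum(pos)
  sum(diff(c(0, rec)) * prec)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "evaluation_report (n = %d, threshold = %g, lncRNA positive)\n",
      "  TP %d  FP %d  TN %d  FN %d\n",
      "  accuracy %.4f  sensitivity %.4f  specificity %.4f  precision %.4f\n",
      "  AUROC %.4f  AUPRC %.4f\n"
    ),
    x$n, x$threshold, x$TP, x$FP, x$TN, x$FN,
    x$accuracy, x$sensitivity, x$specificity, x$precision,
    x$auroc, x$auprc
  ))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Optionally also emits ROC and PR point tables as TSV next to the report.
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path.
#' @param labels,scores Original labels/scores; when supplied, point tables
#'   `<path>.roc.tsv` and `<path>.pr.tsv` are written.
#' @export
write_evaluation_report <- function(report, path, labels = NULL,
                                    scores = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(labels) && !is.null(scores)) {
    if (is.logical(labels)) labels <- ifelse(labels, "lncRNA", "coding")
    pos <- labels == "lncRNA"
    o <- order(scores, decreasing = TRUE)
    y <- pos[o]
    s <- scores[o]
    keep <- !duplicated(s, fromLast = TRUE)
    tp <- cumsum(y)[keep]
    fp <- cumsum(!y)[keep]
    df <- data.frame(
      score = s[keep],
      tpr = tp / sum(pos),
      fpr = fp / sum(!pos),
      precision = tp / (tp + fp)
    )
    utils::write.table(df[, c("score", "fpr", "tpr")],
      paste0(path, ".roc.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(df[, c("score", "tpr", "precision")],
      paste0(path, ".pr.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
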