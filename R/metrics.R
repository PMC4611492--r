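#' Classification metrics from confusion counts
#'
#' Computes sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' accuracy `Acc = (TP+TN)/total` (all as percentages) and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero MCC denominator yields `MCC = 0` with a warning.
#'
#' @param tp,tn,fp,fn Nonnegative integer confusion counts; both classes
#'   must be present (`tp + fn > 0`, `tn + fp > 0`).
#' @return An object of class `eval_report`; see [tidy.eval_report()].
#' @export
#' @examples
#' metrics_from_counts(tp = 397, tn = 426, fp = 124, fn = 128)
metrics_from_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_input("confusion counts must be nonnegative integers.")
  }
  if (tp + fn == 0) abort_input("no positive samples (tp + fn = 0).")
  if (tn + fp == 0) abort_input("no negative samples (tn + fp = 0).")
  sn <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / sum(counts)
  denom <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  if (denom == 0) {
    warn("MCC denominator is zero; defining MCC = 0.")
    mcc <- 0
  } else {
    mcc <- (tp * tn - fp * fn) / denom
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sn = sn, sp = sp, acc = acc, mcc = mcc,
                 auc = NA_real_, roc = NULL, predictions = NULL),
            class = "eval_report")
}

#' Reconstruct confusion counts from printed rates
#'
#' Given sensitivity and specificity printed to two decimals and the class
#' sizes, recovers the integer confusion counts. A count matches if its
#' percentage rounds **or** truncates to the printed value (published tables
#' mix both conventions); the match must be unique.
#'
#' @param sn_pct,sp_pct Printed sensitivity/specificity percentages.
#' @param n_pos,n_neg Number of positive/negative samples.
#' @return A list with `tp`, `fn`, `tn`, `fp`.
#' @export
#' @examples
#' counts_from_rates(75.62, 77.45, 525, 550)
counts_from_rates <- function(sn_pct, sp_pct, n_pos, n_neg) {
  match_count <- function(rate, n, what) {
    x <- 0:n
    pct <- 100 * x / n
    hit <- x[round(pct, 2) == rate | floor(pct * 100 + 1e-9) / 100 == rate]
    if (length(hit) == 0) {
      abort_input(paste0("no integer ", what, " count matches ", rate, "% of ", n, "."))
    }
    if (length(hit) > 1) {
      abort_input(paste0("ambiguous ", what, " count for ", rate, "% of ", n, ": ",
                         paste(hit, collapse = ", ")))
    }
    hit
  }
  tp <- match_count(sn_pct, n_pos, "true-positive")
  tn <- match_count(sp_pct, n_neg, "true-negative")
  list(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by sweeping a decision threshold over the distinct
#' score values and computes the area under it as the Mann-Whitney
#' statistic: the probability that a random positive scores above a random
#' negative, ties counted one half. Constant scores therefore give
#' AUC = 0.5.
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param labels Class labels in `{-1, +1}` (or a logical vector, `TRUE` =
#'   positive).
#' @return A list with `roc` (tibble of `threshold`, `fpr`, `tpr`, starting
#'   at (0,0) and ending at (1,1)) and `auc`.
#' @export
#' @examples
#' roc_auc(c(3, 2, 1, 0), c(1, 1, -1, -1))$auc
roc_auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  if (length(scores) != length(y)) abort_input("scores and labels differ in length.")
  np <- sum(y == 1); nn <- sum(y == -1)
  if (np == 0 || nn == 0) abort_input("both classes must be present for ROC analysis.")
  r <- rank(scores)  # midranks: ties counted 1/2
  auc <- (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == -1)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # one point per distinct score
  roc <- tibble(threshold = c(Inf, ss[last]),
                fpr = c(0, fp[last] / nn),
                tpr = c(0, tp[last] / np))
  list(roc = roc, auc = auc)
}

# Accept +1/-1, 0/1, logical, or a factor/character of two levels where the
# positive class is "1"; returns an integer vector in {-1, +1}.
normalize_labels <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, 1L, -1L))
  if (is.factor(labels) || is.character(labels)) {
    labels <- suppressWarnings(as.numeric(as.character(labels)))
  }
  if (any(is.na(labels))) abort_input("labels must be numeric +1/-1.")
  u <- sort(unique(labels))
  if (identical(u, c(0, 1))) return(as.integer(2 * labels - 1))
  if (!all(labels %in% c(-1, 1))) abort_input("labels must be in {-1, +1}.")
  as.integer(labels)
}

# Internal: full report from per-sample predictions.
eval_report_from_predictions <- function(labels, scores, predicted) {
  y <- normalize_labels(labels)
  rep <- metrics_from_counts(tp = sum(y == 1 & predicted == 1),
                             tn = sum(y == -1 & predicted == -1),
                             fp = sum(y == -1 & predicted == 1),
                             fn = sum(y == 1 & predicted == -1))
  ra <- roc_auc(scores, y)
  rep$auc <- ra$auc
  rep$roc <- ra$roc
  rep$predictions <- tibble(label = y, score = scores, predicted = predicted)
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  counts: TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.3f", x$sn, x$sp, x$acc, x$mcc))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' Tidy methods for evaluation reports
#'
#' `tidy()` returns one row per metric; `glance()` returns a one-row tibble
#' with counts and metrics side by side.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(metric = c("sn", "sp", "acc", "mcc", "auc"),
         value = c(x$sn, x$sp, x$acc, x$mcc, x$auc))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
         sn = x$sn, sp = x$sp, acc = x$acc, mcc = x$mcc, auc = x$auc)
}

#' Write an evaluation report to JSON / its ROC points to CSV
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- list(counts = list(tp = report$tp, tn = report$tn,
                            fp = report$fp, fn = report$fn),
              metrics = list(sn = report$sn, sp = report$sp,
                             acc = report$acc, mcc = report$mcc,
                             auc = report$auc))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
write_roc_csv <- function(report, path) {
  if (is.null(report$roc)) abort_input("report carries no ROC points.")
  utils::write.csv(as.data.frame(report$roc), path, row.names = FALSE)
  invisible(path)
}
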