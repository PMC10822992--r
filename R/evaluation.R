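#' Intersection over union of two boxes
#'
#' Overlap area divided by union area under the continuous-coordinate
#' convention (`width = x_max - x_min`). Disjoint boxes score 0; when both
#' boxes are degenerate (zero area) the IoU is defined as 0.
#'
#' @param a,b boxes (`bbox` or length-4 numeric).
#' @return A fraction in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 2/6
#' @export
iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  ix <- min(a[[3]], b[[3]]) - max(a[[1]], b[[1]])
  iy <- min(a[[4]], b[[4]]) - max(a[[2]], b[[2]])
  inter <- max(ix, 0) * max(iy, 0)
  union <- box_width(a) * box_height(a) + box_width(b) * box_height(b) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Confusion-matrix metrics for binary diagnoses
#'
#' Counts true/false positives/negatives (positive = 1 = glaucoma) and the
#' derived rates: `accuracy = (tp + tn) / n`, `sensitivity = tp / (tp + fn)`,
#' `specificity = tn / (tn + fp)`. A rate whose denominator is zero is
#' reported as `NA`, never silently as 0.
#'
#' @param actual,predicted equal-length binary (0/1) vectors.
#' @return A list of class `"confusion_metrics"` with `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  actual <- as.integer(actual); predicted <- as.integer(predicted)
  if (!all(actual %in% 0:1) || !all(predicted %in% 0:1))
    stop("labels must be binary 0/1", call. = FALSE)
  tp <- sum(actual == 1 & predicted == 1)
  fp <- sum(actual == 0 & predicted == 1)
  tn <- sum(actual == 0 & predicted == 0)
  fn <- sum(actual == 1 & predicted == 0)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = rate(tp + tn, tp + fp + tn + fn),
         sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp)),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("tp %d  fp %d  tn %d  fn %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy %.4f  sensitivity %.4f  specificity %.4f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' ROC curve and AUC from a continuous risk score
#'
#' Sweeps the decision threshold over the unique score values (ties grouped
#' into one step), with "positive" meaning `score >= threshold`. The area
#' under the curve is the trapezoidal integral over false-positive rate,
#' which with this tie handling equals the normalized Mann-Whitney U
#' statistic. In this pipeline the natural score is the continuous
#' cup-to-disc ratio.
#'
#' @param scores numeric risk scores (higher = more disease-like).
#' @param actual binary 0/1 truth labels.
#' @return A list of class `"roc_result"`: `points` (data frame `fpr`,
#'   `tpr`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, actual) {
  if (length(scores) != length(actual))
    stop("scores and actual must have equal length", call. = FALSE)
  actual <- as.integer(actual)
  n_pos <- sum(actual == 1); n_neg <- sum(actual == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; a <- actual[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # end of each tie group
  tpr <- c(0, cumsum(a)[keep] / n_pos)
  fpr <- c(0, cumsum(1 - a)[keep] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

#' Precision-recall curve and average precision
#'
#' Threshold sweep as in [roc_curve()]; average precision is the
#' step-function definition `sum over recall increments of precision`
#' (no interpolation). With all-identical scores this reduces to the
#' positive prevalence.
#'
#' @inheritParams roc_curve
#' @return A list of class `"pr_result"`: `points` (data frame `recall`,
#'   `precision`) and `average_precision`.
#' @export
pr_curve <- function(scores, actual) {
  if (length(scores) != length(actual))
    stop("scores and actual must have equal length", call. = FALSE)
  actual <- as.integer(actual)
  n_pos <- sum(actual == 1)
  if (n_pos == 0)
    stop("average precision undefined: no positive labels", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; a <- actual[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(a)[keep]
  fp <- cumsum(1 - a)[keep]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(recall = recall, precision = precision),
                 average_precision = ap),
            class = "pr_result")
}

#' Assemble a full evaluation report
#'
#' Combines diagnostic metrics (confusion counts and rates, ROC/AUC, PR/AP
#' computed from a continuous score when one is supplied) with localization
#' quality (mean IoU between predicted and ground-truth boxes, per
#' structure when both are given). Any component whose inputs are missing
#' or degenerate (single-class truth, no positives) is reported as `NULL`
#' rather than failing the whole report.
#'
#' @param actual,predicted binary 0/1 label vectors.
#' @param scores optional continuous risk scores (e.g. predicted CDR).
#' @param pred_boxes,gt_boxes optional lists of boxes, matched by position,
#'   for the IoU summary.
#' @return A list of class `"eval_report"` with elements `confusion`,
#'   `mean_iou`, `iou` (per-pair vector), `roc`, `pr`.
#' @export
evaluation_report <- function(actual, predicted, scores = NULL,
                              pred_boxes = NULL, gt_boxes = NULL) {
  report <- list(confusion = confusion_metrics(actual, predicted),
                 mean_iou = NULL, iou = NULL, roc = NULL, pr = NULL)
  if (!is.null(pred_boxes)) {
    stopifnot(length(pred_boxes) == length(gt_boxes))
    report$iou <- mapply(iou, pred_boxes, gt_boxes)
    report$mean_iou <- mean(report$iou)
  }
  if (!is.null(scores)) {
    report$roc <- tryCatch(roc_curve(scores, actual), error = function(e) NULL)
    report$pr <- tryCatch(pr_curve(scores, actual), error = function(e) NULL)
  }
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$confusion)
  if (!is.null(x$mean_iou)) cat(sprintf("mean IoU %.4f\n", x$mean_iou))
  if (!is.null(x$roc)) cat(sprintf("AUC %.4f\n", x$roc$auc))
  if (!is.null(x$pr)) cat(sprintf("AP  %.4f\n", x$pr$average_precision))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' The scalar metrics go to JSON; the ROC and PR curves are optionally
#' written as CSV files (one point per row) next to it.
#'
#' @param report an `"eval_report"`.
#' @param path output JSON path.
#' @param curves_csv also write `<path>_roc.csv` / `<path>_pr.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, curves_csv = FALSE) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(
    tp = report$confusion$tp, fp = report$confusion$fp,
    tn = report$confusion$tn, fn = report$confusion$fn,
    accuracy = report$confusion$accuracy,
    sensitivity = report$confusion$sensitivity,
    specificity = report$confusion$specificity,
    mean_iou = report$mean_iou,
    auc = if (!is.null(report$roc)) report$roc$auc,
    average_precision = if (!is.null(report$pr)) report$pr$average_precision)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (curves_csv) {
    stem <- sub("\\.json$", "", path)
    if (!is.null(report$roc))
      utils::write.csv(report$roc$points, paste0(stem, "_roc.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(report$pr))
      utils::write.csv(report$pr$points, paste0(stem, "_pr.csv"),
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Plot ROC / precision-recall curves
#'
#' Returns a ggplot object (requires the suggested ggplot2 package).
#'
#' @param x a `"roc_result"` or `"pr_result"`.
#' @return A ggplot object.
#' @export
plot_curve <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_curve() needs the ggplot2 package", call. = FALSE)
  if (inherits(x, "roc_result")) {
    ggplot2::ggplot(x$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                    title = sprintf("ROC (AUC = %.3f)", x$auc))
  } else if (inherits(x, "pr_result")) {
    ggplot2::ggplot(x$points,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (AP = %.3f)",
                                    x$average_precision))
  } else {
    stop("plot_curve() expects a roc_result or pr_result", call. = FALSE)
  }
}
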