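# Dice loss, overlap metrics, confidence intervals and zero-dice counts.

#' Soft dice coefficient
#'
#' `D = 2 * sum(p*g) / (sum(p^2) + sum(g^2))` over all pixels, with
#' squared denominators.  When both maps are identically zero the
#' coefficient is defined by convention (`empty_value`, default 1: an
#' empty prediction of an empty reference is perfect).
#'
#' @param pred Probability map in `[0, 1]`.
#' @param gt Binary reference map of the same shape.
#' @param empty_value Value returned when both maps are all-zero.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient_soft <- function(pred, gt, empty_value = 1) {
  if (!identical(dim(pred), dim(gt)) &&
      !(is.null(dim(pred)) && is.null(dim(gt)) &&
        length(pred) == length(gt)))
    stop("pred and gt shapes differ", call. = FALSE)
  if (any(pred < 0 | pred > 1)) stop("pred outside [0, 1]", call. = FALSE)
  if (any(gt < 0 | gt > 1)) stop("gt outside [0, 1]", call. = FALSE)
  denom <- sum(pred^2) + sum(gt^2)
  if (denom == 0) return(empty_value)
  2 * sum(pred * gt) / denom
}

#' Soft dice loss and its gradient
#'
#' `dice_loss(p, g) = 1 - dice_coefficient_soft(p, g)`;
#' `dice_loss_grad` returns the analytic gradient with respect to `pred`.
#'
#' @inheritParams dice_coefficient_soft
#' @return `dice_loss`: scalar in `[0, 1]`; `dice_loss_grad`: array of
#'   the same shape as `pred`.
#' @export
dice_loss <- function(pred, gt, empty_value = 1) {
  1 - dice_coefficient_soft(pred, gt, empty_value)
}

#' @rdname dice_loss
#' @export
dice_loss_grad <- function(pred, gt) {
  denom <- sum(pred^2) + sum(gt^2)
  if (denom == 0) return(pred * 0)
  num <- 2 * sum(pred * gt)
  # d(1 - num/denom)/dp = -(2*g*denom - num*2*p) / denom^2
  -(2 * gt * denom - num * 2 * pred) / denom^2
}

#' Pixelwise confusion counts
#'
#' Foreground pixels are the positive class, background the negative.
#'
#' @param pred_mask,gt_mask Binary arrays of identical shape.
#' @return Object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(pred_mask, gt_mask) {
  if (length(pred_mask) != length(gt_mask) ||
      !identical(dim(pred_mask), dim(gt_mask)))
    stop("mask shapes differ", call. = FALSE)
  p <- as.logical(pred_mask)
  g <- as.logical(gt_mask)
  structure(list(TP = sum(p & g), TN = sum(!p & !g),
                 FP = sum(p & !g), FN = sum(!p & g)),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' `accuracy = (TP+TN)/total`; `iou = TP/(TP+FP+FN)`;
#' `dsc = 2TP/(2TP+FP+FN)`.  When prediction and reference are both
#' empty (TP = FP = FN = 0), IoU and DSC are 1 by convention.  The
#' algebraic identity `dsc = 2*iou/(1+iou)` holds for all counts.
#'
#' @param c A `confusion_counts` object.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy_score <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) stop("empty confusion counts", call. = FALSE)
  (c$TP + c$TN) / tot
}

#' @rdname accuracy_score
#' @export
iou_score <- function(c) {
  d <- c$TP + c$FP + c$FN
  if (d == 0) return(1)
  c$TP / d
}

#' @rdname accuracy_score
#' @export
dsc_score <- function(c) {
  d <- 2 * c$TP + c$FP + c$FN
  if (d == 0) return(1)
  2 * c$TP / d
}

#' Aggregate per-sample metrics into a report
#'
#' Means come with normal-theory 95% half-widths `1.96 * sd / sqrt(n)`
#' across samples; `zero_dice_count` counts samples whose DSC is exactly
#' zero (predictions sharing no foreground pixel with a non-empty
#' reference, or missing a structure entirely).
#'
#' @param per_sample Data frame with columns `sample_id`, `dsc`, `iou`,
#'   `accuracy`.
#' @return Object of class `metric_report` with fields `per_sample`,
#'   `mean` (named vector), `ci_halfwidth` (named vector),
#'   `zero_dice_count`, `n`.
#' @export
aggregate_metrics <- function(per_sample) {
  stopifnot(is.data.frame(per_sample), nrow(per_sample) >= 1,
            all(c("sample_id", "dsc", "iou", "accuracy") %in%
                  names(per_sample)))
  cols <- c("dsc", "iou", "accuracy")
  mu <- vapply(cols, function(cl) mean(per_sample[[cl]]), numeric(1))
  hw <- vapply(cols, function(cl) {
    s <- stats::sd(per_sample[[cl]])
    if (is.na(s)) 0 else 1.96 * s / sqrt(nrow(per_sample))
  }, numeric(1))
  structure(list(per_sample = per_sample, mean = mu, ci_halfwidth = hw,
                 zero_dice_count = sum(per_sample$dsc == 0),
                 n = nrow(per_sample)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report over", x$n, "samples\n")
  for (cl in names(x$mean)) {
    cat(sprintf("  %-8s %.5f +/- %.5f\n", cl, x$mean[[cl]],
                x$ci_halfwidth[[cl]]))
  }
  cat("  zero-dice samples:", x$zero_dice_count, "\n")
  invisible(x)
}

#' Write a metric report to CSV (per sample) and JSON (aggregates)
#'
#' @param report A `metric_report`.
#' @param csv_path,json_path Output files (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  if (!is.null(csv_path))
    utils::write.csv(report$per_sample, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(mean = as.list(report$mean),
           ci_halfwidth = as.list(report$ci_halfwidth),
           zero_dice_count = report$zero_dice_count, n = report$n),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Fold-wise zero-dice table
#'
#' Tabulates, for each evaluated fold, how many test slices scored a
#' dice of exactly zero — the accounting used to report systematically
#' missed structures.
#'
#' @param reports Named list of `metric_report`s, one per fold.
#' @return Data frame with columns `fold`, `total_samples`,
#'   `zero_dice_samples`.
#' @export
zero_dice_table <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "metric_report")))
  nms <- names(reports)
  if (is.null(nms)) nms <- paste0("fold", seq_along(reports))
  data.frame(fold = nms,
             total_samples = vapply(reports, function(r) r$n, numeric(1)),
             zero_dice_samples = vapply(reports,
                                        function(r) r$zero_dice_count,
                                        numeric(1)),
             row.names = NULL)
}
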