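# Inference and overlap metrics.

#' Predict a binary segmentation mask
#'
#' Runs only the encoder and decoder-1 in evaluation mode (the boundary
#' decoder and discriminators are never evaluated) and binarizes the heat
#' map with a strict `> threshold` rule, so values exactly at the
#' threshold map to background.
#'
#' @param gen A generator (or a model list holding one in `$gen`).
#' @param image Normalized image matrix in `[0, 1]`.
#' @param threshold Binarization threshold in `(0, 1)`; default 0.5.
#' @return Binary matrix (0/1) of the image's size.
#' @export
predict_mask <- function(gen, image, threshold = 0.5) {
  if (!inherits(gen, "generator")) gen <- gen$gen
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  fwd <- forward_generator(gen, image, train = FALSE, decoders = 1L)
  h <- fwd$h[, , 1L, 1L]
  (h > threshold) * 1
}

check_mask_pair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("masks must be binary")
}

#' Dice coefficient between two binary masks
#'
#' `2|pred & gt| / (|pred| + |gt|)`; 1 by convention when both masks are
#' empty.
#' @param pred,gt Binary matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, gt) {
  check_mask_pair(pred, gt)
  denom <- sum(pred) + sum(gt)
  if (denom == 0) return(1)
  2 * sum(pred * gt) / denom
}

#' Intersection over union (Jaccard index) of two binary masks
#'
#' `|pred & gt| / |pred | gt|`; 1 by convention when both masks are empty.
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(pred, gt) {
  check_mask_pair(pred, gt)
  uni <- sum(pmax(pred, gt))
  if (uni == 0) return(1)
  sum(pred * gt) / uni
}

#' Sensitivity (true positive rate) of a predicted mask
#'
#' `TP / (TP + FN)` over foreground pixels; `NA` when the ground truth is
#' empty (excluded from aggregation).
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`, or `NA` for an empty ground truth.
#' @export
sensitivity <- function(pred, gt) {
  check_mask_pair(pred, gt)
  if (sum(gt) == 0) return(NA_real_)
  sum(pred * gt) / sum(gt)
}

#' Precision (positive predictive value) of a predicted mask
#'
#' `TP / (TP + FP)`; `NA` when the prediction is empty (excluded from
#' aggregation).
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`, or `NA` for an empty prediction.
#' @export
precision <- function(pred, gt) {
  check_mask_pair(pred, gt)
  if (sum(pred) == 0) return(NA_real_)
  sum(pred * gt) / sum(pred)
}

#' Evaluate a model over a test set
#'
#' Computes per-slice dice, IoU, sensitivity and precision and aggregates
#' by the arithmetic mean, excluding undefined (`NA`) items per metric.
#'
#' @param gen Generator or model list.
#' @param test_items List of `list(image =, mask =)` pairs.
#' @param threshold Binarization threshold.
#' @return A list of class `metrics_report` with fields `dc`, `iou`,
#'   `trp`, `ppv`, `n_items` and a per-item data frame `per_item`.
#' @export
evaluate_dataset <- function(gen, test_items, threshold = 0.5) {
  if (length(test_items) == 0L) stop("empty test set")
  rows <- lapply(seq_along(test_items), function(i) {
    it <- test_items[[i]]
    pred <- predict_mask(gen, it$image, threshold)
    data.frame(item = i,
               dc = dice_coefficient(pred, it$mask),
               iou = iou(pred, it$mask),
               trp = sensitivity(pred, it$mask),
               ppv = precision(pred, it$mask))
  })
  per_item <- do.call(rbind, rows)
  structure(list(dc = mean(per_item$dc),
                 iou = mean(per_item$iou),
                 trp = mean(per_item$trp, na.rm = TRUE),
                 ppv = mean(per_item$ppv, na.rm = TRUE),
                 n_items = nrow(per_item),
                 per_item = per_item),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics over %d items: DC %.4f | IoU %.4f | TRP %.4f | PPV %.4f\n",
              x$n_items, x$dc, x$iou, x$trp, x$ppv))
  invisible(x)
}
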