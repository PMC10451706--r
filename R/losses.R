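# The six training losses and the combined generator objective.

#' Loss weights of the generator objective
#'
#' Defaults follow the calibration used for the full-scale networks:
#' `lambda_b = 0.2` on the boundary loss, `lambda_adv_e = 0.0005` on the
#' feature-level adversarial loss and `lambda_adv_d = 0.003` on the
#' output-level adversarial loss.
#'
#' @param lambda_b Weight of the boundary (Sobel MSE) loss.
#' @param lambda_adv_e Weight of the feature-level adversarial loss.
#' @param lambda_adv_d Weight of the output-level adversarial loss.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_b = 0.2, lambda_adv_e = 0.0005,
                         lambda_adv_d = 0.003) {
  if (any(c(lambda_b, lambda_adv_e, lambda_adv_d) < 0))
    stop("loss weights must be non-negative")
  structure(list(lambda_b = lambda_b, lambda_adv_e = lambda_adv_e,
                 lambda_adv_d = lambda_adv_d), class = "loss_weights")
}

#' Soft dice loss between a heat map and a binary mask
#'
#' `1 - (2 * sum(h * v) + eps) / (sum(h) + sum(v) + eps)` with
#' `eps = 1e-6` guarding empty masks; probabilities are used directly
#' (no thresholding). The value lies in `[0, 1]` and is 0 exactly when the
#' heat map reproduces the mask.
#'
#' @param heat Numeric matrix/array in `[0, 1]`.
#' @param mask Binary matrix/array of the same shape.
#' @return Scalar loss.
#' @export
dice_loss <- function(heat, mask) {
  if (!identical(dim(heat), dim(mask)) &&
      !identical(length(heat), length(mask)))
    stop("heat and mask shapes differ")
  if (min(heat) < 0 || max(heat) > 1) stop("heat map values must be in [0, 1]")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  eps <- 1e-6
  1 - (2 * sum(heat * mask) + eps) / (sum(heat) + sum(mask) + eps)
}

#' Batch segmentation loss (mean per-image dice loss)
#'
#' @param heats,masks Lists of equal length, or `(H, W, 1, N)` arrays.
#' @return Scalar: the per-image [dice_loss()] averaged over the batch.
#' @export
segmentation_loss <- function(heats, masks) {
  heats <- batch_as_list(heats); masks <- batch_as_list(masks)
  if (length(heats) != length(masks)) stop("batch sizes differ")
  if (length(heats) == 0L) stop("empty batch")
  mean(mapply(dice_loss, heats, masks))
}

batch_as_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.matrix(x)) return(list(x))
  d <- dim(x)
  lapply(seq_len(d[4]), function(n) array(x[, , , n], d[1:2]))
}

#' Boundary loss (mean squared error against the Sobel edge label)
#'
#' @param boundary_map Predicted boundary map (Sobel magnitude of the
#'   boundary decoder output).
#' @param boundary_label Sobel edge label derived from the ground truth.
#' @return Scalar: mean over pixels of the squared residual.
#' @export
boundary_loss <- function(boundary_map, boundary_label) {
  if (!identical(dim(boundary_map), dim(boundary_label)))
    stop("boundary map and label shapes differ")
  mean((boundary_label - boundary_map)^2)
}

#' Adversarial loss on target-domain score maps
#'
#' Cross-entropy of the discriminator's per-location "source" probability
#' against the flipped domain label (target scored as source), i.e. the
#' mean of `-log(score)` over score-map locations. Computed on
#' target-domain maps only; drives the generator to make target outputs
#' look source-like.
#'
#' @param scores Score map values in `(0, 1)`.
#' @return Scalar loss (non-negative).
#' @export
adversarial_loss <- function(scores) {
  s <- as.numeric(scores)
  if (any(s <= 0) || any(s >= 1)) stop("scores must lie strictly in (0, 1)")
  mean(-log(s))
}

#' Domain classification loss for a discriminator
#'
#' Cross-entropy with the true domain labels (source = 1, target = 0):
#' mean of `-log(score)` over source locations plus mean of
#' `-log(1 - score)` over target locations. Updates only the
#' discriminator it is computed for.
#'
#' @param scores_source,scores_target Score maps in `(0, 1)`.
#' @return Scalar loss (non-negative).
#' @export
classification_loss <- function(scores_source, scores_target) {
  ss <- as.numeric(scores_source); st <- as.numeric(scores_target)
  if (any(ss <= 0) || any(ss >= 1) || any(st <= 0) || any(st >= 1))
    stop("scores must lie strictly in (0, 1)")
  mean(-log(ss)) + mean(-log(1 - st))
}

#' Combined generator objective
#'
#' `l_seg + lambda_b * l_b + lambda_adv_e * l_adv_e + lambda_adv_d *
#' l_adv_d`. The classification losses are excluded: they update only the
#' discriminators, so folding them into the quantity the generator
#' minimizes would invert the adversarial game.
#'
#' @param l_seg,l_b,l_adv_e,l_adv_d Scalar loss values (>= 0).
#' @param w A [loss_weights()] object.
#' @return Scalar objective value.
#' @export
generator_objective <- function(l_seg, l_b = 0, l_adv_e = 0, l_adv_d = 0,
                                w = loss_weights()) {
  vals <- c(l_seg, l_b, l_adv_e, l_adv_d)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("loss terms must be finite and non-negative")
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  l_seg + w$lambda_b * l_b + w$lambda_adv_e * l_adv_e + w$lambda_adv_d * l_adv_d
}

# ---- gradients used by the training loop ----------------------------------

# d(mean per-image dice)/d(heat), batch (H, W, 1, N)
dice_loss_grad <- function(heats, masks) {
  d <- dim(heats)
  g <- array(0, d)
  eps <- 1e-6
  for (n in seq_len(d[4])) {
    h <- heats[, , 1L, n]; v <- masks[, , 1L, n]
    num <- 2 * sum(h * v) + eps
    den <- sum(h) + sum(v) + eps
    g[, , 1L, n] <- -(2 * v * den - num) / den^2 / d[4]
  }
  g
}

# mean-over-locations -log(sigmoid(l)) gradient w.r.t. logits
adv_loss_logit_grad <- function(scores) (scores - 1) / length(scores)

# classification-loss logit gradients, per domain map
cls_source_logit_grad <- function(scores) (scores - 1) / length(scores)
cls_target_logit_grad <- function(scores) scores / length(scores)
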