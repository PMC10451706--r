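# Independent brute-force oracles used across the suite. These deliberately
# use plain scalar loops so they share no code with the implementation.

# 3x3 correlation with edge-reflected borders, double-loop
oracle_correlate3 <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  ref <- function(i, n) min(max(i, 1L), n)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (a in -1:1) for (b in -1:1)
      acc <- acc + kern[a + 2L, b + 2L] * img[ref(i + a, h), ref(j + b, w)]
    out[i, j] <- acc
  }
  out
}

oracle_sobel_mag <- function(img, norm_const) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- oracle_correlate3(img, kx)
  gy <- oracle_correlate3(img, t(kx))
  sqrt(gx^2 + gy^2) / norm_const
}

# largest Sobel response on any binary 3x3 patch, by direct enumeration
oracle_sobel_norm <- function() {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  best <- 0
  for (bits in 0:511) {
    patch <- matrix(as.numeric(bitwAnd(bitwShiftR(bits, 0:8), 1L)), 3, 3)
    best <- max(best, sum(kx * patch)^2 + sum(ky * patch)^2)
  }
  sqrt(best)
}

# scalar-loop loss oracles -------------------------------------------------

oracle_dice_loss <- function(heat, mask, eps = 1e-6) {
  num <- 0; sh <- 0; sv <- 0
  for (i in seq_along(heat)) {
    num <- num + heat[i] * mask[i]
    sh <- sh + heat[i]; sv <- sv + mask[i]
  }
  1 - (2 * num + eps) / (sh + sv + eps)
}

oracle_boundary_loss <- function(bmap, blabel) {
  acc <- 0
  for (i in seq_along(bmap)) acc <- acc + (blabel[i] - bmap[i])^2
  acc / length(bmap)
}

oracle_adv_loss <- function(scores) {
  acc <- 0
  for (i in seq_along(scores)) acc <- acc - log(scores[i])
  acc / length(scores)
}

oracle_cls_loss <- function(ss, st) {
  a <- 0; b <- 0
  for (i in seq_along(ss)) a <- a - log(ss[i])
  for (i in seq_along(st)) b <- b - log(1 - st[i])
  a / length(ss) + b / length(st)
}

# pixel-loop metric oracles -------------------------------------------------

oracle_counts <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_dc <- function(pred, gt) {
  n <- oracle_counts(pred, gt)
  if (2 * n$tp + n$fp + n$fn == 0) return(1)
  2 * n$tp / (2 * n$tp + n$fp + n$fn)
}

oracle_iou <- function(pred, gt) {
  n <- oracle_counts(pred, gt)
  if (n$tp + n$fp + n$fn == 0) return(1)
  n$tp / (n$tp + n$fp + n$fn)
}

oracle_trp <- function(pred, gt) {
  n <- oracle_counts(pred, gt)
  if (n$tp + n$fn == 0) return(NA_real_)
  n$tp / (n$tp + n$fn)
}

oracle_ppv <- function(pred, gt) {
  n <- oracle_counts(pred, gt)
  if (n$tp + n$fp == 0) return(NA_real_)
  n$tp / (n$tp + n$fp)
}

# trainable-parameter snapshot (excludes batch-norm running statistics,
# which are not parameters and move during any train-mode forward pass)
param_hash <- function(module) {
  ns <- asNamespace("dduda")
  p <- ns$collect_params(module)
  p <- p[!grepl("\\.(rm|rv)$", names(p))]
  unlist(p, use.names = FALSE)
}

tiny_phantom_batch <- function(n = 2L, seed = 7L, size = 64L) {
  spec <- phantom_spec(image_size = size)
  items <- lapply(seq_len(n), function(i) make_phantom(spec, seed + i))
  list(images = lapply(items, `[[`, "image"),
       masks = lapply(items, `[[`, "mask"),
       boundaries = lapply(items, function(p) make_boundary_label(p$mask)))
}
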