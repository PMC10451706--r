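#' Read a CT volume or single 2-D image as a list of axial slices
#'
#' Supports NIfTI volumes (`.nii`, `.nii.gz`) and 8/16-bit grayscale PNG
#' single-slice images. NIfTI volumes are sliced along the third (axial)
#' axis in ascending slice order; intensities are returned exactly as
#' stored, without windowing or rescaling.
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.png` file.
#' @return A list of numeric matrices (row = y, col = x), one per axial
#'   slice, in ascending slice-index order.
#' @export
load_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path")
  if (!file.exists(path))
    stop("cannot read volume: file does not exist: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file: ", path,
                                             " (", conditionMessage(e), ")"))
    arr <- as.array(vol)
  } else if (grepl("\\.png$", lower)) {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG file: ", path,
                                             " (", conditionMessage(e), ")"))
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] > 1L)
        stop("expected a grayscale PNG, got ", dim(arr)[3], " channels: ", path)
      arr <- arr[, , 1L]
    }
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .png): ", path)
  }
  if (!all(is.finite(arr)))
    stop("volume contains non-finite voxel values: ", path)
  if (length(dim(arr)) == 2L) return(list(unclass(arr[, , drop = TRUE])))
  if (length(dim(arr)) != 3L)
    stop("expected a 2-D image or 3-D volume, got ", length(dim(arr)),
         " dimensions: ", path)
  lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
}

#' Window and min-max normalize a CT slice
#'
#' Intensities are clamped to the diagnostic window `[wl, ww_upper]`
#' (defaults -20 and 200 Hounsfield units, a soft-tissue window for liver
#' work) and then min-max rescaled to `[0, 1]` over the clamped slice.
#' A constant slice maps to all zeros.
#'
#' @param slice Numeric matrix of raw intensities.
#' @param wl Lower clamp bound (default -20).
#' @param ww_upper Upper clamp bound (default 200).
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
window_and_normalize <- function(slice, wl = -20, ww_upper = 200) {
  if (!is.matrix(slice) || !is.numeric(slice))
    stop("`slice` must be a numeric matrix")
  if (!all(is.finite(slice))) stop("slice contains non-finite values")
  if (ww_upper <= wl) stop("`ww_upper` must exceed `wl`")
  x <- pmin(pmax(slice, wl), ww_upper)
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    out <- matrix(0, nrow(slice), ncol(slice))
  } else {
    out <- (x - rng[1]) / (rng[2] - rng[1])
  }
  out
}

# Edge-reflected padding by `p` pixels on every side.
pad_reflect <- function(x, p) {
  h <- nrow(x); w <- ncol(x)
  ri <- c(pmin(p:1, h), seq_len(h), pmax(h - seq_len(p) + 1L, 1L))
  ci <- c(pmin(p:1, w), seq_len(w), pmax(w - seq_len(p) + 1L, 1L))
  x[ri, ci, drop = FALSE]
}

# Maximum attainable Sobel gradient magnitude over all binary 3x3 patches,
# found once by enumerating the 2^9 patches; used to scale magnitudes so a
# binary input yields boundary values in [0, 1].
sobel_norm_constant <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
      ky <- t(kx)
      best <- 0
      for (bits in 0:511) {
        patch <- matrix(as.numeric(bitwAnd(bitwShiftR(bits, 0:8), 1L)), 3, 3)
        best <- max(best, sum(kx * patch)^2 + sum(ky * patch)^2)
      }
      val <<- sqrt(best)
    }
    val
  }
})

# Raw (unscaled) Sobel gradients with edge-reflected borders.
sobel_gradients <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  h <- nrow(image); w <- ncol(image)
  p <- pad_reflect(image, 1L)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (a in 1:3) for (b in 1:3) {
    sub <- p[a:(a + h - 1L), b:(b + w - 1L)]
    gx <- gx + kx[a, b] * sub
    gy <- gy + ky[a, b] * sub
  }
  list(gx = gx, gy = gy)
}

#' Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernels with edge-reflected borders and
#' returns `sqrt(Gx^2 + Gy^2)` scaled by the maximum response attainable on
#' a binary image (found by enumerating all binary 3x3 patches), so that
#' binary inputs give magnitudes in `[0, 1]`.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return Non-negative numeric matrix of the same size.
#' @export
sobel_magnitude <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix")
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3x3 for the Sobel operator")
  g <- sobel_gradients(image)
  sqrt(g$gx^2 + g$gy^2) / sobel_norm_constant()
}

# Backward pass of sobel_magnitude: given dL/d(magnitude), return dL/d(image).
# Needed when the boundary decoder is trained against Sobel edge maps.
sobel_magnitude_bwd <- function(image, gmag) {
  g <- sobel_gradients(image)
  k <- sobel_norm_constant()
  s <- sqrt(g$gx^2 + g$gy^2)
  scale <- ifelse(s > 0, gmag / (k * s), 0)
  ggx <- scale * g$gx
  ggy <- scale * g$gy
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  h <- nrow(image); w <- ncol(image)
  # adjoint of valid correlation on the padded image: scatter-add each tap
  gp <- matrix(0, h + 2L, w + 2L)
  for (a in 1:3) for (b in 1:3) {
    gp[a:(a + h - 1L), b:(b + w - 1L)] <-
      gp[a:(a + h - 1L), b:(b + w - 1L)] + kx[a, b] * ggx + ky[a, b] * ggy
  }
  # fold the reflected border rows/cols back onto their source pixels
  gi <- gp[2:(h + 1L), 2:(w + 1L)]
  gi[1L, ] <- gi[1L, ] + gp[1L, 2:(w + 1L)]
  gi[h, ] <- gi[h, ] + gp[h + 2L, 2:(w + 1L)]
  gi[, 1L] <- gi[, 1L] + gp[2:(h + 1L), 1L]
  gi[, w] <- gi[, w] + gp[2:(h + 1L), w + 2L]
  gi[1L, 1L] <- gi[1L, 1L] + gp[1L, 1L]
  gi[1L, w] <- gi[1L, w] + gp[1L, w + 2L]
  gi[h, 1L] <- gi[h, 1L] + gp[h + 2L, 1L]
  gi[h, w] <- gi[h, w] + gp[h + 2L, w + 2L]
  gi
}

#' Derive a boundary label from a binary segmentation mask
#'
#' The boundary label is the Sobel gradient magnitude of the mask
#' ([sobel_magnitude]); for a binary mask all values lie in `[0, 1]` and
#' are zero wherever the mask is locally constant. Labels are kept
#' continuous (not thresholded) because the boundary decoder is trained
#' with a squared-error loss against them.
#'
#' @param mask Binary numeric matrix (values 0/1).
#' @return Numeric matrix in `[0, 1]`, same size as `mask`.
#' @export
make_boundary_label <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop("`mask` must be a binary (0/1) matrix")
  sobel_magnitude(mask)
}
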