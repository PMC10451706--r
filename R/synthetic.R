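# Seeded two-domain phantom generator: annotated "source" slices of smooth
# blob organs on noisy backgrounds, and a "target" domain produced by fresh
# draws from the same geometric family pushed through a deterministic
# intensity remapping (contrast compression, gamma, noise, blur) that
# mimics the contrast-enhancement and inter-center shifts of multi-phase CT.

#' Phantom generation parameters
#'
#' @param image_size Side length in pixels (divisible by 16).
#' @param n_blobs Integer range (length-2) of blob counts per image.
#' @param blob_radius_range Blob radius range as a fraction of the image.
#' @param foreground_intensity,background_intensity Length-2 `c(mean, sd)`
#'   of the per-image tissue intensities (normalized units).
#' @param noise_sd Pixelwise Gaussian noise standard deviation.
#' @param smoothness Gaussian blur sigma applied to the blob border.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, n_blobs = c(1L, 2L),
                         blob_radius_range = c(0.15, 0.35),
                         foreground_intensity = c(0.65, 0.05),
                         background_intensity = c(0.30, 0.05),
                         noise_sd = 0.03, smoothness = 1.0) {
  if (image_size %% 16L) stop("image_size must be divisible by 16")
  structure(list(image_size = as.integer(image_size),
                 n_blobs = as.integer(n_blobs),
                 blob_radius_range = blob_radius_range,
                 foreground_intensity = foreground_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, smoothness = smoothness),
            class = "phantom_spec")
}

#' Domain-shift parameters for the target domain
#'
#' The shift maps each pixel `x` to
#' `clip(0.5 + contrast_scale * (x^gamma - 0.5) + noise)` followed by a
#' Gaussian blur; geometry (the mask) is unchanged. The default contrast
#' compression emulates the poor-contrast phases, the blur and extra noise
#' the acquisition differences between centers.
#'
#' @param contrast_scale Contrast compression factor in `(0, 1]`.
#' @param gamma Gamma exponent (> 0).
#' @param extra_noise_sd Additional Gaussian noise sd.
#' @param blur_sigma Gaussian blur sigma (0 disables).
#' @return List of class `domain_shift_spec`.
#' @export
domain_shift_spec <- function(contrast_scale = 0.5, gamma = 1.4,
                              extra_noise_sd = 0.02, blur_sigma = 0.7) {
  if (contrast_scale <= 0 || contrast_scale > 1)
    stop("contrast_scale must be in (0, 1]")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(contrast_scale = contrast_scale, gamma = gamma,
                 extra_noise_sd = extra_noise_sd, blur_sigma = blur_sigma),
            class = "domain_shift_spec")
}

# separable Gaussian blur with edge-reflected borders
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(x); w <- ncol(x)
  p <- pad_reflect(x, r)
  tmp <- matrix(0, h, w + 2L * r)
  for (a in seq_along(k))
    tmp <- tmp + k[a] * p[(a):(a + h - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (a in seq_along(k))
    out <- out + k[a] * tmp[, (a):(a + w - 1L), drop = FALSE]
  out
}

# derive a reproducible per-item substream seed from a master seed
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647)
}

#' Generate one phantom slice with its mask
#'
#' Renders 1-2 (per `spec`) smooth radially perturbed elliptical blobs;
#' the mask is the exact rendered support, while the image assigns
#' mask-dependent tissue intensities with a blurred border, plus Gaussian
#' noise, clipped to `[0, 1]`.
#'
#' @param spec A [phantom_spec()].
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @return List with `image` (matrix in `[0, 1]`) and `mask` (binary
#'   matrix).
#' @export
make_phantom <- function(spec = phantom_spec(), rng_seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  n <- spec$image_size
  nb <- sample(spec$n_blobs[1]:spec$n_blobs[2], 1L)
  xs <- matrix(rep(seq_len(n), each = n), n)   # column coords
  ys <- matrix(rep(seq_len(n), times = n), n)  # row coords
  mask <- matrix(0, n, n)
  for (b in seq_len(nb)) {
    cx <- runif(1, 0.25, 0.75) * n
    cy <- runif(1, 0.25, 0.75) * n
    r0 <- runif(1, spec$blob_radius_range[1], spec$blob_radius_range[2]) * n
    stretch <- runif(1, 0.8, 1.25)
    amp <- runif(3, 0, 0.12) / (1:3)
    phase <- runif(3, 0, 2 * pi)
    dx <- (xs - cx) / stretch
    dy <- (ys - cy) * stretch
    dist <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    rtheta <- r0 * (1 + amp[1] * cos(2 * theta + phase[1]) +
                        amp[2] * cos(3 * theta + phase[2]) +
                        amp[3] * cos(4 * theta + phase[3]))
    mask <- pmax(mask, (dist <= rtheta) * 1)
  }
  fg <- min(max(rnorm(1, spec$foreground_intensity[1],
                      spec$foreground_intensity[2]), 0.05), 0.95)
  bg <- min(max(rnorm(1, spec$background_intensity[1],
                      spec$background_intensity[2]), 0.05), 0.95)
  base <- bg + (fg - bg) * gaussian_blur(mask, spec$smoothness)
  img <- base
  if (spec$noise_sd > 0) img <- img + rnorm(n * n, 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Apply the target-domain intensity shift to an image
#'
#' @param image Matrix in `[0, 1]`.
#' @param shift A [domain_shift_spec()].
#' @param rng_seed Seed for the noise component.
#' @return Shifted image matrix in `[0, 1]`.
#' @export
apply_domain_shift <- function(image, shift = domain_shift_spec(),
                               rng_seed = 1L) {
  if (min(image) < 0 || max(image) > 1) stop("image must be in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  y <- 0.5 + shift$contrast_scale * (image^shift$gamma - 0.5)
  if (shift$extra_noise_sd > 0)
    y <- y + rnorm(length(image), 0, shift$extra_noise_sd)
  y <- pmin(pmax(y, 0), 1)
  dim(y) <- dim(image)
  gaussian_blur(y, shift$blur_sigma)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Generate a seeded two-domain phantom dataset
#'
#' Source items carry images, masks and Sobel boundary labels; target
#' items are fresh draws from the same geometric family with the domain
#' shift applied (unpaired domains), whose masks are held out for
#' evaluation only. When `out_dir` is given, the dataset is also written
#' to disk with target masks under `target/eval_only/` so a training run
#' can never read them by accident.
#'
#' @param n_source,n_target Number of slices per domain (>= 1).
#' @param spec A [phantom_spec()].
#' @param shift A [domain_shift_spec()].
#' @param seed Master seed; per-image substreams are derived from it.
#' @param out_dir Optional output directory.
#' @return List with `source` (`images`, `masks`, `boundaries`), `target`
#'   (`images`) and `target_eval` (`masks`, evaluation only).
#' @export
generate_dataset <- function(n_source, n_target, spec = phantom_spec(),
                             shift = domain_shift_spec(), seed = 1L,
                             out_dir = NULL) {
  if (n_source < 1L || n_target < 1L) stop("need at least one slice per domain")
  src <- lapply(seq_len(n_source),
                function(i) make_phantom(spec, substream_seed(seed, i)))
  tgt <- lapply(seq_len(n_target), function(i) {
    ph <- make_phantom(spec, substream_seed(seed, 100000L + i))
    ph$image <- apply_domain_shift(ph$image, shift,
                                   substream_seed(seed, 200000L + i))
    ph
  })
  out <- list(
    source = list(images = lapply(src, `[[`, "image"),
                  masks = lapply(src, `[[`, "mask"),
                  boundaries = lapply(src, function(p) make_boundary_label(p$mask))),
    target = list(images = lapply(tgt, `[[`, "image")),
    target_eval = list(masks = lapply(tgt, `[[`, "mask")))
  if (!is.null(out_dir)) write_dataset_dir(out, out_dir)
  out
}

write_dataset_dir <- function(ds, dir) {
  paths <- c("source/images", "source/masks", "source/boundaries",
             "target/images", "target/eval_only/masks")
  for (p in paths) dir.create(file.path(dir, p), recursive = TRUE,
                              showWarnings = FALSE)
  fn <- function(i) sprintf("%04d", i)
  for (i in seq_along(ds$source$images)) {
    png::writePNG(ds$source$images[[i]],
                  file.path(dir, "source/images", paste0(fn(i), ".png")))
    png::writePNG(ds$source$masks[[i]],
                  file.path(dir, "source/masks", paste0(fn(i), ".png")))
    saveRDS(ds$source$boundaries[[i]],
            file.path(dir, "source/boundaries", paste0(fn(i), ".rds")))
  }
  for (i in seq_along(ds$target$images)) {
    png::writePNG(ds$target$images[[i]],
                  file.path(dir, "target/images", paste0(fn(i), ".png")))
    png::writePNG(ds$target_eval$masks[[i]],
                  file.path(dir, "target/eval_only/masks", paste0(fn(i), ".png")))
  }
  invisible(dir)
}

#' Read a dataset directory written by [generate_dataset()]
#'
#' Training use never touches `target/eval_only/`; pass
#' `include_eval = TRUE` explicitly to load the held-out target masks for
#' evaluation.
#'
#' @param dir Dataset directory.
#' @param include_eval Load the held-out target masks too?
#' @return Same structure as [generate_dataset()] (without `target_eval`
#'   unless requested).
#' @export
read_dataset_dir <- function(dir, include_eval = FALSE) {
  rd_png <- function(p) {
    x <- png::readPNG(p)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    x
  }
  list_sorted <- function(sub) sort(list.files(file.path(dir, sub),
                                               full.names = TRUE))
  out <- list(
    source = list(
      images = lapply(list_sorted("source/images"), rd_png),
      masks = lapply(list_sorted("source/masks"),
                     function(p) round(rd_png(p))),
      boundaries = lapply(list_sorted("source/boundaries"), readRDS)),
    target = list(images = lapply(list_sorted("target/images"), rd_png)))
  if (include_eval)
    out$target_eval <- list(masks = lapply(list_sorted("target/eval_only/masks"),
                                           function(p) round(rd_png(p))))
  out
}
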