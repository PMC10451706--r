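test_that("phantoms are reproducible and noiseless ones are two-valued", {
  spec <- phantom_spec()
  a <- make_phantom(spec, 123L); b <- make_phantom(spec, 123L)
  expect_identical(a, b)
  expect_false(identical(a$mask, make_phantom(spec, 124L)$mask))

  spec0 <- phantom_spec(noise_sd = 0, foreground_intensity = c(0.65, 0),
                        background_intensity = c(0.30, 0))
  ph <- make_phantom(spec0, 9L)
  # away from the blurred border the image takes exactly the two tissue values
  blur_reach <- dduda:::gaussian_blur(ph$mask, spec0$smoothness)
  interior <- blur_reach > 1 - 1e-9; exterior <- blur_reach < 1e-9
  expect_true(all(abs(ph$image[interior] - 0.65) < 1e-9))
  expect_true(all(abs(ph$image[exterior] - 0.30) < 1e-9))
  expect_true(sum(interior) > 0 && sum(exterior) > 0)
})

test_that("mask foreground fractions stay inside the geometry's bounds", {
  spec <- phantom_spec()
  fr <- vapply(1:60, function(s) mean(make_phantom(spec, s)$mask), 0)
  # 1-2 blobs, radius fraction 0.15-0.35, shape perturbation <= 22%,
  # stretch in [0.8, 1.25]: area fraction within [pi*(0.15*0.78*0.8)^2, 1)
  lo <- pi * (0.15 * 0.78 * 0.8)^2
  expect_true(all(fr > lo * 0.9))
  expect_true(all(fr < 0.85))
  expect_gt(mean(fr), 0.05)
})

test_that("the identity shift leaves images untouched; contrast halves the range", {
  img <- make_phantom(phantom_spec(noise_sd = 0), 3L)$image
  ident <- domain_shift_spec(contrast_scale = 1, gamma = 1,
                             extra_noise_sd = 0, blur_sigma = 0)
  expect_equal(apply_domain_shift(img, ident, 1L), img)
  half <- domain_shift_spec(contrast_scale = 0.5, gamma = 1,
                            extra_noise_sd = 0, blur_sigma = 0)
  shifted <- apply_domain_shift(img, half, 1L)
  expect_equal(diff(range(shifted)), 0.5 * diff(range(img)), tolerance = 1e-12)
  expect_equal(mean(range(shifted)), 0.5 + 0.5 * (mean(range(img)) - 0.5),
               tolerance = 1e-12)
})

test_that("the shift separates intensity distributions beyond sampling noise", {
  spec <- phantom_spec(); shift <- domain_shift_spec()
  ks_shift <- ks_null <- numeric(20)
  for (s in 1:20) {
    a <- make_phantom(spec, 1000L + s)$image
    b <- make_phantom(spec, 2000L + s)$image
    bt <- apply_domain_shift(b, shift, 3000L + s)
    ks_shift[s] <- suppressWarnings(stats::ks.test(a, bt)$statistic)
    ks_null[s] <- suppressWarnings(stats::ks.test(a, b)$statistic)
  }
  expect_gt(mean(ks_shift), mean(ks_null))
  expect_gt(mean(ks_shift - ks_null), 0.02)
})

test_that("generate_dataset is seed-reproducible with held-out target masks", {
  ds <- generate_dataset(5, 4, seed = 77L)
  ds2 <- generate_dataset(5, 4, seed = 77L)
  expect_identical(ds, ds2)
  expect_length(ds$source$images, 5L)
  expect_length(ds$source$masks, 5L)
  expect_length(ds$source$boundaries, 5L)
  expect_length(ds$target$images, 4L)
  expect_null(ds$target$masks)
  expect_length(ds$target_eval$masks, 4L)
  expect_identical(ds$source$boundaries[[2]],
                   make_boundary_label(ds$source$masks[[2]]))
})

test_that("the on-disk layout quarantines target masks under eval_only", {
  dir <- file.path(tempdir(), "ds_layout")
  unlink(dir, recursive = TRUE)
  ds <- generate_dataset(3, 2, seed = 5L, out_dir = dir)
  expect_length(list.files(file.path(dir, "source/images")), 3L)
  expect_length(list.files(file.path(dir, "source/boundaries")), 3L)
  expect_length(list.files(file.path(dir, "target/images")), 2L)
  expect_length(list.files(file.path(dir, "target/eval_only/masks")), 2L)
  # the default reader never touches eval_only
  back <- read_dataset_dir(dir)
  expect_null(back$target_eval)
  expect_length(back$target$images, 2L)
  expect_identical(back$source$masks[[1]], ds$source$masks[[1]])
  withme <- read_dataset_dir(dir, include_eval = TRUE)
  expect_identical(withme$target_eval$masks[[2]], ds$target_eval$masks[[2]])
})
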