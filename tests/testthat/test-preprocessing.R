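test_that("load_volume round-trips a NIfTI volume in slice order", {
  vol <- array(seq_len(6 * 6 * 4), c(6, 6, 4)) * 1.0
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  slices <- load_volume(f)
  expect_length(slices, 4L)
  for (k in 1:4) expect_equal(unclass(slices[[k]]), vol[, , k],
                              ignore_attr = TRUE)
})

test_that("load_volume reads a single grayscale PNG as one slice", {
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  f <- tempfile(fileext = ".png")
  png::writePNG(img, f)
  slices <- load_volume(f)
  expect_length(slices, 1L)
  expect_equal(dim(slices[[1]]), c(8L, 8L))
  expect_lt(max(abs(slices[[1]] - img)), 1 / 254)
})

test_that("load_volume rejects missing files, bad formats, non-finite voxels", {
  expect_error(load_volume(file.path(tempdir(), "nope.nii")), "exist")
  f <- tempfile(fileext = ".txt")
  writeLines("x", f)
  expect_error(load_volume(f), "unsupported")
  vol <- array(1, c(4, 4, 2)); vol[2, 2, 1] <- NaN
  f2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f2)
  expect_error(load_volume(f2), "finite")
})

test_that("window_and_normalize clamps to [-20, 200] then rescales", {
  sl <- matrix(c(-50, -20, 90, 250), 2, 2)
  out <- window_and_normalize(sl)
  expect_equal(as.numeric(out), c(0, 0, 0.5, 1))
})

test_that("constant slices normalize to all zeros", {
  expect_equal(window_and_normalize(matrix(37, 4, 4)), matrix(0, 4, 4))
})

test_that("windowing is idempotent and ignores monotone out-of-window shifts", {
  set.seed(11)
  sl <- matrix(runif(64, -200, 400), 8, 8)
  once <- window_and_normalize(sl)
  # a normalized slice re-windowed spans [0, 1] already: rescaling is identity
  expect_equal(window_and_normalize(once, wl = 0, ww_upper = 1), once)
  shifted <- sl
  shifted[sl < -20] <- sl[sl < -20] - 500   # push further below the window
  shifted[sl > 200] <- sl[sl > 200] + 300   # and further above
  expect_equal(window_and_normalize(shifted), once)
})

test_that("sobel magnitude is zero on constants and matches the oracle", {
  expect_equal(sobel_magnitude(matrix(3.7, 6, 6)), matrix(0, 6, 6))
  k <- oracle_sobel_norm()
  set.seed(5)
  for (r in 1:10) {
    img <- matrix(runif(64), 8, 8)
    expect_lt(max(abs(sobel_magnitude(img) - oracle_sobel_mag(img, k))), 1e-10)
  }
  expect_error(sobel_magnitude(matrix(1, 2, 2)), "3x3")
})

test_that("a vertical step edge activates only the two adjacent columns", {
  img <- cbind(matrix(0, 5, 2), matrix(1, 5, 3))
  mag <- sobel_magnitude(img)
  expect_true(all(mag[, c(1, 4, 5)] == 0))
  expect_true(all(mag[, 2:3] > 0))
  expect_equal(max(mag), min(mag[, 2:3]))  # uniform response along the edge
})

test_that("boundary labels vanish on constant masks and on 3x3-constant pixels", {
  expect_equal(make_boundary_label(matrix(0, 8, 8)), matrix(0, 8, 8))
  expect_equal(make_boundary_label(matrix(1, 8, 8)), matrix(0, 8, 8))
  set.seed(21)
  for (r in 1:20) {
    m <- matrix(rbinom(100, 1, 0.4), 10, 10)
    z <- make_boundary_label(m)
    expect_true(all(z >= 0 & z <= 1))
    pad <- dduda:::pad_reflect(m, 1L)
    for (i in 2:9) for (j in 2:9) {
      if (length(unique(as.numeric(pad[(i - 1):(i + 1) + 1, (j - 1):(j + 1) + 1]))) == 1L)
        expect_identical(z[i, j], 0)
    }
  }
})

test_that("a centered square mask lights up exactly its rim", {
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  z <- make_boundary_label(m)
  k <- oracle_sobel_norm()
  expect_equal(z, oracle_sobel_mag(m, k), tolerance = 1e-12)
  inner <- z[4:5, 4:5]   # strictly interior pixels of the square
  expect_true(all(inner == 0))
  # the response is confined to the one-pixel inner/outer rim
  expect_true(all(z[c(1, 8), ] == 0) && all(z[, c(1, 8)] == 0))
  expect_true(all(z[3:6, 3] > 0) && all(z[3, 3:6] > 0))  # inner rim fires
  expect_error(make_boundary_label(m + 0.5), "binary")
})
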