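test_that("encoder channel widths double per block from base_channels", {
  ns <- asNamespace("dduda")
  set.seed(1)
  gen64 <- build_generator(generator_config(base_channels = 64))
  outch <- vapply(gen64$enc, function(b) dim(b$c2$conv$w)[4], 0)
  expect_equal(outch, c(64, 128, 256, 512, 1024))
  gen8 <- build_generator(generator_config(base_channels = 8))
  expect_equal(dim(gen8$enc[[5]]$c2$conv$w)[4], 128)  # 8 * 2^4
})

test_that("the two decoders are structurally identical (equal param counts)", {
  set.seed(2)
  gen <- build_generator(generator_config(base_channels = 8))
  expect_equal(dduda:::decoder_param_count(gen$dec1),
               dduda:::decoder_param_count(gen$dec2))
})

test_that("generator output shapes obey the /16 and same-size contracts", {
  set.seed(3)
  gen <- build_generator(generator_config(base_channels = 8))
  x <- matrix(runif(64 * 64), 64, 64)
  fwd <- forward_generator(gen, x)
  expect_equal(dim(fwd$f), c(4L, 4L, 128L, 1L))
  expect_equal(dim(fwd$h), c(64L, 64L, 1L, 1L))
  expect_equal(dim(fwd$d2), c(64L, 64L, 1L, 1L))
  expect_true(all(fwd$h > 0 & fwd$h < 1))
  expect_error(forward_generator(gen, matrix(0.5, 40, 40)), "divisible")
  expect_error(forward_generator(gen, matrix(2, 64, 64)), "\\[0, 1\\]")
})

test_that("heat maps keep the input size for varying valid sizes", {
  set.seed(4)
  gen <- build_generator(generator_config(base_channels = 4))
  for (sz in c(16L, 32L, 48L)) {
    fwd <- forward_generator(gen, matrix(runif(sz * sz), sz, sz), decoders = 1L)
    expect_equal(dim(fwd$h)[1:2], c(sz, sz))
    expect_equal(dim(fwd$f)[1:2], c(sz / 16L, sz / 16L))
  }
})

test_that("generator forward is deterministic in evaluation mode", {
  set.seed(5)
  gen <- build_generator(generator_config(base_channels = 4))
  x <- matrix(runif(32 * 32), 32, 32)
  a <- forward_generator(gen, x)
  b <- forward_generator(gen, x)
  expect_identical(a$h, b$h)
  expect_identical(a$f, b$f)
})

test_that("decoder-2 has no path into the heat map", {
  set.seed(6)
  gen <- build_generator(generator_config(base_channels = 4))
  x <- matrix(runif(32 * 32), 32, 32)
  h_both <- forward_generator(gen, x, decoders = c(1L, 2L))$h
  gen$dec2 <- NULL
  h_dropped <- forward_generator(gen, x)$h
  expect_identical(h_both, h_dropped)
})

test_that("doubling base_channels changes only the feature-map channel dim", {
  set.seed(7)
  g1 <- build_generator(generator_config(base_channels = 4))
  g2 <- build_generator(generator_config(base_channels = 8))
  x <- matrix(runif(32 * 32), 32, 32)
  f1 <- forward_generator(g1, x); f2 <- forward_generator(g2, x)
  expect_equal(dim(f1$h), dim(f2$h))
  expect_equal(dim(f1$f)[c(1, 2, 4)], dim(f2$f)[c(1, 2, 4)])
  expect_equal(dim(f2$f)[3], 2L * dim(f1$f)[3])
})

test_that("discriminators halve spatial dims five times and stay in (0,1)", {
  set.seed(8)
  d <- build_discriminator(discriminator_config(1L))
  s128 <- forward_discriminator(d, array(runif(128 * 128), c(128, 128, 1, 1)))
  expect_equal(dim(s128$scores)[1:2], c(4L, 4L))
  s64 <- forward_discriminator(d, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_equal(dim(s64$scores)[1:2], c(2L, 2L))
  s32 <- forward_discriminator(d, array(runif(32 * 32), c(32, 32, 1, 1)))
  expect_equal(dim(s32$scores)[1:2], c(1L, 1L))
  expect_true(all(s128$scores > 0 & s128$scores < 1))
  expect_error(forward_discriminator(d, array(runif(32 * 32 * 2),
                                              c(32, 32, 2, 1))), "channels")
})

test_that("the feature-level discriminator accepts desk-scale bottlenecks", {
  set.seed(9)
  de <- build_discriminator(discriminator_config(64L))
  f <- array(rnorm(4 * 4 * 64 * 2), c(4, 4, 64, 2))
  sc <- forward_discriminator(de, f)
  expect_equal(dim(sc$scores), c(1L, 1L, 1L, 2L))
  expect_true(all(sc$scores > 0 & sc$scores < 1))
})

test_that("checkpoints restore exact predictions; inference manifests drop decoder-2", {
  set.seed(10)
  gen <- build_generator(generator_config(base_channels = 4))
  x <- matrix(runif(32 * 32), 32, 32)
  h0 <- predict_mask(gen, x)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(list(gen = gen, cfg = list(seed = 10L)), f,
                  components = "encoder_dec1")
  ck <- load_checkpoint(f)
  expect_false(ck$manifest$dec2)
  expect_null(ck$gen$dec2)
  expect_identical(predict_mask(ck$gen, x), h0)
})
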