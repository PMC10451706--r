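test_that("dice loss hits its closed-form spot values", {
  m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1
  expect_equal(dice_loss(m, m), 0, tolerance = 1e-6)
  expect_equal(dice_loss(matrix(0, 4, 4), m), 1, tolerance = 1e-3)
  # 4 foreground pixels each, overlap 2 -> 1 - 4/8
  h <- matrix(0, 4, 4); h[2:3, 2:3] <- 1
  v <- matrix(0, 4, 4); v[1:2, 2:3] <- 1
  expect_equal(dice_loss(h, v), 0.5, tolerance = 1e-6)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0.3, 2, 2)), "binary")
})

test_that("segmentation loss is the batch mean of per-image dice losses", {
  set.seed(31)
  h1 <- matrix(runif(16), 4, 4); v1 <- matrix(rbinom(16, 1, 0.5), 4, 4)
  h2 <- matrix(runif(16), 4, 4); v2 <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_equal(segmentation_loss(list(h1), list(v1)), dice_loss(h1, v1))
  expect_equal(segmentation_loss(list(h1, h2), list(v1, v2)),
               mean(c(dice_loss(h1, v1), dice_loss(h2, v2))))
  expect_equal(segmentation_loss(list(h1, h2), list(v1, v2)),
               segmentation_loss(list(h2, h1), list(v2, v1)))
  expect_error(segmentation_loss(list(), list()), "empty")
})

test_that("boundary loss is a mean squared residual with quadratic scaling", {
  z <- matrix(0, 4, 4)
  expect_equal(boundary_loss(z, z), 0)
  expect_equal(boundary_loss(matrix(0.5, 4, 4), z), 0.25)
  set.seed(32)
  b <- matrix(runif(16), 4, 4); zz <- matrix(runif(16), 4, 4)
  expect_equal(boundary_loss(zz + 3 * (b - zz), zz), 9 * boundary_loss(b, zz))
})

test_that("adversarial loss matches -log closed forms and is monotone", {
  eps <- 1e-7
  expect_equal(adversarial_loss(matrix(1 - eps, 2, 2)), -log(1 - eps))
  expect_equal(adversarial_loss(matrix(0.5, 3, 3)), log(2))
  s <- matrix(0.6, 2, 2); s2 <- s; s2[1, 1] <- 0.4
  expect_gt(adversarial_loss(s2), adversarial_loss(s))
  expect_error(adversarial_loss(matrix(c(0, 0.5, 0.5, 0.5), 2, 2)), "strictly")
})

test_that("classification loss closed forms and complement symmetry hold", {
  eps <- 1e-7
  expect_lt(classification_loss(matrix(1 - eps, 2, 2), matrix(eps, 2, 2)),
            1e-6)
  expect_equal(classification_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
               2 * log(2))
  set.seed(33)
  ss <- matrix(runif(16, 0.1, 0.9), 4, 4)
  st <- matrix(runif(16, 0.1, 0.9), 4, 4)
  expect_equal(classification_loss(ss, st),
               classification_loss(1 - st, 1 - ss))
  # spatial permutation invariance
  p <- sample(16)
  expect_equal(classification_loss(ss, st),
               classification_loss(matrix(ss[p], 4, 4), matrix(st[p], 4, 4)))
})

test_that("the generator objective is the stated weighted sum without Lcls", {
  expect_equal(generator_objective(0.5, 1.0, 0, 0), 0.7)
  expect_equal(generator_objective(0, 0, 0, 0), 0)
  expect_equal(generator_objective(0, 0, 1, 1), 0.0035)
  w <- loss_weights()
  set.seed(34)
  for (r in 1:10) {
    ls <- runif(4)
    expect_equal(generator_objective(ls[1], ls[2], ls[3], ls[4], w),
                 ls[1] + 0.2 * ls[2] + 0.0005 * ls[3] + 0.003 * ls[4])
  }
  expect_error(loss_weights(lambda_b = -1), "non-negative")
  expect_error(generator_objective(-0.1), "non-negative")
})
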