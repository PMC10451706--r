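test_that("pair_batches implements the wrap-around cycling rule", {
  s1 <- pair_batches(10, 10, 5, seed = 1L)
  expect_length(s1, 2L)
  expect_setequal(unlist(lapply(s1, `[[`, "source")), 1:10)

  s2 <- pair_batches(10, 4, 2, seed = 1L)
  expect_length(s2, 5L)
  tgt <- unlist(lapply(s2, `[[`, "target"))
  expect_length(tgt, 10L)
  expect_setequal(unique(tgt), 1:4)  # smaller set wraps around
  expect_setequal(unlist(lapply(s2, `[[`, "source")), 1:10)

  s3 <- pair_batches(10, 4, 2, seed = 2L)
  expect_false(identical(s2, s3))
  sup <- pair_batches(6, 0, 3, seed = 1L)
  expect_null(sup[[1]]$target)
})

test_that("training modes build exactly the sub-networks they need", {
  cfg_sup <- train_config(mode = "supervised", base_channels = 4,
                          image_size = 64, seed = 1)
  st <- new_train_state(cfg_sup)
  expect_null(st$de); expect_null(st$dd)
  expect_false(is.null(st$gen$dec2))

  cfg_nb <- train_config(mode = "supervised", boundary_enabled = FALSE,
                         base_channels = 4, seed = 1)
  expect_null(new_train_state(cfg_nb)$gen$dec2)

  st_uda <- new_train_state(train_config(mode = "uda_output",
                                         base_channels = 4, seed = 1))
  expect_null(st_uda$de); expect_false(is.null(st_uda$dd))

  st_dd <- new_train_state(train_config(mode = "dd_uda", base_channels = 4,
                                        seed = 1))
  expect_false(is.null(st_dd$de)); expect_false(is.null(st_dd$dd))
  expect_equal(st_dd$de$cfg$in_channels, 64L)  # base 4 -> bottleneck 64
})

test_that("supervised iterations leave adversarial loss fields absent", {
  sb <- tiny_phantom_batch(2)
  st <- new_train_state(train_config(mode = "supervised", base_channels = 4,
                                     batch_size = 2, seed = 3,
                                     lr_generator = 1e-3))
  rec <- train_iteration(st, sb)
  expect_false(is.na(rec[["l_seg"]]))
  expect_false(is.na(rec[["l_b"]]))
  expect_true(all(is.na(rec[c("l_adv_e", "l_adv_d", "l_cls_e", "l_cls_d")])))
  expect_error(train_iteration(
    new_train_state(train_config(mode = "dd_uda", base_channels = 4,
                                 batch_size = 2, seed = 3)), sb), "target")
})

test_that("a dd_uda iteration records all six losses finitely", {
  sb <- tiny_phantom_batch(2)
  tb <- list(images = tiny_phantom_batch(2, seed = 40)$images)
  st <- new_train_state(train_config(mode = "dd_uda", base_channels = 4,
                                     batch_size = 2, seed = 3,
                                     lr_generator = 1e-3,
                                     lr_discriminators = 1e-4))
  rec <- train_iteration(st, sb, tb)
  expect_true(all(is.finite(rec)))
  expect_gte(rec[["l_seg"]], 0); expect_gte(rec[["l_adv_d"]], 0)
})

test_that("train with zero epochs returns an initialized, unupdated model", {
  ds <- generate_dataset(4, 4, seed = 2L)
  cfg <- train_config(mode = "supervised", base_channels = 4, epochs = 0,
                      batch_size = 2, seed = 9)
  m <- train(cfg, ds$source)
  expect_s3_class(m, "dduda_model")
  expect_equal(nrow(m$history), 0L)
  ref <- new_train_state(cfg)
  expect_identical(param_hash(m$gen), param_hash(ref$gen))
})

test_that("identical seeds reproduce the loss history exactly", {
  ds <- generate_dataset(4, 4, seed = 6L)
  cfg <- train_config(mode = "dd_uda", base_channels = 4, epochs = 2,
                      batch_size = 2, seed = 11, lr_generator = 1e-3,
                      lr_discriminators = 1e-4)
  m1 <- train(cfg, ds$source, ds$target)
  m2 <- train(cfg, ds$source, ds$target)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 2L * 2L)  # 2 epochs x ceil(4/2) steps
  expect_true(all(is.finite(as.matrix(m1$history))))
  m3 <- train(train_config(mode = "dd_uda", base_channels = 4, epochs = 2,
                           batch_size = 2, seed = 12, lr_generator = 1e-3,
                           lr_discriminators = 1e-4), ds$source, ds$target)
  expect_false(identical(m1$history$l_seg, m3$history$l_seg))
})

test_that("validation tracking restores the best-scoring weights", {
  ds <- generate_dataset(4, 4, seed = 8L)
  val <- lapply(1:2, function(i) list(image = ds$source$images[[i]],
                                      mask = ds$source$masks[[i]]))
  cfg <- train_config(mode = "supervised", base_channels = 4, epochs = 2,
                      batch_size = 2, seed = 13, lr_generator = 1e-3)
  m <- train(cfg, ds$source, validation = val)
  expect_length(m$validation_dc, 2L)
  got <- evaluate_dataset(m$gen, val)$dc
  expect_equal(got, max(m$validation_dc), tolerance = 1e-12)
})
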