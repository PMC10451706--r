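# Five-step alternating adversarial training.
#
# Each iteration: (1) dice segmentation loss on source heat maps, update
# encoder + decoder-1; (2) Sobel boundary loss on source boundary maps,
# update encoder + decoder-2; (3) adversarial losses on target feature and
# heat maps with flipped domain labels, update encoder + decoder-1;
# (4) feature-level classification loss, update De only; (5) output-level
# classification loss, update Dd only. Modes degrade: "supervised" runs
# (1)-(2); "uda_output" runs (1)(2)(3, output part)(5); "dd_uda" runs all.

#' Training configuration
#'
#' Defaults follow the full-scale calibration: Adam, generator learning
#' rate `1e-5`, discriminator learning rate `1e-6`, batch size 8. Those
#' rates are matched to runs of hundreds of thousands of iterations; for
#' short desk-scale experiments use larger rates (see
#' [synthetic_benchmark_config()]).
#'
#' @param mode `"supervised"`, `"uda_output"` (single output-level
#'   discriminator) or `"dd_uda"` (feature- and output-level).
#' @param boundary_enabled Build and train the boundary decoder?
#' @param weights A [loss_weights()].
#' @param lr_generator,lr_discriminators Adam learning rates (> 0).
#' @param batch_size Slices per domain per iteration (>= 1).
#' @param epochs Number of epochs (>= 0).
#' @param seed Integer seed controlling initialization and batch order.
#' @param image_size Expected slice size (divisible by 16).
#' @param base_channels Generator width (see [generator_config()]).
#' @param activation Generator activation.
#' @return List of class `train_config`.
#' @export
train_config <- function(mode = c("dd_uda", "uda_output", "supervised"),
                         boundary_enabled = TRUE,
                         weights = loss_weights(),
                         lr_generator = 1e-5, lr_discriminators = 1e-6,
                         batch_size = 8L, epochs = 1L, seed = 1L,
                         image_size = 64L, base_channels = 64L,
                         activation = "relu") {
  mode <- match.arg(mode)
  if (lr_generator <= 0 || lr_discriminators <= 0)
    stop("learning rates must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (image_size %% 16L) stop("image_size must be divisible by 16")
  structure(list(mode = mode, boundary_enabled = boundary_enabled,
                 weights = weights, lr_generator = lr_generator,
                 lr_discriminators = lr_discriminators,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels),
                 activation = activation),
            class = "train_config")
}

#' Initialize a training state
#'
#' Builds the generator (without decoder-2 if the boundary branch is
#' disabled) and the discriminators the mode calls for, with seeded
#' normal(0, 0.02) convolution weights.
#'
#' @param cfg A [train_config()].
#' @return An environment of class `train_state`.
#' @export
new_train_state <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  s <- new.env(parent = emptyenv())
  s$cfg <- cfg
  s$gen <- build_generator(generator_config(
    base_channels = cfg$base_channels,
    activation = if (cfg$activation == "relu") "relu" else "leaky_relu"))
  if (!cfg$boundary_enabled) s$gen$dec2 <- NULL
  s$de <- NULL; s$dd <- NULL
  if (cfg$mode == "dd_uda")
    s$de <- build_discriminator(discriminator_config(16L * cfg$base_channels))
  if (cfg$mode %in% c("dd_uda", "uda_output"))
    s$dd <- build_discriminator(discriminator_config(1L))
  s$iter <- 0L
  s$history <- list()
  class(s) <- "train_state"
  s
}

gen_seg_layers <- function(s) c(param_layers(s$gen$enc), param_layers(s$gen$dec1))
gen_bnd_layers <- function(s) c(param_layers(s$gen$enc), param_layers(s$gen$dec2))

list_to_batch <- function(lst) {
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE), c(d[1], d[2], 1L, length(lst)))
}

#' One alternating training iteration
#'
#' Runs the five steps (degraded per mode) on one paired batch, mutating
#' the state in place, and returns the loss record for the iteration.
#' Losses for steps a mode does not run are `NA`.
#'
#' @param state A [new_train_state()] environment.
#' @param source_batch List with `images`, `masks`, `boundaries` (lists of
#'   matrices).
#' @param target_batch List with `images`, or `NULL` in supervised mode.
#' @param step_callback Optional `function(step)` invoked after each of
#'   the five steps completes (used to audit gradient routing).
#' @return Named numeric loss record, invisibly also appended to
#'   `state$history`.
#' @export
train_iteration <- function(state, source_batch, target_batch = NULL,
                            step_callback = NULL) {
  cfg <- state$cfg
  w <- cfg$weights
  if (cfg$mode != "supervised" && is.null(target_batch))
    stop("mode '", cfg$mode, "' requires a target batch")
  cb <- function(k) if (!is.null(step_callback)) step_callback(k)

  x_s <- list_to_batch(source_batch$images)
  v_s <- list_to_batch(source_batch$masks)
  rec <- c(l_seg = NA_real_, l_b = NA_real_, l_adv_e = NA_real_,
           l_adv_d = NA_real_, l_cls_e = NA_real_, l_cls_d = NA_real_)

  # (1) supervised segmentation on source
  seg_layers <- gen_seg_layers(state)
  zero_grads(seg_layers)
  fwd1 <- forward_generator(state$gen, x_s, train = TRUE, decoders = 1L)
  rec["l_seg"] <- segmentation_loss(fwd1$h, v_s)
  generator_bwd(state$gen, fwd1, 1L, dice_loss_grad(fwd1$h, v_s))
  adam_update(seg_layers, cfg$lr_generator)
  f_s <- fwd1$f; h_s <- fwd1$h   # detached maps for the discriminator steps
  cb(1L)

  # (2) boundary regression on source
  if (cfg$boundary_enabled) {
    bnd_layers <- gen_bnd_layers(state)
    zero_grads(bnd_layers)
    fwd2 <- forward_generator(state$gen, x_s, train = TRUE, decoders = 2L)
    d <- dim(fwd2$d2)
    gb <- array(0, d)
    lb <- 0
    for (n in seq_len(d[4])) {
      d2n <- fwd2$d2[, , 1L, n]
      bmap <- sobel_magnitude(d2n)
      z <- source_batch$boundaries[[n]]
      lb <- lb + boundary_loss(bmap, z)
      gmag <- -2 * (z - bmap) / (d[1] * d[2]) / d[4]
      gb[, , 1L, n] <- sobel_magnitude_bwd(d2n, gmag)
    }
    rec["l_b"] <- lb / d[4]
    generator_bwd(state$gen, fwd2, 2L, gb)
    adam_update(bnd_layers, cfg$lr_generator)
  }
  cb(2L)

  # (3) adversarial alignment on target (flipped domain labels)
  de_fwd_t <- NULL; dd_fwd_t <- NULL; fwd3 <- NULL
  if (cfg$mode != "supervised") {
    x_t <- list_to_batch(target_batch$images)
    zero_grads(seg_layers)
    fwd3 <- forward_generator(state$gen, x_t, train = TRUE, decoders = 1L)
    dd_fwd_t <- forward_discriminator(state$dd, fwd3$h, train = TRUE)
    rec["l_adv_d"] <- adversarial_loss(dd_fwd_t$scores)
    gh_t <- discriminator_bwd(
      state$dd, dd_fwd_t,
      w$lambda_adv_d * adv_loss_logit_grad(dd_fwd_t$scores),
      need_gx = TRUE, update_params = FALSE)
    gf_extra <- NULL
    if (cfg$mode == "dd_uda") {
      de_fwd_t <- forward_discriminator(state$de, fwd3$f, train = TRUE)
      rec["l_adv_e"] <- adversarial_loss(de_fwd_t$scores)
      gf_extra <- discriminator_bwd(
        state$de, de_fwd_t,
        w$lambda_adv_e * adv_loss_logit_grad(de_fwd_t$scores),
        need_gx = TRUE, update_params = FALSE)
    }
    generator_bwd(state$gen, fwd3, 1L, gh_t, gf_extra)
    adam_update(seg_layers, cfg$lr_generator)
  }
  cb(3L)

  # (4) feature-level classification, De only (detached inputs)
  if (cfg$mode == "dd_uda") {
    de_layers <- param_layers(state$de)
    zero_grads(de_layers)
    de_fwd_s <- forward_discriminator(state$de, f_s, train = TRUE)
    rec["l_cls_e"] <- classification_loss(de_fwd_s$scores, de_fwd_t$scores)
    discriminator_bwd(state$de, de_fwd_s,
                      cls_source_logit_grad(de_fwd_s$scores),
                      need_gx = FALSE, update_params = TRUE)
    discriminator_bwd(state$de, de_fwd_t,
                      cls_target_logit_grad(de_fwd_t$scores),
                      need_gx = FALSE, update_params = TRUE)
    adam_update(de_layers, cfg$lr_discriminators)
  }
  cb(4L)

  # (5) output-level classification, Dd only (detached inputs)
  if (cfg$mode != "supervised") {
    dd_layers <- param_layers(state$dd)
    zero_grads(dd_layers)
    dd_fwd_s <- forward_discriminator(state$dd, h_s, train = TRUE)
    rec["l_cls_d"] <- classification_loss(dd_fwd_s$scores, dd_fwd_t$scores)
    discriminator_bwd(state$dd, dd_fwd_s,
                      cls_source_logit_grad(dd_fwd_s$scores),
                      need_gx = FALSE, update_params = TRUE)
    discriminator_bwd(state$dd, dd_fwd_t,
                      cls_target_logit_grad(dd_fwd_t$scores),
                      need_gx = FALSE, update_params = TRUE)
    adam_update(dd_layers, cfg$lr_discriminators)
  }
  cb(5L)

  state$iter <- state$iter + 1L
  state$history[[state$iter]] <- rec
  invisible(rec)
}

#' Seeded batch pairing with wrap-around cycling
#'
#' One epoch covers `ceil(max(n_source, n_target) / batch_size)` steps;
#' both domains are independently shuffled and the smaller one wraps
#' around so every sample of both domains is visited.
#'
#' @param n_source,n_target Dataset sizes (`n_target = 0` for supervised
#'   training).
#' @param batch_size Batch size.
#' @param seed Seed for this epoch's shuffles.
#' @return List of steps, each `list(source = idx, target = idx-or-NULL)`.
#' @export
pair_batches <- function(n_source, n_target, batch_size, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  steps <- ceiling(max(n_source, n_target) / batch_size)
  len <- steps * batch_size
  s_idx <- rep(sample.int(n_source), length.out = len)
  t_idx <- if (n_target > 0L) rep(sample.int(n_target), length.out = len)
  lapply(seq_len(steps), function(k) {
    rng <- ((k - 1L) * batch_size + 1L):(k * batch_size)
    list(source = s_idx[rng],
         target = if (is.null(t_idx)) NULL else t_idx[rng])
  })
}

#' Train a model
#'
#' Iterates paired, seeded source/target batches over epochs with the
#' five-step procedure. Deterministic: the same configuration and seed
#' reproduce the loss history exactly on the same numeric backend.
#'
#' @param cfg A [train_config()].
#' @param source_data List with `images`, `masks` and optionally
#'   `boundaries` (computed from the masks if missing); lists of matrices.
#' @param target_data List with `images` (unannotated), or `NULL` in
#'   supervised mode.
#' @param validation Optional list of `list(image =, mask =)` items; when
#'   given, the source-validation dice score is tracked each epoch and the
#'   best-scoring weights are restored at the end.
#' @param log_csv Optional path; the per-iteration loss log is written
#'   there as CSV.
#' @param checkpoint_dir Optional directory for per-epoch checkpoints.
#' @return A list of class `dduda_model`: `gen`, `de`, `dd`, `cfg`,
#'   `history` (one row per iteration) and `validation_dc` per epoch.
#' @export
train <- function(cfg, source_data, target_data = NULL, validation = NULL,
                  log_csv = NULL, checkpoint_dir = NULL) {
  if (length(source_data$images) == 0L) stop("source dataset is empty")
  if (cfg$mode != "supervised" && length(target_data$images) == 0L)
    stop("target dataset is empty")
  if (is.null(source_data$boundaries) && cfg$boundary_enabled)
    source_data$boundaries <- lapply(source_data$masks, make_boundary_label)

  state <- new_train_state(cfg)
  n_s <- length(source_data$images)
  n_t <- if (is.null(target_data)) 0L else length(target_data$images)
  val_dc <- numeric(0)
  best <- list(dc = -Inf, params = NULL)

  for (epoch in seq_len(cfg$epochs)) {
    steps <- pair_batches(n_s, n_t, cfg$batch_size,
                          substream_seed(cfg$seed, 300000L + epoch))
    for (st in steps) {
      sb <- list(images = source_data$images[st$source],
                 masks = source_data$masks[st$source],
                 boundaries = source_data$boundaries[st$source])
      tb <- if (is.null(st$target)) NULL else
        list(images = target_data$images[st$target])
      train_iteration(state, sb, tb)
    }
    if (!is.null(validation)) {
      rep_ <- evaluate_dataset(state$gen, validation)
      val_dc <- c(val_dc, rep_$dc)
      if (rep_$dc > best$dc)
        best <- list(dc = rep_$dc, params = list(
          enc = collect_params(state$gen$enc),
          dec1 = collect_params(state$gen$dec1)))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(list(gen = state$gen, de = state$de, dd = state$dd,
                           cfg = cfg),
                      file.path(checkpoint_dir,
                                sprintf("epoch_%03d.rds", epoch)))
    }
  }

  if (!is.null(validation) && !is.null(best$params)) {
    restore_params(state$gen$enc, best$params$enc)
    restore_params(state$gen$dec1, best$params$dec1)
  }

  history <- as.data.frame(do.call(rbind, state$history))
  if (nrow(history) > 0) history <- cbind(iteration = seq_len(nrow(history)),
                                          history)
  if (!is.null(log_csv)) write.csv(history, log_csv, row.names = FALSE)
  structure(list(gen = state$gen, de = state$de, dd = state$dd, cfg = cfg,
                 history = history, validation_dc = val_dc),
            class = "dduda_model")
}
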