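# Desk-scale synthetic two-domain benchmark: trains the adaptation modes
# on phantom data and measures source- and target-domain accuracy.

#' Training configuration for the desk-scale synthetic benchmark
#'
#' Same architecture and loss weights as [train_config()] but sized for a
#' CPU experiment: `base_channels = 8`, 20 epochs, and Adam learning rates
#' `1e-3` (generator) / `1e-4` (discriminators). The larger rates keep the
#' full-scale 10:1 generator:discriminator ratio while matching the much
#' shorter optimization horizon — Adam's per-step parameter displacement
#' is of order the learning rate, so a few hundred steps at the
#' full-scale `1e-5` could not move weights initialized at sd 0.02.
#'
#' @param mode Adaptation mode (see [train_config()]).
#' @param seed Integer seed.
#' @param epochs Number of epochs.
#' @param base_channels Generator width.
#' @param boundary_enabled Train the boundary decoder?
#' @return A [train_config()].
#' @export
synthetic_benchmark_config <- function(mode = "dd_uda", seed = 1L,
                                       epochs = 20L, base_channels = 8L,
                                       boundary_enabled = TRUE) {
  train_config(mode = mode, boundary_enabled = boundary_enabled,
               lr_generator = 1e-3, lr_discriminators = 1e-4,
               batch_size = 8L, epochs = epochs, seed = seed,
               image_size = 64L, base_channels = base_channels)
}

#' Run the synthetic two-domain adaptation benchmark
#'
#' For each replicate seed: generates a phantom source domain (annotated)
#' and an intensity-shifted target domain (unannotated), trains one model
#' per requested mode, and evaluates the source-domain test dice score and
#' the target-domain test IoU. Source and target test sets are fresh
#' draws never seen in training.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param modes Modes to train (subset of
#'   `c("supervised", "uda_output", "dd_uda")`).
#' @param n_source,n_target Training slices per domain.
#' @param n_test Test slices per domain.
#' @param epochs Epochs per training run.
#' @param spec,shift Phantom and domain-shift parameters.
#' @param base_channels Generator width.
#' @param verbose Print progress?
#' @return Data frame with one row per (seed, mode):
#'   `source_dc`, `source_iou`, `target_dc`, `target_iou`.
#' @export
run_synthetic_benchmark <- function(seeds = 1:3,
                                    modes = c("supervised", "uda_output",
                                              "dd_uda"),
                                    n_source = 64L, n_target = 64L,
                                    n_test = 32L, epochs = 20L,
                                    spec = phantom_spec(),
                                    shift = domain_shift_spec(),
                                    base_channels = 8L, verbose = FALSE) {
  rows <- list()
  for (seed in seeds) {
    tr <- generate_dataset(n_source, n_target, spec, shift, seed = seed)
    src_test <- lapply(seq_len(n_test), function(i) {
      ph <- make_phantom(spec, substream_seed(seed, 400000L + i))
      list(image = ph$image, mask = ph$mask)
    })
    tgt_test <- lapply(seq_len(n_test), function(i) {
      ph <- make_phantom(spec, substream_seed(seed, 500000L + i))
      list(image = apply_domain_shift(ph$image, shift,
                                      substream_seed(seed, 600000L + i)),
           mask = ph$mask)
    })
    for (mode in modes) {
      cfg <- synthetic_benchmark_config(mode = mode, seed = seed,
                                        epochs = epochs,
                                        base_channels = base_channels)
      t0 <- Sys.time()
      model <- train(cfg, tr$source,
                     if (mode == "supervised") NULL else tr$target)
      src_rep <- evaluate_dataset(model$gen, src_test)
      tgt_rep <- evaluate_dataset(model$gen, tgt_test)
      if (verbose)
        message(sprintf("seed %d %-10s %5.1fs  src DC %.3f  tgt IoU %.3f",
                        seed, mode,
                        as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        src_rep$dc, tgt_rep$iou))
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, mode = mode,
        source_dc = src_rep$dc, source_iou = src_rep$iou,
        target_dc = tgt_rep$dc, target_iou = tgt_rep$iou)
    }
  }
  do.call(rbind, rows)
}
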