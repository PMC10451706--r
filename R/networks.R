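# Boundary-enhanced generator (one encoder, two U-Net-style decoders) and
# the fully convolutional domain discriminators.

#' Generator configuration
#'
#' The segmentation generator is a five-block U-Net-style encoder with two
#' structurally identical decoders hanging off the shared bottleneck:
#' decoder-1 produces the per-pixel foreground-probability heat map,
#' decoder-2 the map whose Sobel magnitude is the boundary map. Channel
#' widths double per block from `base_channels`; `base_channels = 64`
#' matches the full-size network, smaller values give desk-scale models.
#'
#' @param in_channels Input image channels (CT slices are single-channel).
#' @param base_channels First-block channel width; must be >= 4.
#' @param activation `"relu"` (default) or `"leaky_relu"` (slope 0.2).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(in_channels = 1L, base_channels = 64L,
                             activation = c("relu", "leaky_relu")) {
  activation <- match.arg(activation)
  if (base_channels < 4L) stop("base_channels must be >= 4")
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = 5L, activation = activation),
            class = "generator_config")
}

new_decoder <- function(base, act) {
  ch <- base * c(16L, 8L, 4L, 2L, 1L)
  stages <- lapply(1:4, function(s) {
    cin <- ch[s]; cout <- ch[s + 1L]
    list(up = new_tconv(cin, cout),
         c1 = new_cba(2L * cout, cout, act),
         c2 = new_cba(cout, cout, act))
  })
  head <- new_conv(1L, base, 1L, pad = "none")
  list(stages = stages, head = head)
}

#' Build the boundary-enhanced segmentation generator
#'
#' Encoder: five blocks of two 3x3 conv + batchnorm + activation layers,
#' 2x2 max-pooling after blocks 1-4, channels doubling per block. Each
#' decoder: four stages of 2x2 stride-2 transpose convolution (halving
#' channels), concatenation with the matching encoder block output, and two
#' 3x3 conv blocks; a final 1x1 convolution plus sigmoid maps to one
#' channel. The decoders share the encoder but not their weights.
#'
#' @param config A [generator_config()].
#' @return An object of class `generator` (mutable; holds parameters and
#'   optimizer state).
#' @export
build_generator <- function(config = generator_config()) {
  base <- config$base_channels
  act <- if (config$activation == "relu") "relu" else "leaky"
  ch <- base * c(1L, 2L, 4L, 8L, 16L)
  cin <- c(config$in_channels, ch[-5L])
  enc <- lapply(1:5, function(b) list(c1 = new_cba(cin[b], ch[b], act),
                                      c2 = new_cba(ch[b], ch[b], act)))
  gen <- list(cfg = config,
              enc = enc,
              dec1 = new_decoder(base, act),
              dec2 = new_decoder(base, act))
  class(gen) <- "generator"
  gen
}

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  x
}

check_div16 <- function(d) {
  if (d[1] < 16L || d[2] < 16L || d[1] %% 16L || d[2] %% 16L)
    stop("input spatial size must be >= 16 and divisible by 16, got ",
         d[1], "x", d[2])
}

encoder_fwd <- function(gen, x, train) {
  skips <- vector("list", 5L)
  caches <- vector("list", 5L)
  pools <- vector("list", 4L)
  h <- x
  for (b in 1:5) {
    f1 <- cba_fwd(gen$enc[[b]]$c1, h, train)
    f2 <- cba_fwd(gen$enc[[b]]$c2, f1$y, train)
    caches[[b]] <- list(c1 = f1, c2 = f2)
    skips[[b]] <- f2$y
    if (b < 5L) {
      p <- ft_maxpool_fwd(f2$y)
      pools[[b]] <- p$idx
      h <- p$y
    } else h <- f2$y
  }
  list(f = h, skips = skips, caches = caches, pools = pools)
}

# Backward through the encoder given the gradient at the bottleneck and the
# gradients accumulated at each skip tap.
encoder_bwd <- function(gen, ec, gf, gskips) {
  g <- gf
  for (b in 5:1) {
    if (!is.null(gskips[[b]])) g <- ft_add(g, gskips[[b]])
    g <- cba_bwd(gen$enc[[b]]$c2, ec$caches[[b]]$c2, g)
    g <- cba_bwd(gen$enc[[b]]$c1, ec$caches[[b]]$c1, g, need_gx = (b > 1L))
    if (b > 1L) g <- ft_maxpool_bwd(g, ec$pools[[b - 1L]])
  }
  invisible()
}

decoder_fwd <- function(dec, f, skips, train) {
  h <- f
  caches <- vector("list", 4L)
  for (s in 1:4) {
    st <- dec$stages[[s]]
    up <- tconv_fwd(st$up, h)
    cat_in <- ft_concat(up, skips[[5L - s]])
    f1 <- cba_fwd(st$c1, cat_in, train)
    f2 <- cba_fwd(st$c2, f1$y, train)
    caches[[s]] <- list(x = h, up = up, c1 = f1, c2 = f2)
    h <- f2$y
  }
  logits <- ft_download(conv_fwd(dec$head, h))
  list(y = sigmoid(logits), head_in = h, caches = caches)
}

# Backward through a decoder from the gradient w.r.t. its sigmoid output
# (an R array). Returns the gradient at the bottleneck plus per-block
# skip gradients (float handles).
decoder_bwd <- function(dec, dc, gy) {
  if (is_ft(gy)) gy <- ft_download(gy)
  glog <- ft_upload(gy * dc$y * (1 - dc$y))
  g <- conv_bwd(dec$head, dc$head_in, glog)
  gskips <- vector("list", 5L)
  for (s in 4:1) {
    st <- dec$stages[[s]]
    ca <- dc$caches[[s]]
    g <- cba_bwd(st$c2, ca$c2, g)
    g <- cba_bwd(st$c1, ca$c1, g)
    sp <- ft_split(g, ft_dim(ca$up)[3])
    gskips[[5L - s]] <- sp$b
    g <- tconv_bwd(st$up, ca$x, sp$a)
  }
  list(gf = g, gskips = gskips)
}

#' Run the generator forward
#'
#' @param gen A [build_generator()] object.
#' @param images A matrix, or an `(H, W, 1, N)` array, of normalized
#'   intensities in `[0, 1]`; spatial dims must be divisible by 16.
#' @param train Logical; batch statistics (TRUE) vs running statistics.
#' @param decoders Which decoders to evaluate (subset of `c(1, 2)`).
#' @return List with `f` (bottleneck feature map), `h` (heat map, present
#'   if decoder 1 ran), `d2` (decoder-2 sigmoid output, if decoder 2 ran),
#'   and internal caches used by the training steps.
#' @export
forward_generator <- function(gen, images, train = FALSE, decoders = c(1L, 2L)) {
  if (is_ft(images)) {
    x <- images
    check_div16(ft_dim(x))
  } else {
    xa <- as_batch(images)
    check_div16(dim(xa))
    if (min(xa) < 0 || max(xa) > 1)
      stop("generator input must be normalized to [0, 1]")
    x <- ft_upload(xa)
  }
  ec <- encoder_fwd(gen, x, train)
  out <- list(f = ft_download(ec$f), enc = ec)
  if (1L %in% decoders) {
    d1 <- decoder_fwd(gen$dec1, ec$f, ec$skips, train)
    out$h <- d1$y; out$dec1 <- d1
  }
  if (2L %in% decoders && !is.null(gen$dec2)) {
    d2 <- decoder_fwd(gen$dec2, ec$f, ec$skips, train)
    out$d2 <- d2$y; out$dec2 <- d2
  }
  out
}

# Backward through one decoder and the encoder. `gout` is the gradient
# w.r.t. that decoder's sigmoid output; `gf_extra` is an additional
# gradient arriving directly at the bottleneck (feature-level adversarial
# path). Gradients accumulate inside the layer environments.
generator_bwd <- function(gen, fwd, decoder, gout, gf_extra = NULL) {
  dec <- if (decoder == 1L) gen$dec1 else gen$dec2
  dc <- if (decoder == 1L) fwd$dec1 else fwd$dec2
  db <- decoder_bwd(dec, dc, gout)
  gf <- db$gf
  if (!is.null(gf_extra)) gf <- ft_add(gf, as_ft(gf_extra))
  encoder_bwd(gen, fwd$enc, gf, db$gskips)
  invisible()
}

#' Discriminator configuration
#'
#' Five 4x4 stride-2 convolutions with channel sequence
#' `{64, 128, 256, 512, 1}`, batch normalization after the middle three
#' layers, leaky ReLU (slope 0.2) after all but the last, and a sigmoid
#' squashing of the final single-channel map. Fully convolutional: any
#' input size is accepted and each layer halves the spatial dims
#' (ceil-mode, clamped at 1x1).
#'
#' @param in_channels Input channels: 1 for the output-level discriminator
#'   on heat maps, `base_channels * 16` for the feature-level one.
#' @return A list of class `discriminator_config`.
#' @export
discriminator_config <- function(in_channels = 1L) {
  if (in_channels < 1L) stop("in_channels must be >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 channels = c(64L, 128L, 256L, 512L, 1L),
                 kernel = 4L, stride = 2L, leaky_slope = 0.2),
            class = "discriminator_config")
}

#' Build a domain discriminator
#'
#' @param config A [discriminator_config()].
#' @return An object of class `discriminator`.
#' @export
build_discriminator <- function(config = discriminator_config()) {
  ch <- config$channels
  cin <- c(config$in_channels, ch[-5L])
  layers <- lapply(1:5, function(i) {
    l <- list(conv = new_conv(4L, cin[i], ch[i], stride = 2L, pad = "same"))
    if (i %in% 2:4) l$bn <- new_bn(ch[i])
    l
  })
  d <- list(cfg = config, layers = layers)
  class(d) <- "discriminator"
  d
}

#' Run a discriminator forward
#'
#' @param d A [build_discriminator()] object.
#' @param x `(H, W, C, N)` array (feature map or heat map batch).
#' @param train Logical; batch vs running statistics.
#' @return List with `scores` (per-location probability of "source",
#'   clamped to `[1e-7, 1 - 1e-7]`), `logits`, and caches.
#' @export
forward_discriminator <- function(d, x, train = FALSE) {
  if (!is_ft(x)) {
    x <- as_batch(x)
    if (dim(x)[3] != d$cfg$in_channels)
      stop("discriminator expects ", d$cfg$in_channels,
           " input channels, got ", dim(x)[3])
    x <- ft_upload(x)
  } else if (ft_dim(x)[3] != d$cfg$in_channels) {
    stop("discriminator expects ", d$cfg$in_channels, " input channels, got ",
         ft_dim(x)[3])
  }
  caches <- vector("list", 5L)
  h <- x
  sl <- d$cfg$leaky_slope
  for (i in 1:5) {
    l <- d$layers[[i]]
    cv <- conv_fwd(l$conv, h)
    ca <- list(x = h)
    if (!is.null(l$bn)) {
      bn <- ft_bnact_fwd(cv, l$bn$w, l$bn$b, l$bn$running_mean,
                         l$bn$running_var, l$bn$momentum, l$bn$eps, train, sl)
      ca$y <- bn$out; ca$xhat <- bn$xhat; ca$invstd <- bn$invstd
      h <- bn$out
    } else if (i < 5L) {
      ca$pre <- cv
      h <- ft_act_fwd(cv, sl)
    } else h <- cv
    caches[[i]] <- ca
  }
  logits <- ft_download(h)
  eps <- 1e-7
  list(scores = pmin(pmax(sigmoid(logits), eps), 1 - eps), logits = logits,
       caches = caches)
}

# Backward from the gradient w.r.t. the logits. With update_params = FALSE
# only the input gradient is computed (generator-side adversarial step);
# with need_gx = FALSE only parameter gradients (discriminator update).
discriminator_bwd <- function(d, fwd, glogits, need_gx = TRUE,
                              update_params = TRUE) {
  g <- as_ft(glogits)
  sl <- d$cfg$leaky_slope
  for (i in 5:1) {
    l <- d$layers[[i]]
    ca <- fwd$caches[[i]]
    if (!is.null(l$bn)) {
      gb <- ft_bnact_bwd(ca$y, ca$xhat, ca$invstd, l$bn$w, g, sl, TRUE)
      if (update_params) {
        l$bn$gw <- if (is.null(l$bn$gw)) gb$ggamma else l$bn$gw + gb$ggamma
        l$bn$gb <- if (is.null(l$bn$gb)) gb$gbeta else l$bn$gb + gb$gbeta
      }
      g <- gb$gx
    } else if (i < 5L) {
      g <- ft_act_bwd(ca$pre, g, sl)
    }
    gi <- (i > 1L) || need_gx
    g <- conv_bwd(l$conv, ca$x, g, need_gx = gi, need_gw = update_params)
  }
  if (need_gx) g else invisible(NULL)
}

#' Predicted parameter shapes match between the two decoders
#' @noRd
decoder_param_count <- function(dec) {
  sum(vapply(param_layers(dec), function(l) length(l$w) + length(l$b), 0))
}

# ---- checkpoints -----------------------------------------------------------

#' Save model components to a checkpoint file
#'
#' Stores parameters (and batch-norm running statistics) of the generator
#' and any discriminators, together with their configurations and a
#' manifest of which sub-networks are present. Inference checkpoints may
#' drop decoder-2 and the discriminators.
#'
#' @param model A trained model as returned by [train()] (or a list with
#'   elements `gen`, and optionally `de`, `dd`).
#' @param path Output file path (RDS).
#' @param components Character subset of
#'   `c("encoder_dec1", "dec2", "de", "dd")`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path,
                            components = c("encoder_dec1", "dec2", "de", "dd")) {
  stopifnot(!is.null(model$gen))
  keep_dec2 <- "dec2" %in% components && !is.null(model$gen$dec2)
  obj <- list(manifest = list(
                encoder_dec1 = TRUE,
                dec2 = keep_dec2,
                de = "de" %in% components && !is.null(model$de),
                dd = "dd" %in% components && !is.null(model$dd)),
              gen_cfg = model$gen$cfg,
              enc = collect_params(model$gen$enc),
              dec1 = collect_params(model$gen$dec1),
              seed = model$cfg$seed)
  if (keep_dec2) obj$dec2 <- collect_params(model$gen$dec2)
  if (obj$manifest$de) {
    obj$de_cfg <- model$de$cfg; obj$de <- collect_params(model$de)
  }
  if (obj$manifest$dd) {
    obj$dd_cfg <- model$dd$cfg; obj$dd <- collect_params(model$dd)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return A list with `gen` (decoder-2 absent if not stored), optional
#'   `de`/`dd`, and the stored `manifest`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  gen <- build_generator(obj$gen_cfg)
  restore_params(gen$enc, obj$enc)
  restore_params(gen$dec1, obj$dec1)
  if (isTRUE(obj$manifest$dec2)) restore_params(gen$dec2, obj$dec2)
  else gen$dec2 <- NULL
  out <- list(gen = gen, manifest = obj$manifest, cfg = list(seed = obj$seed))
  if (isTRUE(obj$manifest$de)) {
    out$de <- build_discriminator(obj$de_cfg); restore_params(out$de, obj$de)
  }
  if (isTRUE(obj$manifest$dd)) {
    out$dd <- build_discriminator(obj$dd_cfg); restore_params(out$dd, obj$dd)
  }
  out
}
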