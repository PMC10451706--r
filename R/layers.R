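# Internal layer machinery. A "layer" is an environment holding double
# master parameters (plus Adam state) and a float32 mirror used by the
# compiled kernels; activations flow between layers as float tensor
# handles (external pointers into src/ops.cpp) laid out (H, W, C, N).

rnorm_array <- function(dim, sd = 0.02) array(rnorm(prod(dim), 0, sd), dim)

is_ft <- function(x) typeof(x) == "externalptr"

as_ft <- function(x) if (is_ft(x)) x else ft_upload(x)

refresh_mirror <- function(l) {
  if (l$kind %in% c("conv", "tconv")) l$wf <- ft_upload(l$w)
  invisible(l)
}

new_conv <- function(k, cin, cout, stride = 1L, pad = c("unit", "same", "none")) {
  pad <- match.arg(pad)
  e <- new.env(parent = emptyenv())
  e$kind <- "conv"; e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$pad <- pad
  e$w <- rnorm_array(c(k, k, cin, cout))
  e$b <- numeric(cout)
  refresh_mirror(e)
}

new_tconv <- function(cin, cout) {
  e <- new.env(parent = emptyenv())
  e$kind <- "tconv"
  e$w <- rnorm_array(c(2L, 2L, cin, cout))
  e$b <- numeric(cout)
  refresh_mirror(e)
}

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$kind <- "bn"; e$momentum <- momentum; e$eps <- eps
  e$w <- rep(1, c)   # gamma
  e$b <- rep(0, c)   # beta
  e$running_mean <- rep(0, c)
  e$running_var <- rep(1, c)
  e
}

conv_pads <- function(lyr, h, w) {
  if (lyr$pad == "unit") return(c(1L, 1L, 1L, 1L))
  if (lyr$pad == "none") return(c(0L, 0L, 0L, 0L))
  # "same"-style ceil-mode padding for stride-2 kernels: output ceil(n/s),
  # clamped at 1x1 so arbitrarily small maps (e.g. desk-scale bottlenecks)
  # stay valid. Identical to symmetric padding 1 for even input sizes.
  s <- lyr$stride; k <- lyr$k
  ho <- max(ceiling(h / s), 1L); wo <- max(ceiling(w / s), 1L)
  pt <- max((ho - 1L) * s + k - h, 0L)
  pl <- max((wo - 1L) * s + k - w, 0L)
  c(pt %/% 2L, pt - pt %/% 2L, pl %/% 2L, pl - pl %/% 2L)
}

conv_fwd <- function(lyr, x) {
  d <- ft_dim(x)
  p <- conv_pads(lyr, d[1], d[2])
  ft_conv_fwd(x, lyr$wf, lyr$b, lyr$stride, p[1], p[2], p[3], p[4])
}

conv_bwd <- function(lyr, x, gy, need_gx = TRUE, need_gw = TRUE) {
  d <- ft_dim(x)
  p <- conv_pads(lyr, d[1], d[2])
  g <- ft_conv_bwd(x, lyr$wf, gy, lyr$stride, p[1], p[2], p[3], p[4],
                   need_gx, need_gw)
  if (need_gw) {
    lyr$gw <- if (is.null(lyr$gw)) g$gw else lyr$gw + g$gw
    lyr$gb <- if (is.null(lyr$gb)) g$gb else lyr$gb + g$gb
  }
  g$gx
}

tconv_fwd <- function(lyr, x) ft_tconv_fwd(x, lyr$wf, lyr$b)

tconv_bwd <- function(lyr, x, gy, need_gx = TRUE) {
  g <- ft_tconv_bwd(x, lyr$wf, gy, need_gx)
  lyr$gw <- if (is.null(lyr$gw)) g$gw else lyr$gw + g$gw
  lyr$gb <- if (is.null(lyr$gb)) g$gb else lyr$gb + g$gb
  g$gx
}

act_slope <- function(act, slope = 0.2) {
  switch(act, relu = 0, leaky = slope, none = -1)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# conv -> batchnorm -> activation composite
new_cba <- function(cin, cout, act) {
  list(conv = new_conv(3L, cin, cout), bn = new_bn(cout), act = act)
}

cba_fwd <- function(blk, x, train) {
  cv <- conv_fwd(blk$conv, x)
  bn <- ft_bnact_fwd(cv, blk$bn$w, blk$bn$b, blk$bn$running_mean,
                     blk$bn$running_var, blk$bn$momentum, blk$bn$eps,
                     train, act_slope(blk$act))
  list(y = bn$out, x = x, xhat = bn$xhat, invstd = bn$invstd, train = train)
}

cba_bwd <- function(blk, cache, gy, need_gx = TRUE) {
  g <- ft_bnact_bwd(cache$y, cache$xhat, cache$invstd, blk$bn$w, gy,
                    act_slope(blk$act), cache$train)
  bn <- blk$bn
  bn$gw <- if (is.null(bn$gw)) g$ggamma else bn$gw + g$ggamma
  bn$gb <- if (is.null(bn$gb)) g$gbeta else bn$gb + g$gbeta
  conv_bwd(blk$conv, cache$x, g$gx, need_gx = need_gx)
}

# ---- parameter bookkeeping -------------------------------------------------

# collect every parameter-bearing layer environment in a module (nested list)
param_layers <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) { out[[length(out) + 1L]] <<- x; return(invisible()) }
    if (is.list(x)) for (el in x) walk(el)
  }
  walk(module)
  out
}

zero_grads <- function(layers) {
  for (l in layers) { l$gw <- NULL; l$gb <- NULL }
  invisible()
}

adam_update <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (is.null(l$gw)) next
    if (is.null(l$m_w)) {
      l$m_w <- numeric(length(l$w)); l$v_w <- numeric(length(l$w))
      l$m_b <- numeric(length(l$b)); l$v_b <- numeric(length(l$b))
      l$t <- 0L
    }
    l$t <- l$t + 1L
    cpp_adam_step(l$w, l$gw, l$m_w, l$v_w, l$t, lr, beta1, beta2, eps)
    cpp_adam_step(l$b, l$gb, l$m_b, l$v_b, l$t, lr, beta1, beta2, eps)
    l$gw <- NULL; l$gb <- NULL
    refresh_mirror(l)
  }
  invisible()
}

# flat named list of parameter values (used for checkpoints and tests)
collect_params <- function(module) {
  layers <- param_layers(module)
  out <- list()
  # multiply by 1 to force fresh allocations: parameters are updated
  # in place by compiled code, which must never reach a stored snapshot
  for (i in seq_along(layers)) {
    out[[paste0("layer", i, ".w")]] <- layers[[i]]$w * 1
    out[[paste0("layer", i, ".b")]] <- layers[[i]]$b * 1
    if (layers[[i]]$kind == "bn") {
      out[[paste0("layer", i, ".rm")]] <- layers[[i]]$running_mean * 1
      out[[paste0("layer", i, ".rv")]] <- layers[[i]]$running_var * 1
    }
  }
  out
}

restore_params <- function(module, params) {
  layers <- param_layers(module)
  for (i in seq_along(layers)) {
    layers[[i]]$w <- params[[paste0("layer", i, ".w")]] * 1
    layers[[i]]$b <- params[[paste0("layer", i, ".b")]] * 1
    if (layers[[i]]$kind == "bn") {
      layers[[i]]$running_mean <- params[[paste0("layer", i, ".rm")]] * 1
      layers[[i]]$running_var <- params[[paste0("layer", i, ".rv")]] * 1
    }
    refresh_mirror(layers[[i]])
  }
  invisible(module)
}
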