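# ---------------------------------------------------------------------------
# Reusable network operators: anti-aliased down-sampling (blur-pool),
# sub-pixel up-sampling (pixel shuffle), spectral/instance/batch-normalized
# convolution blocks, squeeze-excitation gates (cSE / sSE / scSE) and the
# hierarchical feature synthesis (HFS) residual aggregator.
#
# Feature maps are arrays with dim (H, W, C).
# ---------------------------------------------------------------------------

#' Block configuration for network operators
#'
#' @param width channel count the block operates on.
#' @param negative_slope LeakyReLU slope (default 0.2).
#' @param blur_size anti-aliasing kernel size, one of 2:5 (default 3).
#' @param scse_mode one of `"scse"`, `"cse"`, `"sse"`, `"none"` — which
#'   squeeze-excitation branch(es) the block applies (the ablation arms).
#' @param scse_reduction bottleneck reduction of the channel gate; must divide
#'   `width`. Default: the largest divisor of `width` that is at most 16.
#' @param scse_combine how the two gate branches are combined:
#'   `"max"` (default), `"add"` or `"multiply"`.
#' @return a list of class `block_config`.
#' @export
block_config <- function(width, negative_slope = 0.2, blur_size = 3L,
                         scse_mode = c("scse", "cse", "sse", "none"),
                         scse_reduction = NULL,
                         scse_combine = c("max", "add", "multiply")) {
  scse_mode <- match.arg(scse_mode)
  scse_combine <- match.arg(scse_combine)
  stopifnot(width >= 1, blur_size %in% 2:5)
  if (is.null(scse_reduction)) {
    divs <- which(width %% seq_len(width) == 0)
    scse_reduction <- max(divs[divs <= 16])
  }
  if (width %% scse_reduction != 0)
    stop("scse_reduction must divide width")
  structure(list(width = as.integer(width),
                 negative_slope = negative_slope,
                 blur_size = as.integer(blur_size),
                 scse_mode = scse_mode,
                 scse_reduction = as.integer(scse_reduction),
                 scse_combine = scse_combine),
            class = "block_config")
}

#' Binomial anti-aliasing kernel
#'
#' Outer product of binomial coefficients of order `size - 1`, normalized to
#' sum to one. This is the low-pass filter applied before subsampling so that
#' down-sampling does not alias high-frequency content.
#'
#' @param size kernel side length, one of 2, 3, 4, 5.
#' @return a `size x size` matrix with non-negative entries summing to 1.
#' @export
make_blur_kernel <- function(size) {
  if (!size %in% 2:5) stop("blur kernel size must be one of 2, 3, 4, 5")
  a <- choose(size - 1, 0:(size - 1))
  k <- outer(a, a)
  k / sum(k)
}

#' Anti-aliased down-sampling (blur-pool)
#'
#' Convolves every channel with the binomial kernel under reflection padding,
#' then subsamples every `stride`-th row and column starting at index 1, so
#' the output spatial size is `ceiling(input / stride)`.
#'
#' @param x feature map, array `(H, W, C)` (a matrix is treated as 1 channel).
#' @param stride subsampling stride (default 2).
#' @param blur_size kernel size (default 3).
#' @return down-sampled feature map with the same channel count.
#' @export
blurpool <- function(x, stride = 2L, blur_size = 3L) {
  x <- as_feature_array(x)
  if (min(dim(x)[1:2]) < blur_size)
    stop("blurpool: spatial size smaller than blur kernel")
  ag_blurpool(NULL, x, make_blur_kernel(blur_size), stride)
}

#' Sub-pixel rearrangement (pixel shuffle) and its inverse
#'
#' `pixel_shuffle` rearranges an `(H, W, C*r^2)` map into `(H*r, W*r, C)`:
#' output channel `c` at position `(r*h + i, r*w + j)` takes input channel
#' `c*r^2 + i*r + j` at `(h, w)` (0-based offsets). It is a bijection on
#' entries; `pixel_unshuffle` is its exact inverse.
#'
#' @param x feature map array.
#' @param r upscale factor.
#' @return rearranged feature map.
#' @export
pixel_shuffle <- function(x, r) {
  x <- as_feature_array(x)
  if (dim(x)[3] %% (r * r) != 0)
    stop("pixel_shuffle: channel count not divisible by r^2")
  cpp_pixel_shuffle(x, as.integer(r))
}

#' @rdname pixel_shuffle
#' @export
pixel_unshuffle <- function(x, r) {
  x <- as_feature_array(x)
  if (any(dim(x)[1:2] %% r != 0))
    stop("pixel_unshuffle: spatial size not divisible by r")
  cpp_pixel_unshuffle(x, as.integer(r))
}

as_feature_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L, all(is.finite(x)))
  x
}

# ---------------------------------------------------------------------------
# layers: parameterized building blocks
# ---------------------------------------------------------------------------

xavier_bound <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

new_layer <- function(.kind, ...) {
  l <- new.env(parent = emptyenv())
  l$kind <- .kind
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  class(l) <- c(paste0("layer_", .kind), "nn_layer")
  l
}

#' Convolution layer constructor
#'
#' @param cin,cout input/output channels.
#' @param k kernel size (scalar).
#' @param stride stride.
#' @param pad either a single integer or `c(top, bottom, left, right)`.
#' @param pad_mode `"zero"` or `"reflect"`.
#' @param spectral apply spectral normalization (one power-iteration step per
#'   training forward; the left-singular-vector estimate is persistent).
#' @param bias include a bias term.
#' @return an `nn_layer` environment holding `ag_param` weights.
#' @export
new_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                       pad_mode = "zero", spectral = FALSE, bias = TRUE) {
  fan_in <- k * k * cin
  fan_out <- k * k * cout
  b <- xavier_bound(fan_in, fan_out)
  w <- array(runif(k * k * cin * cout, -b, b), dim = c(k, k, cin, cout))
  new_layer("conv2d",
            params = list(w = ag_param(w),
                          b = if (bias) ag_param(numeric(cout)) else NULL),
            k = as.integer(k), stride = as.integer(stride), pad = pad,
            pad_mode = pad_mode, spectral = spectral,
            sn_u = rep(1 / sqrt(cout), cout),
            cin = as.integer(cin), cout = as.integer(cout))
}

new_norm2d <- function(channels, kind = c("instance", "batch", "none"),
                       eps = 1e-5, momentum = 0.1) {
  kind <- match.arg(kind)
  new_layer("norm2d",
            params = if (kind == "none") list() else
              list(gamma = ag_param(rep(1, channels)),
                   beta = ag_param(numeric(channels))),
            norm_kind = kind, eps = eps, momentum = momentum,
            running_mean = numeric(channels),
            running_var = rep(1, channels), channels = as.integer(channels))
}

new_dense <- function(nin, nout) {
  b <- xavier_bound(nin, nout)
  new_layer("dense",
            params = list(w = ag_param(matrix(runif(nin * nout, -b, b),
                                              nrow = nout, ncol = nin)),
                          b = ag_param(numeric(nout))),
            nin = as.integer(nin), nout = as.integer(nout))
}

conv2d_forward <- function(layer, x, tape = NULL, train = FALSE,
                           trainable = train) {
  w <- ag_use_param(tape, layer$params$w, trainable)
  if (layer$spectral) w <- ag_spectral_norm(tape, w, layer, update = train)
  b <- if (is.null(layer$params$b)) numeric(layer$cout)
       else ag_use_param(tape, layer$params$b, trainable)
  ag_conv2d(tape, x, w, b, stride = layer$stride, pad = layer$pad,
            pad_mode = layer$pad_mode)
}

norm2d_forward <- function(layer, x, tape = NULL, train = FALSE,
                           trainable = train) {
  if (layer$norm_kind == "none") return(x)
  gamma <- ag_use_param(tape, layer$params$gamma, trainable)
  beta <- ag_use_param(tape, layer$params$beta, trainable)
  if (layer$norm_kind == "instance" || train) {
    out <- ag_instance_norm(tape, x, gamma, beta, eps = layer$eps)
    if (layer$norm_kind == "batch" && train) {
      # track running statistics from the per-sample moments (batch size 1)
      xv <- node_value(x)
      n <- prod(dim(xv)[1:2])
      xm <- matrix(xv, nrow = n)
      mu <- colMeans(xm)
      va <- colSums(sweep(xm, 2L, mu)^2) / max(n - 1, 1)
      m <- layer$momentum
      layer$running_mean <- (1 - m) * layer$running_mean + m * mu
      layer$running_var <- (1 - m) * layer$running_var + m * va
    }
    return(out)
  }
  # batch norm, evaluation mode: frozen running statistics
  ag_bn_eval(tape, x, gamma, beta, layer$running_mean, layer$running_var,
             layer$eps)
}

# ---------------------------------------------------------------------------
# conv block: (spectral) conv -> instance/batch norm -> LeakyReLU
# ---------------------------------------------------------------------------

#' Normalized convolution block constructor
#'
#' Convolution (optionally spectrally normalized) followed by instance or
#' batch normalization and a LeakyReLU. Spatial size is preserved
#' (`pad = k %/% 2`).
#'
#' @inheritParams new_conv2d
#' @param norm `"instance"`, `"batch"` or `"none"`.
#' @param negative_slope LeakyReLU slope.
#' @export
new_conv_block <- function(cin, cout, k = 3L, spectral = TRUE,
                           norm = "instance", negative_slope = 0.2,
                           pad_mode = "zero") {
  new_layer("conv_block",
            conv = new_conv2d(cin, cout, k = k, pad_mode = pad_mode,
                              spectral = spectral),
            norm = new_norm2d(cout, norm),
            negative_slope = negative_slope)
}

conv_block_forward <- function(blk, x, tape = NULL, train = FALSE,
                               trainable = train) {
  h <- conv2d_forward(blk$conv, x, tape, train, trainable)
  h <- norm2d_forward(blk$norm, h, tape, train, trainable)
  ag_leaky_relu(tape, h, blk$negative_slope)
}

#' Apply a normalized convolution block to a feature map
#'
#' Functional form of [new_conv_block()]: builds (or reuses) the layer and
#' runs it in evaluation mode.
#'
#' @param x feature map `(H, W, C)`.
#' @param cfg a [block_config()]; `cfg$width` gives the output channels.
#' @param use_spectral_norm constrain the conv weight's spectral norm to 1.
#' @param norm normalization kind.
#' @param layer optional pre-built layer to reuse (weights persist).
#' @return the transformed feature map (same spatial size).
#' @export
conv_block <- function(x, cfg, use_spectral_norm = TRUE, norm = "instance",
                       layer = NULL) {
  x <- as_feature_array(x)
  if (is.null(layer))
    layer <- new_conv_block(dim(x)[3], cfg$width, spectral = use_spectral_norm,
                            norm = norm, negative_slope = cfg$negative_slope)
  conv_block_forward(layer, x, NULL)
}

# ---------------------------------------------------------------------------
# squeeze-excitation gates
# ---------------------------------------------------------------------------

new_cse <- function(channels, reduction) {
  if (channels %% reduction != 0) stop("reduction must divide channels")
  mid <- max(1L, channels %/% reduction)
  new_layer("cse", fc1 = new_dense(channels, mid),
            fc2 = new_dense(mid, channels))
}

cse_forward <- function(layer, x, tape = NULL, train = FALSE,
                        trainable = train) {
  s <- ag_gap(tape, x)
  s <- ag_relu(tape, ag_dense(tape, s, ag_use_param(tape, layer$fc1$params$w, trainable),
                              ag_use_param(tape, layer$fc1$params$b, trainable)))
  s <- ag_sigmoid(tape, ag_dense(tape, s, ag_use_param(tape, layer$fc2$params$w, trainable),
                                 ag_use_param(tape, layer$fc2$params$b, trainable)))
  ag_scale_channels(tape, x, s)
}

new_sse <- function(channels) {
  new_layer("sse", conv = new_conv2d(channels, 1L, k = 1L, pad = 0L))
}

sse_forward <- function(layer, x, tape = NULL, train = FALSE,
                        trainable = train) {
  g <- conv2d_forward(layer$conv, x, tape, train, trainable)
  g <- ag_sigmoid(tape, g)
  ag_scale_spatial(tape, x, g)
}

#' Channel squeeze-excitation gate (cSE)
#'
#' Global average pool over space, a two-layer bottleneck
#' (`C -> C/reduction -> C`, ReLU between), sigmoid, and a per-channel
#' multiplicative gate in (0, 1) applied back onto the input.
#'
#' @param x feature map `(H, W, C)`.
#' @param reduction bottleneck reduction (must divide C).
#' @param layer optional pre-built gate to reuse.
#' @return gated feature map, same shape.
#' @export
cse_gate <- function(x, reduction = 2L, layer = NULL) {
  x <- as_feature_array(x)
  if (is.null(layer)) layer <- new_cse(dim(x)[3], reduction)
  cse_forward(layer, x, NULL)
}

#' Spatial squeeze-excitation gate (sSE)
#'
#' A 1x1 convolution to a single channel, sigmoid, and the resulting spatial
#' gate map in (0, 1) broadcast-multiplied onto every channel.
#'
#' @inheritParams cse_gate
#' @export
sse_gate <- function(x, layer = NULL) {
  x <- as_feature_array(x)
  if (is.null(layer)) layer <- new_sse(dim(x)[3])
  sse_forward(layer, x, NULL)
}

new_scse <- function(channels, cfg) {
  new_layer("scse",
            cse = if (cfg$scse_mode %in% c("scse", "cse"))
              new_cse(channels, cfg$scse_reduction) else NULL,
            sse = if (cfg$scse_mode %in% c("scse", "sse"))
              new_sse(channels) else NULL,
            mode = cfg$scse_mode, combine = cfg$scse_combine)
}

scse_forward <- function(layer, x, tape = NULL, train = FALSE,
                         trainable = train) {
  if (layer$mode == "none") return(x)
  if (layer$mode == "cse") return(cse_forward(layer$cse, x, tape, train, trainable))
  if (layer$mode == "sse") return(sse_forward(layer$sse, x, tape, train, trainable))
  a <- cse_forward(layer$cse, x, tape, train, trainable)
  b <- sse_forward(layer$sse, x, tape, train, trainable)
  switch(layer$combine,
         max = ag_pmax(tape, a, b),
         add = ag_add(tape, a, b),
         multiply = ag_mul(tape, a, b),
         stop("unknown scSE combine mode: ", layer$combine))
}

#' Concurrent spatial and channel squeeze-excitation (scSE)
#'
#' Elementwise combination (default `max`) of the cSE and sSE branch outputs;
#' `scse_mode = "cse"`/`"sse"` in the config selects a single branch (the
#' ablation arms), `"none"` is the identity.
#'
#' @param x feature map `(H, W, C)`.
#' @param cfg a [block_config()].
#' @param layer optional pre-built block to reuse.
#' @export
scse_block <- function(x, cfg, layer = NULL) {
  x <- as_feature_array(x)
  if (is.null(layer)) layer <- new_scse(dim(x)[3], cfg)
  scse_forward(layer, x, NULL)
}

# ---------------------------------------------------------------------------
# residual block and HFS aggregation
# ---------------------------------------------------------------------------

#' Residual block constructor (conv block -> conv -> scSE, plus skip)
#'
#' The residual branch is a normalized conv block followed by a plain
#' convolution (no activation) and the configured squeeze-excitation gate;
#' the trunk adds the branch back onto the input. Both the trunk and the
#' branch output are returned by the forward so the HFS aggregator can reuse
#' residual features.
#'
#' @param channels feature width.
#' @param cfg a [block_config()].
#' @export
new_residual_block <- function(channels, cfg) {
  new_layer("residual",
            cb = new_conv_block(channels, channels, spectral = TRUE,
                                norm = "instance",
                                negative_slope = cfg$negative_slope),
            conv2 = new_conv2d(channels, channels, k = 3L, spectral = TRUE),
            scse = new_scse(channels, cfg))
}

residual_forward <- function(blk, x, tape = NULL, train = FALSE,
                             trainable = train) {
  h <- conv_block_forward(blk$cb, x, tape, train, trainable)
  h <- conv2d_forward(blk$conv2, h, tape, train, trainable)
  h <- scse_forward(blk$scse, h, tape, train, trainable)
  list(trunk = ag_add(tape, x, h), residual = h)
}

#' Apply a residual block
#'
#' @param x feature map `(H, W, C)`.
#' @param cfg a [block_config()].
#' @param layer optional pre-built block.
#' @return list with `trunk` (`x + branch`) and `residual_feature` (branch).
#' @export
residual_block <- function(x, cfg, layer = NULL) {
  x <- as_feature_array(x)
  if (is.null(layer)) layer <- new_residual_block(dim(x)[3], cfg)
  r <- residual_forward(layer, x, NULL)
  list(trunk = r$trunk, residual_feature = r$residual)
}

#' Hierarchical feature synthesis (HFS) module constructor
#'
#' Three residual blocks run sequentially; their residual-branch outputs are
#' concatenated with the last trunk output (4C channels), fused back to C
#' channels by a 1x1 convolution, and added to the module input. With the
#' fuse convolution zero-initialized the module is exactly the identity.
#'
#' @param channels feature width.
#' @param cfg a [block_config()].
#' @export
new_hfs <- function(channels, cfg) {
  new_layer("hfs",
            blocks = list(new_residual_block(channels, cfg),
                          new_residual_block(channels, cfg),
                          new_residual_block(channels, cfg)),
            fuse = new_conv2d(4L * channels, channels, k = 1L, pad = 0L))
}

hfs_forward <- function(mod, x, tape = NULL, train = FALSE,
                        trainable = train) {
  h <- x
  residuals <- vector("list", 3L)
  for (i in 1:3) {
    r <- residual_forward(mod$blocks[[i]], h, tape, train, trainable)
    residuals[[i]] <- r$residual
    h <- r$trunk
  }
  cat4 <- ag_concat_c(tape, c(residuals, list(h)))
  fused <- conv2d_forward(mod$fuse, cat4, tape, train, trainable)
  ag_add(tape, x, fused)
}

#' Apply an HFS module to a feature map
#'
#' @param x feature map `(H, W, C)`.
#' @param cfg a [block_config()].
#' @param layer optional pre-built module.
#' @export
hfs_aggregate <- function(x, cfg, layer = NULL) {
  x <- as_feature_array(x)
  if (is.null(layer)) layer <- new_hfs(dim(x)[3], cfg)
  hfs_forward(layer, x, NULL)
}

# ---------------------------------------------------------------------------
# parameter walking
# ---------------------------------------------------------------------------

#' Collect all trainable parameters of a layer/module tree
#'
#' @param x an `nn_layer`, a list of them, or a module holding them.
#' @return flat named list of `ag_param` environments.
#' @export
nn_params <- function(x) {
  out <- list()
  walk <- function(obj, prefix) {
    if (is.null(obj)) return(invisible())
    if (is_param(obj)) {
      out[[prefix]] <<- obj
    } else if (inherits(obj, "nn_layer")) {
      for (nm in ls(obj, sorted = TRUE)) {
        if (nm %in% c("kind", "sn_u", "sn_sigma", "running_mean",
                      "running_var")) next
        walk(get(nm, envir = obj), paste0(prefix, ".", nm))
      }
    } else if (is.list(obj)) {
      nms <- names(obj)
      for (i in seq_along(obj)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(obj[[i]], paste0(prefix, ".", nm))
      }
    }
  }
  walk(x, "p")
  out
}

#' Total parameter count of a module
#' @param x module or layer.
#' @export
nn_param_count <- function(x) {
  sum(vapply(nn_params(x), function(p) length(p$value), numeric(1)))
}
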