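# ---------------------------------------------------------------------------
# The translation generator: anti-aliased encoder -> HFS core -> sub-pixel
# decoder, with a sigmoid tail so outputs live on the same [0, 1] scale as
# min-max normalized inputs.
# ---------------------------------------------------------------------------

#' Generator configuration
#'
#' The generator is: head (reflection-padded 7x7 conv to `base_width`,
#' instance norm, LeakyReLU) -> `n_down` encoder stages (spectrally
#' normalized stride-1 3x3 conv doubling the width, instance norm, LeakyReLU,
#' blur-pool stride 2) -> `n_hfs` HFS modules -> `n_down` decoder stages
#' (spectrally normalized 3x3 conv expanding channels by `r^2/2`, instance
#' norm, LeakyReLU, pixel shuffle by `r`) -> reflection-padded 7x7 conv to 1
#' channel and sigmoid. All down-sampling is anti-aliased (no bare strided
#' convolution, no max-pool).
#'
#' @param in_channels input channels (1 for grayscale CT).
#' @param base_width head width (default 64; desk-scale presets use less).
#' @param n_down number of encoder/decoder stages (default 2).
#' @param n_hfs number of HFS modules at the bottleneck (default 3).
#' @param r pixel-shuffle upscale factor per decoder stage; must be 2 so that
#'   `r^n_down` undoes the encoder's `2^n_down` blur-pool down-sampling.
#' @param blur_size anti-aliasing kernel size.
#' @param negative_slope LeakyReLU slope.
#' @param scse_mode squeeze-excitation arm: `"scse"`, `"cse"`, `"sse"`,
#'   `"none"`.
#' @param scse_combine combination of the two gates (default `"max"`).
#' @param scse_reduction channel-gate bottleneck reduction (`NULL` = auto).
#' @param head_kernel head/tail kernel size (default 7).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(in_channels = 1L, base_width = 64L, n_down = 2L,
                             n_hfs = 3L, r = 2L, blur_size = 3L,
                             negative_slope = 0.2, scse_mode = "scse",
                             scse_combine = "max", scse_reduction = NULL,
                             head_kernel = 7L) {
  if (r^n_down != 2^n_down)
    stop("generator_config: r^n_down must equal the encoder's total ",
         "down-sampling 2^n_down (use r = 2)")
  structure(as.list(environment()), class = "generator_config")
}

#' Build a generator network
#'
#' @param cfg a [generator_config()].
#' @return object of class `aac_generator` (layers plus config).
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  w <- cfg$base_width
  hk <- cfg$head_kernel
  head <- list(conv = new_conv2d(cfg$in_channels, w, k = hk,
                                 pad = (hk - 1L) %/% 2L, pad_mode = "reflect"),
               norm = new_norm2d(w, "instance"))
  enc <- list()
  for (i in seq_len(cfg$n_down)) {
    enc[[i]] <- list(conv = new_conv2d(w, 2L * w, k = 3L, spectral = TRUE),
                     norm = new_norm2d(2L * w, "instance"))
    w <- 2L * w
  }
  bcfg <- block_config(w, negative_slope = cfg$negative_slope,
                       blur_size = cfg$blur_size, scse_mode = cfg$scse_mode,
                       scse_reduction = cfg$scse_reduction,
                       scse_combine = cfg$scse_combine)
  hfs <- lapply(seq_len(cfg$n_hfs), function(i) new_hfs(w, bcfg))
  dec <- list()
  for (i in seq_len(cfg$n_down)) {
    wout <- w %/% 2L
    dec[[i]] <- list(conv = new_conv2d(w, wout * cfg$r^2, k = 3L,
                                       spectral = TRUE),
                     norm = new_norm2d(wout * cfg$r^2, "instance"))
    w <- wout
  }
  tail <- list(conv = new_conv2d(w, cfg$in_channels, k = hk,
                                 pad = (hk - 1L) %/% 2L,
                                 pad_mode = "reflect"))
  structure(list(head = head, enc = enc, hfs = hfs, dec = dec, tail = tail,
                 cfg = cfg,
                 blur_kernel = make_blur_kernel(cfg$blur_size)),
            class = "aac_generator")
}

# core forward on a (H, W, C) array or tape node
g_forward <- function(G, x, tape = NULL, train = FALSE, trainable = train) {
  cfg <- G$cfg
  slope <- cfg$negative_slope
  h <- conv2d_forward(G$head$conv, x, tape, train, trainable)
  h <- norm2d_forward(G$head$norm, h, tape, train, trainable)
  h <- ag_leaky_relu(tape, h, slope)
  for (st in G$enc) {
    h <- conv2d_forward(st$conv, h, tape, train, trainable)
    h <- norm2d_forward(st$norm, h, tape, train, trainable)
    h <- ag_leaky_relu(tape, h, slope)
    h <- ag_blurpool(tape, h, G$blur_kernel, 2L)
  }
  for (m in G$hfs) h <- hfs_forward(m, h, tape, train, trainable)
  for (st in G$dec) {
    h <- conv2d_forward(st$conv, h, tape, train, trainable)
    h <- norm2d_forward(st$norm, h, tape, train, trainable)
    h <- ag_leaky_relu(tape, h, slope)
    h <- ag_pixel_shuffle(tape, h, cfg$r)
  }
  h <- conv2d_forward(G$tail$conv, h, tape, train, trainable)
  ag_sigmoid(tape, h)
}

#' Run a generator on a normalized CT slice
#'
#' Deterministic given the weights: instance normalization uses per-sample
#' statistics only, and no random operation is involved.
#'
#' @param G an `aac_generator` from [build_generator()].
#' @param x a normalized [ct_image()] (pixels in \[0, 1\]) whose sides are
#'   divisible by `2^n_down`.
#' @return a normalized `generated` [ct_image()] of the same size.
#' @export
generator_forward <- function(G, x) {
  stopifnot(inherits(G, "aac_generator"), inherits(x, "ct_image"))
  if (!x$normalized)
    stop("generator_forward: input must be min-max normalized")
  d <- dim(x$pixels)
  div <- 2^G$cfg$n_down
  if (any(d %% div != 0))
    stop("generator_forward: image size must be divisible by 2^n_down = ", div)
  xa <- array(x$pixels, dim = c(d, 1L))
  out <- g_forward(G, xa, NULL, train = FALSE)
  ct_image(matrix(out, d[1], d[2]), "generated", normalized = TRUE,
           background_value = x$background_value, source_id = x$source_id,
           norm_min = x$norm_min, norm_max = x$norm_max)
}

#' Summarize generator structure (for structural assertions)
#'
#' Lists every convolution with its stride, and every down-sampling step with
#' its kind, so tests can assert the anti-aliasing contract: all convs are
#' stride 1 and all down-sampling happens in blur-pool layers.
#'
#' @param G an `aac_generator`.
#' @return data.frame with columns `stage`, `op`, `stride`.
#' @export
generator_structure <- function(G) {
  rows <- list()
  add <- function(stage, op, stride)
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, op = op,
                                             stride = stride)
  add("head", "conv", G$head$conv$stride)
  for (i in seq_along(G$enc)) {
    add(paste0("enc", i), "conv", G$enc[[i]]$conv$stride)
    add(paste0("enc", i), "blurpool", 2L)
  }
  for (i in seq_along(G$hfs))
    for (b in 1:3) {
      add(paste0("hfs", i), "conv", G$hfs[[i]]$blocks[[b]]$cb$conv$stride)
      add(paste0("hfs", i), "conv", G$hfs[[i]]$blocks[[b]]$conv2$stride)
    }
  for (i in seq_along(G$dec)) {
    add(paste0("dec", i), "conv", G$dec[[i]]$conv$stride)
    add(paste0("dec", i), "pixel_shuffle", 1L)
  }
  add("tail", "conv", G$tail$conv$stride)
  do.call(rbind, rows)
}
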