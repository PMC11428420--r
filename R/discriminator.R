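# ---------------------------------------------------------------------------
# Multi-scale patch discriminator bank: three discriminators judging realism
# at full, half and quarter input sizes (512/256/128 at training resolution),
# each a stack of spectrally-normalized stride-1 convolutions followed by
# anti-aliased blur-pool down-sampling; only the first block carries batch
# normalization.  The final stage zero-pads rows only (1 on top and bottom)
# and applies a 4x4 stride-1 convolution to one channel, yielding a spatial
# score map (non-square for square inputs).
# ---------------------------------------------------------------------------

#' Discriminator bank configuration
#'
#' @param input_size side length of the scale-1 input (512 at training
#'   resolution; 64 at desk/test scale).
#' @param n_scales number of scales N (default 3).
#' @param base_width width of the first block (default 64).
#' @param blur_size anti-aliasing kernel size.
#' @param negative_slope LeakyReLU slope.
#' @param n_blocks down-sampling blocks per scale; `NULL` picks
#'   `min(4, log2(size) - 2)` per scale (4 at 512, PatchGAN convention,
#'   fewer at small test sizes so the final 4x4 convolution still fits).
#' @param input_mode `"random_crop"` (scales 2, 3 are random native-resolution
#'   crops) or `"pyramid"` (blur + subsample down-scalings).
#' @return list of class `discriminator_config` with `input_sizes`
#'   (strictly decreasing).
#' @export
discriminator_config <- function(input_size = 512L, n_scales = 3L,
                                 base_width = 64L, blur_size = 3L,
                                 negative_slope = 0.2, n_blocks = NULL,
                                 input_mode = c("random_crop", "pyramid")) {
  input_mode <- match.arg(input_mode)
  input_sizes <- as.integer(input_size / 2^(seq_len(n_scales) - 1L))
  stopifnot(all(diff(input_sizes) < 0), min(input_sizes) >= 8L)
  if (is.null(n_blocks))
    n_blocks <- pmin(4L, as.integer(floor(log2(input_sizes))) - 2L)
  n_blocks <- rep_len(as.integer(n_blocks), n_scales)
  structure(list(input_size = as.integer(input_size),
                 n_scales = as.integer(n_scales),
                 base_width = as.integer(base_width),
                 blur_size = as.integer(blur_size),
                 negative_slope = negative_slope, n_blocks = n_blocks,
                 input_sizes = input_sizes, input_mode = input_mode),
            class = "discriminator_config")
}

build_discriminator_scale <- function(cfg, scale) {
  nb <- cfg$n_blocks[scale]
  blocks <- list()
  cin <- 1L
  w <- cfg$base_width
  for (i in seq_len(nb)) {
    # reflect padding keeps flat regions flat (no zero-pad border artifacts);
    # the printed rows-only ZeroPad2d is reserved for the final stage
    blocks[[i]] <- list(
      conv = new_conv2d(cin, w, k = 4L, pad = c(1L, 2L, 1L, 2L),
                        pad_mode = "reflect", spectral = TRUE),
      norm = new_norm2d(w, if (i == 1L) "batch" else "none"))
    cin <- w
    w <- min(2L * w, 8L * cfg$base_width)
  }
  final <- new_conv2d(cin, 1L, k = 4L, pad = c(1L, 1L, 0L, 0L))
  structure(list(blocks = blocks, final = final, cfg = cfg, scale = scale,
                 blur_kernel = make_blur_kernel(cfg$blur_size)),
            class = "aac_discriminator")
}

#' Build the multi-scale discriminator bank
#'
#' @param cfg a [discriminator_config()].
#' @return list of class `aac_disc_bank` with one `aac_discriminator` per
#'   scale.
#' @export
build_discriminator_bank <- function(cfg) {
  structure(list(scales = lapply(seq_len(cfg$n_scales), function(i)
    build_discriminator_scale(cfg, i)), cfg = cfg),
    class = "aac_disc_bank")
}

d_forward <- function(D, x, tape = NULL, train = FALSE, trainable = train,
                      prob = TRUE) {
  slope <- D$cfg$negative_slope
  h <- x
  for (b in D$blocks) {
    h <- conv2d_forward(b$conv, h, tape, train, trainable)
    h <- norm2d_forward(b$norm, h, tape, train, trainable)
    h <- ag_leaky_relu(tape, h, slope)
    h <- ag_blurpool(tape, h, D$blur_kernel, 2L)
  }
  h <- conv2d_forward(D$final, h, tape, train, trainable)
  if (prob) h <- ag_sigmoid(tape, h)
  h
}

#' Run one discriminator on an image
#'
#' @param D an `aac_discriminator` (one element of the bank's `$scales`).
#' @param img a [ct_image()] (normalized) or a numeric matrix/array sized for
#'   this scale.
#' @param prob if `TRUE` (default) apply a sigmoid so scores are patch-level
#'   realism probabilities in (0, 1); otherwise return logits.
#' @param train training mode (batch-norm uses per-sample statistics and
#'   updates running averages); `FALSE` = evaluation mode, deterministic with
#'   frozen statistics.
#' @return a `score_map`: numeric matrix of per-patch scores with attribute
#'   `form` = `"probability"` or `"logit"`.
#' @export
discriminator_forward <- function(D, img, prob = TRUE, train = FALSE) {
  x <- if (inherits(img, "ct_image")) img$pixels else img
  x <- as_feature_array(x)
  out <- d_forward(D, x, NULL, train = train, prob = prob)
  structure(matrix(out, dim(out)[1], dim(out)[2]),
            form = if (prob) "probability" else "logit", class = "score_map")
}

#' Closed-form score-map size
#'
#' Applies the layer-by-layer (kernel, stride, padding) size recursion of the
#' configured stack: each block is a same-size 4x4 stride-1 convolution
#' (pad 1/2) followed by blur-pool (`ceiling(s/2)`); the final rows-only
#' padded 4x4 convolution maps `(h, w)` to `(h - 1, w - 3)`.
#'
#' @param cfg a [discriminator_config()].
#' @param scale which discriminator (1..n_scales).
#' @param input_size optional explicit input side length.
#' @return integer vector `(height, width)` of the score map.
#' @export
score_map_size <- function(cfg, scale, input_size = cfg$input_sizes[scale]) {
  s <- input_size
  for (i in seq_len(cfg$n_blocks[scale])) {
    s <- s + 1L + 2L - 4L + 1L       # conv k=4, s=1, pad (1,2): size kept
    s <- as.integer(ceiling(s / 2))  # blur-pool stride 2
  }
  c(height = s + 1L + 1L - 4L + 1L,  # final conv k=4, pad rows (1,1)
    width = s - 4L + 1L)
}

#' Build the three scale inputs for an image
#'
#' In `random_crop` mode (default) the scale-1 input is the full image and
#' scales 2, 3 are random crops of the configured sizes at native resolution;
#' in `pyramid` mode the smaller scales are blur-pool down-scalings. Sizes
#' scale proportionally when the image is smaller than the configured
#' training resolution.
#'
#' @param img [ct_image()] or numeric matrix at full resolution.
#' @param cfg a [discriminator_config()].
#' @param seed optional seed making the crop windows reproducible.
#' @return list of `n_scales` numeric matrices.
#' @export
make_multiscale_inputs <- function(img, cfg, seed = NULL) {
  x <- if (inherits(img, "ct_image")) img$pixels else img
  n <- nrow(x)
  sizes <- as.integer(n / 2^(seq_len(cfg$n_scales) - 1L))
  if (any(sizes > c(n, n, n)[seq_len(cfg$n_scales)]))
    stop("make_multiscale_inputs: crop size exceeds image")
  local_seed(seed, {
    out <- vector("list", cfg$n_scales)
    for (i in seq_len(cfg$n_scales)) {
      s <- sizes[i]
      if (i == 1L) {
        out[[i]] <- x
      } else if (cfg$input_mode == "random_crop") {
        r0 <- sample.int(n - s + 1L, 1L)
        c0 <- sample.int(ncol(x) - s + 1L, 1L)
        out[[i]] <- x[r0:(r0 + s - 1L), c0:(c0 + s - 1L)]
      } else {
        y <- out[[i - 1L]]
        y3 <- array(y, dim = c(dim(y), 1L))
        y3 <- cpp_blurpool_fw(y3, make_blur_kernel(cfg$blur_size), 2L)
        out[[i]] <- matrix(y3, dim(y3)[1], dim(y3)[2])
      }
    }
    out
  })
}

#' Score an image with the whole multi-scale bank
#'
#' @param bank an `aac_disc_bank`.
#' @param img image at full resolution.
#' @param seed crop reproducibility seed.
#' @param prob probability-form scores (default).
#' @return list of `n_scales` `score_map`s, ordered D1..DN.
#' @export
multiscale_scores <- function(bank, img, seed = NULL, prob = TRUE) {
  inputs <- make_multiscale_inputs(img, bank$cfg, seed = seed)
  lapply(seq_along(bank$scales), function(i)
    discriminator_forward(bank$scales[[i]], inputs[[i]], prob = prob))
}
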