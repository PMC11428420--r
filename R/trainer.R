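# ---------------------------------------------------------------------------
# Unpaired training loop: two generators (G: low->standard, F: standard->low)
# and two multi-scale discriminator banks, Adam with a fixed learning rate,
# one discriminator update followed by one generator update per step.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Published protocol: Adam with beta1 = 0.9, beta2 = 0.999, learning rate
#' fixed at 1e-4 (no decay), batch size 1, input size 512, 5000 epochs.
#' The desk-scale preset ([desk_train_config()]) keeps the optimizer settings
#' and shrinks image size, width and epochs so the loop runs on one CPU.
#'
#' @param lr learning rate (fixed schedule).
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size images per step (1, the published setting).
#' @param epochs passes over the larger domain.
#' @param input_size training image side length.
#' @param seed seed for initialization, shuffling and crops.
#' @param checkpoint_every save a checkpoint every this many epochs when an
#'   output directory is given (0 = only final).
#' @param weights a [loss_weights()].
#' @param gen a [generator_config()].
#' @param disc a [discriminator_config()].
#' @param gen_adv_mode generator adversarial form, `"non_saturating"`
#'   (default, standard practice) or `"saturating"` (the printed objective).
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 1L, epochs = 5000L, input_size = 512L,
                         seed = 1L, checkpoint_every = 0L,
                         weights = loss_weights(),
                         gen = generator_config(),
                         disc = discriminator_config(input_size = input_size),
                         gen_adv_mode = "non_saturating") {
  stopifnot(lr >= 0, batch_size >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Desk-scale training preset
#'
#' 64x64 inputs, narrow widths (6), one HFS module, 10 epochs: the published
#' optimizer settings at a size a single CPU can train in minutes (width was
#' set by the CPU-time budget of the smoke protocol, not by its outcome).
#' Used by the smoke tests.
#'
#' @param ... overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  args <- list(...)
  defaults <- list(
    epochs = 10L, input_size = 64L,
    gen = generator_config(base_width = 6L, n_hfs = 1L),
    disc = discriminator_config(input_size = 64L, base_width = 6L))
  defaults[names(args)] <- args
  do.call(train_config, defaults)
}

#' Xavier-uniform weight initialization
#'
#' Every convolution/dense weight is drawn uniformly in
#' `c(-1, 1) * sqrt(6 / (fan_in + fan_out))`; biases and normalization shifts
#' are set to zero, normalization scales to one. Reproducible given `seed`.
#'
#' @param module any layer/module tree (generator, discriminator bank, ...).
#' @param seed optional integer seed.
#' @return the module, invisibly (parameters are updated in place).
#' @export
init_weights <- function(module, seed = NULL) {
  params <- nn_params(module)
  local_seed(seed, {
    for (nm in names(params)) {
      p <- params[[nm]]
      v <- p$value
      d <- dim(v)
      if (!is.null(d) && length(d) == 4L) {
        b <- xavier_bound(d[1] * d[2] * d[3], d[1] * d[2] * d[4])
        p$value <- array(runif(length(v), -b, b), dim = d)
      } else if (!is.null(d) && length(d) == 2L) {
        b <- xavier_bound(d[2], d[1])
        p$value <- matrix(runif(length(v), -b, b), d[1], d[2])
      } else if (grepl("\\.gamma$", nm)) {
        p$value <- rep(1, length(v))
      } else {
        p$value <- numeric(length(v))
      }
      p$grad <- NULL
      p$adam_m <- NULL
      p$adam_v <- NULL
    }
  })
  invisible(module)
}

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$params <- params
  o$lr <- lr; o$b1 <- beta1; o$b2 <- beta2; o$eps <- eps
  o$t <- 0L
  class(o) <- "adam_opt"
  o
}

adam_step <- function(o) {
  o$t <- o$t + 1L
  bc1 <- 1 - o$b1^o$t
  bc2 <- 1 - o$b2^o$t
  for (p in o$params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$adam_m)) {
      p$adam_m <- g * 0
      p$adam_v <- g * 0
    }
    p$adam_m <- o$b1 * p$adam_m + (1 - o$b1) * g
    p$adam_v <- o$b2 * p$adam_v + (1 - o$b2) * g * g
    p$value <- p$value -
      o$lr * (p$adam_m / bc1) / (sqrt(p$adam_v / bc2) + o$eps)
  }
  invisible(o)
}

#' Assemble the full translation model
#'
#' @param cfg a [train_config()].
#' @return list of class `aac_cyclegan`: generators `G` (low -> standard) and
#'   `F` (standard -> low), discriminator banks `D_Y` (judges standard-dose)
#'   and `D_X` (judges low-dose).
#' @export
build_cyclegan <- function(cfg) {
  m <- list(G = build_generator(cfg$gen), F = build_generator(cfg$gen),
            D_X = build_discriminator_bank(cfg$disc),
            D_Y = build_discriminator_bank(cfg$disc), cfg = cfg)
  class(m) <- "aac_cyclegan"
  init_weights(m, seed = cfg$seed)
  m
}

cheap_hash <- function(obj) {
  sprintf("%08x", as.integer(cpp_crc32(serialize(obj, NULL, version = 2L)) %%
                               .Machine$integer.max))
}

# multiscale inputs as tape nodes (for the generator update), crop origins
# drawn from the current RNG stream
multiscale_nodes <- function(tape, node, cfg) {
  d <- dim(node_value(node))
  n <- d[1]
  out <- vector("list", cfg$n_scales)
  for (i in seq_len(cfg$n_scales)) {
    s <- as.integer(n / 2^(i - 1L))
    if (i == 1L) {
      out[[i]] <- node
    } else if (cfg$input_mode == "random_crop") {
      r0 <- sample.int(n - s + 1L, 1L)
      c0 <- sample.int(d[2] - s + 1L, 1L)
      out[[i]] <- ag_crop(tape, node, r0, c0, s, s)
    } else {
      out[[i]] <- ag_blurpool(tape, out[[i - 1L]],
                              make_blur_kernel(cfg$blur_size), 2L)
    }
  }
  out
}

# discriminator-side objective of one direction as a tape node
adv_obj_node <- function(tape, bank, real_mat, fake_mat, eps = LOG_EPS) {
  cfg <- bank$cfg
  reals <- make_multiscale_inputs(real_mat, cfg)
  fakes <- make_multiscale_inputs(fake_mat, cfg)
  terms <- vector("list", cfg$n_scales)
  for (i in seq_len(cfg$n_scales)) {
    sr <- d_forward(bank$scales[[i]], as_feature_array(reals[[i]]), tape,
                    train = TRUE, trainable = TRUE)
    sf <- d_forward(bank$scales[[i]], as_feature_array(fakes[[i]]), tape,
                    train = TRUE, trainable = TRUE)
    t1 <- ag_mean(tape, ag_log(tape, ag_clamp(tape, sr, eps, 1 - eps)))
    t2 <- ag_mean(tape, ag_log(tape, ag_clamp(tape, ag_sub(tape, 1, sf),
                                              eps, 1 - eps)))
    terms[[i]] <- ag_add(tape, t1, t2)
  }
  acc <- terms[[1]]
  for (i in seq_len(cfg$n_scales)[-1]) acc <- ag_add(tape, acc, terms[[i]])
  ag_smul(tape, acc, 1 / cfg$n_scales)
}

# generator-side adversarial node for one direction
gen_adv_node <- function(tape, bank, fake_node, mode, eps = LOG_EPS) {
  cfg <- bank$cfg
  crops <- multiscale_nodes(tape, fake_node, cfg)
  terms <- vector("list", cfg$n_scales)
  for (i in seq_len(cfg$n_scales)) {
    s <- d_forward(bank$scales[[i]], crops[[i]], tape, train = TRUE,
                   trainable = FALSE)
    terms[[i]] <- if (mode == "saturating")
      ag_mean(tape, ag_log(tape, ag_clamp(tape, ag_sub(tape, 1, s),
                                          eps, 1 - eps)))
    else
      ag_smul(tape, ag_mean(tape, ag_log(tape, ag_clamp(tape, s, eps,
                                                        1 - eps))), -1)
  }
  acc <- terms[[1]]
  for (i in seq_len(cfg$n_scales)[-1]) acc <- ag_add(tape, acc, terms[[i]])
  ag_smul(tape, acc, 1 / cfg$n_scales)
}

l1_node <- function(tape, a, b) ag_mean(tape, ag_abs(tape, ag_sub(tape, a, b)))

#' One optimizer step on an unpaired image pair
#'
#' Discriminators first (all scales, both directions, on detached fakes),
#' then both generators jointly under the weighted objective. The loss
#' breakdown identity `total = lambda_adv*(adv_G+adv_F) + lambda_cyc*cyc +
#' lambda_idt*idt` is asserted against the value actually backpropagated.
#'
#' @param state training state from [fit()]/[init_train_state()].
#' @param x,y normalized pixel matrices (low-dose, standard-dose).
#' @return the [joint_loss()] breakdown of the generator update.
#' @export
train_step <- function(state, x, y) {
  model <- state$model
  cfg <- model$cfg
  wts <- cfg$weights
  xa <- array(x, dim = c(dim(x), 1L))
  ya <- array(y, dim = c(dim(y), 1L))

  # -- discriminator update (fakes detached: plain eager forwards) ----------
  fake_y_det <- g_forward(model$G, xa, NULL, train = TRUE)
  fake_x_det <- g_forward(model$F, ya, NULL, train = TRUE)
  d_params <- c(nn_params(model$D_X), nn_params(model$D_Y))
  zero_grads(d_params)
  tape_d <- ag_tape()
  obj_y <- adv_obj_node(tape_d, model$D_Y, y,
                        matrix(fake_y_det, nrow(y), ncol(y)))
  obj_x <- adv_obj_node(tape_d, model$D_X, x,
                        matrix(fake_x_det, nrow(x), ncol(x)))
  d_loss <- ag_smul(tape_d, ag_add(tape_d, obj_y, obj_x), -1)
  if (!is.finite(node_value(d_loss)))
    stop("train_step: discriminator loss is not finite")
  ag_backward(tape_d, d_loss)
  adam_step(state$opt_d)
  zero_grads(d_params)

  # -- generator update ------------------------------------------------------
  g_params <- c(nn_params(model$G), nn_params(model$F))
  zero_grads(g_params)
  tape <- ag_tape()
  xn <- ag_leaf(tape, xa)
  yn <- ag_leaf(tape, ya)
  fake_y <- g_forward(model$G, xn, tape, train = TRUE, trainable = TRUE)
  fake_x <- g_forward(model$F, yn, tape, train = TRUE, trainable = TRUE)
  rec_x <- g_forward(model$F, fake_y, tape, train = TRUE, trainable = TRUE)
  rec_y <- g_forward(model$G, fake_x, tape, train = TRUE, trainable = TRUE)
  idt_y <- g_forward(model$G, yn, tape, train = TRUE, trainable = TRUE)
  idt_x <- g_forward(model$F, xn, tape, train = TRUE, trainable = TRUE)

  adv_g <- gen_adv_node(tape, model$D_Y, fake_y, cfg$gen_adv_mode)
  adv_f <- gen_adv_node(tape, model$D_X, fake_x, cfg$gen_adv_mode)
  cyc <- ag_add(tape, l1_node(tape, rec_y, yn), l1_node(tape, rec_x, xn))
  idt <- ag_add(tape, l1_node(tape, idt_y, yn), l1_node(tape, idt_x, xn))
  total <- ag_add(tape,
                  ag_smul(tape, ag_add(tape, adv_g, adv_f), wts$lambda_adv),
                  ag_add(tape, ag_smul(tape, cyc, wts$lambda_cyc),
                         ag_smul(tape, idt, wts$lambda_idt)))
  breakdown <- joint_loss(list(adv_G = node_value(adv_g),
                               adv_F = node_value(adv_f),
                               cyc = node_value(cyc),
                               idt = node_value(idt),
                               d_loss = node_value(d_loss)), wts)
  if (abs(breakdown$total - node_value(total)) > 1e-9 * max(1, abs(breakdown$total)))
    stop("train_step: loss breakdown identity violated")
  ag_backward(tape, total)
  adam_step(state$opt_g)
  zero_grads(g_params)
  state$step <- state$step + 1L
  breakdown
}

#' Initialize a training state (model + optimizers)
#'
#' @param cfg a [train_config()].
#' @param model optional pre-built [build_cyclegan()] model.
#' @export
init_train_state <- function(cfg, model = NULL) {
  if (is.null(model)) model <- build_cyclegan(cfg)
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$opt_g <- adam_init(c(nn_params(model$G), nn_params(model$F)), cfg$lr,
                        cfg$beta1, cfg$beta2)
  st$opt_d <- adam_init(c(nn_params(model$D_X), nn_params(model$D_Y)),
                        cfg$lr, cfg$beta1, cfg$beta2)
  st$step <- 0L
  st$epoch <- 0L
  class(st) <- "train_state"
  st
}

#' Train on an unpaired dataset
#'
#' Epochs iterate `max(n_low, n_std)` steps; each domain is shuffled
#' independently every epoch and the shorter list wraps around, so the
#' pairing of low/standard slices within a step is arbitrary (unpaired).
#' Source-id disjointness of the two training domains is asserted, and the
#' paired evaluation set (if present in `dataset`) is never touched.
#'
#' @param dataset list with `low` and `std` lists of [ct_image()] (as from
#'   [make_unpaired_dataset()]).
#' @param cfg a [train_config()].
#' @param out_dir optional directory for the JSONL loss log and checkpoints.
#' @param state optional training state to resume from.
#' @return the final `train_state`, with `$loss_log` (data.frame, one row per
#'   step).
#' @export
fit <- function(dataset, cfg, out_dir = NULL, state = NULL) {
  if (!length(dataset$low) || !length(dataset$std))
    stop("fit: empty training dataset")
  ids_low <- vapply(dataset$low, function(im) im$source_id, character(1))
  ids_std <- vapply(dataset$std, function(im) im$source_id, character(1))
  if (length(intersect(ids_low, ids_std)))
    stop("fit: low/standard training sets share source ids (paired data?)")
  if (!is.null(dataset$paired_eval)) {
    ids_pair <- vapply(dataset$paired_eval, function(p) p$clean$source_id,
                       character(1))
    if (length(intersect(ids_pair, c(ids_low, ids_std))))
      stop("fit: paired evaluation set leaks into training")
  }
  xs <- lapply(dataset$low, function(im) minmax_normalize(im)$pixels)
  ys <- lapply(dataset$std, function(im) minmax_normalize(im)$pixels)
  if (is.null(state)) {
    set.seed(cfg$seed)
    state <- init_train_state(cfg)
  }
  n_steps <- max(length(xs), length(ys))
  log_rows <- state$loss_log %||% NULL
  for (ep in seq_len(cfg$epochs)) {
    ix <- rep_len(sample.int(length(xs)), n_steps)
    iy <- rep_len(sample.int(length(ys)), n_steps)
    for (s in seq_len(n_steps)) {
      bd <- train_step(state, xs[[ix[s]]], ys[[iy[s]]])
      log_rows <- rbind(log_rows,
                        data.frame(epoch = state$epoch + 1L, step = state$step,
                                   total = bd$total, adv_G = bd$adv_G,
                                   adv_F = bd$adv_F, cyc = bd$cyc,
                                   idt = bd$idt, d_loss = bd$d_loss))
    }
    state$epoch <- state$epoch + 1L
    if (!is.null(out_dir) && cfg$checkpoint_every > 0 &&
        state$epoch %% cfg$checkpoint_every == 0)
      save_checkpoint(state, file.path(out_dir,
                                       sprintf("ckpt_ep%04d.rds", state$epoch)))
  }
  state$loss_log <- log_rows
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(out_dir, "loss_log.jsonl"), "w")
    for (i in seq_len(nrow(log_rows)))
      writeLines(jsonlite::toJSON(as.list(log_rows[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    close(con)
    save_checkpoint(state, file.path(out_dir, "ckpt_final.rds"))
  }
  state
}

#' Save / load a training checkpoint
#'
#' The checkpoint carries all weights and optimizer state plus the RNG state
#' and a config hash, so a resumed run reproduces the uninterrupted loss
#' trace.
#'
#' @param state a `train_state`.
#' @param path destination `.rds` path.
#' @export
save_checkpoint <- function(state, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  obj <- list(model = state$model, opt_g = state$opt_g, opt_d = state$opt_d,
              step = state$step, epoch = state$epoch,
              loss_log = state$loss_log %||% NULL,
              rng = get0(".Random.seed", globalenv(), inherits = FALSE),
              cfg_hash = cheap_hash(state$model$cfg))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint path to read.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  st <- new.env(parent = emptyenv())
  st$model <- obj$model
  st$opt_g <- obj$opt_g
  st$opt_d <- obj$opt_d
  st$step <- obj$step
  st$epoch <- obj$epoch
  st$loss_log <- obj$loss_log
  if (!is.null(obj$rng)) assign(".Random.seed", obj$rng, envir = globalenv())
  class(st) <- "train_state"
  st
}

#' Denoise a raw CT slice
#'
#' Min-max normalizes the input, runs the low-to-standard generator, and maps
#' the result back onto the input's raw intensity range.
#'
#' @param state a `train_state`, checkpoint, or `aac_cyclegan` model.
#' @param img a raw [ct_image()].
#' @return a raw `generated` [ct_image()] with attribute `checkpoint_hash`.
#' @export
denoise <- function(state, img) {
  model <- if (inherits(state, "aac_cyclegan")) state else state$model
  stopifnot(inherits(model, "aac_cyclegan"), inherits(img, "ct_image"))
  xn <- minmax_normalize(img)
  out <- generator_forward(model$G, xn)
  out <- denormalize(out, xn$norm_min, xn$norm_max)
  attr(out, "checkpoint_hash") <- cheap_hash(model$cfg)
  out
}
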