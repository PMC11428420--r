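ns <- asNamespace("aacdenoise")

tiny_cfg <- function(seed = 1L, lr = 1e-4, epochs = 1L) {
  train_config(lr = lr, epochs = epochs, input_size = 32L, seed = seed,
               gen = generator_config(base_width = 4L, n_hfs = 1L),
               disc = discriminator_config(input_size = 32L, base_width = 4L))
}

tiny_data <- function(n_low = 2L, n_std = 2L, seed = 1L) {
  spec <- phantom_spec(image_size = 32L, n_organs_range = c(1L, 2L))
  make_unpaired_dataset(spec, n_low, n_std, seed = seed, n_paired = 1L)
}

test_that("xavier initialization respects per-layer bounds and zero biases", {
  G <- build_generator(generator_config(base_width = 4L, n_hfs = 1L))
  init_weights(G, seed = 42)
  params <- nn_params(G)
  for (nm in names(params)) {
    v <- params[[nm]]$value
    d <- dim(v)
    if (!is.null(d) && length(d) == 4L) {
      bound <- sqrt(6 / (d[1] * d[2] * d[3] + d[1] * d[2] * d[4]))
      expect_true(all(abs(v) <= bound), info = nm)
      expect_gt(max(abs(v)), 0.5 * bound)  # actually drawn, not degenerate
    } else if (!is.null(d) && length(d) == 2L) {
      bound <- sqrt(6 / (d[1] + d[2]))
      expect_true(all(abs(v) <= bound), info = nm)
    } else if (grepl("\\.gamma$", nm)) {
      expect_true(all(v == 1), info = nm)
    } else {
      expect_true(all(v == 0), info = nm)  # biases and shifts exactly zero
    }
  }
  # seed reproducibility
  G2 <- build_generator(generator_config(base_width = 4L, n_hfs = 1L))
  init_weights(G2, seed = 42)
  p2 <- nn_params(G2)
  for (nm in names(params))
    expect_identical(params[[nm]]$value, p2[[nm]]$value)
})

test_that("zero learning rate makes a training step a weight no-op", {
  ds <- tiny_data()
  cfg <- tiny_cfg(lr = 0)
  set.seed(cfg$seed)
  st <- init_train_state(cfg)
  before <- lapply(c(nn_params(st$model$G), nn_params(st$model$F),
                     nn_params(st$model$D_X), nn_params(st$model$D_Y)),
                   function(p) p$value)
  x <- minmax_normalize(ds$low[[1]])$pixels
  y <- minmax_normalize(ds$std[[1]])$pixels
  bd <- train_step(st, x, y)
  after <- lapply(c(nn_params(st$model$G), nn_params(st$model$F),
                    nn_params(st$model$D_X), nn_params(st$model$D_Y)),
                  function(p) p$value)
  expect_identical(before, after)
  # breakdown identity holds
  expect_equal(bd$total,
               0.1 * (bd$adv_G + bd$adv_F) + 10 * bd$cyc + 2 * bd$idt,
               tolerance = 1e-12)
})

test_that("training is reproducible and bookkeeping counts steps", {
  ds <- tiny_data()
  st1 <- fit(ds, tiny_cfg(seed = 5, epochs = 2L))
  st2 <- fit(ds, tiny_cfg(seed = 5, epochs = 2L))
  expect_equal(st1$loss_log$total, st2$loss_log$total, tolerance = 0)
  # 2 epochs x max(2, 2) steps
  expect_equal(nrow(st1$loss_log), 4L)
  expect_equal(st1$step, 4L)

  ds44 <- tiny_data(4L, 4L)
  st3 <- fit(ds44, tiny_cfg(seed = 5, epochs = 2L))
  expect_equal(nrow(st3$loss_log), 8L)  # 8 generator updates at batch 1
})

test_that("checkpoint resume reproduces the uninterrupted loss trace", {
  ds <- tiny_data()
  full <- fit(ds, tiny_cfg(seed = 9, epochs = 2L))
  dir <- tempfile(); dir.create(dir)
  half <- fit(ds, tiny_cfg(seed = 9, epochs = 1L))
  f <- save_checkpoint(half, file.path(dir, "ck.rds"))
  resumed <- load_checkpoint(f)
  resumed <- fit(ds, tiny_cfg(seed = 9, epochs = 1L), state = resumed)
  expect_equal(resumed$loss_log$total, full$loss_log$total, tolerance = 1e-12)
})

test_that("fit guards the dataset contracts", {
  ds <- tiny_data()
  expect_error(fit(list(low = list(), std = ds$std), tiny_cfg()), "empty")
  leaky <- ds
  leaky$std[[1]]$source_id <- leaky$low[[1]]$source_id
  expect_error(fit(leaky, tiny_cfg()), "source ids")
  leak2 <- ds
  leak2$paired_eval[[1]]$clean$source_id <- ds$low[[1]]$source_id
  expect_error(fit(leak2, tiny_cfg()), "leaks")
})

test_that("denoise maps back to the raw intensity scale", {
  ds <- tiny_data()
  cfg <- tiny_cfg()
  set.seed(1)
  st <- init_train_state(cfg)
  img <- ds$paired_eval[[1]]$low
  out <- denoise(st, img)
  expect_s3_class(out, "ct_image")
  expect_equal(dim(out$pixels), dim(img$pixels))
  expect_false(out$normalized)
  expect_gte(min(out$pixels), min(img$pixels))
  expect_lte(max(out$pixels), max(img$pixels))
  expect_true(all(is.finite(out$pixels)))
  expect_match(attr(out, "checkpoint_hash"), "^[0-9a-f]{8}$")
  flat <- ct_image(matrix(7, 32, 32), "low_dose")
  expect_error(denoise(st, flat), "constant")
})

test_that("loss log is written as JSONL with per-term entries", {
  ds <- tiny_data()
  dir <- tempfile()
  st <- fit(ds, tiny_cfg(seed = 2, epochs = 1L), out_dir = dir)
  lines <- readLines(file.path(dir, "loss_log.jsonl"))
  expect_length(lines, 2L)
  row <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("total", "adv_G", "adv_F", "cyc", "idt", "d_loss") %in%
                    names(row)))
  expect_equal(row$total, st$loss_log$total[1], tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "ckpt_final.rds")))
})
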