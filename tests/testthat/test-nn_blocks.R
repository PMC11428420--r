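ns <- asNamespace("aacdenoise")

test_that("blur kernels are normalized binomial outer products", {
  expect_equal(make_blur_kernel(2), matrix(0.25, 2, 2))
  expect_equal(make_blur_kernel(3),
               outer(c(1, 2, 1), c(1, 2, 1)) / 16)
  for (s in 2:5) {
    k <- make_blur_kernel(s)
    expect_lt(abs(sum(k) - 1), 1e-12)
    expect_true(all(k >= 0))
    # separable: rank 1
    expect_lt(svd(k)$d[2], 1e-14)
  }
  expect_error(make_blur_kernel(6), "size")
})

test_that("blurpool preserves constants, matches the oracle, halves size", {
  ones <- array(1, dim = c(8, 8, 1))
  out <- blurpool(ones)
  expect_equal(dim(out), c(4L, 4L, 1L))
  expect_equal(as.numeric(out), rep(1, 16))

  # unit impulse: sampled positions carry kernel entries
  imp <- array(0, dim = c(9, 9, 1)); imp[5, 5, 1] <- 1
  got <- blurpool(imp, blur_size = 3)
  want <- naive_blurpool(imp, make_blur_kernel(3))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[3, 3, 1], 4 / 16)  # kernel center lands on (5,5)

  set.seed(20)
  for (i in 1:3) {
    x <- array(rnorm(11 * 13 * 2), dim = c(11, 13, 2))
    expect_equal(blurpool(x), naive_blurpool(x, make_blur_kernel(3)),
                 tolerance = 1e-12)
  }
  expect_equal(dim(blurpool(array(0, c(7, 7, 1)))), c(4L, 4L, 1L))
  expect_error(blurpool(array(0, c(2, 2, 1)), blur_size = 3), "smaller")
})

test_that("pixel shuffle is the exact sub-pixel bijection", {
  x <- array(c(1, 2, 3, 4), dim = c(1, 1, 4))
  expect_equal(pixel_shuffle(x, 2)[, , 1],
               matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  set.seed(21)
  xr <- array(rnorm(6 * 6 * 8), dim = c(6, 6, 8))
  expect_identical(pixel_shuffle(xr, 1), xr)
  expect_identical(pixel_unshuffle(pixel_shuffle(xr, 2), 2), xr)
  expect_equal(sort(as.numeric(pixel_shuffle(xr, 2))), sort(as.numeric(xr)))
  expect_error(pixel_shuffle(array(0, c(2, 2, 3)), 2), "divisible")
})

test_that("conv block honors spectral norm and activation contracts", {
  cfg <- block_config(width = 4L)
  set.seed(22)
  x <- array(rnorm(6 * 6 * 3), dim = c(6, 6, 3))
  blk <- ns$new_conv_block(3L, 4L, spectral = TRUE)
  out <- ns$conv_block_forward(blk, x, NULL, train = TRUE)
  expect_equal(dim(out), c(6L, 6L, 4L))

  # spectral norm: leading singular value of normalized weight <= 1 + 1e-3
  for (i in 1:20) invisible(ns$conv_block_forward(blk, x, NULL, train = TRUE))
  wsn <- ns$ag_spectral_norm(NULL, blk$conv$params$w$value, blk$conv,
                             update = FALSE)
  expect_lte(svd(matrix(wsn, 27, 4))$d[1], 1 + 1e-3)

  # zero input through zero-bias affine normalization stays exactly zero
  z <- ns$conv_block_forward(blk, array(0, c(6, 6, 3)), NULL)
  expect_equal(as.numeric(z), rep(0, 6 * 6 * 4))

  # LeakyReLU slope through an identity convolution, no normalization
  idblk <- ns$new_conv_block(1L, 1L, spectral = FALSE, norm = "none",
                             negative_slope = 0.2)
  idblk$conv$params$w$value <- array(c(0, 0, 0, 0, 1, 0, 0, 0, 0),
                                     dim = c(3, 3, 1, 1))
  idblk$conv$params$b$value <- 0
  o <- ns$conv_block_forward(idblk, array(-1, c(4, 4, 1)), NULL)
  expect_equal(as.numeric(o), rep(-0.2, 16))
})

test_that("cSE gate bounds and fixed-weight behavior", {
  set.seed(23)
  x <- array(rnorm(5 * 5 * 4), dim = c(5, 5, 4))
  lay <- ns$new_cse(4L, 2L)
  out <- ns$cse_forward(lay, x, NULL)
  expect_true(all(abs(out) <= abs(x)))
  expect_equal(ns$cse_forward(lay, x * 0, NULL), x * 0)

  # all-zero bottleneck: gate = sigmoid(0) = 0.5 exactly
  lay$fc1$params$w$value[] <- 0; lay$fc1$params$b$value[] <- 0
  lay$fc2$params$w$value[] <- 0; lay$fc2$params$b$value[] <- 0
  expect_equal(ns$cse_forward(lay, x, NULL), x / 2, tolerance = 1e-15)
  expect_error(ns$new_cse(4L, 3L), "divide")
})

test_that("sSE gate is a shared spatial map", {
  set.seed(24)
  x <- array(rnorm(5 * 5 * 3), dim = c(5, 5, 3))
  lay <- ns$new_sse(3L)
  out <- ns$sse_forward(lay, x, NULL)
  # the gate is identical across channels
  gate <- out / x
  expect_equal(gate[, , 1], gate[, , 2], tolerance = 1e-12)
  expect_equal(gate[, , 1], gate[, , 3], tolerance = 1e-12)
  expect_true(all(gate > 0 & gate < 1))

  lay$conv$params$w$value[] <- 0
  lay$conv$params$b$value[] <- 0
  expect_equal(ns$sse_forward(lay, x * 0, NULL), x * 0)
  # saturated gate: large positive bias drives the gate to 1
  lay$conv$params$b$value[] <- 50
  expect_equal(ns$sse_forward(lay, x, NULL), x, tolerance = 1e-12)
})

test_that("scSE selects branches and combines as configured", {
  set.seed(25)
  x <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4))
  cfg <- block_config(4L, scse_reduction = 2L)
  lay <- ns$new_scse(4L, cfg)
  # branch selection equals running the branch alone
  lay_c <- ns$new_scse(4L, block_config(4L, scse_mode = "cse",
                                        scse_reduction = 2L))
  lay_c$cse <- lay$cse
  expect_equal(ns$scse_forward(lay_c, x, NULL),
               ns$cse_forward(lay$cse, x, NULL))
  lay_s <- ns$new_scse(4L, block_config(4L, scse_mode = "sse"))
  lay_s$sse <- lay$sse
  expect_equal(ns$scse_forward(lay_s, x, NULL),
               ns$sse_forward(lay$sse, x, NULL))

  # max of identical branch outputs equals either branch: zero both gates
  # so each branch is exactly x/2
  lay2 <- ns$new_scse(4L, cfg)
  for (p in nn_params(lay2)) p$value[] <- 0
  expect_equal(ns$scse_forward(lay2, x, NULL), x / 2, tolerance = 1e-15)
  expect_equal(ns$scse_forward(lay2, x, NULL),
               ns$cse_forward(lay2$cse, x, NULL))

  # max >= multiply elementwise on non-negative normalized-scale inputs
  # (both gated branches land in [0, 1), where a*b <= max(a, b))
  xp <- array(runif(6 * 6 * 4), dim = c(6, 6, 4))
  lmax <- ns$new_scse(4L, block_config(4L, scse_combine = "max",
                                       scse_reduction = 2L))
  lmul <- ns$new_scse(4L, block_config(4L, scse_combine = "multiply",
                                       scse_reduction = 2L))
  lmul$cse <- lmax$cse; lmul$sse <- lmax$sse
  expect_true(all(ns$scse_forward(lmax, xp, NULL) >=
                    ns$scse_forward(lmul, xp, NULL) - 1e-12))
})

test_that("functional wrappers build default layers and keep shapes", {
  set.seed(29)
  x <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  cfg <- block_config(4L, scse_reduction = 2L)
  expect_equal(dim(conv_block(x, cfg)), c(8L, 8L, 4L))
  expect_equal(dim(cse_gate(x, reduction = 2L)), dim(x))
  expect_equal(dim(sse_gate(x)), dim(x))
  expect_equal(dim(scse_block(x, cfg)), dim(x))
  r <- residual_block(x, cfg)
  expect_named(r, c("trunk", "residual_feature"))
  expect_equal(r$trunk - x, r$residual_feature, tolerance = 1e-15)
  expect_equal(dim(hfs_aggregate(x, cfg)), dim(x))
})

test_that("residual block returns trunk and branch consistently", {
  set.seed(26)
  cfg <- block_config(4L, scse_reduction = 2L)
  x <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4))
  blk <- ns$new_residual_block(4L, cfg)
  r <- ns$residual_forward(blk, x, NULL)
  expect_equal(dim(r$trunk), dim(x))
  expect_equal(dim(r$residual), dim(x))
  expect_equal(r$trunk - x, r$residual, tolerance = 1e-15)

  # zero branch weights: identity trunk
  for (p in nn_params(blk)) p$value[] <- 0
  blk$cb$norm$params$gamma$value[] <- 1
  r0 <- ns$residual_forward(blk, x, NULL)
  expect_equal(r0$trunk, x)
  expect_equal(as.numeric(r0$residual), rep(0, length(x)))
})

test_that("HFS aggregation is identity at zero fuse and matches an oracle", {
  set.seed(27)
  cfg <- block_config(4L, scse_reduction = 2L)
  x <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  mod <- ns$new_hfs(4L, cfg)
  mod$fuse$params$w$value[] <- 0
  mod$fuse$params$b$value[] <- 0
  expect_equal(ns$hfs_forward(mod, x, NULL), x, tolerance = 1e-15)

  # straight-line recomputation with plain R arithmetic
  mod2 <- ns$new_hfs(4L, cfg)
  for (p in nn_params(mod2)) p$value <- p$value * 0.3
  got <- ns$hfs_forward(mod2, x, NULL)
  expect_equal(dim(got), dim(x))

  oracle_spectral <- function(wv, u) {
    M <- matrix(wv, nrow = prod(dim(wv)[1:3]), ncol = dim(wv)[4])
    v <- as.numeric(M %*% u); v <- v / sqrt(sum(v^2))
    u2 <- as.numeric(crossprod(M, v)); u2 <- u2 / sqrt(sum(u2^2))
    wv / sum(u2 * crossprod(M, v))
  }
  oracle_in <- function(h, gamma, beta, eps = 1e-5) {
    d <- dim(h)
    hm <- matrix(h, ncol = d[3])
    mu <- colMeans(hm); va <- colSums(sweep(hm, 2, mu)^2) / (d[1] * d[2])
    hh <- sweep(sweep(hm, 2, mu), 2, sqrt(va + eps), `/`)
    array(sweep(sweep(hh, 2, gamma, `*`), 2, beta, `+`), dim = d)
  }
  oracle_block <- function(blk, h) {
    w1 <- oracle_spectral(blk$cb$conv$params$w$value, blk$cb$conv$sn_u)
    a <- naive_conv2d(h, w1, blk$cb$conv$params$b$value, pad = 1L)
    a <- oracle_in(a, blk$cb$norm$params$gamma$value,
                   blk$cb$norm$params$beta$value)
    a <- ifelse(a >= 0, a, 0.2 * a); dim(a) <- dim(h)
    w2 <- oracle_spectral(blk$conv2$params$w$value, blk$conv2$sn_u)
    a <- naive_conv2d(a, w2, blk$conv2$params$b$value, pad = 1L)
    # scSE, combine = max
    s <- colMeans(matrix(a, ncol = dim(a)[3]))
    s <- pmax(blk$scse$cse$fc1$params$w$value %*% s +
                blk$scse$cse$fc1$params$b$value, 0)
    s <- 1 / (1 + exp(-(blk$scse$cse$fc2$params$w$value %*% s +
                          blk$scse$cse$fc2$params$b$value)))
    ac <- sweep(matrix(a, ncol = dim(a)[3]), 2, as.numeric(s), `*`)
    ac <- array(ac, dim = dim(a))
    g <- naive_conv2d(a, blk$scse$sse$conv$params$w$value,
                      blk$scse$sse$conv$params$b$value, pad = 0L)
    g <- 1 / (1 + exp(-g[, , 1]))
    as_ <- a * as.vector(g)
    dim(as_) <- dim(a)
    res <- pmax(ac, as_)
    list(trunk = h + res, residual = res)
  }
  h <- x
  residuals <- list()
  for (i in 1:3) {
    # freeze power-iteration state to the stored u by one eval-mode pass
    r <- oracle_block(mod2$blocks[[i]], h)
    residuals[[i]] <- r$residual
    h <- r$trunk
  }
  cat4 <- array(c(residuals[[1]], residuals[[2]], residuals[[3]], h),
                dim = c(8, 8, 16))
  fused <- naive_conv2d(cat4, mod2$fuse$params$w$value,
                        mod2$fuse$params$b$value, pad = 0L)
  want <- x + fused
  expect_equal(got, want, tolerance = 1e-6)
})
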