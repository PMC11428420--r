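# Gradient correctness of the tape against central finite differences, and
# the C++ convolution against a plain-R dense oracle.  These back the whole
# training loop, so they are checked tightly.

ns <- asNamespace("aacdenoise")

tape_scalar <- function(build) {
  t <- ns$ag_tape()
  out <- build(t)
  ns$ag_backward(t, out$loss)
  out
}

test_that("conv2d forward equals the dense R oracle", {
  set.seed(10)
  x <- array(rnorm(7 * 8 * 2), dim = c(7, 8, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
  b <- rnorm(3)
  for (mode in c("zero", "reflect")) for (stride in c(1L, 2L)) {
    got <- ns$ag_conv2d(NULL, x, w, b, stride = stride, pad = 1L,
                        pad_mode = mode)
    want <- naive_conv2d(x, w, b, stride = stride, pad = 1L, mode = mode)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # asymmetric rows-only zero padding (the discriminator's final stage)
  got <- ns$ag_conv2d(NULL, x, w, b, pad = c(1L, 1L, 0L, 0L))
  want <- naive_conv2d(x, w, b, pad = c(1L, 1L, 0L, 0L))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("conv2d gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(5 * 6 * 2), dim = c(5, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 2) * 0.4, dim = c(3, 3, 2, 2))
  b <- rnorm(2)
  for (mode in c("zero", "reflect")) {
    run <- function(xv, wv, bv) {
      tape_scalar(function(t) {
        xn <- ns$ag_leaf(t, xv, TRUE)
        wn <- ns$ag_leaf(t, wv, TRUE)
        bn <- ns$ag_leaf(t, bv, TRUE)
        o <- ns$ag_conv2d(t, xn, wn, bn, pad = 1L, pad_mode = mode)
        list(loss = ns$ag_mean(t, ns$ag_mul(t, o, o)),
             xn = xn, wn = wn, bn = bn)
      })
    }
    r <- run(x, w, b)
    val <- function(...) ns$node_value(run(...)$loss)
    expect_lt(rel_err(r$xn$grad, num_grad(function(v) val(v, w, b), x)), 1e-6)
    expect_lt(rel_err(r$wn$grad, num_grad(function(v) val(x, v, b), w)), 1e-6)
    expect_lt(rel_err(r$bn$grad, num_grad(function(v) val(x, w, v), b)), 1e-6)
  }
})

test_that("blurpool, pixel shuffle and crop gradients match finite differences", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 2), dim = c(6, 6, 2))
  k <- make_blur_kernel(3)
  run_bp <- function(xv) tape_scalar(function(t) {
    xn <- ns$ag_leaf(t, xv, TRUE)
    o <- ns$ag_blurpool(t, xn, k, 2L)
    list(loss = ns$ag_mean(t, ns$ag_mul(t, o, o)), xn = xn)
  })
  r <- run_bp(x)
  expect_lt(rel_err(r$xn$grad,
                    num_grad(function(v) ns$node_value(run_bp(v)$loss), x)),
            1e-6)

  x8 <- array(rnorm(4 * 4 * 8), dim = c(4, 4, 8))
  run_ps <- function(xv) tape_scalar(function(t) {
    xn <- ns$ag_leaf(t, xv, TRUE)
    o <- ns$ag_pixel_shuffle(t, xn, 2L)
    o <- ns$ag_crop(t, o, 2L, 3L, 5L, 4L)
    list(loss = ns$ag_mean(t, ns$ag_mul(t, o, o)), xn = xn)
  })
  r <- run_ps(x8)
  expect_lt(rel_err(r$xn$grad,
                    num_grad(function(v) ns$node_value(run_ps(v)$loss), x8)),
            1e-6)
})

test_that("normalization and gate op gradients match finite differences", {
  set.seed(13)
  x <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  g0 <- rnorm(3); b0 <- rnorm(3)
  run_in <- function(xv, gv, bv) tape_scalar(function(t) {
    xn <- ns$ag_leaf(t, xv, TRUE)
    gn <- ns$ag_leaf(t, gv, TRUE)
    bn <- ns$ag_leaf(t, bv, TRUE)
    o <- ns$ag_instance_norm(t, xn, gn, bn)
    list(loss = ns$ag_mean(t, ns$ag_mul(t, o, o)), xn = xn, gn = gn, bn = bn)
  })
  r <- run_in(x, g0, b0)
  val <- function(...) ns$node_value(run_in(...)$loss)
  expect_lt(rel_err(r$xn$grad, num_grad(function(v) val(v, g0, b0), x)), 1e-5)
  expect_lt(rel_err(r$gn$grad, num_grad(function(v) val(x, v, b0), g0)), 1e-6)
  expect_lt(rel_err(r$bn$grad, num_grad(function(v) val(x, g0, v), b0)), 1e-6)

  # channel gate chain (global pool -> dense -> sigmoid -> scale)
  wd <- matrix(rnorm(9), 3, 3)
  bd <- rnorm(3)
  run_g <- function(xv, wv) tape_scalar(function(t) {
    xn <- ns$ag_leaf(t, xv, TRUE)
    wn <- ns$ag_leaf(t, wv, TRUE)
    s <- ns$ag_sigmoid(t, ns$ag_dense(t, ns$ag_gap(t, xn), wn, bd))
    o <- ns$ag_scale_channels(t, xn, s)
    list(loss = ns$ag_mean(t, ns$ag_abs(t, o)), xn = xn, wn = wn)
  })
  r <- run_g(x, wd)
  gx <- num_grad(function(v) ns$node_value(run_g(v, wd)$loss), x)
  expect_lt(rel_err(r$xn$grad, gx), 1e-5)
})

test_that("spectral normalization matches an SVD oracle and its gradient", {
  set.seed(15)
  w <- array(rnorm(3 * 3 * 2 * 4) * 0.5, dim = c(3, 3, 2, 4))
  lay <- new.env(); lay$sn_u <- rep(0.5, 4)
  for (i in 1:100) invisible(ns$ag_spectral_norm(NULL, w, lay, update = TRUE))
  sv <- svd(matrix(w, nrow = 18, ncol = 4))$d[1]
  expect_lt(abs(lay$sn_sigma - sv) / sv, 1e-6)
  wsn <- ns$ag_spectral_norm(NULL, w, lay, update = FALSE)
  expect_lte(svd(matrix(wsn, 18, 4))$d[1], 1 + 1e-3)

  run_sn <- function(wv) tape_scalar(function(t) {
    wn <- ns$ag_leaf(t, wv, TRUE)
    o <- ns$ag_spectral_norm(t, wn, lay, update = FALSE)
    list(loss = ns$ag_mean(t, ns$ag_mul(t, o, o)), wn = wn)
  })
  r <- run_sn(w)
  expect_lt(rel_err(r$wn$grad,
                    num_grad(function(v) ns$node_value(run_sn(v)$loss), w)),
            1e-4)
})

test_that("shared parameters accumulate gradients across uses", {
  # f(w) = mean(w*x) + mean(w*w) uses the same leaf twice
  set.seed(16)
  w <- array(rnorm(4), dim = c(2, 2, 1))
  x <- array(rnorm(4), dim = c(2, 2, 1))
  t <- ns$ag_tape()
  wn <- ns$ag_leaf(t, w, TRUE)
  s <- ns$ag_add(t, ns$ag_mean(t, ns$ag_mul(t, wn, x)),
                 ns$ag_mean(t, ns$ag_mul(t, wn, wn)))
  ns$ag_backward(t, s)
  expect_equal(wn$grad, x / 4 + 2 * w / 4, tolerance = 1e-12)
})
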