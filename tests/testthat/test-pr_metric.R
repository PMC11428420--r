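test_that("knn radii match brute-force distances", {
  pts <- matrix(c(0, 1, 3), ncol = 1)
  expect_equal(unname(knn_radius(pts, 1)), c(1, 1, 2))
  dup <- matrix(rep(c(0, 5), each = 2), ncol = 1)
  expect_equal(unname(knn_radius(dup, 1)), rep(0, 4))
  set.seed(50)
  m <- matrix(rnorm(30 * 4), 30, 4)
  r1 <- knn_radius(m, 1); r3 <- knn_radius(m, 3); r5 <- knn_radius(m, 5)
  expect_true(all(r3 >= r1) && all(r5 >= r3))
  expect_error(knn_radius(m, 30), "smaller")
})

test_that("manifold membership and the metric match the O(n^2) oracle", {
  set.seed(51)
  r <- matrix(rnorm(20 * 2), 20, 2)
  q <- matrix(rnorm(10 * 2), 10, 2)
  for (k in c(1, 3, 5)) {
    rad <- knn_radius(r, k)
    for (i in seq_len(nrow(q))) {
      want <- as.integer(any(sqrt(colSums((t(r) - q[i, ])^2)) <= rad))
      expect_identical(in_manifold(q[i, ], r, k), want)
    }
  }
  expect_equal(in_manifold(r[4, ], r, 3), 1L)
  far <- r[1, ] + 1e6
  expect_equal(in_manifold(far, r, 3), 0L)

  # exact agreement with brute force on a larger problem
  set.seed(52)
  A <- matrix(rnorm(120 * 16), 120, 16)
  B <- matrix(rnorm(80 * 16), 80, 16) * 1.3 + 0.2
  for (k in c(1, 3, 5)) {
    want <- brute_pr(A, B, k)
    expect_identical(improved_precision(A, B, k), want$precision)
    expect_identical(improved_recall(A, B, k), want$recall)
  }
})

test_that("metric invariants: self-identity, separation, duality, monotonicity", {
  set.seed(53)
  A <- matrix(rnorm(40 * 8), 40, 8)
  expect_equal(improved_precision(A, A, 3), 1.0)
  expect_equal(improved_recall(A, A, 3), 1.0)

  B <- A + 1000  # two far-separated clusters
  expect_equal(improved_precision(A, B, 3), 0.0)
  expect_equal(improved_recall(A, B, 3), 0.0)

  C <- matrix(rnorm(35 * 8), 35, 8) * 1.4
  expect_identical(improved_precision(A, C, 3), improved_recall(C, A, 3))
  expect_identical(improved_precision(C, A, 4), improved_recall(A, C, 4))

  p_by_k <- vapply(c(1, 2, 4, 8), function(k) improved_precision(A, C, k),
                   numeric(1))
  expect_true(all(diff(p_by_k) >= 0))

  # row-permutation invariance
  expect_identical(improved_precision(A[sample(40), ], C[sample(35), ], 3),
                   improved_precision(A, C, 3))
})

test_that("feature extraction is deterministic and discriminative", {
  set.seed(54)
  ims <- lapply(1:6, function(i) matrix(runif(16 * 16), 16, 16))
  f1 <- extract_features(ims, "random_projection", d = 8L)
  f2 <- extract_features(ims, "random_projection", d = 8L)
  expect_identical(f1$matrix, f2$matrix)
  expect_equal(dim(f1$matrix), c(6L, 8L))

  # constant offset shifts the mean component of patch_stats
  a <- matrix(runif(64), 8, 8)
  fs <- extract_features(list(a, a + 0.3), "patch_stats")
  expect_equal(fs$matrix[2, 1] - fs$matrix[1, 1], 0.3, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fs$matrix[1, ], fs$matrix[2, ])))

  expect_error(extract_features(ims, "inception_mid"), "offline")
  expect_error(extract_features(list(), "patch_stats"), "empty")
})

test_that("evaluate_pr protocol: self-comparison, psi semantics, outliers", {
  spec <- test_phantom_spec()
  imgs <- lapply(1:6, function(i)
    apply_dose_noise(generate_clean_phantom(spec, seed = i)$image, 150, spec,
                     seed = i))
  self <- evaluate_pr(imgs, imgs, k = 3, patch_size = 16L, n_patches = 3L,
                      seed = 7)
  expect_equal(self$precision, 1.0)
  expect_equal(self$recall, 1.0)

  other <- lapply(7:12, function(i)
    apply_dose_noise(generate_clean_phantom(spec, seed = i)$image, 30, spec,
                     seed = i))
  r_null <- evaluate_pr(imgs, other, k = 3, patch_size = 16L, n_patches = 3L,
                        seed = 9, truncation_psi = NULL)
  r_one <- evaluate_pr(imgs, other, k = 3, patch_size = 16L, n_patches = 3L,
                       seed = 9, truncation_psi = 1.0)
  expect_identical(r_null$precision, r_one$precision)
  expect_identical(r_null$recall, r_one$recall)

  # planted far outliers among generated features: tightening psi filters
  # them first, so precision is non-decreasing as psi decreases
  set.seed(55)
  R <- matrix(rnorm(60 * 8), 60, 8)
  G0 <- rbind(matrix(rnorm(40 * 8, sd = 0.9), 40, 8),
              matrix(rnorm(10 * 8) + 50, 10, 8))
  prec_at <- function(psi) {
    g <- G0
    if (psi < 1) {
      dd <- sqrt(colSums((t(g) - colMeans(R))^2))
      g <- g[dd <= quantile(dd, psi), , drop = FALSE]
    }
    improved_precision(R, g, 3)
  }
  ps <- vapply(c(1, 0.9, 0.8, 0.6), prec_at, numeric(1))
  expect_true(all(diff(ps) >= 0))
})
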