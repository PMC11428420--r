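# ---------------------------------------------------------------------------
# Improved precision and recall for generative models: each feature set's
# support is approximated by the union of k-NN hyperspheres around its
# members (K = 3 in the published protocol); precision is the fraction of
# generated features falling inside the real manifold, recall the fraction
# of real features inside the generated manifold.
# ---------------------------------------------------------------------------

#' Bundle feature vectors
#'
#' @param matrix numeric n x d matrix, one feature vector per row.
#' @param source `"real"` or `"generated"`.
#' @export
feature_set <- function(matrix, source = c("real", "generated")) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop("feature_set: non-finite features")
  structure(list(matrix = matrix, source = source), class = "feature_set")
}

fs_matrix <- function(x) if (inherits(x, "feature_set")) x$matrix else as.matrix(x)

pairwise_dist <- function(a, b) {
  # Euclidean distances, rows of a vs rows of b
  an <- rowSums(a * a); bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Per-point k-NN hypersphere radii
#'
#' `radius[i]` is the Euclidean distance from row i to its k-th nearest
#' neighbor among the *other* rows (self excluded); ties are broken by the
#' sorted distance order.
#'
#' @param phi feature matrix or [feature_set()].
#' @param k neighbor order (default 3); must satisfy `k < n`.
#' @export
knn_radius <- function(phi, k = 3L) {
  m <- fs_matrix(phi)
  n <- nrow(m)
  if (k >= n) stop("knn_radius: k must be smaller than the number of rows")
  d <- pairwise_dist(m, m)
  diag(d) <- Inf
  apply(d, 1L, function(r) sort(r)[k])
}

#' k-NN manifold membership indicator
#'
#' Returns 1 iff `phi` lies within the k-NN hypersphere of at least one row
#' of `Phi` — i.e. `||phi - phi'|| <= ||phi' - NN_k(phi')||` for some
#' `phi' in Phi`; boundary equality counts as inside.
#'
#' @param phi query feature vector.
#' @param Phi reference [feature_set()] or matrix.
#' @param k neighbor order.
#' @param radii optional precomputed [knn_radius()] of `Phi`.
#' @export
in_manifold <- function(phi, Phi, k = 3L, radii = NULL) {
  m <- fs_matrix(Phi)
  if (is.null(radii)) radii <- knn_radius(m, k)
  d <- sqrt(colSums((t(m) - as.numeric(phi))^2))
  as.integer(any(d <= radii))
}

#' Improved precision and recall
#'
#' `improved_precision` = mean over generated features of membership in the
#' real manifold; `improved_recall` = mean over real features of membership
#' in the generated manifold. The two are dual:
#' `improved_precision(A, B, k) == improved_recall(B, A, k)`.
#'
#' @param phi_r real [feature_set()] or matrix.
#' @param phi_g generated [feature_set()] or matrix.
#' @param k neighbor order (published protocol: 3).
#' @export
improved_precision <- function(phi_r, phi_g, k = 3L) {
  r <- fs_matrix(phi_r); g <- fs_matrix(phi_g)
  if (k >= nrow(r)) stop("improved_precision: real set too small for k")
  radii <- knn_radius(r, k)
  d <- pairwise_dist(g, r)                    # n_g x n_r
  mean(apply(sweep(d, 2L, radii, `<=`), 1L, any))
}

#' @rdname improved_precision
#' @export
improved_recall <- function(phi_r, phi_g, k = 3L) {
  improved_precision(phi_g, phi_r, k)
}

#' Extract feature vectors from images or patches
#'
#' Offline extractors are first class so no pretrained weights are needed:
#' `random_projection` projects the flattened pixels through a fixed seeded
#' Gaussian matrix; `patch_stats` computes low-order summary statistics
#' (mean, sd, quantiles, gradient energy). `inception_mid` — the published
#' choice, the middle layers of an ImageNet InceptionV3 — requires pretrained
#' weights that cannot be bundled offline and raises an informative error.
#'
#' @param images list of [ct_image()]s, `ct_patch`es or matrices, all the
#'   same size.
#' @param extractor `"random_projection"`, `"patch_stats"` or
#'   `"inception_mid"`.
#' @param d embedding dimension for `random_projection` (default 32).
#' @param seed seed fixing the projection matrix (default 77; the same seed
#'   must be used for both sets being compared).
#' @param source label stored on the resulting [feature_set()].
#' @export
extract_features <- function(images, extractor = c("random_projection",
                                                   "patch_stats",
                                                   "inception_mid"),
                             d = 32L, seed = 77L, source = "real") {
  extractor <- match.arg(extractor)
  if (!length(images)) stop("extract_features: empty image list")
  mats <- lapply(images, function(im) {
    if (inherits(im, "ct_image")) im$pixels
    else if (inherits(im, "ct_patch")) im$pixels
    else as.matrix(im)
  })
  if (extractor == "inception_mid")
    stop("extract_features: InceptionV3 weights are not available offline; ",
         "use extractor = 'random_projection' or 'patch_stats'")
  if (extractor == "random_projection") {
    p <- length(mats[[1]])
    proj <- local_seed(seed, matrix(rnorm(p * d, sd = 1 / sqrt(d)), p, d))
    feats <- t(vapply(mats, function(m) as.numeric(crossprod(proj,
                                                             as.numeric(m))),
                      numeric(d)))
  } else {
    feats <- t(vapply(mats, function(m) {
      gx <- diff(m); gy <- t(diff(t(m)))
      c(mean(m), stats::sd(m),
        stats::quantile(m, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE),
        mean(abs(gx)), mean(abs(gy)), sqrt(mean(gx^2)))
    }, numeric(10)))
  }
  feature_set(feats, source = source)
}

#' Patch-based precision/recall evaluation protocol
#'
#' From each raw image a scan-cylinder ROI mask is computed, the slice is
#' min-max normalized, and `n_patches` ROI-covered patches are sampled;
#' features are extracted from all patches of each set and the improved
#' precision/recall computed. With `truncation_psi < 1` the generated
#' features are first filtered to those within the psi-quantile of distance
#' to the real feature mean (a quantile-filter reading of the truncation
#' trick for translation models, where no latent exists to truncate);
#' `truncation_psi = 1` keeps every feature and `NULL` disables the filter
#' entirely (identical results).
#'
#' @param real_images,gen_images lists of raw [ct_image()]s.
#' @param k neighbor order (default 3).
#' @param patch_size patch side (default 128 at training resolution; use 16
#'   or 32 for 64-pixel desk images).
#' @param n_patches patches sampled per image (default 4).
#' @param extractor feature extractor passed to [extract_features()].
#' @param truncation_psi `NULL` (off), or a quantile in (0, 1].
#' @param min_foreground_frac ROI coverage threshold for patches.
#' @param seed sampling reproducibility.
#' @return list of class `pr_result`: `precision`, `recall`, `k`, `n_real`,
#'   `n_gen`, `truncation_psi`.
#' @export
evaluate_pr <- function(real_images, gen_images, k = 3L, patch_size = 128L,
                        n_patches = 4L,
                        extractor = "random_projection",
                        truncation_psi = NULL, min_foreground_frac = 0.5,
                        seed = NULL) {
  # patch sampling is seeded per image position so that identical image
  # lists yield identical patch sets (the self-comparison sanity contract)
  collect <- function(images, base) {
    out <- list()
    for (i in seq_along(images)) {
      im <- images[[i]]
      mask <- compute_roi_mask(im)
      nim <- minmax_normalize(im)
      local_seed(base + i, {
        for (j in seq_len(n_patches))
          out[[length(out) + 1L]] <-
            sample_patch(nim, mask, size = patch_size,
                         min_foreground_frac = min_foreground_frac)
      })
    }
    out
  }
  local_seed(seed, {
    base <- sample.int(2^30, 1L)
    pr_patches <- collect(real_images, base)
    pg_patches <- collect(gen_images, base)
    fr <- extract_features(pr_patches, extractor, source = "real")
    fg <- extract_features(pg_patches, extractor, source = "generated")
    gmat <- fg$matrix
    if (!is.null(truncation_psi)) {
      stopifnot(truncation_psi > 0, truncation_psi <= 1)
      if (truncation_psi < 1) {
        center <- colMeans(fr$matrix)
        dists <- sqrt(colSums((t(gmat) - center)^2))
        keep <- dists <= stats::quantile(dists, truncation_psi, names = FALSE)
        gmat <- gmat[keep, , drop = FALSE]
        if (nrow(gmat) <= k)
          stop("evaluate_pr: too few generated features survive truncation")
      }
    }
    structure(list(precision = improved_precision(fr$matrix, gmat, k),
                   recall = improved_recall(fr$matrix, gmat, k),
                   k = k, n_real = nrow(fr$matrix), n_gen = nrow(gmat),
                   truncation_psi = truncation_psi),
              class = "pr_result")
  })
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  (k=%d, n_real=%d, n_gen=%d%s)\n",
              x$precision, x$recall, x$k, x$n_real, x$n_gen,
              if (is.null(x$truncation_psi)) ""
              else sprintf(", psi=%.2f", x$truncation_psi)))
  invisible(x)
}
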