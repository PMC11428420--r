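# ---------------------------------------------------------------------------
# CT slice container, min-max normalization, scan-cylinder ROI masking and
# ROI-restricted random patch sampling.
# ---------------------------------------------------------------------------

#' A single 2D CT slice
#'
#' @param pixels numeric matrix (height x width), HU-like intensities or
#'   normalized \[0, 1\] values.
#' @param domain_tag one of `"low_dose"`, `"standard_dose"`, `"generated"`,
#'   `"clean_reference"`.
#' @param normalized logical; if `TRUE` every pixel must lie in \[0, 1\].
#' @param background_value raw intensity assigned outside the scan cylinder
#'   (default -2048).
#' @param source_id opaque identifier of the originating scan/phantom.
#' @param norm_min,norm_max original intensity range retained after
#'   normalization (for denormalization); `NA` when raw.
#' @return object of class `ct_image`.
#' @export
ct_image <- function(pixels, domain_tag = c("low_dose", "standard_dose",
                                            "generated", "clean_reference"),
                     normalized = FALSE, background_value = -2048,
                     source_id = "unknown", norm_min = NA_real_,
                     norm_max = NA_real_) {
  domain_tag <- match.arg(domain_tag)
  stopifnot(is.matrix(pixels), nrow(pixels) > 0, ncol(pixels) > 0)
  if (!all(is.finite(pixels))) stop("ct_image: pixel values must be finite")
  if (normalized && (min(pixels) < 0 || max(pixels) > 1))
    stop("ct_image: normalized image must lie in [0, 1]")
  structure(list(pixels = pixels, domain_tag = domain_tag,
                 normalized = normalized,
                 background_value = background_value, source_id = source_id,
                 norm_min = norm_min, norm_max = norm_max),
            class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image %dx%d  domain=%s  %s  source=%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$domain_tag,
              if (x$normalized) "normalized [0,1]" else
                sprintf("raw [%.0f, %.0f]", min(x$pixels), max(x$pixels)),
              x$source_id))
  invisible(x)
}

#' Min-max normalize a CT slice to \[0, 1\]
#'
#' Applies `(X - min(X)) / (max(X) - min(X))` per slice: the minimum maps to
#' 0 and the maximum to 1. The original range is retained in
#' `norm_min`/`norm_max` so [denormalize()] can invert the map.
#'
#' @param img a [ct_image()].
#' @return normalized `ct_image`.
#' @export
minmax_normalize <- function(img) {
  stopifnot(inherits(img, "ct_image"))
  if (img$normalized) return(img)
  lo <- min(img$pixels); hi <- max(img$pixels)
  if (hi <= lo)
    stop("minmax_normalize: constant image (max == min), range is degenerate")
  out <- img
  out$pixels <- (img$pixels - lo) / (hi - lo)
  out$normalized <- TRUE
  out$norm_min <- lo
  out$norm_max <- hi
  out
}

#' Invert min-max normalization
#'
#' @param img a normalized [ct_image()].
#' @param orig_min,orig_max the raw range to map \[0, 1\] back onto; defaults
#'   to the range recorded by [minmax_normalize()].
#' @return raw-intensity `ct_image`.
#' @export
denormalize <- function(img, orig_min = img$norm_min,
                        orig_max = img$norm_max) {
  stopifnot(inherits(img, "ct_image"))
  if (!img$normalized) stop("denormalize: image is not normalized")
  if (!is.finite(orig_min) || !is.finite(orig_max) || orig_max <= orig_min)
    stop("denormalize: need orig_max > orig_min")
  out <- img
  out$pixels <- img$pixels * (orig_max - orig_min) + orig_min
  out$normalized <- FALSE
  out$norm_min <- NA_real_
  out$norm_max <- NA_real_
  out
}

#' Scan-cylinder region-of-interest mask
#'
#' The reconstruction cylinder's outside is fixed at `background_value`
#' (typically -2048), so foreground is wherever the raw intensity exceeds
#' `background_value + tol`. Must be computed on the raw (unnormalized)
#' image; that is the documented contract.
#'
#' @param img a raw [ct_image()].
#' @param tol tolerance above the background value (default 1 HU).
#' @return logical matrix of the same shape, `TRUE` on foreground.
#' @export
compute_roi_mask <- function(img, tol = 1) {
  stopifnot(inherits(img, "ct_image"))
  if (img$normalized)
    stop("compute_roi_mask: mask is defined on the raw intensity image")
  img$pixels > img$background_value + tol
}

#' Sample a random ROI-covered patch
#'
#' Top-left corners are drawn uniformly over all in-bounds positions;
#' candidates whose foreground fraction under `mask` is below
#' `min_foreground_frac` are rejected and resampled, up to `max_attempts`.
#'
#' @param img a [ct_image()].
#' @param mask logical matrix from [compute_roi_mask()].
#' @param size patch side length (default 128).
#' @param min_foreground_frac minimum fraction of `TRUE` mask pixels the
#'   patch must cover (default 0.5).
#' @param max_attempts rejection-sampling budget (default 100).
#' @return list of class `ct_patch`: `pixels` (size x size), `origin`
#'   (row, col of the top-left corner), `foreground_fraction`.
#' @export
sample_patch <- function(img, mask, size = 128L, min_foreground_frac = 0.5,
                         max_attempts = 100L) {
  stopifnot(inherits(img, "ct_image"), is.matrix(mask),
            all(dim(mask) == dim(img$pixels)),
            min_foreground_frac >= 0, min_foreground_frac <= 1)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  if (size > min(h, w))
    stop("sample_patch: patch size exceeds image size")
  for (attempt in seq_len(max_attempts)) {
    r0 <- sample.int(h - size + 1L, 1L)
    c0 <- sample.int(w - size + 1L, 1L)
    frac <- mean(mask[r0:(r0 + size - 1L), c0:(c0 + size - 1L)])
    if (frac >= min_foreground_frac) {
      return(structure(list(pixels = img$pixels[r0:(r0 + size - 1L),
                                                c0:(c0 + size - 1L)],
                            origin = c(row = r0, col = c0),
                            foreground_fraction = frac),
                       class = "ct_patch"))
    }
  }
  stop(sprintf(paste0("sample_patch: no patch with foreground fraction >= ",
                      "%.2f found in %d attempts (rejection rule: ROI ",
                      "coverage below threshold)"),
               min_foreground_frac, max_attempts))
}

#' Read / write CT slices (NPZ, PNG, DICOM)
#'
#' `npz` round-trips float64 arrays bit-exactly; `png` stores 8- or 16-bit
#' grayscale (values quantized to the declared bit depth over the recorded
#' intensity window); `dicom` reads single-frame little-endian CT slices and
#' applies RescaleSlope/RescaleIntercept so pixels come back in HU (writing
#' DICOM is not supported).
#'
#' @param path file path.
#' @param format `"npz"`, `"png"` or `"dicom"`; inferred from the extension
#'   when missing.
#' @param ... passed to the format-specific reader/writer.
#' @return [ct_image()] for `read_image`; invisibly `path` for `write_image`.
#' @export
read_image <- function(path, format = NULL, ...) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  format <- format %||% guess_format(path)
  switch(format,
         npz = read_npz_image(path, ...),
         png = read_png_image(path, ...),
         dicom = read_dicom_image(path, ...),
         stop("read_image: unsupported format: ", format))
}

#' @rdname read_image
#' @param img a [ct_image()] to write.
#' @export
write_image <- function(img, path, format = NULL, ...) {
  stopifnot(inherits(img, "ct_image"))
  format <- format %||% guess_format(path)
  switch(format,
         npz = write_npz_image(img, path, ...),
         png = write_png_image(img, path, ...),
         dicom = stop("write_image: DICOM writing is not supported; ",
                      "use npz or png"),
         stop("write_image: unsupported format: ", format))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, npz = "npz", png = "png", dcm = "dicom", dicom = "dicom",
         stop("cannot infer image format from extension: ", path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mse_images <- function(a, b) {
  pa <- if (inherits(a, "ct_image")) a$pixels else a
  pb <- if (inherits(b, "ct_image")) b$pixels else b
  mean((pa - pb)^2)
}
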