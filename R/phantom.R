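# ---------------------------------------------------------------------------
# Synthetic unpaired LDCT/SDCT-like phantoms.
#
# A phantom is an elliptical "body" of soft-tissue intensity on a -2048
# background, with a few brighter elliptical "organs" inside and an optional
# high-intensity rim (bone analog).  Dose-dependent noise is applied in the
# image domain: Gaussian noise with sigma scaling as sqrt(reference/dose),
# attenuation-linked photon noise with the same scaling, and low-amplitude
# directional streaks below a dose threshold.  The background stays exactly
# at background_value so scan-cylinder ROI masking behaves like real CT.
# ---------------------------------------------------------------------------

#' Phantom generation settings
#'
#' @param image_size side length in pixels (default 512; tests use 64).
#' @param n_organs_range integer range (lo, hi) of organ count.
#' @param background_value intensity outside the scan cylinder (default
#'   -2048).
#' @param body_intensity_range soft-tissue HU range of the body ellipse.
#' @param organ_intensity_range HU range of organ ellipses (kept above the
#'   body range so organs are distinct connected components).
#' @param rim_intensity_range HU range of the bone-analog rim.
#' @param rim whether to draw the rim.
#' @param reference_dose_mA the tube current at which `gaussian_sigma_ref`
#'   applies (150, the standard-dose setting).
#' @param gaussian_sigma_ref Gaussian noise sigma in HU at the reference dose
#'   (default 30); at dose d the sigma is
#'   `gaussian_sigma_ref * sqrt(reference/d)`.
#' @param photon_sigma_ref attenuation-linked photon noise sigma in HU at the
#'   reference dose (default 10), same dose scaling.
#' @param streak_amplitude amplitude (HU) of directional streak artifacts
#'   added below `streak_dose_threshold` (default 50).
#' @param streak_dose_threshold dose (mA) below which streaks appear
#'   (default 50, so 30 mA acquisitions show streaks, 150 mA do not).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L, n_organs_range = c(2L, 5L),
                         background_value = -2048,
                         body_intensity_range = c(20, 80),
                         organ_intensity_range = c(120, 300),
                         rim_intensity_range = c(700, 1200), rim = TRUE,
                         reference_dose_mA = 150,
                         gaussian_sigma_ref = 30, photon_sigma_ref = 10,
                         streak_amplitude = 50, streak_dose_threshold = 50) {
  stopifnot(image_size >= 32, reference_dose_mA > 0,
            diff(n_organs_range) >= 0, diff(body_intensity_range) >= 0,
            diff(organ_intensity_range) >= 0,
            diff(rim_intensity_range) >= 0, streak_amplitude >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# mask of an ellipse on the pixel grid
ellipse_mask <- function(n, cx, cy, a, b, theta = 0) {
  x <- matrix(rep(seq_len(n), n), nrow = n)        # row coordinate
  y <- matrix(rep(seq_len(n), each = n), nrow = n) # col coordinate
  xr <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
  yr <- -(x - cx) * sin(theta) + (y - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate a clean reference phantom
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (deterministic output) or `NULL` to use the
#'   current RNG state.
#' @param source_id identifier stored on the image.
#' @return list with `image` (a `clean_reference` [ct_image()]) and `shapes`
#'   (metadata: one entry per placed shape with center/axes/angle/intensity).
#' @export
generate_clean_phantom <- function(spec, seed = NULL,
                                   source_id = paste0("phantom-", seed %||% "rng")) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(seed, {
    for (restart in 1:20) {
      out <- phantom_attempt(spec, source_id)
      if (!is.null(out)) return(out)
    }
    stop("generate_clean_phantom: could not place organs (geometry too tight)")
  })
}

# one full placement attempt; NULL when the organ layout does not fit
phantom_attempt <- function(spec, source_id) {
  {
    n <- spec$image_size
    px <- matrix(spec$background_value, n, n)
    cx <- n / 2 + runif(1, -0.04, 0.04) * n
    cy <- n / 2 + runif(1, -0.04, 0.04) * n
    a <- runif(1, 0.32, 0.42) * n
    b <- runif(1, 0.30, 0.40) * n
    th <- runif(1, 0, pi)
    body_int <- runif(1, spec$body_intensity_range[1],
                      spec$body_intensity_range[2])
    body <- ellipse_mask(n, cx, cy, a, b, th)
    px[body] <- body_int
    shapes <- list(list(type = "body", center = c(cx, cy), axes = c(a, b),
                        angle = th, intensity = body_int))
    rim_frac <- 0.93
    if (spec$rim) {
      rim_int <- runif(1, spec$rim_intensity_range[1],
                       spec$rim_intensity_range[2])
      inner <- ellipse_mask(n, cx, cy, a * rim_frac, b * rim_frac, th)
      px[body & !inner] <- rim_int
      shapes[[length(shapes) + 1L]] <-
        list(type = "rim", center = c(cx, cy),
             axes = c(a, b), inner_axes = c(a * rim_frac, b * rim_frac),
             angle = th, intensity = rim_int)
    }
    n_org <- if (diff(spec$n_organs_range) == 0) spec$n_organs_range[1]
             else sample(spec$n_organs_range[1]:spec$n_organs_range[2], 1L)
    placed <- list()  # centers + max radius, to avoid merged components
    made <- 0L
    tries <- 0L
    while (made < n_org) {
      tries <- tries + 1L
      if (tries > 300L) return(NULL)
      oa <- runif(1, 0.04, 0.10) * n
      ob <- runif(1, 0.04, 0.10) * n
      oth <- runif(1, 0, pi)
      om <- max(oa, ob)
      # organ must fit inside the rim's inner ellipse with a 2 px margin
      sa <- a * rim_frac - om - 2
      sb <- b * rim_frac - om - 2
      if (sa <= 2 || sb <= 2) next
      u <- runif(1); r <- sqrt(runif(1))
      ox <- cx + r * sa * cos(2 * pi * u) * cos(th) -
        r * sb * sin(2 * pi * u) * sin(th)
      oy <- cy + r * sa * cos(2 * pi * u) * sin(th) +
        r * sb * sin(2 * pi * u) * cos(th)
      ok <- TRUE
      for (p in placed)
        if (sqrt((p$c[1] - ox)^2 + (p$c[2] - oy)^2) < p$r + om + 3) {
          ok <- FALSE; break
        }
      if (!ok) next
      oi <- runif(1, spec$organ_intensity_range[1],
                  spec$organ_intensity_range[2])
      px[ellipse_mask(n, ox, oy, oa, ob, oth)] <- oi
      placed[[length(placed) + 1L]] <- list(c = c(ox, oy), r = om)
      shapes[[length(shapes) + 1L]] <-
        list(type = "organ", center = c(ox, oy), axes = c(oa, ob),
             angle = oth, intensity = oi)
      made <- made + 1L
    }
    list(image = ct_image(px, "clean_reference",
                          background_value = spec$background_value,
                          source_id = source_id),
         shapes = shapes)
  }
}

#' Apply dose-dependent acquisition noise to a clean phantom
#'
#' Noise sigma scales as `sqrt(reference_dose / dose_mA)`: Gaussian noise,
#' attenuation-linked photon noise, and (below the streak dose threshold)
#' a few randomly oriented low-amplitude streak ridges. The background is
#' left exactly at `background_value`, and the noise is zero-mean so the
#' expectation over draws equals the clean image.
#'
#' @param clean a `clean_reference` [ct_image()] in raw intensity.
#' @param dose_mA tube current in mA (30 = low dose, 150 = standard).
#' @param spec the [phantom_spec()] that generated `clean`.
#' @param seed optional integer seed.
#' @return a `low_dose` or `standard_dose` [ct_image()].
#' @export
apply_dose_noise <- function(clean, dose_mA, spec, seed = NULL) {
  stopifnot(inherits(clean, "ct_image"), inherits(spec, "phantom_spec"))
  if (clean$normalized || clean$domain_tag != "clean_reference")
    stop("apply_dose_noise: expects a raw clean_reference image")
  if (dose_mA <= 0) stop("apply_dose_noise: dose_mA must be positive")
  local_seed(seed, {
    px <- clean$pixels
    fg <- px != spec$background_value
    nfg <- sum(fg)
    scale <- sqrt(spec$reference_dose_mA / dose_mA)
    noise <- rnorm(nfg, 0, spec$gaussian_sigma_ref * scale)
    # photon noise: denser tissue attenuates more -> fewer photons -> noisier
    att <- sqrt(pmax(px[fg] + 1000, 0) / 1000)
    noise <- noise + rnorm(nfg, 0, 1) * spec$photon_sigma_ref * scale * att
    out <- px
    out[fg] <- out[fg] + noise
    if (dose_mA < spec$streak_dose_threshold && spec$streak_amplitude > 0) {
      n <- nrow(px)
      xg <- matrix(rep(seq_len(n), n), nrow = n)
      yg <- matrix(rep(seq_len(n), each = n), nrow = n)
      for (s in seq_len(4L)) {
        phi <- runif(1, 0, pi)
        idx <- which(fg)
        anchor <- idx[sample.int(length(idx), 1L)]
        ax <- (anchor - 1L) %% n + 1L
        ay <- (anchor - 1L) %/% n + 1L
        d <- (xg - ax) * sin(phi) - (yg - ay) * cos(phi)
        w <- runif(1, 0.7, 1.5)
        amp <- sample(c(-1, 1), 1L) * runif(1, 0.5, 1) * spec$streak_amplitude
        ridge <- amp * exp(-d^2 / (2 * w^2))
        out[fg] <- out[fg] + ridge[fg]
      }
    }
    tag <- if (dose_mA < spec$reference_dose_mA) "low_dose" else "standard_dose"
    ct_image(out, tag, background_value = spec$background_value,
             source_id = clean$source_id)
  })
}

#' Generate an unpaired LDCT/SDCT training set plus a paired evaluation set
#'
#' The low-dose and standard-dose training sets come from disjoint clean
#' phantoms (no shared `source_id`), emulating unpaired acquisition. A small
#' paired set (clean phantom plus its own 30 mA rendering) is generated
#' separately for evaluation only and must never enter training.
#'
#' @param spec a [phantom_spec()].
#' @param n_low,n_std training set sizes.
#' @param seed integer seed controlling the whole dataset.
#' @param n_paired size of the paired evaluation set (default 10).
#' @param low_dose_mA,std_dose_mA tube currents (defaults 30 and 150).
#' @return list with `low`, `std` (lists of [ct_image()]) and `paired_eval`
#'   (list of `list(clean =, low =)`).
#' @export
make_unpaired_dataset <- function(spec, n_low, n_std, seed = 1L,
                                  n_paired = 10L, low_dose_mA = 30,
                                  std_dose_mA = 150) {
  stopifnot(n_low >= 1, n_std >= 1)
  local_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_low + n_std + n_paired)
    mk <- function(i, tag) {
      ph <- generate_clean_phantom(spec, seed = seeds[i],
                                   source_id = sprintf("ph-%s-%03d", tag, i))
      ph$image
    }
    low <- lapply(seq_len(n_low), function(i) {
      apply_dose_noise(mk(i, "low"), low_dose_mA, spec, seed = seeds[i] %% 1e9 + 7)
    })
    std <- lapply(seq_len(n_std), function(i) {
      apply_dose_noise(mk(n_low + i, "std"), std_dose_mA, spec,
                       seed = seeds[n_low + i] %% 1e9 + 7)
    })
    paired <- lapply(seq_len(n_paired), function(i) {
      j <- n_low + n_std + i
      clean <- mk(j, "paired")
      list(clean = clean,
           low = apply_dose_noise(clean, low_dose_mA, spec,
                                  seed = seeds[j] %% 1e9 + 7))
    })
    list(low = low, std = std, paired_eval = paired)
  })
}
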