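# ---------------------------------------------------------------------------
# The joint objective: multi-scale adversarial loss, cycle-consistency and
# identity L1 terms, and their weighted combination.  Expectations are
# arithmetic means over spatial score positions; probabilities are clipped
# to [eps, 1 - eps] before logarithms.
# ---------------------------------------------------------------------------

LOG_EPS <- 1e-7

#' Loss weights of the joint objective
#'
#' Defaults are the published operating point: adversarial 0.1, cycle 10.0,
#' identity 2.0 (chosen there to align the scales of the three terms).
#'
#' @param lambda_adv adversarial weight.
#' @param lambda_cyc cycle-consistency weight.
#' @param lambda_idt identity weight.
#' @export
loss_weights <- function(lambda_adv = 0.1, lambda_cyc = 10.0,
                         lambda_idt = 2.0) {
  stopifnot(lambda_adv >= 0, lambda_cyc >= 0, lambda_idt >= 0)
  structure(list(lambda_adv = lambda_adv, lambda_cyc = lambda_cyc,
                 lambda_idt = lambda_idt), class = "loss_weights")
}

score_values <- function(s) {
  v <- if (inherits(s, "score_map")) unclass(s) else s
  as.numeric(v)
}

#' Multi-scale adversarial objective (discriminator side)
#'
#' `(1/N) * sum_i [ E log D_i(real) + E log(1 - D_i(fake)) ]` with
#' probability-form scores clipped to `[eps, 1 - eps]`. As printed this is
#' the value the discriminator maximizes; its optimum approaches 0 from
#' below.
#'
#' @param scores_real,scores_fake lists of N probability score maps.
#' @param eps log-clipping constant (default 1e-7).
#' @return scalar value of the objective.
#' @export
adversarial_loss <- function(scores_real, scores_fake, eps = LOG_EPS) {
  if (!is.list(scores_real)) scores_real <- list(scores_real)
  if (!is.list(scores_fake)) scores_fake <- list(scores_fake)
  if (length(scores_real) != length(scores_fake))
    stop("adversarial_loss: score lists have different lengths")
  terms <- mapply(function(sr, sf) {
    pr <- pmin(pmax(score_values(sr), eps), 1 - eps)
    pf <- pmin(pmax(score_values(sf), eps), 1 - eps)
    mean(log(pr)) + mean(log(1 - pf))
  }, scores_real, scores_fake)
  mean(terms)
}

#' Generator-side adversarial loss
#'
#' `saturating`: `(1/N) sum_i E log(1 - D_i(G(x)))`, the printed objective the
#' generator minimizes. `non_saturating` (default in training):
#' `-(1/N) sum_i E log D_i(G(x))`, same ordering in D but with strong
#' gradients when the generator is losing.
#'
#' @param scores_fake list of N probability score maps of generated images.
#' @param mode `"non_saturating"` or `"saturating"`.
#' @param eps log-clipping constant.
#' @export
generator_adversarial_loss <- function(scores_fake,
                                       mode = c("non_saturating",
                                                "saturating"),
                                       eps = LOG_EPS) {
  mode <- match.arg(mode)
  if (!is.list(scores_fake)) scores_fake <- list(scores_fake)
  terms <- vapply(scores_fake, function(sf) {
    pf <- pmin(pmax(score_values(sf), eps), 1 - eps)
    if (mode == "saturating") mean(log(1 - pf)) else -mean(log(pf))
  }, numeric(1))
  mean(terms)
}

as_image_fn <- function(f) {
  if (is.function(f)) return(f)
  if (inherits(f, "aac_generator"))
    return(function(m) {
      a <- g_forward(f, array(m, dim = c(dim(m), 1L)), NULL)
      matrix(a, nrow(m), ncol(m))
    })
  stop("expected a function or an aac_generator")
}

img_mat <- function(x) if (inherits(x, "ct_image")) x$pixels else x

#' Cycle-consistency loss
#'
#' `E || G(F(y)) - y ||_1 + E || F(G(x)) - x ||_1` (means over pixels):
#' translating to the other domain and back must recover the input.
#'
#' @param x,y normalized images (matrices or [ct_image()]s) from the two
#'   domains.
#' @param G,F the two generators (functions on matrices or `aac_generator`s).
#' @export
cycle_consistency_loss <- function(x, y, G, F) {
  x <- img_mat(x); y <- img_mat(y)
  Gf <- as_image_fn(G); Ff <- as_image_fn(F)
  if (!all(dim(x) == dim(y))) stop("cycle loss: shape mismatch")
  mean(abs(Gf(Ff(y)) - y)) + mean(abs(Ff(Gf(x)) - x))
}

#' Identity loss
#'
#' `E || G(y) - y ||_1 + E || F(x) - x ||_1`: a generator applied to an image
#' already in its target domain should not change it.
#'
#' @inheritParams cycle_consistency_loss
#' @export
identity_loss <- function(x, y, G, F) {
  x <- img_mat(x); y <- img_mat(y)
  Gf <- as_image_fn(G); Ff <- as_image_fn(F)
  if (!all(dim(x) == dim(y))) stop("identity loss: shape mismatch")
  mean(abs(Gf(y) - y)) + mean(abs(Ff(x) - x))
}

#' Combine loss parts into the joint objective
#'
#' `total = lambda_adv * (adv_G + adv_F) + lambda_cyc * cyc +
#' lambda_idt * idt`; the breakdown identity holds exactly by construction
#' and is re-asserted on every training step.
#'
#' @param parts list with numeric `adv_G`, `adv_F`, `cyc`, `idt` (additional
#'   entries such as per-discriminator losses are carried through).
#' @param weights a [loss_weights()].
#' @return list of class `loss_breakdown`.
#' @export
joint_loss <- function(parts, weights = loss_weights()) {
  need <- c("adv_G", "adv_F", "cyc", "idt")
  for (nm in need) {
    v <- parts[[nm]]
    if (is.null(v) || !is.finite(v))
      stop("joint_loss: part '", nm, "' is missing or non-finite")
  }
  total <- weights$lambda_adv * (parts$adv_G + parts$adv_F) +
    weights$lambda_cyc * parts$cyc + weights$lambda_idt * parts$idt
  structure(c(parts, list(weights = weights, total = total)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss total %.5f  (adv_G %.4f  adv_F %.4f  cyc %.5f  idt %.5f)\n",
    x$total, x$adv_G, x$adv_F, x$cyc, x$idt))
  invisible(x)
}
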