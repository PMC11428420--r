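#' @useDynLib aacdenoise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode autodiff tape.
#
# Feature maps are plain R arrays with dim (H, W, C).  Every op below works in
# two modes: with `tape = NULL` it is an eager, memory-light computation that
# returns a plain array (used for inference); with a tape it records a node so
# ag_backward() can run the chain rule in reverse creation order.
#
# Parameters live in small environments (class "ag_param") so optimizers can
# update them in place; ag_use_param() interns one leaf node per parameter per
# tape, which makes weight sharing (e.g. a generator appearing twice in the
# cycle loss) accumulate gradients correctly.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$param_counter <- 0L

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t$pnodes <- list()   # param id -> node
  t$params <- list()   # param id -> param env
  class(t) <- "ag_tape"
  t
}

is_node <- function(x) inherits(x, "ag_node")

node_value <- function(x) if (is_node(x)) x$value else x

new_node <- function(tape, value, parents = list(), backward = NULL) {
  stopifnot(!is.null(tape))
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$requires <- any(vapply(parents, function(p) is_node(p) && p$requires,
                           logical(1)))
  class(n) <- "ag_node"
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- n
  n$id <- tape$n
  n
}

ag_leaf <- function(tape, value, requires = FALSE) {
  n <- new_node(tape, value)
  n$requires <- requires
  n
}

#' Create a trainable parameter
#'
#' Parameters are environments so that optimizers can mutate values in place;
#' `$grad` is filled by the tape backward pass.
#'
#' @param value initial numeric array.
#' @return an object of class `ag_param`.
#' @keywords internal
ag_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  .ag$param_counter <- .ag$param_counter + 1L
  p$id <- as.character(.ag$param_counter)
  class(p) <- "ag_param"
  p
}

is_param <- function(x) inherits(x, "ag_param")

# Intern a parameter on the tape (one node per parameter per tape).
ag_use_param <- function(tape, par, trainable = TRUE) {
  if (is.null(tape)) return(par$value)
  nd <- tape$pnodes[[par$id]]
  if (is.null(nd)) {
    nd <- ag_leaf(tape, par$value, requires = trainable)
    tape$pnodes[[par$id]] <- nd
    tape$params[[par$id]] <- par
  }
  nd
}

accum_grad <- function(node, g) {
  if (!is_node(node) || !node$requires) return(invisible())
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible()
}

#' Run backpropagation on a tape
#'
#' Seeds the output node with gradient 1 and walks the tape in reverse
#' creation order; afterwards every parameter used on the tape has its
#' `$grad` field set (zero-filled if the parameter did not influence `node`).
#'
#' @param tape an `ag_tape`.
#' @param node the scalar output node.
#' @keywords internal
ag_backward <- function(tape, node) {
  stopifnot(is_node(node), length(node$value) == 1L)
  node$grad <- 1
  if (!node$requires) {
    warning("ag_backward: output does not depend on any trainable parameter")
  }
  for (i in seq(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (is_node(p) && p$requires && !is.null(gs[[k]])) accum_grad(p, gs[[k]])
    }
  }
  for (pid in names(tape$params)) {
    par <- tape$params[[pid]]
    nd <- tape$pnodes[[pid]]
    g <- nd$grad
    if (is.null(g)) g <- array(0, dim = dim_or_len(par$value))
    par$grad <- if (is.null(par$grad)) g else par$grad + g
  }
  invisible(node)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible()
}

# --- elementwise & structural ops ------------------------------------------

ag_add <- function(tape, a, b) {
  v <- node_value(a) + node_value(b)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(a, b), function(g) list(g, g))
}

ag_sub <- function(tape, a, b) {
  v <- node_value(a) - node_value(b)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(tape, a, b) {
  av <- node_value(a); bv <- node_value(b)
  v <- av * bv
  if (is.null(tape)) return(v)
  new_node(tape, v, list(a, b), function(g) list(g * bv, g * av))
}

ag_smul <- function(tape, x, k) {  # multiply by a constant scalar
  v <- node_value(x) * k
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) list(g * k))
}

ag_neg <- function(tape, x) ag_smul(tape, x, -1)

ag_leaky_relu <- function(tape, x, slope = 0.2) {
  xv <- node_value(x)
  neg <- xv < 0
  fac <- 1 - (1 - slope) * neg   # 1 where x >= 0, slope where x < 0
  v <- xv * fac
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) list(g * fac))
}

ag_relu <- function(tape, x) ag_leaky_relu(tape, x, slope = 0)

ag_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-node_value(x)))
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) list(g * v * (1 - v)))
}

ag_abs <- function(tape, x) {
  xv <- node_value(x)
  v <- abs(xv)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) list(g * sign(xv)))
}

ag_log <- function(tape, x) {
  xv <- node_value(x)
  v <- log(xv)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) list(g / xv))
}

ag_clamp <- function(tape, x, lo, hi) {
  xv <- node_value(x)
  v <- pmin(pmax(xv, lo), hi)
  if (!is.null(dim(xv))) dim(v) <- dim(xv)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) {
    d <- g * as.numeric(xv >= lo & xv <= hi)
    if (!is.null(dim(g))) dim(d) <- dim(g)
    list(d)
  })
}

ag_pmax <- function(tape, a, b) {  # elementwise max; ties route to `a`
  av <- node_value(a); bv <- node_value(b)
  v <- pmax(av, bv)
  if (!is.null(dim(av))) dim(v) <- dim(av)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(a, b), function(g) {
    m <- as.numeric(av >= bv)
    da <- g * m; db <- g * (1 - m)
    if (!is.null(dim(g))) { dim(da) <- dim(g); dim(db) <- dim(g) }
    list(da, db)
  })
}

ag_mean <- function(tape, x) {
  xv <- node_value(x)
  v <- mean(xv)
  if (is.null(tape)) return(v)
  n <- length(xv)
  new_node(tape, v, list(x), function(g) {
    d <- array(g / n, dim = dim_or_len(xv))
    list(d)
  })
}

ag_concat_c <- function(tape, xs) {  # concatenate along channel axis
  vs <- lapply(xs, node_value)
  d <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  v <- array(unlist(vs, use.names = FALSE), dim = c(d[1], d[2], sum(cs)))
  if (is.null(tape)) return(v)
  new_node(tape, v, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (k in seq_along(xs)) {
      out[[k]] <- g[, , at + seq_len(cs[k]), drop = FALSE]
      at <- at + cs[k]
    }
    out
  })
}

ag_crop <- function(tape, x, r0, c0, h, w) {  # r0, c0: 1-based top-left
  xv <- node_value(x)
  d <- dim(xv)
  stopifnot(r0 >= 1, c0 >= 1, r0 + h - 1 <= d[1], c0 + w - 1 <= d[2])
  v <- xv[r0:(r0 + h - 1), c0:(c0 + w - 1), , drop = FALSE]
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[r0:(r0 + h - 1), c0:(c0 + w - 1), ] <- g
    list(dx)
  })
}

# --- conv / pooling / shuffle ----------------------------------------------

# pad: single integer (symmetric) or c(top, bottom, left, right)
ag_conv2d <- function(tape, x, w, b, stride = 1L, pad = 0L,
                      pad_mode = c("zero", "reflect")) {
  pad_mode <- match.arg(pad_mode)
  mode <- if (pad_mode == "reflect") 1L else 0L
  if (length(pad) == 1L) pad <- rep(pad, 4L)
  xv <- node_value(x); wv <- node_value(w); bv <- node_value(b)
  need_x <- is_node(x) && x$requires
  need_w <- (is_node(w) && w$requires) || (is_node(b) && b$requires)
  want_col <- !is.null(tape) && need_w
  r <- cpp_conv2d_fw(xv, wv, bv, as.integer(stride), pad[1], pad[2], pad[3],
                     pad[4], mode, want_col)
  if (is.null(tape)) return(r$out)
  col <- r$col
  new_node(tape, r$out, list(x, w, b), function(g) {
    bw <- cpp_conv2d_bw(xv, wv, g, col, as.integer(stride), pad[1], pad[2],
                        pad[3], pad[4], mode, need_x, need_w)
    list(bw$dx, bw$dw, if (is.null(bw$db)) NULL else as.numeric(bw$db))
  })
}

ag_blurpool <- function(tape, x, kernel, stride = 2L) {
  if (stride < 1) stop("blurpool: stride must be >= 1")
  xv <- node_value(x)
  H <- dim(xv)[1]; W <- dim(xv)[2]
  v <- cpp_blurpool_fw(xv, kernel, as.integer(stride))
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) {
    list(cpp_blurpool_bw(g, kernel, as.integer(stride), H, W))
  })
}

ag_pixel_shuffle <- function(tape, x, r) {
  xv <- node_value(x)
  v <- cpp_pixel_shuffle(xv, as.integer(r))
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x),
           function(g) list(cpp_pixel_unshuffle(g, as.integer(r))))
}

ag_pixel_unshuffle <- function(tape, x, r) {
  xv <- node_value(x)
  v <- cpp_pixel_unshuffle(xv, as.integer(r))
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x),
           function(g) list(cpp_pixel_shuffle(g, as.integer(r))))
}

# --- normalization ----------------------------------------------------------

# Per-channel normalization over the spatial axes (instance norm for a single
# sample; identical statistics serve batch norm at batch size 1 in training).
ag_instance_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- node_value(x); gv <- node_value(gamma); bv <- node_value(beta)
  d <- dim(xv); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(xv, nrow = n, ncol = C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  va <- colSums(xc * xc) / n
  isd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(isd, each = n)
  v <- array(xhat * rep(gv, each = n) + rep(bv, each = n), dim = d)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = n, ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- gm * rep(gv, each = n)
    # dx = isd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- (dxhat * n - rep(s1, each = n) - xhat * rep(s2, each = n)) *
      rep(isd / n, each = n)
    list(array(dx, dim = d), dgamma, dbeta)
  })
}

# Batch-norm inference path: frozen running statistics, differentiable in
# x, gamma and beta.
ag_bn_eval <- function(tape, x, gamma, beta, rmean, rvar, eps = 1e-5) {
  xv <- node_value(x); gv <- node_value(gamma); bv <- node_value(beta)
  d <- dim(xv)
  isd <- 1 / sqrt(rvar + eps)
  xm <- matrix(xv, ncol = d[3])
  xhat <- sweep(sweep(xm, 2L, rmean), 2L, isd, `*`)
  v <- array(sweep(sweep(xhat, 2L, gv, `*`), 2L, bv, `+`), dim = d)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x, gamma, beta), function(g) {
    gm <- matrix(g, ncol = d[3])
    list(array(sweep(gm, 2L, gv * isd, `*`), dim = d),
         colSums(gm * xhat), colSums(gm))
  })
}

# --- squeeze-excitation helpers --------------------------------------------

ag_gap <- function(tape, x) {  # global average pool -> length-C vector
  xv <- node_value(x)
  d <- dim(xv); n <- d[1] * d[2]
  v <- colMeans(matrix(xv, nrow = n, ncol = d[3]))
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x), function(g) {
    list(array(rep(g / n, each = n), dim = d))
  })
}

ag_dense <- function(tape, x, w, b) {  # w: (out x in), x: vector
  xv <- node_value(x); wv <- node_value(w); bv <- node_value(b)
  v <- as.numeric(wv %*% xv + bv)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x, w, b), function(g) {
    list(as.numeric(crossprod(wv, g)), outer(g, xv), g)
  })
}

ag_scale_channels <- function(tape, x, gate) {  # gate: length-C vector
  xv <- node_value(x); gv <- node_value(gate)
  d <- dim(xv); n <- d[1] * d[2]
  v <- array(sweep(matrix(xv, nrow = n), 2L, gv, `*`), dim = d)
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x, gate), function(g) {
    gm <- matrix(g, nrow = n)
    dx <- array(sweep(gm, 2L, gv, `*`), dim = d)
    dgate <- colSums(gm * matrix(xv, nrow = n))
    list(dx, dgate)
  })
}

ag_scale_spatial <- function(tape, x, gate) {  # gate: (H, W, 1) array
  xv <- node_value(x); gv <- node_value(gate)
  d <- dim(xv)
  gmat <- array(gv, dim = c(d[1], d[2]))
  v <- xv * as.vector(gmat)   # recycles over channels (column-major: H,W fastest)
  dim(v) <- d
  if (is.null(tape)) return(v)
  new_node(tape, v, list(x, gate), function(g) {
    dx <- g * as.vector(gmat)
    dim(dx) <- d
    dgate <- array(rowSums(matrix(g * xv, ncol = d[3])), dim = c(d[1], d[2], 1))
    list(dx, dgate)
  })
}

# --- spectral normalization -------------------------------------------------

# One power-iteration step on the (c_out x K) matricized kernel; u is the
# persistent left singular vector estimate stored in the layer.  Gradients
# treat u, v as constants (standard practice).
ag_spectral_norm <- function(tape, w, layer, update = TRUE) {
  wv <- node_value(w)
  d <- dim(wv)
  K <- prod(d[1:3]); cout <- d[4]
  M <- matrix(wv, nrow = K, ncol = cout)  # K x cout; A = t(M) is cout x K
  u <- layer$sn_u
  if (is.null(u)) u <- rep(1 / sqrt(cout), cout)
  vvec <- as.numeric(M %*% u)             # A^T u
  vvec <- vvec / max(sqrt(sum(vvec^2)), 1e-12)
  u <- as.numeric(crossprod(M, vvec))     # A v
  u <- u / max(sqrt(sum(u^2)), 1e-12)
  if (update) layer$sn_u <- u
  sigma <- max(sum(u * crossprod(M, vvec)), 1e-12)
  layer$sn_sigma <- sigma
  v <- wv / sigma
  if (is.null(tape)) return(v)
  new_node(tape, v, list(w), function(g) {
    coef <- sum(g * v) / sigma
    duv <- array(outer(vvec, u), dim = d)  # (K x cout) -> kernel layout
    list(g / sigma - coef * duv)
  })
}
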