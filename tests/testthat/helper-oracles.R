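# Independent oracles used across tests.  These deliberately avoid the
# package's C++/tape code paths: plain R loops and closed forms only.

# dense 2D convolution oracle (stride 1 unless given), pad: single int or
# c(top, bottom, left, right), mode "zero" or "reflect"
naive_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L,
                         mode = "zero") {
  if (length(pad) == 1L) pad <- rep(pad, 4L)
  d <- dim(x); kh <- dim(w)[1]; kw <- dim(w)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  if (is.null(b)) b <- numeric(cout)
  idx <- function(p, n) {        # padded coordinate -> source index or NA
    s <- p
    if (mode == "reflect") {
      if (s < 1) s <- 2 - s
      if (s > n) s <- 2 * n - s
    } else if (s < 1 || s > n) return(NA_integer_)
    s
  }
  Hp <- d[1] + pad[1] + pad[2]; Wp <- d[2] + pad[3] + pad[4]
  Ho <- (Hp - kh) %/% stride + 1L; Wo <- (Wp - kw) %/% stride + 1L
  out <- array(0, dim = c(Ho, Wo, cout))
  for (co in seq_len(cout)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- b[co]
    for (ci in seq_len(cin)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      ri <- idx((ho - 1L) * stride + ki - pad[1], d[1])
      cj <- idx((wo - 1L) * stride + kj - pad[3], d[2])
      if (!is.na(ri) && !is.na(cj))
        acc <- acc + x[ri, cj, ci] * w[ki, kj, ci, co]
    }
    out[ho, wo, co] <- acc
  }
  out
}

# blur-pool oracle: same-size reflect blur then subsample from index 1
naive_blurpool <- function(x, kernel, stride = 2L) {
  k <- dim(kernel)[1]
  pt <- (k - 1L) %/% 2L
  w4 <- array(0, dim = c(k, k, dim(x)[3], dim(x)[3]))
  for (c in seq_len(dim(x)[3])) w4[, , c, c] <- kernel
  blurred <- naive_conv2d(x, w4, pad = c(pt, k - 1L - pt, pt, k - 1L - pt),
                          mode = "reflect")
  blurred[seq(1, dim(x)[1], stride), seq(1, dim(x)[2], stride), , drop = FALSE]
}

# brute-force improved precision/recall (O(n^2) double loops)
brute_pr <- function(phi_r, phi_g, k) {
  radii <- function(m) {
    n <- nrow(m)
    r <- numeric(n)
    for (i in seq_len(n)) {
      d <- sqrt(rowSums((m[-i, , drop = FALSE] -
                           matrix(m[i, ], n - 1, ncol(m), byrow = TRUE))^2))
      r[i] <- sort(d)[k]
    }
    r
  }
  member <- function(q, m, rad) {
    for (i in seq_len(nrow(m)))
      if (sqrt(sum((q - m[i, ])^2)) <= rad[i]) return(1L)
    0L
  }
  rr <- radii(phi_r); rg <- radii(phi_g)
  prec <- mean(vapply(seq_len(nrow(phi_g)), function(i)
    member(phi_g[i, ], phi_r, rr), integer(1)))
  rec <- mean(vapply(seq_len(nrow(phi_r)), function(i)
    member(phi_r[i, ], phi_g, rg), integer(1)))
  list(precision = prec, recall = rec)
}

# connected components (4-neighborhood) of a logical matrix
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nlab <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nlab <- nlab + 1L
    queue <- s
    lab[s] <- nlab
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nrow(mask) + 1L
      j <- (cur - 1L) %/% nrow(mask) + 1L
      for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + dd[1]; jj <- j + dd[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          nx <- (jj - 1L) * nrow(mask) + ii
          lab[nx] <- nlab
          queue <- c(queue, nx)
        }
      }
    }
  }
  nlab
}

# finite differences of a scalar function over an array
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(1, max(abs(a)), max(abs(b)))

# minimal explicit-VR little-endian single-frame DICOM fixture
write_test_dicom <- function(path, pixels_stored, slope = 1,
                             intercept = -1024) {
  rows <- nrow(pixels_stored); cols <- ncol(pixels_stored)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  elem_short <- function(g, e, vr, value_raw) {
    w16(g); w16(e)
    writeChar(vr, con, eos = NULL)
    w16(length(value_raw))
    writeBin(value_raw, con)
  }
  elem_ow <- function(g, e, value_raw) {
    w16(g); w16(e)
    writeChar("OW", con, eos = NULL)
    w16(0)
    writeBin(length(value_raw), con, size = 4L, endian = "little")
    writeBin(value_raw, con)
  }
  str_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2) r <- c(r, charToRaw(" "))
    r
  }
  us_raw <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                                 endian = "little")
  elem_short(0x0002, 0x0010, "UI", str_raw("1.2.840.10008.1.2.1"))
  elem_short(0x0028, 0x0004, "CS", str_raw("MONOCHROME2"))
  elem_short(0x0028, 0x0010, "US", us_raw(rows))
  elem_short(0x0028, 0x0011, "US", us_raw(cols))
  elem_short(0x0028, 0x0100, "US", us_raw(16L))
  elem_short(0x0028, 0x0103, "US", us_raw(0L))
  elem_short(0x0028, 0x1052, "DS", str_raw(as.character(intercept)))
  elem_short(0x0028, 0x1053, "DS", str_raw(as.character(slope)))
  # pixel data row-major, uint16
  v <- as.integer(t(pixels_stored))
  elem_ow(0x7fe0, 0x0010, writeBin(v, raw(), size = 2L, endian = "little"))
  invisible(path)
}

# tiny deterministic test phantom spec
test_phantom_spec <- function(...) phantom_spec(image_size = 64L, ...)
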