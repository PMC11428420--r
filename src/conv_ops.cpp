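// Low-level numerical kernels for the network modules.
//
// Feature maps are arma::cube with layout (H, W, C): rows = image rows,
// columns = image columns, slices = channels.  Convolution weights arrive
// from R as a 4-d array with dim (kh, kw, c_in, c_out); R's column-major
// flattening makes kh the fastest index, which fixes the im2col row order
// used below.  Padding (zero or reflect) is folded into the im2col /
// col2im index maps, so the reflect adjoint in the backward pass is exact
// by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// source index for padded coordinate p (0-based), -1 = outside (zero pad)
static void build_map(int n, int pad_lo, int pad_hi, int mode,
                      std::vector<int>& map) {
  map.resize(n + pad_lo + pad_hi);
  for (int p = 0; p < (int)map.size(); ++p) {
    int src = p - pad_lo;
    if (mode == 1) {  // reflect, edge not repeated
      if (src < 0) src = -src;
      if (src >= n) src = 2 * (n - 1) - src;
      if (src < 0 || src >= n) stop("reflect padding wider than the image");
    } else if (src < 0 || src >= n) {
      src = -1;
    }
    map[p] = src;
  }
}

// ---------------------------------------------------------------------------
// padding (kept for blur-pool and tests)
// ---------------------------------------------------------------------------

// mode: 0 = zero, 1 = reflect
// [[Rcpp::export]]
arma::cube cpp_pad(const arma::cube& x, int pt, int pb, int pl, int pr,
                   int mode) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  std::vector<int> rmap, cmap;
  build_map(H, pt, pb, mode, rmap);
  build_map(W, pl, pr, mode, cmap);
  arma::cube out(rmap.size(), cmap.size(), C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)cmap.size(); ++j) {
      if (cmap[j] < 0) continue;
      for (int i = 0; i < (int)rmap.size(); ++i)
        if (rmap[i] >= 0) out(i, j, c) = x(rmap[i], cmap[j], c);
    }
  return out;
}

// exact adjoint of cpp_pad
// [[Rcpp::export]]
arma::cube cpp_pad_adjoint(const arma::cube& g, int pt, int pb, int pl, int pr,
                           int H, int W, int mode) {
  const int C = g.n_slices;
  std::vector<int> rmap, cmap;
  build_map(H, pt, pb, mode, rmap);
  build_map(W, pl, pr, mode, cmap);
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)cmap.size(); ++j) {
      if (cmap[j] < 0) continue;
      for (int i = 0; i < (int)rmap.size(); ++i)
        if (rmap[i] >= 0) out(rmap[i], cmap[j], c) += g(i, j, c);
    }
  return out;
}

// ---------------------------------------------------------------------------
// conv2d via padded-index im2col + GEMM
// ---------------------------------------------------------------------------

static arma::mat im2col_pad(const arma::cube& x, int kh, int kw, int stride,
                            const std::vector<int>& rmap,
                            const std::vector<int>& cmap, int Ho, int Wo) {
  const int Cin = x.n_slices;
  arma::mat col(kh * kw * Cin, (size_t)Ho * Wo, arma::fill::zeros);
  const int K = kh * kw * Cin;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = col.colptr((size_t)ho + (size_t)Ho * wo);
      for (int c = 0; c < Cin; ++c) {
        const arma::mat& s = x.slice(c);
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = cmap[wo * stride + kj];
          const int base = c * kh * kw + kj * kh;
          if (jj < 0) continue;
          const double* srcc = s.colptr(jj);
          for (int ki = 0; ki < kh; ++ki) {
            const int ii = rmap[ho * stride + ki];
            if (ii >= 0) dst[base + ki] = srcc[ii];
          }
        }
      }
      (void)K;
    }
  }
  return col;
}

static void col2im_pad(arma::cube& dx, const arma::mat& dcol, int kh, int kw,
                       int stride, const std::vector<int>& rmap,
                       const std::vector<int>& cmap, int Ho, int Wo) {
  const int Cin = dx.n_slices;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = dcol.colptr((size_t)ho + (size_t)Ho * wo);
      for (int c = 0; c < Cin; ++c) {
        arma::mat& s = dx.slice(c);
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = cmap[wo * stride + kj];
          if (jj < 0) continue;
          const int base = c * kh * kw + kj * kh;
          double* dstc = s.colptr(jj);
          for (int ki = 0; ki < kh; ++ki) {
            const int ii = rmap[ho * stride + ki];
            if (ii >= 0) dstc[ii] += src[base + ki];
          }
        }
      }
    }
  }
}

// forward; returns the column matrix too when want_col (cached for backward)
// [[Rcpp::export]]
List cpp_conv2d_fw(const arma::cube& x, const NumericVector& w,
                   const arma::vec& b, int stride, int pt, int pb, int pl,
                   int pr, int mode, bool want_col) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if ((int)x.n_slices != cin) stop("conv2d: channel mismatch");
  std::vector<int> rmap, cmap;
  build_map(x.n_rows, pt, pb, mode, rmap);
  build_map(x.n_cols, pl, pr, mode, cmap);
  const int Ho = ((int)rmap.size() - kh) / stride + 1;
  const int Wo = ((int)cmap.size() - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than padded input");
  arma::mat col = im2col_pad(x, kh, kw, stride, rmap, cmap, Ho, Wo);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * cin, cout,
                     false, true);  // K x cout view
  arma::mat outm = Wm.t() * col;    // cout x (Ho*Wo)
  arma::cube out(Ho, Wo, cout);
  for (int c = 0; c < cout; ++c) {
    arma::vec rowv = outm.row(c).t();
    if (b.n_elem) rowv += b[c];
    out.slice(c) = arma::reshape(rowv, Ho, Wo);
  }
  List res = List::create(Named("out") = out);
  if (want_col) res["col"] = col;
  return res;
}

// backward; col may be NULL (rebuilt if needed for the weight gradient)
// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const NumericVector& w,
                   const arma::cube& gout, Nullable<NumericMatrix> col_,
                   int stride, int pt, int pb, int pl, int pr, int mode,
                   bool need_xgrad, bool need_wgrad) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  std::vector<int> rmap, cmap;
  build_map(x.n_rows, pt, pb, mode, rmap);
  build_map(x.n_cols, pl, pr, mode, cmap);
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  arma::mat gm(cout, (size_t)Ho * Wo);
  for (int c = 0; c < cout; ++c)
    gm.row(c) = arma::vectorise(gout.slice(c)).t();

  List res;
  if (need_wgrad) {
    arma::mat dW;
    if (col_.isNotNull()) {
      NumericMatrix colr(col_);
      const arma::mat col(colr.begin(), colr.nrow(), colr.ncol(), false,
                          true);
      dW = col * gm.t();
    } else {
      arma::mat col = im2col_pad(x, kh, kw, stride, rmap, cmap, Ho, Wo);
      dW = col * gm.t();
    }
    NumericVector dw(w.size());
    std::copy(dW.begin(), dW.end(), dw.begin());
    dw.attr("dim") = wd;
    res["dw"] = dw;
    res["db"] = arma::vec(arma::sum(gm, 1));
  }
  if (need_xgrad) {
    const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * cin, cout,
                       false, true);
    arma::mat dcol = Wm * gm;  // K x N
    arma::cube dx(x.n_rows, x.n_cols, cin, arma::fill::zeros);
    col2im_pad(dx, dcol, kh, kw, stride, rmap, cmap, Ho, Wo);
    res["dx"] = dx;
  }
  return res;
}

// ---------------------------------------------------------------------------
// depthwise blur-pool: same-size reflect-padded blur then subsample
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_blurpool_fw(const arma::cube& x, const arma::mat& k,
                           int stride) {
  const int kh = k.n_rows, kw = k.n_cols;
  const int pt = (kh - 1) / 2, pb = kh - 1 - pt;
  const int pl = (kw - 1) / 2, pr = kw - 1 - pl;
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  std::vector<int> rmap, cmap;
  build_map(H, pt, pb, 1, rmap);
  build_map(W, pl, pr, 1, cmap);
  const int Ho = (H + stride - 1) / stride, Wo = (W + stride - 1) / stride;
  arma::cube out(Ho, Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    arma::mat& o = out.slice(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = cmap[wo * stride + kj];
          for (int ki = 0; ki < kh; ++ki)
            acc += k(ki, kj) * s(rmap[ho * stride + ki], jj);
        }
        o(ho, wo) = acc;
      }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_blurpool_bw(const arma::cube& gout, const arma::mat& k,
                           int stride, int H, int W) {
  const int kh = k.n_rows, kw = k.n_cols;
  const int pt = (kh - 1) / 2, pb = kh - 1 - pt;
  const int pl = (kw - 1) / 2, pr = kw - 1 - pl;
  const int C = gout.n_slices, Ho = gout.n_rows, Wo = gout.n_cols;
  std::vector<int> rmap, cmap;
  build_map(H, pt, pb, 1, rmap);
  build_map(W, pl, pr, 1, cmap);
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& g = gout.slice(c);
    arma::mat& d = dx.slice(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double gv = g(ho, wo);
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = cmap[wo * stride + kj];
          for (int ki = 0; ki < kh; ++ki)
            d(rmap[ho * stride + ki], jj) += gv * k(ki, kj);
        }
      }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// pixel shuffle / unshuffle (exact rearrangement)
// ---------------------------------------------------------------------------

// input (H, W, C*r^2) -> (H*r, W*r, C); output channel c at (r*h+i, r*w+j)
// takes input channel c*r^2 + i*r + j at (h, w)  [i = row offset, j = col].
// [[Rcpp::export]]
arma::cube cpp_pixel_shuffle(const arma::cube& x, int r) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  if (Cin % (r * r) != 0) stop("pixel_shuffle: channels not divisible by r^2");
  const int C = Cin / (r * r);
  arma::cube out(H * r, W * r, C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < r; ++j) {
        const arma::mat& s = x.slice(c * r * r + i * r + j);
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            out(r * h + i, r * w + j, c) = s(h, w);
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_pixel_unshuffle(const arma::cube& x, int r) {
  const int Hr = x.n_rows, Wr = x.n_cols, C = x.n_slices;
  if (Hr % r != 0 || Wr % r != 0) stop("pixel_unshuffle: size not divisible by r");
  const int H = Hr / r, W = Wr / r;
  arma::cube out(H, W, C * r * r);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < r; ++j) {
        arma::mat& o = out.slice(c * r * r + i * r + j);
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            o(h, w) = x(r * h + i, r * w + j, c);
      }
  return out;
}
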