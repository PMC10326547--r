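#include <Rcpp.h>
using namespace Rcpp;

// Low-level kernels behind the CNN engine. Convolutions are expressed as
// im2col + BLAS matrix products on the R side; these kernels only gather and
// scatter patches, and implement 2x2 max pooling with argmax bookkeeping.
// Arrays follow R's column-major (H, W, C) layout throughout; the im2col
// column index is ki + kh*(kj + kw*c), matching R's linearisation of a
// (kh, kw, C) array, so weight tensors can be reshaped with matrix().

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericMatrix out(H * W, kh * kw * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* po = &out(0, col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - ph;
            if (si < 0 || si >= H) continue;
            po[i + H * j] = px[si + H * (sj + W * c)];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add columns back onto the padded image grid.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector out(H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double* pc = &cols(0, col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - ph;
            if (si < 0 || si >= H) continue;
            po[si + H * (sj + W * c)] += pc[i + H * j];
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2, ceil-mode output size (partial windows kept).
// Returns the pooled array and 1-based linear argmax indices into the input.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int H, int W, int C) {
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector out(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = R_NegInf; int bi = -1;
        for (int dj = 0; dj < 2; ++dj) {
          const int j = 2 * jo + dj;
          if (j >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int i = 2 * io + di;
            if (i >= H) continue;
            const int lin = i + H * (j + W * c);
            if (px[lin] > best) { best = px[lin]; bi = lin; }
          }
        }
        out[io + Ho * (jo + Wo * c)] = best;
        idx[io + Ho * (jo + Wo * c)] = bi + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Route pooled gradients back to the argmax positions.
// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector g, IntegerVector idx, int H, int W, int C) {
  NumericVector out(H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  for (R_xlen_t k = 0; k < g.size(); ++k) out[idx[k] - 1] += g[k];
  return out;
}
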