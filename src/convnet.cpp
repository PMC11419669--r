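// Dense-prediction network primitives: 3x3 same-padding convolution,
// 2x2 max-pooling and nearest-neighbour upsampling, each with an
// analytic backward pass. Convolution is im2col + GEMM, computed in
// single precision (the accumulation error is far below the training
// noise floor); tensors are (H, W, C) cubes matching R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fmat im2col3(const arma::fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::fmat cols(9 * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const float* src = &x(0, js, c);
          float* dstcol = cols.memptr() + k;  // stride 9C between pixels
          const int i_lo = (di < 0) ? 1 : 0;
          const int i_hi = (di > 0) ? H - 1 : H;
          for (int i = i_lo; i < i_hi; ++i) {
            dstcol[(size_t)(i + H * j) * (9 * C)] = src[i + di];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im3(const arma::fmat& gcols, arma::fcube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          float* dst = &gx(0, js, c);
          const float* srccol = gcols.memptr() + k;
          const int i_lo = (di < 0) ? 1 : 0;
          const int i_hi = (di > 0) ? H - 1 : H;
          for (int i = i_lo; i < i_hi; ++i) {
            dst[i + di] += srccol[(size_t)(i + H * j) * (9 * C)];
          }
        }
      }
    }
  }
}

static arma::fcube as_f(const arma::cube& x) {
  return arma::conv_to<arma::fcube>::from(x);
}

// w: (3, 3, Cin, Cout) flattened column-major, i.e. a (9*Cin, Cout) matrix.
// [[Rcpp::export]]
arma::cube cpp_conv3_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  arma::fcube xf = as_f(x);
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());
  arma::fmat cols = im2col3(xf);
  arma::fmat y = cols.t() * wf;        // (H*W, Cout), matches cube memory
  y.each_row() += bf;
  arma::fcube yc(y.memptr(), H, W, Cout, false, true);
  return arma::conv_to<arma::cube>::from(yc);
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& gout) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices,
            Cout = gout.n_slices;
  arma::fcube xf = as_f(x);
  arma::fcube gf = as_f(gout);
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::fmat G(gf.memptr(), H * W, Cout, false, true);
  arma::fmat cols = im2col3(xf);
  arma::fmat gw = cols * G;            // (9*Cin, Cout)
  arma::fvec gb = arma::sum(G, 0).t();
  arma::fmat gcols = wf * G.t();       // (9*Cin, H*W)
  arma::fcube gxf(H, W, Cin, arma::fill::zeros);
  col2im3(gcols, gxf);
  return List::create(
    _["gx"] = arma::conv_to<arma::cube>::from(gxf),
    _["gw"] = arma::conv_to<arma::mat>::from(gw),
    _["gb"] = arma::conv_to<arma::vec>::from(gb));
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);          // linear index into x per channel slab
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf; arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = ii + H * jj; }
          }
        }
        y(i, j, c) = best; idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::ucube& idx, const arma::cube& gout,
                            int H, int W) {
  const int C = gout.n_slices, Ho = gout.n_rows, Wo = gout.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slab = gx.slice_memptr(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        slab[idx(i, j, c)] += gout(i, j, c);
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gout) {
  const int H = gout.n_rows / 2, W = gout.n_cols / 2, C = gout.n_slices;
  arma::cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gout(2 * i, 2 * j, c) + gout(2 * i + 1, 2 * j, c) +
                      gout(2 * i, 2 * j + 1, c) + gout(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// Nearest-seed (Voronoi) labelling of a pixel grid. Seeds are given in
// pixel coordinates (x = column, y = row, 1-based centres allowed as
// doubles); returns an integer H x W label matrix (1-based seed index).
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_label(int H, int W, const arma::vec& sx,
                                const arma::vec& sy) {
  const int n = sx.n_elem;
  IntegerMatrix lab(H, W);
  for (int j = 0; j < W; ++j) {
    const double px = j + 1.0;
    for (int i = 0; i < H; ++i) {
      const double py = i + 1.0;
      double best = arma::datum::inf; int bi = 0;
      for (int s = 0; s < n; ++s) {
        const double dx = px - sx[s], dy = py - sy[s];
        const double d = dx * dx + dy * dy;
        if (d < best) { best = d; bi = s + 1; }
      }
      lab(i, j) = bi;
    }
  }
  return lab;
}
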