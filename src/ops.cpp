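// Hot numerical kernels for the detector engine.
// Tensor layout matches R arrays: cube(H, W, C), column-major, H fastest.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col: x (H,W,Cin) -> col (k*k*Cin, Ho*Wo) for a k x k window,
// given stride and zero padding. Column index runs over output (io, jo)
// with io fastest, matching the (Ho,Wo) cube layout downstream.
static mat im2col(const cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  mat col(k * k * C, Ho * Wo, fill::zeros);
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int ci = jo * Ho + io;
      double* dst = col.colptr(ci);
      const int i0 = io * stride - pad;
      const int j0 = jo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int dj = 0; dj < k; ++dj) {
          const int j = j0 + dj;
          for (int di = 0; di < k; ++di) {
            const int i = i0 + di;
            // row index: di + k*dj + k*k*c
            if (i >= 0 && i < H && j >= 0 && j < W)
              dst[di + k * dj + k * k * c] = x(i, j, c);
          }
        }
      }
    }
  }
  return col;
}

// col2im: scatter-add the columns back into an (H,W,Cin) gradient.
static cube col2im(const mat& col, int H, int W, int C, int k, int stride,
                   int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  cube x(H, W, C, fill::zeros);
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int ci = jo * Ho + io;
      const double* src = col.colptr(ci);
      const int i0 = io * stride - pad;
      const int j0 = jo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int dj = 0; dj < k; ++dj) {
          const int j = j0 + dj;
          for (int di = 0; di < k; ++di) {
            const int i = i0 + di;
            if (i >= 0 && i < H && j >= 0 && j < W)
              x(i, j, c) += src[di + k * dj + k * k * c];
          }
        }
      }
    }
  }
  return x;
}

// Standard conv2d forward. wmat is (k*k*Cin, Cout); bias length Cout.
// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& wmat,
                     const arma::vec& bias, int k, int stride, int pad) {
  const int Cout = wmat.n_cols;
  const int Ho = (x.n_rows + 2 * pad - k) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - k) / stride + 1;
  mat col = im2col(x, k, stride, pad);
  mat y = wmat.t() * col;          // (Cout, Ho*Wo)
  y.each_col() += bias;
  cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    mat plane(y.row(c));
    out.slice(c) = reshape(plane, Ho, Wo);
  }
  return out;
}

// Backward pass: returns dx, dW (same shape as wmat), db.
// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& wmat,
                     const arma::cube& dy, int k, int stride, int pad) {
  const int Cout = wmat.n_cols;
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  mat dyf(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    dyf.row(c) = vectorise(dy.slice(c)).t();
  mat col = im2col(x, k, stride, pad);
  mat dW = col * dyf.t();                       // (k*k*Cin, Cout)
  vec db = sum(dyf, 1);
  mat dcol = wmat * dyf;                        // (k*k*Cin, Ho*Wo)
  cube dx = col2im(dcol, x.n_rows, x.n_cols, x.n_slices, k, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Depthwise conv, stride 1, "same" zero padding: each channel is convolved
// (cross-correlated) with its own k x k kernel slice. Used by the vortex
// kernel banks, whose kernels are fixed buffers; only dx is ever needed and
// is obtained by calling this with the spatially flipped kernel.
// [[Rcpp::export]]
arma::cube dwconv_fw(const arma::cube& x, const arma::cube& kern) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int k = kern.n_rows;
  const int pad = k / 2;
  cube y(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    const mat& ks = kern.slice(c);
    mat& ys = y.slice(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double acc = 0.0;
        for (int dj = 0; dj < k; ++dj) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int ii = i + di - pad;
            if (ii < 0 || ii >= H) continue;
            acc += xs(ii, jj) * ks(di, dj);
          }
        }
        ys(i, j) = acc;
      }
    }
  }
  return y;
}

// Bilinear sampling of x at real-valued coordinates (si(i,j), sj(i,j)),
// clamped to the image border; identical sampling for every channel.
// [[Rcpp::export]]
arma::cube bilinear_warp_fw(const arma::cube& x, const arma::mat& si,
                            const arma::mat& sj) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H, W, C);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double u = si(i, j), v = sj(i, j);
      if (u < 0) u = 0; if (u > H - 1) u = H - 1;
      if (v < 0) v = 0; if (v > W - 1) v = W - 1;
      const int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
      const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      const double fu = u - i0, fv = v - j0;
      const double w00 = (1 - fu) * (1 - fv), w01 = (1 - fu) * fv;
      const double w10 = fu * (1 - fv), w11 = fu * fv;
      for (int c = 0; c < C; ++c)
        y(i, j, c) = w00 * x(i0, j0, c) + w01 * x(i0, j1, c) +
                     w10 * x(i1, j0, c) + w11 * x(i1, j1, c);
    }
  }
  return y;
}

// Gradient of bilinear sampling w.r.t. x (coordinates are fixed buffers).
// [[Rcpp::export]]
arma::cube bilinear_warp_bw(const arma::cube& dy, const arma::mat& si,
                            const arma::mat& sj, int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int j = 0; j < (int)dy.n_cols; ++j) {
    for (int i = 0; i < (int)dy.n_rows; ++i) {
      double u = si(i, j), v = sj(i, j);
      if (u < 0) u = 0; if (u > H - 1) u = H - 1;
      if (v < 0) v = 0; if (v > W - 1) v = W - 1;
      const int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
      const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      const double fu = u - i0, fv = v - j0;
      const double w00 = (1 - fu) * (1 - fv), w01 = (1 - fu) * fv;
      const double w10 = fu * (1 - fv), w11 = fu * fv;
      for (int c = 0; c < C; ++c) {
        const double g = dy(i, j, c);
        dx(i0, j0, c) += w00 * g;
        dx(i0, j1, c) += w01 * g;
        dx(i1, j0, c) += w10 * g;
        dx(i1, j1, c) += w11 * g;
      }
    }
  }
  return dx;
}

// Spiral channel reindexing, cyclic mode:
//   y(i,j,c) = x(i,j, (c + shift(i,j)) mod C)
// shift is an integer matrix of non-negative per-pixel shifts.
// [[Rcpp::export]]
arma::cube channel_shift_fw(const arma::cube& x, const arma::imat& shift) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H, W, C);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int s = shift(i, j) % C;
      for (int c = 0; c < C; ++c)
        y(i, j, c) = x(i, j, (c + s) % C);
    }
  return y;
}

// Adjoint of channel_shift_fw (inverse permutation scatter).
// [[Rcpp::export]]
arma::cube channel_shift_bw(const arma::cube& dy, const arma::imat& shift) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int s = shift(i, j) % C;
      for (int c = 0; c < C; ++c)
        dx(i, j, (c + s) % C) += dy(i, j, c);
    }
  return dx;
}

// Paper-literal broadcast mode: y(i,j,c) = x(i,j, shift(i,j)) for all c.
// [[Rcpp::export]]
arma::cube channel_broadcast_fw(const arma::cube& x, const arma::imat& shift) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H, W, C);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double v = x(i, j, shift(i, j) % C);
      for (int c = 0; c < C; ++c) y(i, j, c) = v;
    }
  return y;
}
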