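// Convolutional primitives for the ESTAN network.
//
// Tensors are arma::cube with layout (H, W, C).  A convolution weight is a
// matrix of size (kh*kw*Cin) x Cout whose row block k*Cin..(k+1)*Cin-1
// holds the kernel tap k = ky*kw + kx (row-major over the kernel window).
// All convolutions are zero-padded "same" with odd kernel extents, so
// output spatial shape equals input spatial shape.
//
// The forward pass is organised as kh*kw shifted GEMMs rather than a
// single im2col: memory stays O(H*W*C) even for the 15x1 kernels, and the
// inner products still go through BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Valid output/input rectangle for kernel tap (ky, kx) with pads (ph, pw).
struct ShiftRegion {
  int oy0, ox0, iy0, ix0, nh, nw;
  bool empty;
};

ShiftRegion shift_region(int H, int W, int ky, int kx, int ph, int pw) {
  ShiftRegion r;
  r.oy0 = std::max(0, ph - ky);
  int oy1 = std::min(H, H + ph - ky);
  r.ox0 = std::max(0, pw - kx);
  int ox1 = std::min(W, W + pw - kx);
  r.nh = oy1 - r.oy0;
  r.nw = ox1 - r.ox0;
  r.iy0 = r.oy0 + ky - ph;
  r.ix0 = r.ox0 + kx - pw;
  r.empty = (r.nh <= 0 || r.nw <= 0);
  return r;
}

// Flatten a spatial sub-rectangle of every slice into (nh*nw) x C.
void gather(const cube& x, const ShiftRegion& r, int y0, int x0, mat& out) {
  const int C = x.n_slices;
  out.set_size(r.nh * r.nw, C);
  for (int c = 0; c < C; ++c)
    out.col(c) = vectorise(x.slice(c).submat(y0, x0, y0 + r.nh - 1,
                                             x0 + r.nw - 1));
}

// Add (nh*nw) x C back into a spatial sub-rectangle of every slice.
void scatter_add(cube& x, const ShiftRegion& r, int y0, int x0,
                 const mat& m) {
  const int C = x.n_slices;
  for (int c = 0; c < C; ++c)
    x.slice(c).submat(y0, x0, y0 + r.nh - 1, x0 + r.nw - 1) +=
        reshape(m.col(c), r.nh, r.nw);
}

} // namespace

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int kh, int kw, bool relu) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  if ((int)w.n_rows != kh * kw * Cin)
    Rcpp::stop("conv2d_fwd: weight rows %d != kh*kw*Cin = %d",
               (int)w.n_rows, kh * kw * Cin);
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c) y.slice(c).fill(b[c]);
  mat xs, ys;
  for (int ky = 0; ky < kh; ++ky) {
    for (int kx = 0; kx < kw; ++kx) {
      ShiftRegion r = shift_region(H, W, ky, kx, ph, pw);
      if (r.empty) continue;
      gather(x, r, r.iy0, r.ix0, xs);
      const mat wk = w.rows((ky * kw + kx) * Cin,
                            (ky * kw + kx + 1) * Cin - 1);
      ys = xs * wk;
      scatter_add(y, r, r.oy0, r.ox0, ys);
    }
  }
  if (relu) y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return y;
}

// Backward pass.  `y` is the forward output (post-ReLU when relu=TRUE);
// its zero set masks the incoming gradient.
// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& y, const arma::cube& dy,
                      int kh, int kw, bool relu) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  cube g = dy;
  if (relu) {
    for (int c = 0; c < Cout; ++c)
      g.slice(c) %= conv_to<mat>::from(y.slice(c) > 0.0);
  }
  cube dx(H, W, Cin, fill::zeros);
  mat dw(w.n_rows, w.n_cols, fill::zeros);
  vec db(Cout);
  for (int c = 0; c < Cout; ++c) db[c] = accu(g.slice(c));
  mat xs, gs, dxs;
  for (int ky = 0; ky < kh; ++ky) {
    for (int kx = 0; kx < kw; ++kx) {
      ShiftRegion r = shift_region(H, W, ky, kx, ph, pw);
      if (r.empty) continue;
      gather(x, r, r.iy0, r.ix0, xs);
      gather(g, r, r.oy0, r.ox0, gs);
      const int k0 = (ky * kw + kx) * Cin;
      dw.rows(k0, k0 + Cin - 1) += xs.t() * gs;
      dxs = gs * w.rows(k0, k0 + Cin - 1).t();
      // accumulate into the input rectangle
      ShiftRegion ri = r;
      scatter_add(dx, ri, r.iy0, r.ix0, dxs);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2.  Returns pooled cube and the argmax code
// (sy*2 + sx) per output cell for the backward scatter.
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2)
    Rcpp::stop("maxpool2_fwd: spatial size %dx%d not divisible by 2", H, W);
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double v00 = s(2 * i, 2 * j),     v10 = s(2 * i + 1, 2 * j);
        double v01 = s(2 * i, 2 * j + 1), v11 = s(2 * i + 1, 2 * j + 1);
        double best = v00; unsigned code = 0;
        if (v10 > best) { best = v10; code = 2; }
        if (v01 > best) { best = v01; code = 1; }
        if (v11 > best) { best = v11; code = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = code;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& dy) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        unsigned code = idx(i, j, c);
        dx(2 * i + (code >> 1), 2 * j + (code & 1u), c) += dy(i, j, c);
      }
  return dx;
}

// Transposed convolution, 2x2 kernel, stride 2 (2x upsampling).  Weight is
// Cin x (4*Cout); column block q*Cout..(q+1)*Cout-1 maps to output offset
// q = sy*2 + sx inside each 2x2 block.  Linear (no activation).
// [[Rcpp::export]]
arma::cube upconv2_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols / 4;
  if ((int)w.n_rows != Cin || (int)w.n_cols != 4 * Cout)
    Rcpp::stop("upconv2_fwd: weight shape mismatch");
  mat xm(H * W, Cin);
  for (int c = 0; c < Cin; ++c) xm.col(c) = vectorise(x.slice(c));
  mat ym = xm * w; // (H*W) x (4*Cout)
  cube y(2 * H, 2 * W, Cout);
  for (int c = 0; c < Cout; ++c) {
    for (int q = 0; q < 4; ++q) {
      const int sy = q >> 1, sx = q & 1;
      mat m = reshape(ym.col(q * Cout + c), H, W);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          y(2 * i + sy, 2 * j + sx, c) = m(i, j) + b[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List upconv2_bwd(const arma::cube& x, const arma::mat& w,
                       const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols / 4;
  mat xm(H * W, Cin);
  for (int c = 0; c < Cin; ++c) xm.col(c) = vectorise(x.slice(c));
  mat gym(H * W, 4 * Cout);
  vec db(Cout, fill::zeros);
  for (int c = 0; c < Cout; ++c) {
    db[c] = accu(dy.slice(c));
    for (int q = 0; q < 4; ++q) {
      const int sy = q >> 1, sx = q & 1;
      mat m(H, W);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          m(i, j) = dy(2 * i + sy, 2 * j + sx, c);
      gym.col(q * Cout + c) = vectorise(m);
    }
  }
  mat dxm = gym * w.t();
  mat dw = xm.t() * gym;
  cube dx(H, W, Cin);
  for (int c = 0; c < Cin; ++c) dx.slice(c) = reshape(dxm.col(c), H, W);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Nearest-neighbour 2x upsampling and its adjoint (used when the decoder
// is configured with upsample = "nearest").
// [[Rcpp::export]]
arma::cube upnn2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upnn2_bwd(const arma::cube& dy) {
  const int Ho = dy.n_rows / 2, Wo = dy.n_cols / 2, C = dy.n_slices;
  cube dx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
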