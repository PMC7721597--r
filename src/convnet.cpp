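// Low-level numerical kernels for the conv-net engine and the metrics module.
// Tensors are arma::cube with layout (H, W, C); batch size is always 1.
// Weight matrices: conv      W  is (C_out x k*k*C_in),
//                  tconv     Wt is (C_in  x k*k*C_out),
// patch row index within a column = c*k*k + kj*k + ki (channel-major).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int conv_out(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static mat im2col(const cube& x, int k, int s, int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = conv_out(H, k, s, p), Wo = conv_out(W, k, s, p);
  mat cols(k * k * C, (uword)Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = c * k * k + kj * k + ki;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + ki;
            if (hi < 0 || hi >= H) continue;
            cols(row, (uword)wo * Ho + ho) = x(hi, wi, c);
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add adjoint of im2col: cols has the geometry of an input of size
// (H, W, C) convolved with (k, s, p).
static cube col2im(const mat& cols, int H, int W, int C, int k, int s, int p) {
  const int Ho = conv_out(H, k, s, p), Wo = conv_out(W, k, s, p);
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = c * k * k + kj * k + ki;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + ki;
            if (hi < 0 || hi >= H) continue;
            x(hi, wi, c) += cols(row, (uword)wo * Ho + ho);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube nn_conv2d_fw(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int k, int s, int p) {
  const int Ho = conv_out(x.n_rows, k, s, p), Wo = conv_out(x.n_cols, k, s, p);
  const mat cols = im2col(x, k, s, p);
  const mat ym = W * cols;  // (C_out x Ho*Wo)
  cube y(Ho, Wo, W.n_rows);
  for (uword c = 0; c < W.n_rows; ++c)
    y.slice(c) = reshape(ym.row(c), Ho, Wo) + b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_conv2d_bw(const arma::cube& x, const arma::mat& W,
                        const arma::cube& dy, int k, int s, int p) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Co = dy.n_slices;
  mat dym(Co, (uword)Ho * Wo);
  for (int c = 0; c < Co; ++c)
    dym.row(c) = vectorise(dy.slice(c)).t();
  const mat cols = im2col(x, k, s, p);
  mat dW = dym * cols.t();
  vec db = sum(dym, 1);
  mat dcols = W.t() * dym;
  cube dx = col2im(dcols, x.n_rows, x.n_cols, x.n_slices, k, s, p);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Transposed convolution: output size Ho = (H - 1)*s - 2p + k.
// [[Rcpp::export]]
arma::cube nn_tconv2d_fw(const arma::cube& x, const arma::mat& Wt,
                         const arma::vec& b, int k, int s, int p) {
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  const int Ho = (H - 1) * s - 2 * p + k, Wo = (W - 1) * s - 2 * p + k;
  const int Co = Wt.n_cols / (k * k);
  mat xm(Ci, (uword)H * W);
  for (int c = 0; c < Ci; ++c)
    xm.row(c) = vectorise(x.slice(c)).t();
  // columns of ycols live on the x grid; scatter-add into the y raster
  mat ycols = Wt.t() * xm;  // (k*k*Co x H*W)
  cube y = col2im(ycols, Ho, Wo, Co, k, s, p);
  for (int c = 0; c < Co; ++c)
    y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_tconv2d_bw(const arma::cube& x, const arma::mat& Wt,
                         const arma::cube& dy, int k, int s, int p) {
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  const int Co = dy.n_slices;
  mat xm(Ci, (uword)H * W);
  for (int c = 0; c < Ci; ++c)
    xm.row(c) = vectorise(x.slice(c)).t();
  const mat dycols = im2col(dy, k, s, p);  // (k*k*Co x H*W)
  mat dWt = xm * dycols.t();               // (Ci x k*k*Co)
  mat dxm = Wt * dycols;                   // (Ci x H*W)
  cube dx(H, W, Ci);
  for (int c = 0; c < Ci; ++c)
    dx.slice(c) = reshape(dxm.row(c), H, W);
  vec db(Co);
  for (int c = 0; c < Co; ++c)
    db(c) = accu(dy.slice(c));
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dWt") = dWt,
                            Rcpp::Named("db") = db);
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher), separable over the three axes. `f` holds 0 at feature
// voxels and +inf elsewhere; `sp` is the physical sample spacing (mm).
static void dt1d(const double* f, double* d, int n, double sp) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -datum::inf;
  z[1] = datum::inf;
  const double sp2 = sp * sp;
  for (int q = 1; q < n; ++q) {
    double s0;
    while (true) {
      const int vk = v[kk];
      s0 = ((f[q] + sp2 * q * q) - (f[vk] + sp2 * vk * vk)) /
           (2.0 * sp2 * (q - vk));
      if (s0 <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s0;
    z[kk + 1] = datum::inf;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    const double dq = sp * (q - v[kk]);
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
arma::cube edt_mm(const arma::ucube& feature, const arma::vec& spacing) {
  const int H = feature.n_rows, W = feature.n_cols, D = feature.n_slices;
  cube g(H, W, D);
  for (int z = 0; z < D; ++z)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y)
        g(y, x, z) = feature(y, x, z) ? 0.0 : 1e30;  // finite sentinel keeps dt1d well-defined

  std::vector<double> buf(std::max(H, std::max(W, D)));
  std::vector<double> out(buf.size());
  // axis 1 (rows)
  for (int z = 0; z < D; ++z)
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) buf[y] = g(y, x, z);
      dt1d(buf.data(), out.data(), H, spacing(0));
      for (int y = 0; y < H; ++y) g(y, x, z) = out[y];
    }
  // axis 2 (cols)
  for (int z = 0; z < D; ++z)
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) buf[x] = g(y, x, z);
      dt1d(buf.data(), out.data(), W, spacing(1));
      for (int x = 0; x < W; ++x) g(y, x, z) = out[x];
    }
  // axis 3 (slices)
  if (D > 1)
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        for (int z = 0; z < D; ++z) buf[z] = g(y, x, z);
        dt1d(buf.data(), out.data(), D, spacing(2));
        for (int z = 0; z < D; ++z) g(y, x, z) = out[z];
      }
  return sqrt(g);
}

// ---------------------------------------------------------------------------
// Separable bicubic resampling (Keys kernel, a = -0.5) with edge clamping.
static inline double cubic_w(double t) {
  const double a = -0.5, at = std::fabs(t);
  if (at <= 1.0) return (a + 2.0) * at * at * at - (a + 3.0) * at * at + 1.0;
  if (at < 2.0)  return a * at * at * at - 5.0 * a * at * at + 8.0 * a * at - 4.0 * a;
  return 0.0;
}

// [[Rcpp::export]]
arma::mat resize_bicubic(const arma::mat& src, int ho, int wo) {
  const int h = src.n_rows, w = src.n_cols;
  const double sy = (double)h / ho, sx = (double)w / wo;
  mat tmp(ho, w);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < ho; ++y) {
      const double fy = (y + 0.5) * sy - 0.5;
      const int iy = (int)std::floor(fy);
      double acc = 0.0, wsum = 0.0;
      for (int m = -1; m <= 2; ++m) {
        const int yy = std::min(std::max(iy + m, 0), h - 1);
        const double ww = cubic_w(fy - (iy + m));
        acc += ww * src(yy, x);
        wsum += ww;
      }
      tmp(y, x) = acc / wsum;
    }
  }
  mat dst(ho, wo);
  for (int y = 0; y < ho; ++y) {
    for (int x = 0; x < wo; ++x) {
      const double fx = (x + 0.5) * sx - 0.5;
      const int ix = (int)std::floor(fx);
      double acc = 0.0, wsum = 0.0;
      for (int m = -1; m <= 2; ++m) {
        const int xx = std::min(std::max(ix + m, 0), w - 1);
        const double ww = cubic_w(fx - (ix + m));
        acc += ww * tmp(y, xx);
        wsum += ww;
      }
      dst(y, x) = acc / wsum;
    }
  }
  return dst;
}
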