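// Low-level numerical kernels: 3-D convolution (im2col + GEMM), transposed
// convolution, grid resampling and in-plane rotation.
//
// Tensor layout: a volume with C channels on an X*Y*Z grid is stored
// channels-first as an R array dim c(C, X, Y, Z), i.e. a flat vector with
// index c + C*(x + X*(y + Y*z)).  Armadillo views it as a (C, X*Y*Z) matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather patches into a (C*k^3, No) matrix.  Row index is
// c + C*(kx + k*(ky + k*kz)); column index enumerates output voxels with
// x fastest.  Out-of-bounds taps are zero.
static arma::mat vol2col(const arma::mat& x, int C, int X, int Y, int Z,
                         int k, int stride, int pad) {
  const int Xo = out_dim(X, k, stride, pad);
  const int Yo = out_dim(Y, k, stride, pad);
  const int Zo = out_dim(Z, k, stride, pad);
  arma::mat col(C * k * k * k, (arma::uword)Xo * Yo * Zo, arma::fill::zeros);
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const arma::uword n = (arma::uword)ox + (arma::uword)Xo * (oy + (arma::uword)Yo * oz);
        double* dst = col.colptr(n);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride + kz - pad;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride + kx - pad;
              if (ix < 0 || ix >= X) continue;
              const double* src = x.colptr((arma::uword)ix + (arma::uword)X * (iy + (arma::uword)Y * iz));
              double* d = dst + (arma::uword)C * (kx + k * (ky + (arma::uword)k * kz));
              std::copy(src, src + C, d);
            }
          }
        }
      }
  return col;
}

// Scatter-add inverse of vol2col.
static arma::mat col2vol(const arma::mat& col, int C, int X, int Y, int Z,
                         int k, int stride, int pad) {
  const int Xo = out_dim(X, k, stride, pad);
  const int Yo = out_dim(Y, k, stride, pad);
  const int Zo = out_dim(Z, k, stride, pad);
  arma::mat x(C, (arma::uword)X * Y * Z, arma::fill::zeros);
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const arma::uword n = (arma::uword)ox + (arma::uword)Xo * (oy + (arma::uword)Yo * oz);
        const double* src0 = col.colptr(n);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride + kz - pad;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride + kx - pad;
              if (ix < 0 || ix >= X) continue;
              double* dst = x.colptr((arma::uword)ix + (arma::uword)X * (iy + (arma::uword)Y * iz));
              const double* s = src0 + (arma::uword)C * (kx + k * (ky + (arma::uword)k * kz));
              for (int c = 0; c < C; ++c) dst[c] += s[c];
            }
          }
        }
      }
  return x;
}

// Exported im2col / col2im so the R side can cache the col matrix from the
// forward pass and reuse it in the backward pass.
// [[Rcpp::export]]
NumericMatrix cpp_vol2col(NumericVector x, IntegerVector dims,
                          int k, int stride, int pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const arma::mat xm(x.begin(), C, (arma::uword)X * Y * Z, false);
  arma::mat col = vol2col(xm, C, X, Y, Z, k, stride, pad);
  return NumericMatrix(col.n_rows, col.n_cols, col.begin());
}

// [[Rcpp::export]]
NumericVector cpp_col2vol(NumericMatrix col, IntegerVector dims,
                          int k, int stride, int pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const arma::mat cm(col.begin(), col.nrow(), col.ncol(), false);
  arma::mat x = col2vol(cm, C, X, Y, Z, k, stride, pad);
  NumericVector res(x.begin(), x.end());
  res.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return res;
}

// Transposed convolution (kernel k, stride k, no padding): doubles each
// spatial dim when k = stride = 2.  w: (C_in, C_out*k^3); output grid
// (C_out, X*k, Y*k, Z*k).
// [[Rcpp::export]]
NumericVector cpp_convt3d_fw(NumericVector x, IntegerVector dims,
                             NumericMatrix w, NumericVector b, int k) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Xo = X * k, Yo = Y * k, Zo = Z * k;
  const int Cout = w.ncol() / (k * k * k);
  const arma::mat xm(x.begin(), C, (arma::uword)X * Y * Z, false);
  const arma::mat wm(w.begin(), C, w.ncol(), false);
  arma::mat col = wm.t() * xm;                    // (C_out*k^3, N_in)
  arma::mat out = col2vol(col, Cout, Xo, Yo, Zo, k, k, 0);
  out.each_col() += arma::vec(b.begin(), b.size());
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return res;
}

// [[Rcpp::export]]
List cpp_convt3d_bw(NumericVector x, IntegerVector dims,
                    NumericMatrix w, NumericVector dout, int k) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Xo = X * k, Yo = Y * k, Zo = Z * k;
  const int Cout = w.ncol() / (k * k * k);
  const arma::mat xm(x.begin(), C, (arma::uword)X * Y * Z, false);
  const arma::mat wm(w.begin(), C, w.ncol(), false);
  const arma::mat dm(dout.begin(), Cout, (arma::uword)Xo * Yo * Zo, false);
  arma::mat dcol = vol2col(dm, Cout, Xo, Yo, Zo, k, k, 0); // (C_out*k^3, N_in)
  arma::mat dx = wm * dcol;
  arma::mat dw = xm * dcol.t();
  arma::vec db = arma::sum(dm, 1);
  NumericVector dxv(dx.begin(), dx.end());
  dxv.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return List::create(_["dx"] = dxv,
                      _["dw"] = NumericMatrix(dw.n_rows, dw.n_cols, dw.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

static inline double sample_trilinear(const double* v, int X, int Y, int Z,
                                      double fx, double fy, double fz) {
  fx = std::min(std::max(fx, 0.0), (double)X - 1);
  fy = std::min(std::max(fy, 0.0), (double)Y - 1);
  fz = std::min(std::max(fz, 0.0), (double)Z - 1);
  const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
  const double dx = fx - x0, dy = fy - y0, dz = fz - z0;
  auto at = [&](int x, int y, int z) {
    return v[(arma::uword)x + (arma::uword)X * (y + (arma::uword)Y * z)];
  };
  const double c00 = at(x0, y0, z0) * (1 - dx) + at(x1, y0, z0) * dx;
  const double c10 = at(x0, y1, z0) * (1 - dx) + at(x1, y1, z0) * dx;
  const double c01 = at(x0, y0, z1) * (1 - dx) + at(x1, y0, z1) * dx;
  const double c11 = at(x0, y1, z1) * (1 - dx) + at(x1, y1, z1) * dx;
  const double c0 = c00 * (1 - dy) + c10 * dy;
  const double c1 = c01 * (1 - dy) + c11 * dy;
  return c0 * (1 - dz) + c1 * dz;
}

static inline double sample_nearest(const double* v, int X, int Y, int Z,
                                    double fx, double fy, double fz) {
  int x = (int)std::lround(fx), y = (int)std::lround(fy), z = (int)std::lround(fz);
  x = std::min(std::max(x, 0), X - 1);
  y = std::min(std::max(y, 0), Y - 1);
  z = std::min(std::max(z, 0), Z - 1);
  return v[(arma::uword)x + (arma::uword)X * (y + (arma::uword)Y * z)];
}

// Resample a single-channel volume to a new grid.  Voxel (0,0,0) centres are
// identified; input coordinate = output index * (out_spacing / in_spacing).
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector dims,
                             IntegerVector odims, NumericVector scale,
                             bool nearest) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = odims[0], Yo = odims[1], Zo = odims[2];
  NumericVector out((arma::uword)Xo * Yo * Zo);
  const double* v = x.begin();
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const double fx = ox * scale[0], fy = oy * scale[1], fz = oz * scale[2];
        out[(arma::uword)ox + (arma::uword)Xo * (oy + (arma::uword)Yo * oz)] =
          nearest ? sample_nearest(v, X, Y, Z, fx, fy, fz)
                  : sample_trilinear(v, X, Y, Z, fx, fy, fz);
      }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  return out;
}

// In-plane (x-y) rotation about the grid centre by `theta` radians,
// sampled by inverse mapping; `fill` used outside the source grid.
// [[Rcpp::export]]
NumericVector cpp_rotate_inplane(NumericVector x, IntegerVector dims,
                                 double theta, bool nearest, double fill) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  NumericVector out((arma::uword)X * Y * Z);
  const double cx = (X - 1) / 2.0, cy = (Y - 1) / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  const double* v = x.begin();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        // inverse rotation of the output coordinate
        const double dx = xx - cx, dy = y - cy;
        const double fx = cx + ct * dx + st * dy;
        const double fy = cy - st * dx + ct * dy;
        double val;
        if (fx < -0.5 || fx > X - 0.5 || fy < -0.5 || fy > Y - 0.5) {
          val = fill;
        } else {
          val = nearest ? sample_nearest(v, X, Y, Z, fx, fy, (double)z)
                        : sample_trilinear(v, X, Y, Z, fx, fy, (double)z);
        }
        out[(arma::uword)xx + (arma::uword)X * (y + (arma::uword)Y * z)] = val;
      }
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  return out;
}
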