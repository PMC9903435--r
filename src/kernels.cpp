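// Convolution, pooling and optimizer kernels for the residual networks.
//
// Activation layout everywhere: a matrix with (n_samples * n_positions)
// rows and n_channels columns; rows are sample-major, positions linearized
// column-major over the spatial dims.  Convolutions are im2col + GEMM.
// Weight layout: (in_channels * k^d) x out_channels, row index
// c * k^d + (kx + k*(ky [+ k*kz])).
//
// Templated on the element type: float is the default training path,
// double backs exact finite-difference gradient checks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

template <typename eT>
static void im2col3(const arma::Mat<eT>& X, int n, int d1, int d2, int d3,
                    int k, int s, int p, int q1, int q2, int q3,
                    arma::Mat<eT>& out) {
  const int P = d1 * d2 * d3, Q = q1 * q2 * q3;
  const int C = X.n_cols, k3 = k * k * k;
  if (out.n_rows != (arma::uword)n * Q || out.n_cols != (arma::uword)C * k3)
    out.zeros((arma::uword)n * Q, (arma::uword)C * k3);
  // valid output range along one axis for kernel offset ko:
  // need 0 <= o*s - p + ko <= d-1
  auto floor_div = [](int a, int b) {
    return a >= 0 ? a / b : -((-a + b - 1) / b);
  };
  auto lo_of = [s, p](int ko) { return std::max(0, (p - ko + s - 1) / s); };
  auto hi_of = [s, p, floor_div](int ko, int d, int q) {
    return std::min(q - 1, floor_div(d - 1 + p - ko, s));
  };
  for (int c = 0; c < C; ++c) {
    const eT* xc = X.colptr(c);
    for (int kz = 0; kz < k; ++kz) {
      const int oz_lo = lo_of(kz), oz_hi = hi_of(kz, d3, q3);
      for (int ky = 0; ky < k; ++ky) {
        const int oy_lo = lo_of(ky), oy_hi = hi_of(ky, d2, q2);
        for (int kx = 0; kx < k; ++kx) {
          const int ox_lo = lo_of(kx), ox_hi = hi_of(kx, d1, q1);
          const int col = c * k3 + kx + k * (ky + k * kz);
          eT* oc = out.colptr(col);
          for (int b = 0; b < n; ++b) {
            const eT* xb = xc + (size_t)b * P;
            eT* ob = oc + (size_t)b * Q;
            for (int oz = oz_lo; oz <= oz_hi; ++oz) {
              const int iz = oz * s - p + kz;
              for (int oy = oy_lo; oy <= oy_hi; ++oy) {
                const int iy = oy * s - p + ky;
                const eT* xrow = xb + (size_t)d1 * (iy + (size_t)d2 * iz);
                eT* orow = ob + (size_t)q1 * (oy + (size_t)q2 * oz);
                if (s == 1) {
                  for (int ox = ox_lo; ox <= ox_hi; ++ox)
                    orow[ox] = xrow[ox - p + kx];
                } else {
                  for (int ox = ox_lo; ox <= ox_hi; ++ox)
                    orow[ox] = xrow[ox * s - p + kx];
                }
              }
            }
          }
        }
      }
    }
  }
}

template <typename eT>
static void col2im3(const arma::Mat<eT>& cols, int n, int d1, int d2, int d3,
                    int k, int s, int p, int q1, int q2, int q3,
                    arma::Mat<eT>& dX) {
  const int P = d1 * d2 * d3, Q = q1 * q2 * q3;
  const int C = dX.n_cols, k3 = k * k * k;
  auto floor_div = [](int a, int b) {
    return a >= 0 ? a / b : -((-a + b - 1) / b);
  };
  auto lo_of = [s, p](int ko) { return std::max(0, (p - ko + s - 1) / s); };
  auto hi_of = [s, p, floor_div](int ko, int d, int q) {
    return std::min(q - 1, floor_div(d - 1 + p - ko, s));
  };
  for (int c = 0; c < C; ++c) {
    eT* xc = dX.colptr(c);
    for (int kz = 0; kz < k; ++kz) {
      const int oz_lo = lo_of(kz), oz_hi = hi_of(kz, d3, q3);
      for (int ky = 0; ky < k; ++ky) {
        const int oy_lo = lo_of(ky), oy_hi = hi_of(ky, d2, q2);
        for (int kx = 0; kx < k; ++kx) {
          const int ox_lo = lo_of(kx), ox_hi = hi_of(kx, d1, q1);
          const int col = c * k3 + kx + k * (ky + k * kz);
          const eT* oc = cols.colptr(col);
          for (int b = 0; b < n; ++b) {
            eT* xb = xc + (size_t)b * P;
            const eT* ob = oc + (size_t)b * Q;
            for (int oz = oz_lo; oz <= oz_hi; ++oz) {
              const int iz = oz * s - p + kz;
              for (int oy = oy_lo; oy <= oy_hi; ++oy) {
                const int iy = oy * s - p + ky;
                eT* xrow = xb + (size_t)d1 * (iy + (size_t)d2 * iz);
                const eT* orow = ob + (size_t)q1 * (oy + (size_t)q2 * oz);
                for (int ox = ox_lo; ox <= ox_hi; ++ox)
                  xrow[ox * s - p + kx] += orow[ox];
              }
            }
          }
        }
      }
    }
  }
}

// 2D versions: same layout with dims (d1, d2).
template <typename eT>
static void im2col2(const arma::Mat<eT>& X, int n, int d1, int d2,
                    int k, int s, int p, int q1, int q2,
                    arma::Mat<eT>& out) {
  const int P = d1 * d2, Q = q1 * q2;
  const int C = X.n_cols, k2 = k * k;
  if (out.n_rows != (arma::uword)n * Q || out.n_cols != (arma::uword)C * k2)
    out.zeros((arma::uword)n * Q, (arma::uword)C * k2);
  for (int c = 0; c < C; ++c) {
    const eT* xc = X.colptr(c);
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const int col = c * k2 + kx + k * ky;
        eT* oc = out.colptr(col);
        for (int b = 0; b < n; ++b) {
          const eT* xb = xc + (size_t)b * P;
          eT* ob = oc + (size_t)b * Q;
          for (int oy = 0; oy < q2; ++oy) {
            const int iy = oy * s - p + ky;
            if (iy < 0 || iy >= d2) continue;
            for (int ox = 0; ox < q1; ++ox) {
              const int ix = ox * s - p + kx;
              if (ix < 0 || ix >= d1) continue;
              ob[(size_t)q1 * oy + ox] = xb[(size_t)d1 * iy + ix];
            }
          }
        }
      }
  }
}

template <typename eT>
static void col2im2(const arma::Mat<eT>& cols, int n, int d1, int d2,
                    int k, int s, int p, int q1, int q2,
                    arma::Mat<eT>& dX) {
  const int P = d1 * d2, Q = q1 * q2;
  const int C = dX.n_cols, k2 = k * k;
  for (int c = 0; c < C; ++c) {
    eT* xc = dX.colptr(c);
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const int col = c * k2 + kx + k * ky;
        const eT* oc = cols.colptr(col);
        for (int b = 0; b < n; ++b) {
          eT* xb = xc + (size_t)b * P;
          const eT* ob = oc + (size_t)b * Q;
          for (int oy = 0; oy < q2; ++oy) {
            const int iy = oy * s - p + ky;
            if (iy < 0 || iy >= d2) continue;
            for (int ox = 0; ox < q1; ++ox) {
              const int ix = ox * s - p + kx;
              if (ix < 0 || ix >= d1) continue;
              xb[(size_t)d1 * iy + ix] += ob[(size_t)q1 * oy + ox];
            }
          }
        }
      }
  }
}

template <typename eT>
static arma::Mat<eT> to_mat(const NumericMatrix& x) {
  arma::Mat<eT> out(x.nrow(), x.ncol());
  const double* src = x.begin();
  eT* dst = out.memptr();
  const size_t nn = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < nn; ++i) dst[i] = (eT)src[i];
  return out;
}

template <typename eT>
static NumericMatrix from_mat(const arma::Mat<eT>& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  const eT* src = x.memptr();
  double* dst = out.begin();
  const size_t nn = (size_t)x.n_rows * x.n_cols;
  for (size_t i = 0; i < nn; ++i) dst[i] = (double)src[i];
  return out;
}

template <typename eT>
static List conv_fw_impl(const NumericMatrix& X, int n,
                         const IntegerVector& dims,
                         const NumericMatrix& W,
                         const NumericVector& bias,
                         int k, int s, int p, bool keep_cols, SEXP ws) {
  arma::Mat<eT> Xm = to_mat<eT>(X), Wm = to_mat<eT>(W);
  arma::Row<eT> b(bias.size());
  for (int i = 0; i < bias.size(); ++i) b(i) = (eT)bias[i];
  // persistent im2col workspace: allocated once per layer, reused across
  // steps (and consumed by the matching conv_bw call)
  XPtr<arma::Mat<eT>> cols =
      Rf_isNull(ws) ? XPtr<arma::Mat<eT>>(new arma::Mat<eT>(), true)
                    : XPtr<arma::Mat<eT>>(ws);
  if (dims.size() == 3) {
    int q1 = out_extent(dims[0], k, s, p), q2 = out_extent(dims[1], k, s, p),
        q3 = out_extent(dims[2], k, s, p);
    im2col3<eT>(Xm, n, dims[0], dims[1], dims[2], k, s, p, q1, q2, q3,
                *cols);
  } else {
    int q1 = out_extent(dims[0], k, s, p), q2 = out_extent(dims[1], k, s, p);
    im2col2<eT>(Xm, n, dims[0], dims[1], k, s, p, q1, q2, *cols);
  }
  arma::Mat<eT> Y = (*cols) * Wm;
  Y.each_row() += b;
  return List::create(_["y"] = from_mat<eT>(Y), _["ws"] = cols);
}

// Backward using the im2col workspace retained by the forward pass.
template <typename eT>
static List conv_bw_impl(SEXP ws, int n, const IntegerVector& dims,
                         const NumericMatrix& W, const NumericMatrix& dY,
                         int k, int s, int p, bool need_dx, SEXP wsd) {
  XPtr<arma::Mat<eT>> cols(ws);
  arma::Mat<eT> Wm = to_mat<eT>(W), dYm = to_mat<eT>(dY);
  arma::Mat<eT> dW = cols->t() * dYm;
  arma::Row<eT> db = arma::sum(dYm, 0);
  NumericMatrix dXr;
  XPtr<arma::Mat<eT>> dcols =
      Rf_isNull(wsd) ? XPtr<arma::Mat<eT>>(new arma::Mat<eT>(), true)
                     : XPtr<arma::Mat<eT>>(wsd);
  if (need_dx) {
    if (dcols->n_rows != dYm.n_rows || dcols->n_cols != Wm.n_rows)
      dcols->set_size(dYm.n_rows, Wm.n_rows);
    (*dcols) = dYm * Wm.t();
    arma::Mat<eT> dX;
    const int kd = dims.size() == 3 ? k * k * k : k * k;
    dX.zeros((arma::uword)n * (dims.size() == 3 ?
              dims[0] * dims[1] * dims[2] : dims[0] * dims[1]),
             W.nrow() / kd);
    if (dims.size() == 3) {
      int q1 = out_extent(dims[0], k, s, p),
          q2 = out_extent(dims[1], k, s, p),
          q3 = out_extent(dims[2], k, s, p);
      col2im3<eT>(*dcols, n, dims[0], dims[1], dims[2], k, s, p, q1, q2, q3,
                  dX);
    } else {
      int q1 = out_extent(dims[0], k, s, p),
          q2 = out_extent(dims[1], k, s, p);
      col2im2<eT>(*dcols, n, dims[0], dims[1], k, s, p, q1, q2, dX);
    }
    dXr = from_mat<eT>(dX);
  }
  return List::create(_["dX"] = dXr, _["dW"] = from_mat<eT>(dW),
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["wsd"] = dcols);
}

// [[Rcpp::export]]
List conv_fw(NumericMatrix X, int n, IntegerVector dims,
             NumericMatrix W, NumericVector bias,
             int k, int stride, int pad, bool f64, bool keep_cols,
             SEXP ws) {
  if (f64)
    return conv_fw_impl<double>(X, n, dims, W, bias, k, stride, pad,
                                keep_cols, ws);
  return conv_fw_impl<float>(X, n, dims, W, bias, k, stride, pad,
                             keep_cols, ws);
}

// [[Rcpp::export]]
List conv_bw(SEXP ws, int n, IntegerVector dims, NumericMatrix W,
             NumericMatrix dY, int k, int stride, int pad, bool f64,
             bool need_dx, SEXP wsd) {
  if (f64)
    return conv_bw_impl<double>(ws, n, dims, W, dY, k, stride, pad,
                                need_dx, wsd);
  return conv_bw_impl<float>(ws, n, dims, W, dY, k, stride, pad,
                             need_dx, wsd);
}

// Fused elementwise add + ReLU (residual join); mask retained for the
// backward pass.
// [[Rcpp::export]]
List add_relu(NumericMatrix A, NumericMatrix B) {
  const R_xlen_t nn = (R_xlen_t)A.nrow() * A.ncol();
  NumericMatrix Y(A.nrow(), A.ncol());
  LogicalMatrix mask(A.nrow(), A.ncol());
  const double* a = A.begin(); const double* b = B.begin();
  double* y = Y.begin(); int* m = mask.begin();
  for (R_xlen_t i = 0; i < nn; ++i) {
    const double v = a[i] + b[i];
    y[i] = v > 0 ? v : 0.0;
    m[i] = v > 0;
  }
  return List::create(_["y"] = Y, _["mask"] = mask);
}

// [[Rcpp::export]]
List relu_fw(NumericMatrix X) {
  const R_xlen_t nn = (R_xlen_t)X.nrow() * X.ncol();
  NumericMatrix Y(X.nrow(), X.ncol());
  LogicalMatrix mask(X.nrow(), X.ncol());
  const double* x = X.begin(); double* y = Y.begin(); int* m = mask.begin();
  for (R_xlen_t i = 0; i < nn; ++i) {
    y[i] = x[i] > 0 ? x[i] : 0.0;
    m[i] = x[i] > 0;
  }
  return List::create(_["y"] = Y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericMatrix relu_bw(NumericMatrix dY, LogicalMatrix mask) {
  const R_xlen_t nn = (R_xlen_t)dY.nrow() * dY.ncol();
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const double* d = dY.begin(); const int* m = mask.begin();
  double* o = dX.begin();
  for (R_xlen_t i = 0; i < nn; ++i) o[i] = m[i] ? d[i] : 0.0;
  return dX;
}

// Per-column mean and variance in one pass (batch-norm statistics).
// [[Rcpp::export]]
List col_stats(NumericMatrix X) {
  const R_xlen_t nr = X.nrow(); const int nc = X.ncol();
  NumericVector mu(nc), var(nc);
  for (int j = 0; j < nc; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0, ss = 0.0;
    for (R_xlen_t i = 0; i < nr; ++i) { s += xj[i]; ss += xj[i] * xj[i]; }
    const double m = s / nr;
    mu[j] = m;
    double v = ss / nr - m * m;
    var[j] = v > 0 ? v : 0.0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// 2x2(x2) max pooling, stride 2.  Returns pooled activations and the
// 1-based row index of each argmax for the backward scatter.
// [[Rcpp::export]]
List maxpool_fw(NumericMatrix X, int n, IntegerVector dims) {
  const int nd = dims.size();
  const int d1 = dims[0], d2 = dims[1], d3 = nd == 3 ? dims[2] : 1;
  const int q1 = d1 / 2, q2 = d2 / 2, q3 = nd == 3 ? d3 / 2 : 1;
  const int P = d1 * d2 * d3, Q = q1 * q2 * q3, C = X.ncol();
  NumericMatrix Y((R_xlen_t)n * Q, C);
  IntegerMatrix idx((R_xlen_t)n * Q, C);
  const int kz_max = nd == 3 ? 2 : 1;
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    for (int b = 0; b < n; ++b) {
      const double* xb = xc + (size_t)b * P;
      for (int oz = 0; oz < q3; ++oz)
        for (int oy = 0; oy < q2; ++oy)
          for (int ox = 0; ox < q1; ++ox) {
            double best = -1e300; int besti = -1;
            for (int kz = 0; kz < kz_max; ++kz)
              for (int ky = 0; ky < 2; ++ky)
                for (int kx = 0; kx < 2; ++kx) {
                  const int ix = 2 * ox + kx, iy = 2 * oy + ky,
                            iz = 2 * oz + kz;
                  const size_t ii = ix + (size_t)d1 * (iy + (size_t)d2 * iz);
                  if (xb[ii] > best) { best = xb[ii]; besti = (int)ii; }
                }
            const size_t orow = (size_t)b * Q + ox +
                                (size_t)q1 * (oy + (size_t)q2 * oz);
            Y(orow, c) = best;
            idx(orow, c) = (int)((size_t)b * P + besti) + 1;
          }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bw(NumericMatrix dY, IntegerMatrix idx, int in_rows) {
  const int C = dY.ncol();
  NumericMatrix dX(in_rows, C);
  for (int c = 0; c < C; ++c)
    for (R_xlen_t r = 0; r < dY.nrow(); ++r)
      dX(idx(r, c) - 1, c) += dY(r, c);
  return dX;
}

// One Adam update, in place, with fused L2 weight decay (gradient of
// l2 * ||p||^2 is 2 * l2 * p).  b1t, b2t are beta1^t, beta2^t.
// [[Rcpp::export]]
void adam_step_inplace(NumericVector p, NumericVector g, NumericVector m,
                       NumericVector v, double lr, double beta1, double beta2,
                       double eps, double b1t, double b2t, double l2) {
  const R_xlen_t nn = p.size();
  double* pp = p.begin(); const double* gp = g.begin();
  double* mp = m.begin(); double* vp = v.begin();
  const double c1 = 1.0 - beta1, c2 = 1.0 - beta2;
  const double mc = 1.0 / (1.0 - b1t), vc = 1.0 / (1.0 - b2t);
  for (R_xlen_t i = 0; i < nn; ++i) {
    const double gi = gp[i] + 2.0 * l2 * pp[i];
    mp[i] = beta1 * mp[i] + c1 * gi;
    vp[i] = beta2 * vp[i] + c2 * gi * gi;
    pp[i] -= lr * (mp[i] * mc) / (std::sqrt(vp[i] * vc) + eps);
  }
}

// Fused batch-norm forward: xhat = (x - mu) * istd, y = xhat * gamma + beta.
// [[Rcpp::export]]
List bn_fw(NumericMatrix X, NumericVector mu, NumericVector istd,
           NumericVector gamma, NumericVector beta) {
  const R_xlen_t nr = X.nrow(); const int nc = X.ncol();
  NumericMatrix xhat(nr, nc), y(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* xj = &X(0, j);
    double* hj = &xhat(0, j);
    double* yj = &y(0, j);
    const double m = mu[j], s = istd[j], g = gamma[j], b = beta[j];
    for (R_xlen_t i = 0; i < nr; ++i) {
      const double h = (xj[i] - m) * s;
      hj[i] = h;
      yj[i] = h * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// Fused batch-norm backward.
// dx = gamma*istd/m * (m*dy - dbeta - xhat*dgamma)
// [[Rcpp::export]]
List bn_bw(NumericMatrix dY, NumericMatrix xhat, NumericVector istd,
           NumericVector gamma) {
  const R_xlen_t nr = dY.nrow(); const int nc = dY.ncol();
  NumericMatrix dX(nr, nc);
  NumericVector dgamma(nc), dbeta(nc);
  for (int j = 0; j < nc; ++j) {
    const double* dj = &dY(0, j);
    const double* hj = &xhat(0, j);
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < nr; ++i) { sg += dj[i] * hj[i]; sb += dj[i]; }
    dgamma[j] = sg; dbeta[j] = sb;
    const double coef = gamma[j] * istd[j] / (double)nr;
    double* oj = &dX(0, j);
    for (R_xlen_t i = 0; i < nr; ++i)
      oj[i] = coef * ((double)nr * dj[i] - sb - hj[i] * sg);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
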