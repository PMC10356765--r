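// Data-movement primitives for the volumetric network engine.
//
// Feature tensors are stored as dense matrices with channels in rows and
// voxels in columns: an (nx, ny, nz) grid over a batch of b samples becomes a
// c x (nx*ny*nz*b) matrix whose column index is
//   col = i + nx*(j + ny*(k + nz*s))        (0-based, x fastest).
// GEMM itself is left to R's BLAS; these routines only rearrange memory
// (im2col/col2im for 3x3x3 zero-padded convolution, 2x pooling, stride-2
// transposed-convolution scatter/gather, nearest-neighbour upsampling).

#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>
using namespace Rcpp;

// Copy a c x (nx*ny*nz*b) tensor into a spatially 1-voxel zero-padded
// buffer of shape c x ((nx+2)*(ny+2)*(nz+2)*b).
static void pad_tensor(const double* xs, double* xp, int c, int nx, int ny,
                       int nz, int b) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const long npad = (long)px * py * pz * b;
  std::memset(xp, 0, sizeof(double) * c * npad);
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const long src = (long)nx * (j + (long)ny * (k + (long)nz * s));
        const long dst = 1 + (long)px * ((j + 1) + (long)py * ((k + 1) + (long)pz * s));
        std::memcpy(xp + dst * c, xs + src * c, sizeof(double) * c * nx);
      }
}

static void unpad_tensor(const double* xp, double* xs, int c, int nx, int ny,
                         int nz, int b) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const long dst = (long)nx * (j + (long)ny * (k + (long)nz * s));
        const long src = 1 + (long)px * ((j + 1) + (long)py * ((k + 1) + (long)pz * s));
        std::memcpy(xs + dst * c, xp + src * c, sizeof(double) * c * nx);
      }
}

#define SINUSPLAN_MAX_CH 256

// Instruction-set-specific kernel builds (see conv_kernels.h); the AVX2
// variant is used only when the CPU reports avx2 and fma.
namespace sinusplan_base {
void conv_fwd(const double*, const double*, const long*, double*, int, int,
              int, int, int, int);
void conv_bwd(const double*, const double*, const double*, const double*,
              double*, const long*, double*, int, int, int, int, int, int,
              bool);
}
namespace sinusplan_avx2 {
void conv_fwd(const double*, const double*, const long*, double*, int, int,
              int, int, int, int);
void conv_bwd(const double*, const double*, const double*, const double*,
              double*, const long*, double*, int, int, int, int, int, int,
              bool);
}

static bool use_avx2() {
#if defined(__GNUC__) && defined(__x86_64__)
  static const bool ok = __builtin_cpu_supports("avx2") &&
                         __builtin_cpu_supports("fma");
  return ok;
#else
  return false;
#endif
}


// 3x3x3 zero-padded convolution, y = W (*) x, computed in one pass over
// the output columns with the packed kernel held in L1 cache and the
// output accumulated in registers.  W is cout x (27*cin): column block o
// holds the cout x cin matrix for kernel offset o = (dx+1)+3(dy+1)+9(dz+1).
// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(const NumericMatrix& x, const NumericMatrix& W,
                            int cin, int nx, int ny, int nz, int b) {
  const int cout = W.nrow();
  if (cout > SINUSPLAN_MAX_CH) stop("too many output channels");
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const long npad = (long)px * py * pz * b;
  const long n = (long)nx * ny * nz * b;
  std::vector<double> xp((size_t)cin * npad);
  pad_tensor(REAL(x), xp.data(), cin, nx, ny, nz, b);
  // pack wt[o][ci][co] (contiguous over co) and padded-grid shifts
  std::vector<double> wt((size_t)27 * cin * cout);
  long sh[27];
  const double* Wd = REAL(W);
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        sh[o] = dx + (long)px * dy + (long)px * py * dz;
        for (int ci = 0; ci < cin; ++ci)
          for (int co = 0; co < cout; ++co)
            wt[((size_t)o * cin + ci) * cout + co] =
              Wd[co + ((long)o * cin + ci) * cout];
      }
  NumericMatrix y(cout, n);
  if (use_avx2())
    sinusplan_avx2::conv_fwd(xp.data(), wt.data(), sh, REAL(y), cin, cout,
                             nx, ny, nz, b);
  else
    sinusplan_base::conv_fwd(xp.data(), wt.data(), sh, REAL(y), cin, cout,
                             nx, ny, nz, b);
  return y;
}

// Backward pass of the convolution above: given dy (cout x n), returns
// dW (cout x 27cin) and, when needDx, dx (cin x n).  dx is computed in
// gather form, dx(:,j) = sum_o W_o^T dy(:, j - sh_o), over a zero-padded
// copy of dy, so no scatter is needed.
// [[Rcpp::export]]
List cpp_conv3_bwd(const NumericMatrix& x, const NumericMatrix& W,
                   const NumericMatrix& dy, int cin, int nx, int ny, int nz,
                   int b, bool needDx) {
  const int cout = W.nrow();
  if (cin > SINUSPLAN_MAX_CH) stop("too many input channels");
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const long npad = (long)px * py * pz * b;
  std::vector<double> xp((size_t)cin * npad), dyp((size_t)cout * npad);
  pad_tensor(REAL(x), xp.data(), cin, nx, ny, nz, b);
  pad_tensor(REAL(dy), dyp.data(), cout, nx, ny, nz, b);
  const double* Wd = REAL(W);
  // packed transposed kernel wo[o][co][ci] (contiguous over ci) and dW
  // accumulator dwo[o][co][ci]
  std::vector<double> wo((size_t)27 * cin * cout), dwo((size_t)27 * cin * cout, 0.0);
  long sh[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        const int o = (dx_ + 1) + 3 * (dy_ + 1) + 9 * (dz + 1);
        sh[o] = dx_ + (long)px * dy_ + (long)px * py * dz;
        for (int co = 0; co < cout; ++co)
          for (int ci = 0; ci < cin; ++ci)
            wo[((size_t)o * cout + co) * cin + ci] =
              Wd[co + ((long)o * cin + ci) * cout];
      }
  NumericMatrix dxM;
  double* dxd = 0;
  if (needDx) { dxM = NumericMatrix(cin, dy.ncol()); dxd = REAL(dxM); }
  if (use_avx2())
    sinusplan_avx2::conv_bwd(xp.data(), dyp.data(), REAL(dy), wo.data(),
                             dwo.data(), sh, dxd, cin, cout, nx, ny, nz, b,
                             needDx);
  else
    sinusplan_base::conv_bwd(xp.data(), dyp.data(), REAL(dy), wo.data(),
                             dwo.data(), sh, dxd, cin, cout, nx, ny, nz, b,
                             needDx);
  NumericMatrix dW(cout, 27 * cin);
  double* dWd = REAL(dW);
  for (int o = 0; o < 27; ++o)
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < cin; ++ci)
        dWd[co + ((long)o * cin + ci) * cout] =
          dwo[((size_t)o * cout + co) * cin + ci];
  List out = List::create(_["dW"] = dW);
  if (needDx) out["dx"] = dxM;
  return out;
}


// Fused batch-norm + ReLU. Training mode computes batch statistics over the
// columns, normalises, scales, applies ReLU, and returns everything the
// backward pass needs in one sweep; inference mode uses running statistics.
// [[Rcpp::export]]
List cpp_bnrelu_fwd(const NumericMatrix& x, const NumericVector& gamma,
                    const NumericVector& beta, bool train,
                    const NumericVector& rmean, const NumericVector& rvar,
                    double eps) {
  const int c = x.nrow();
  const long n = x.ncol();
  const double* xs = REAL(x);
  NumericMatrix y(c, n);
  double* ys = REAL(y);
  if (!train) {
    std::vector<double> a(c), b(c);
    for (int ch = 0; ch < c; ++ch) {
      a[ch] = gamma[ch] / std::sqrt(rvar[ch] + eps);
      b[ch] = beta[ch] - a[ch] * rmean[ch];
    }
    for (long j = 0; j < n; ++j) {
      const double* xv = xs + j * c;
      double* yv = ys + j * c;
      for (int ch = 0; ch < c; ++ch) {
        const double v = a[ch] * xv[ch] + b[ch];
        yv[ch] = v > 0 ? v : 0.0;
      }
    }
    return List::create(_["y"] = y);
  }
  std::vector<double> mu(c, 0.0), var(c, 0.0);
  for (long j = 0; j < n; ++j) {
    const double* xv = xs + j * c;
    for (int ch = 0; ch < c; ++ch) mu[ch] += xv[ch];
  }
  for (int ch = 0; ch < c; ++ch) mu[ch] /= n;
  for (long j = 0; j < n; ++j) {
    const double* xv = xs + j * c;
    for (int ch = 0; ch < c; ++ch) {
      const double d = xv[ch] - mu[ch];
      var[ch] += d * d;
    }
  }
  NumericMatrix xhat(c, n);
  double* hs = REAL(xhat);
  NumericVector istd(c), muOut(c), varOut(c);
  for (int ch = 0; ch < c; ++ch) {
    var[ch] /= n;
    istd[ch] = 1.0 / std::sqrt(var[ch] + eps);
    muOut[ch] = mu[ch];
    varOut[ch] = var[ch];
  }
  for (long j = 0; j < n; ++j) {
    const double* xv = xs + j * c;
    double* hv = hs + j * c;
    double* yv = ys + j * c;
    for (int ch = 0; ch < c; ++ch) {
      const double h = (xv[ch] - mu[ch]) * istd[ch];
      hv[ch] = h;
      const double v = gamma[ch] * h + beta[ch];
      yv[ch] = v > 0 ? v : 0.0;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                      _["mean"] = muOut, _["var"] = varOut);
}

// Backward pass of the fused block: dy arrives at the ReLU output.
// [[Rcpp::export]]
List cpp_bnrelu_bwd(const NumericVector& gamma, const NumericMatrix& xhat,
                    const NumericVector& istd, const NumericMatrix& y,
                    const NumericMatrix& dy) {
  const int c = dy.nrow();
  const long n = dy.ncol();
  const double* hs = REAL(xhat);
  const double* ys = REAL(y);
  const double* ds = REAL(dy);
  NumericVector dgamma(c), dbeta(c);
  std::vector<double> s1(c, 0.0), s2(c, 0.0);
  for (long j = 0; j < n; ++j) {
    const double* hv = hs + j * c;
    const double* yv = ys + j * c;
    const double* dv = ds + j * c;
    for (int ch = 0; ch < c; ++ch) {
      const double g = yv[ch] > 0 ? dv[ch] : 0.0;
      s1[ch] += g;
      s2[ch] += g * hv[ch];
    }
  }
  NumericMatrix dx(c, n);
  double* os = REAL(dx);
  std::vector<double> m1(c), m2(c), gi(c);
  for (int ch = 0; ch < c; ++ch) {
    dgamma[ch] = s2[ch];
    dbeta[ch] = s1[ch];
    m1[ch] = s1[ch] / n;
    m2[ch] = s2[ch] / n;
    gi[ch] = gamma[ch] * istd[ch];
  }
  for (long j = 0; j < n; ++j) {
    const double* hv = hs + j * c;
    const double* yv = ys + j * c;
    const double* dv = ds + j * c;
    double* ov = os + j * c;
    for (int ch = 0; ch < c; ++ch) {
      const double g = yv[ch] > 0 ? dv[ch] : 0.0;
      ov[ch] = gi[ch] * (g - m1[ch] - hv[ch] * m2[ch]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List cpp_maxpool2(const NumericMatrix& x, int c, int nx, int ny, int nz,
                  int b) {
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const long ncol = (long)mx * my * mz * b;
  NumericMatrix y(c, ncol);
  IntegerMatrix arg(c, ncol);
  const double* xs = REAL(x);
  double* ys = REAL(y);
  int* as = INTEGER(arg);
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          const long oc = i + (long)mx * (j + (long)my * (k + (long)mz * s));
          for (int ch = 0; ch < c; ++ch) {
            double best = R_NegInf; long bcol = -1;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const long icol = (2 * i + dx) +
                    (long)nx * ((2 * j + dy) + (long)ny * ((2 * k + dz) + (long)nz * s));
                  const double v = xs[icol * c + ch];
                  if (v > best) { best = v; bcol = icol; }
                }
            ys[oc * c + ch] = best;
            as[oc * c + ch] = (int)bcol;
          }
        }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool2_bwd(const NumericMatrix& dy,
                               const IntegerMatrix& arg, int ncolIn) {
  const int c = dy.nrow();
  const long ncol = dy.ncol();
  NumericMatrix dx(c, ncolIn);
  const double* ds = REAL(dy);
  const int* as = INTEGER(arg);
  double* os = REAL(dx);
  for (long col = 0; col < ncol; ++col)
    for (int ch = 0; ch < c; ++ch)
      os[(long)as[col * c + ch] * c + ch] += ds[col * c + ch];
  return dx;
}

// [[Rcpp::export]]
NumericMatrix cpp_avgpool(const NumericMatrix& x, int c, int nx, int ny,
                          int nz, int b, int f) {
  const int mx = nx / f, my = ny / f, mz = nz / f;
  const long ncol = (long)mx * my * mz * b;
  NumericMatrix y(c, ncol);
  const double* xs = REAL(x);
  double* ys = REAL(y);
  const double inv = 1.0 / ((double)f * f * f);
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          const long oc = i + (long)mx * (j + (long)my * (k + (long)mz * s));
          for (int ch = 0; ch < c; ++ch) {
            double acc = 0.0;
            for (int dz = 0; dz < f; ++dz)
              for (int dy = 0; dy < f; ++dy)
                for (int dx = 0; dx < f; ++dx) {
                  const long icol = (f * i + dx) +
                    (long)nx * ((f * j + dy) + (long)ny * ((f * k + dz) + (long)nz * s));
                  acc += xs[icol * c + ch];
                }
            ys[oc * c + ch] = acc * inv;
          }
        }
  return y;
}

// Scatter for transposed convolution, kernel 2 stride 2 (blocks tile exactly):
// G is (8*cout) x (nx*ny*nz*b) over the input grid; result is
// cout x (8*nx*ny*nz*b) over the doubled grid.
// [[Rcpp::export]]
NumericMatrix cpp_upconv_scatter(const NumericMatrix& g, int cout, int nx,
                                 int ny, int nz, int b) {
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericMatrix y(cout, (long)ox * oy * oz * b);
  const double* gs = REAL(g);
  double* ys = REAL(y);
  const int grow = 8 * cout;
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const long icol = i + (long)nx * (j + (long)ny * (k + (long)nz * s));
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int o = dx + 2 * dy + 4 * dz;
                const long ocol = (2 * i + dx) +
                  (long)ox * ((2 * j + dy) + (long)oy * ((2 * k + dz) + (long)oz * s));
                std::memcpy(ys + ocol * cout, gs + icol * grow + o * cout,
                            cout * sizeof(double));
              }
        }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_upconv_gather(const NumericMatrix& dy, int cout, int nx,
                                int ny, int nz, int b) {
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericMatrix g(8 * cout, (long)nx * ny * nz * b);
  const double* ds = REAL(dy);
  double* gs = REAL(g);
  const int grow = 8 * cout;
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const long icol = i + (long)nx * (j + (long)ny * (k + (long)nz * s));
          for (int dz = 0; dz < 2; ++dz)
            for (int dy_ = 0; dy_ < 2; ++dy_)
              for (int dx = 0; dx < 2; ++dx) {
                const int o = dx + 2 * dy_ + 4 * dz;
                const long ocol = (2 * i + dx) +
                  (long)ox * ((2 * j + dy_) + (long)oy * ((2 * k + dz) + (long)oz * s));
                std::memcpy(gs + icol * grow + o * cout, ds + ocol * cout,
                            cout * sizeof(double));
              }
        }
  return g;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample_nn(const NumericMatrix& x, int c, int nx, int ny,
                              int nz, int b, int f) {
  const int ox = f * nx, oy = f * ny, oz = f * nz;
  NumericMatrix y(c, (long)ox * oy * oz * b);
  const double* xs = REAL(x);
  double* ys = REAL(y);
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i) {
          const long ocol = i + (long)ox * (j + (long)oy * (k + (long)oz * s));
          const long icol = (i / f) +
            (long)nx * ((j / f) + (long)ny * ((k / f) + (long)nz * s));
          std::memcpy(ys + ocol * c, xs + icol * c, c * sizeof(double));
        }
  return y;
}
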