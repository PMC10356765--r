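// Convolution kernel bodies, included once per instruction-set build
// (see kernels_base.cpp / kernels_avx2.cpp).  SINUSPLAN_KERNEL_NS names the
// namespace of the instantiation.

#include <cstddef>

#define SINUSPLAN_MAX_CH 256

namespace SINUSPLAN_KERNEL_NS {

// Templated inner kernels: fixing the accumulator length at compile time
// lets the compiler keep it in registers and vectorise the channel loops.
template <int COUT>
static void conv_fwd_core(const double* xp, const double* wt, const long* sh,
                          double* yd, int cin, int nx, int ny, int nz, int b) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const long cp0 = 1 + (long)px * ((j + 1) + (long)py * ((k + 1) + (long)pz * s));
        const long c0 = (long)nx * (j + (long)ny * (k + (long)nz * s));
        for (int i = 0; i < nx; ++i) {
          const double* xb = xp + (cp0 + i) * cin;
          // four rotating accumulators break the FMA dependency chain
          double acc[4][COUT];
          for (int a = 0; a < 4; ++a)
            for (int co = 0; co < COUT; ++co) acc[a][co] = 0.0;
          int rot = 0;
          for (int o = 0; o < 27; ++o) {
            const double* xq = xb + sh[o] * cin;
            const double* w = wt + (size_t)o * cin * COUT;
            for (int ci = 0; ci < cin; ++ci) {
              const double v = xq[ci];
              const double* wr = w + (size_t)ci * COUT;
              double* A = acc[rot];
              rot = (rot + 1) & 3;
              for (int co = 0; co < COUT; ++co) A[co] += wr[co] * v;
            }
          }
          double* yv = yd + (c0 + i) * COUT;
          for (int co = 0; co < COUT; ++co)
            yv[co] = (acc[0][co] + acc[1][co]) + (acc[2][co] + acc[3][co]);
        }
      }
}

static void conv_fwd_generic(const double* xp, const double* wt, const long* sh,
                             double* yd, int cin, int cout, int nx, int ny,
                             int nz, int b) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  double acc[SINUSPLAN_MAX_CH];
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const long cp0 = 1 + (long)px * ((j + 1) + (long)py * ((k + 1) + (long)pz * s));
        const long c0 = (long)nx * (j + (long)ny * (k + (long)nz * s));
        for (int i = 0; i < nx; ++i) {
          const double* xb = xp + (cp0 + i) * cin;
          for (int co = 0; co < cout; ++co) acc[co] = 0.0;
          for (int o = 0; o < 27; ++o) {
            const double* xq = xb + sh[o] * cin;
            const double* w = wt + (size_t)o * cin * cout;
            for (int ci = 0; ci < cin; ++ci) {
              const double v = xq[ci];
              const double* wr = w + (size_t)ci * cout;
              for (int co = 0; co < cout; ++co) acc[co] += wr[co] * v;
            }
          }
          double* yv = yd + (c0 + i) * cout;
          for (int co = 0; co < cout; ++co) yv[co] = acc[co];
        }
      }
}

static void conv_fwd_dispatch(const double* xp, const double* wt,
                              const long* sh, double* yd, int cin, int cout,
                              int nx, int ny, int nz, int b) {
  switch (cout) {
  case 2:  conv_fwd_core<2>(xp, wt, sh, yd, cin, nx, ny, nz, b); break;
  case 3:  conv_fwd_core<3>(xp, wt, sh, yd, cin, nx, ny, nz, b); break;
  case 4:  conv_fwd_core<4>(xp, wt, sh, yd, cin, nx, ny, nz, b); break;
  case 5:  conv_fwd_core<5>(xp, wt, sh, yd, cin, nx, ny, nz, b); break;
  case 8:  conv_fwd_core<8>(xp, wt, sh, yd, cin, nx, ny, nz, b); break;
  case 16: conv_fwd_core<16>(xp, wt, sh, yd, cin, nx, ny, nz, b); break;
  case 32: conv_fwd_core<32>(xp, wt, sh, yd, cin, nx, ny, nz, b); break;
  default: conv_fwd_generic(xp, wt, sh, yd, cin, cout, nx, ny, nz, b);
  }
}

template <int CIN>
static void conv_bwd_core(const double* xp, const double* dyp,
                          const double* dyd, const double* wo, double* dwo,
                          const long* sh, double* dxd, int cout, int nx,
                          int ny, int nz, int b, bool needDx) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const long cp0 = 1 + (long)px * ((j + 1) + (long)py * ((k + 1) + (long)pz * s));
        const long c0 = (long)nx * (j + (long)ny * (k + (long)nz * s));
        for (int i = 0; i < nx; ++i) {
          const double* xb = xp + (cp0 + i) * CIN;
          const double* dyb = dyp + (cp0 + i) * cout;
          const double* dyv = dyd + (c0 + i) * cout;
          for (int o = 0; o < 27; ++o) {
            const double* xq = xb + sh[o] * CIN;
            double* dw = dwo + (size_t)o * CIN * cout;
            for (int co = 0; co < cout; ++co) {
              const double dv = dyv[co];
              double* dwr = dw + (size_t)co * CIN;
              for (int ci = 0; ci < CIN; ++ci) dwr[ci] += dv * xq[ci];
            }
          }
          if (needDx) {
            double acc[4][CIN];
            for (int a = 0; a < 4; ++a)
              for (int ci = 0; ci < CIN; ++ci) acc[a][ci] = 0.0;
            int rot = 0;
            for (int o = 0; o < 27; ++o) {
              const double* dq = dyb - sh[o] * cout;
              const double* w = wo + (size_t)o * CIN * cout;
              for (int co = 0; co < cout; ++co) {
                const double dv = dq[co];
                const double* wr = w + (size_t)co * CIN;
                double* A = acc[rot];
                rot = (rot + 1) & 3;
                for (int ci = 0; ci < CIN; ++ci) A[ci] += wr[ci] * dv;
              }
            }
            double* dxv = dxd + (c0 + i) * CIN;
            for (int ci = 0; ci < CIN; ++ci)
              dxv[ci] = (acc[0][ci] + acc[1][ci]) + (acc[2][ci] + acc[3][ci]);
          }
        }
      }
}

static void conv_bwd_generic(const double* xp, const double* dyp,
                             const double* dyd, const double* wo, double* dwo,
                             const long* sh, double* dxd, int cin, int cout,
                             int nx, int ny, int nz, int b, bool needDx) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  double acc[SINUSPLAN_MAX_CH];
  for (int s = 0; s < b; ++s)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const long cp0 = 1 + (long)px * ((j + 1) + (long)py * ((k + 1) + (long)pz * s));
        const long c0 = (long)nx * (j + (long)ny * (k + (long)nz * s));
        for (int i = 0; i < nx; ++i) {
          const double* xb = xp + (cp0 + i) * cin;
          const double* dyb = dyp + (cp0 + i) * cout;
          const double* dyv = dyd + (c0 + i) * cout;
          for (int o = 0; o < 27; ++o) {
            const double* xq = xb + sh[o] * cin;
            double* dw = dwo + (size_t)o * cin * cout;
            for (int co = 0; co < cout; ++co) {
              const double dv = dyv[co];
              double* dwr = dw + (size_t)co * cin;
              for (int ci = 0; ci < cin; ++ci) dwr[ci] += dv * xq[ci];
            }
          }
          if (needDx) {
            for (int ci = 0; ci < cin; ++ci) acc[ci] = 0.0;
            for (int o = 0; o < 27; ++o) {
              const double* dq = dyb - sh[o] * cout;
              const double* w = wo + (size_t)o * cin * cout;
              for (int co = 0; co < cout; ++co) {
                const double dv = dq[co];
                const double* wr = w + (size_t)co * cin;
                for (int ci = 0; ci < cin; ++ci) acc[ci] += wr[ci] * dv;
              }
            }
            double* dxv = dxd + (c0 + i) * cin;
            for (int ci = 0; ci < cin; ++ci) dxv[ci] = acc[ci];
          }
        }
      }
}

static void conv_bwd_dispatch(const double* xp, const double* dyp,
                              const double* dyd, const double* wo, double* dwo,
                              const long* sh, double* dxd, int cin, int cout,
                              int nx, int ny, int nz, int b, bool needDx) {
  switch (cin) {
  case 1:  conv_bwd_core<1>(xp, dyp, dyd, wo, dwo, sh, dxd, cout, nx, ny, nz, b, needDx); break;
  case 2:  conv_bwd_core<2>(xp, dyp, dyd, wo, dwo, sh, dxd, cout, nx, ny, nz, b, needDx); break;
  case 4:  conv_bwd_core<4>(xp, dyp, dyd, wo, dwo, sh, dxd, cout, nx, ny, nz, b, needDx); break;
  case 5:  conv_bwd_core<5>(xp, dyp, dyd, wo, dwo, sh, dxd, cout, nx, ny, nz, b, needDx); break;
  case 8:  conv_bwd_core<8>(xp, dyp, dyd, wo, dwo, sh, dxd, cout, nx, ny, nz, b, needDx); break;
  case 9:  conv_bwd_core<9>(xp, dyp, dyd, wo, dwo, sh, dxd, cout, nx, ny, nz, b, needDx); break;
  case 16: conv_bwd_core<16>(xp, dyp, dyd, wo, dwo, sh, dxd, cout, nx, ny, nz, b, needDx); break;
  case 32: conv_bwd_core<32>(xp, dyp, dyd, wo, dwo, sh, dxd, cout, nx, ny, nz, b, needDx); break;
  default: conv_bwd_generic(xp, dyp, dyd, wo, dwo, sh, dxd, cin, cout, nx, ny, nz, b, needDx);
  }
}


void conv_fwd(const double* xp, const double* wt, const long* sh, double* yd,
              int cin, int cout, int nx, int ny, int nz, int b) {
  conv_fwd_dispatch(xp, wt, sh, yd, cin, cout, nx, ny, nz, b);
}

void conv_bwd(const double* xp, const double* dyp, const double* dyd,
              const double* wo, double* dwo, const long* sh, double* dxd,
              int cin, int cout, int nx, int ny, int nz, int b, bool needDx) {
  conv_bwd_dispatch(xp, dyp, dyd, wo, dwo, sh, dxd, cin, cout, nx, ny, nz, b,
                    needDx);
}

}  // namespace SINUSPLAN_KERNEL_NS
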