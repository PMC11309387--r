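#include <Rcpp.h>
using namespace Rcpp;

// 3-D convolution with zero ("same") padding over tensors laid out as
// column-major arrays (X, Y, Z, C, B): x fastest, batch slowest.  Kernels
// are (K, K, K, Cin, Cout) with odd K.  Direct accumulation over kernel
// offsets keeps row accesses contiguous; for the standard K = 3 case the
// three x-taps are fused into one pass per row so the compiler can
// vectorise long runs.  At the volume sizes used here each channel slab
// fits in L2 cache.

static inline void dims5(const IntegerVector &d, int &X, int &Y, int &Z,
                         int &C, int &B) {
  X = d[0]; Y = d[1]; Z = d[2]; C = d[3]; B = d[4];
}

// One output row: out[q] += sum_dx w[dx] * in[q + dx], zero-padded in x.
static inline void row_fw3(double *__restrict__ o,
                           const double *__restrict__ i, double wm, double w0,
                           double wp, int X) {
  o[0] += w0 * i[0] + wp * i[1];
  for (int q = 1; q < X - 1; ++q)
    o[q] += wm * i[q - 1] + w0 * i[q] + wp * i[q + 1];
  o[X - 1] += wm * i[X - 2] + w0 * i[X - 1];
}

// One row of the backward pass: accumulates the three weight-gradient dot
// products and scatters the input gradient (x-taps fused, zero-padded).
static inline void row_bw3(const double *__restrict__ i,
                           const double *__restrict__ g,
                           double *__restrict__ gi, double wm, double w0,
                           double wp, double &am, double &a0, double &ap,
                           int X) {
  double sm = 0.0, s0 = 0.0, sp = 0.0;
  const double g0 = g[0], gl = g[X - 1];
  s0 += i[0] * g0; sp += i[1] * g0;
  gi[0] += w0 * g0 + wm * g[1];
  for (int q = 1; q < X - 1; ++q) {
    const double gq = g[q];
    sm += i[q - 1] * gq; s0 += i[q] * gq; sp += i[q + 1] * gq;
    gi[q] += wp * g[q - 1] + w0 * gq + wm * g[q + 1];
  }
  sm += i[X - 2] * gl; s0 += i[X - 1] * gl;
  gi[X - 1] += wp * g[X - 2] + w0 * gl;
  am += sm; a0 += s0; ap += sp;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, int K, int Cout,
                            NumericVector bias) {
  int X, Y, Z, Cin, B;
  dims5(xdim, X, Y, Z, Cin, B);
  const int H = K / 2;
  const R_xlen_t sv = (R_xlen_t)X * Y * Z;  // spatial voxels per channel
  NumericVector y((R_xlen_t)sv * Cout * B);
  const double *__restrict__ px = x.begin();
  const double *__restrict__ pw = w.begin();
  const double *__restrict__ pb = bias.begin();
  double *__restrict__ py = y.begin();
  const bool fused = (K == 3 && X >= 2);

  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      double *out = py + sv * (co + (R_xlen_t)Cout * b);
      const double bv = pb[co];
      for (R_xlen_t v = 0; v < sv; ++v) out[v] = bv;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *in = px + sv * (ci + (R_xlen_t)Cin * b);
        for (int kz = 0; kz < K; ++kz) {
          const int dz = kz - H;
          const int z0 = dz < 0 ? -dz : 0, z1 = dz > 0 ? Z - dz : Z;
          for (int ky = 0; ky < K; ++ky) {
            const int dy = ky - H;
            const int y0 = dy < 0 ? -dy : 0, y1 = dy > 0 ? Y - dy : Y;
            const R_xlen_t wbase =
                K * (ky + K * (kz + K * (ci + (R_xlen_t)Cin * co)));
            if (fused) {
              const double wm = pw[wbase], w0 = pw[wbase + 1],
                           wp = pw[wbase + 2];
              for (int z = z0; z < z1; ++z)
                for (int yy = y0; yy < y1; ++yy)
                  row_fw3(out + (R_xlen_t)X * (yy + (R_xlen_t)Y * z),
                          in + (R_xlen_t)X *
                                   ((yy + dy) + (R_xlen_t)Y * (z + dz)),
                          wm, w0, wp, X);
            } else {
              for (int kx = 0; kx < K; ++kx) {
                const int dx = kx - H;
                const int x0 = dx < 0 ? -dx : 0, x1 = dx > 0 ? X - dx : X;
                const double wv = pw[wbase + kx];
                for (int z = z0; z < z1; ++z)
                  for (int yy = y0; yy < y1; ++yy) {
                    const double *__restrict__ i = in + (x0 + dx) +
                        (R_xlen_t)X * ((yy + dy) + (R_xlen_t)Y * (z + dz));
                    double *__restrict__ oo =
                        out + x0 + (R_xlen_t)X * (yy + (R_xlen_t)Y * z);
                    const int n = x1 - x0;
                    for (int q = 0; q < n; ++q) oo[q] += wv * i[q];
                  }
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// Backward pass: returns gradients w.r.t. input, kernel weights and bias.
// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdim, NumericVector w,
                   int K, int Cout, NumericVector gy) {
  int X, Y, Z, Cin, B;
  dims5(xdim, X, Y, Z, Cin, B);
  const int H = K / 2;
  const R_xlen_t sv = (R_xlen_t)X * Y * Z;
  NumericVector gx((R_xlen_t)sv * Cin * B);
  NumericVector gw(w.size());
  NumericVector gb(Cout);
  const double *__restrict__ px = x.begin();
  const double *__restrict__ pw = w.begin();
  const double *__restrict__ pgy = gy.begin();
  double *__restrict__ pgx = gx.begin();
  double *__restrict__ pgw = gw.begin();
  double *__restrict__ pgb = gb.begin();
  const bool fused = (K == 3 && X >= 2);

  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      const double *go = pgy + sv * (co + (R_xlen_t)Cout * b);
      double acc_b = 0.0;
      for (R_xlen_t v = 0; v < sv; ++v) acc_b += go[v];
      pgb[co] += acc_b;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *in = px + sv * (ci + (R_xlen_t)Cin * b);
        double *gi = pgx + sv * (ci + (R_xlen_t)Cin * b);
        for (int kz = 0; kz < K; ++kz) {
          const int dz = kz - H;
          const int z0 = dz < 0 ? -dz : 0, z1 = dz > 0 ? Z - dz : Z;
          for (int ky = 0; ky < K; ++ky) {
            const int dy = ky - H;
            const int y0 = dy < 0 ? -dy : 0, y1 = dy > 0 ? Y - dy : Y;
            const R_xlen_t wbase =
                K * (ky + K * (kz + K * (ci + (R_xlen_t)Cin * co)));
            if (fused) {
              const double wm = pw[wbase], w0 = pw[wbase + 1],
                           wp = pw[wbase + 2];
              double am = 0.0, a0 = 0.0, ap = 0.0;
              for (int z = z0; z < z1; ++z)
                for (int yy = y0; yy < y1; ++yy) {
                  const R_xlen_t off =
                      (R_xlen_t)X * ((yy + dy) + (R_xlen_t)Y * (z + dz));
                  row_bw3(in + off,
                          go + (R_xlen_t)X * (yy + (R_xlen_t)Y * z), gi + off,
                          wm, w0, wp, am, a0, ap, X);
                }
              pgw[wbase] += am; pgw[wbase + 1] += a0; pgw[wbase + 2] += ap;
            } else {
              for (int kx = 0; kx < K; ++kx) {
                const int dx = kx - H;
                const int x0 = dx < 0 ? -dx : 0, x1 = dx > 0 ? X - dx : X;
                const R_xlen_t wi = wbase + kx;
                const double wv = pw[wi];
                double acc_w = 0.0;
                for (int z = z0; z < z1; ++z)
                  for (int yy = y0; yy < y1; ++yy) {
                    const double *__restrict__ g =
                        go + x0 + (R_xlen_t)X * (yy + (R_xlen_t)Y * z);
                    const R_xlen_t off = (x0 + dx) +
                        (R_xlen_t)X * ((yy + dy) + (R_xlen_t)Y * (z + dz));
                    const double *__restrict__ i = in + off;
                    double *__restrict__ gi2 = gi + off;
                    const int n = x1 - x0;
                    for (int q = 0; q < n; ++q) {
                      acc_w += i[q] * g[q];
                      gi2[q] += wv * g[q];
                    }
                  }
                pgw[wi] += acc_w;
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Average pooling by integer factor f (dimensions must divide evenly).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fw(NumericVector x, IntegerVector xdim, int f) {
  int X, Y, Z, C, B;
  dims5(xdim, X, Y, Z, C, B);
  const int Xo = X / f, Yo = Y / f, Zo = Z / f;
  const R_xlen_t svi = (R_xlen_t)X * Y * Z, svo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector y(svo * C * B);
  const double inv = 1.0 / (f * f * f);
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t cb = 0; cb < (R_xlen_t)C * B; ++cb) {
    const double *in = px + svi * cb;
    double *out = py + svo * cb;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          double s = 0.0;
          for (int dz = 0; dz < f; ++dz)
            for (int dy = 0; dy < f; ++dy)
              for (int dx2 = 0; dx2 < f; ++dx2)
                s += in[(xx * f + dx2) +
                        (R_xlen_t)X * ((yy * f + dy) +
                                       (R_xlen_t)Y * (z * f + dz))];
          out[xx + (R_xlen_t)Xo * (yy + (R_xlen_t)Yo * z)] = s * inv;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bw(NumericVector gy, IntegerVector xdim, int f) {
  // xdim is the *input* (pre-pool) shape.
  int X, Y, Z, C, B;
  dims5(xdim, X, Y, Z, C, B);
  const int Xo = X / f, Yo = Y / f, Zo = Z / f;
  const R_xlen_t svi = (R_xlen_t)X * Y * Z, svo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector gx(svi * C * B);
  const double inv = 1.0 / (f * f * f);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (R_xlen_t cb = 0; cb < (R_xlen_t)C * B; ++cb) {
    const double *g = pg + svo * cb;
    double *out = px + svi * cb;
    for (int z = 0; z < Z; ++z)
      for (int yy = 0; yy < Y; ++yy)
        for (int xx = 0; xx < X; ++xx)
          out[xx + (R_xlen_t)X * (yy + (R_xlen_t)Y * z)] =
              inv * g[(xx / f) + (R_xlen_t)Xo * ((yy / f) +
                                                 (R_xlen_t)Yo * (z / f))];
  }
  return gx;
}

// Nearest-neighbour upsampling by integer factor f.
// [[Rcpp::export]]
NumericVector cpp_upsample_fw(NumericVector x, IntegerVector xdim, int f) {
  int X, Y, Z, C, B;
  dims5(xdim, X, Y, Z, C, B);
  const int Xo = X * f, Yo = Y * f, Zo = Z * f;
  const R_xlen_t svi = (R_xlen_t)X * Y * Z, svo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector y(svo * C * B);
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t cb = 0; cb < (R_xlen_t)C * B; ++cb) {
    const double *in = px + svi * cb;
    double *out = py + svo * cb;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx)
          out[xx + (R_xlen_t)Xo * (yy + (R_xlen_t)Yo * z)] =
              in[(xx / f) + (R_xlen_t)X * ((yy / f) + (R_xlen_t)Y * (z / f))];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bw(NumericVector gy, IntegerVector xdim, int f) {
  // xdim is the *input* (pre-upsample) shape; gradient sums over each block.
  int X, Y, Z, C, B;
  dims5(xdim, X, Y, Z, C, B);
  const int Xo = X * f, Yo = Y * f, Zo = Z * f;
  const R_xlen_t svi = (R_xlen_t)X * Y * Z, svo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector gx(svi * C * B);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (R_xlen_t cb = 0; cb < (R_xlen_t)C * B; ++cb) {
    const double *g = pg + svo * cb;
    double *out = px + svi * cb;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx)
          out[(xx / f) + (R_xlen_t)X * ((yy / f) + (R_xlen_t)Y * (z / f))] +=
              g[xx + (R_xlen_t)Xo * (yy + (R_xlen_t)Yo * z)];
  }
  return gx;
}
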