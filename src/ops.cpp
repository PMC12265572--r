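#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Feature maps are R arrays with dim (Z, Y, X, C), column-major: z is the
// fastest-varying index. Kernels have dim (Kz, Ky, Kx, Cin, Cout), odd sizes,
// zero ("same") padding, cross-correlation convention.

static inline long vol_of(const IntegerVector& d) {
  return (long)d[0] * d[1] * d[2];
}

// Line-buffered accumulation: for each output z-column, all (ci, kz, ky,
// kx) contributions are accumulated in an L1-resident buffer before one
// write, instead of sweeping the whole output volume once per weight.
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int Z = xd[0], Y = xd[1], X = xd[2], Ci = xd[3];
  int Kz = wd[0], Ky = wd[1], Kx = wd[2], Co = wd[4];
  if (wd[3] != Ci) stop("kernel input channels do not match input");
  int pz = Kz / 2, py = Ky / 2, px = Kx / 2;
  long plane = (long)Z * Y, volsz = (long)Z * Y * X;
  NumericVector out((R_xlen_t)(volsz * Co));
  out.attr("dim") = IntegerVector::create(Z, Y, X, Co);
  double *po = REAL(out), *pv = REAL(x), *pw = REAL(w);
  std::vector<double> buf(Z);
  for (int co = 0; co < Co; ++co)
    for (int xc = 0; xc < X; ++xc)
      for (int y = 0; y < Y; ++y) {
        std::fill(buf.begin(), buf.end(), b[co]);
        for (int ci = 0; ci < Ci; ++ci)
          for (int kx = 0; kx < Kx; ++kx) {
            int xs = xc + kx - px;
            if (xs < 0 || xs >= X) continue;
            for (int ky = 0; ky < Ky; ++ky) {
              int ys = y + ky - py;
              if (ys < 0 || ys >= Y) continue;
              const double *in = pv + ci * volsz + (long)xs * plane + (long)ys * Z;
              const double *wp = pw + (long)Kz * (ky + (long)Ky * (kx + (long)Kx * (ci + (long)Ci * co)));
              for (int kz = 0; kz < Kz; ++kz) {
                double wv = wp[kz];
                int dz = kz - pz;
                int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
                const double *ip = in + dz;
                for (int z = z0; z < z1; ++z) buf[z] += wv * ip[z];
              }
            }
          }
        std::copy(buf.begin(), buf.end(),
                  po + co * volsz + (long)xc * plane + (long)y * Z);
      }
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int Z = xd[0], Y = xd[1], X = xd[2], Ci = xd[3];
  int Kz = wd[0], Ky = wd[1], Kx = wd[2], Co = wd[4];
  int pz = Kz / 2, py = Ky / 2, px = Kx / 2;
  long plane = (long)Z * Y, volsz = (long)Z * Y * X;
  long ksz = (long)Kz * Ky * Kx;
  NumericVector gx((R_xlen_t)x.size());
  gx.attr("dim") = xd;
  NumericVector gw((R_xlen_t)w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  double *pgo = REAL(gout), *pv = REAL(x), *pw = REAL(w);
  double *pgx = REAL(gx), *pgw = REAL(gw);
  for (int co = 0; co < Co; ++co) {
    double s = 0.0;
    double *g = pgo + co * volsz;
    for (long i = 0; i < volsz; ++i) s += g[i];
    gb[co] = s;
  }
  // input gradient: gx[q, ci] = sum_co sum_k w[k, ci, co] * go[q - d, co];
  // same line-buffered structure with the offset sign flipped
  std::vector<double> buf(Z);
  for (int ci = 0; ci < Ci; ++ci)
    for (int xc = 0; xc < X; ++xc)
      for (int y = 0; y < Y; ++y) {
        std::fill(buf.begin(), buf.end(), 0.0);
        for (int co = 0; co < Co; ++co)
          for (int kx = 0; kx < Kx; ++kx) {
            int xs = xc - (kx - px);
            if (xs < 0 || xs >= X) continue;
            for (int ky = 0; ky < Ky; ++ky) {
              int ys = y - (ky - py);
              if (ys < 0 || ys >= Y) continue;
              const double *go = pgo + co * volsz + (long)xs * plane + (long)ys * Z;
              const double *wp = pw + (long)Kz * (ky + (long)Ky * (kx + (long)Kx * (ci + (long)Ci * co)));
              for (int kz = 0; kz < Kz; ++kz) {
                double wv = wp[kz];
                int dz = kz - pz;
                int z0 = std::max(0, dz), z1 = std::min(Z, Z + dz);
                const double *gp = go - dz;
                for (int z = z0; z < z1; ++z) buf[z] += wv * gp[z];
              }
            }
          }
        std::copy(buf.begin(), buf.end(),
                  pgx + ci * volsz + (long)xc * plane + (long)y * Z);
      }
  // weight gradient: per output channel, accumulate all (ci, k) inner
  // products while sweeping the volume once
  std::vector<double> wacc((size_t)ksz * Ci);
  for (int co = 0; co < Co; ++co) {
    std::fill(wacc.begin(), wacc.end(), 0.0);
    for (int xc = 0; xc < X; ++xc)
      for (int y = 0; y < Y; ++y) {
        const double *go = pgo + co * volsz + (long)xc * plane + (long)y * Z;
        for (int ci = 0; ci < Ci; ++ci)
          for (int kx = 0; kx < Kx; ++kx) {
            int xs = xc + kx - px;
            if (xs < 0 || xs >= X) continue;
            for (int ky = 0; ky < Ky; ++ky) {
              int ys = y + ky - py;
              if (ys < 0 || ys >= Y) continue;
              const double *in = pv + ci * volsz + (long)xs * plane + (long)ys * Z;
              double *wa = &wacc[(size_t)Kz * (ky + (long)Ky * (kx + (long)Kx * ci))];
              for (int kz = 0; kz < Kz; ++kz) {
                int dz = kz - pz;
                int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
                const double *ip = in + dz;
                double acc = 0.0;
                for (int z = z0; z < z1; ++z) acc += go[z] * ip[z];
                wa[kz] += acc;
              }
            }
          }
      }
    for (int ci = 0; ci < Ci; ++ci)
      for (long k = 0; k < ksz; ++k)
        pgw[k + ksz * (ci + (long)Ci * co)] = wacc[(size_t)k + ksz * ci];
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x average pooling over the three spatial dims; spatial dims must be even.
// [[Rcpp::export]]
NumericVector avgpool3d(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int Z = xd[0], Y = xd[1], X = xd[2], C = xd[3];
  int Zo = Z / 2, Yo = Y / 2, Xo = X / 2;
  long plane = (long)Z * Y, volsz = (long)Z * Y * X;
  long oplane = (long)Zo * Yo, ovol = (long)Zo * Yo * Xo;
  NumericVector out((R_xlen_t)(ovol * C));
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  double *po = REAL(out), *pv = REAL(x);
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo) {
          double s = 0.0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz)
                s += pv[c * volsz + (long)(2 * xo + dx) * plane + (long)(2 * yo + dy) * Z + 2 * zo + dz];
          po[c * ovol + (long)xo * oplane + (long)yo * Zo + zo] = s / 8.0;
        }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool3d_bwd(NumericVector g, IntegerVector in_dim) {
  int Z = in_dim[0], Y = in_dim[1], X = in_dim[2], C = in_dim[3];
  int Zo = Z / 2, Yo = Y / 2, Xo = X / 2;
  long plane = (long)Z * Y, volsz = (long)Z * Y * X;
  long oplane = (long)Zo * Yo, ovol = (long)Zo * Yo * Xo;
  NumericVector out((R_xlen_t)(volsz * C));
  out.attr("dim") = in_dim;
  double *po = REAL(out), *pg = REAL(g);
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo) {
          double gv = pg[c * ovol + (long)xo * oplane + (long)yo * Zo + zo] / 8.0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz)
                po[c * volsz + (long)(2 * xo + dx) * plane + (long)(2 * yo + dy) * Z + 2 * zo + dz] = gv;
        }
  return out;
}

// Nearest-neighbour 2x upsampling of (Z,Y,X,C).
// [[Rcpp::export]]
NumericVector upsample3d(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int Z = xd[0], Y = xd[1], X = xd[2], C = xd[3];
  int Zo = 2 * Z, Yo = 2 * Y, Xo = 2 * X;
  long plane = (long)Z * Y, volsz = (long)Z * Y * X;
  long oplane = (long)Zo * Yo, ovol = (long)Zo * Yo * Xo;
  NumericVector out((R_xlen_t)(ovol * C));
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  double *po = REAL(out), *pv = REAL(x);
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo)
          po[c * ovol + (long)xo * oplane + (long)yo * Zo + zo] =
            pv[c * volsz + (long)(xo / 2) * plane + (long)(yo / 2) * Z + zo / 2];
  return out;
}

// [[Rcpp::export]]
NumericVector upsample3d_bwd(NumericVector g) {
  IntegerVector gd = g.attr("dim");
  int Zo = gd[0], Yo = gd[1], Xo = gd[2], C = gd[3];
  int Z = Zo / 2, Y = Yo / 2, X = Xo / 2;
  long plane = (long)Z * Y, volsz = (long)Z * Y * X;
  long oplane = (long)Zo * Yo, ovol = (long)Zo * Yo * Xo;
  NumericVector out((R_xlen_t)(volsz * C));
  out.attr("dim") = IntegerVector::create(Z, Y, X, C);
  double *po = REAL(out), *pg = REAL(g);
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo)
          po[c * volsz + (long)(xo / 2) * plane + (long)(yo / 2) * Z + zo / 2] +=
            pg[c * ovol + (long)xo * oplane + (long)yo * Zo + zo];
  return out;
}

static void sep_axis(const std::vector<double>& in, std::vector<double>& out,
                     int Z, int Y, int X, int axis, const NumericVector& k) {
  int K = k.size(), c = K / 2;
  long plane = (long)Z * Y;
  int n = (axis == 0) ? Z : (axis == 1) ? Y : X;
  long stride = (axis == 0) ? 1 : (axis == 1) ? Z : plane;
  for (int xc = 0; xc < (axis == 2 ? 1 : X); ++xc)
    for (int y = 0; y < (axis == 1 ? 1 : Y); ++y)
      for (int z = 0; z < (axis == 0 ? 1 : Z); ++z) {
        long base;
        if (axis == 0) base = (long)xc * plane + (long)y * Z;
        else if (axis == 1) base = (long)xc * plane + z;
        else base = (long)y * Z + z;
        for (int p = 0; p < n; ++p) {
          double s = 0.0;
          int j0 = std::max(0, c - p), j1 = std::min(K, n - p + c);
          for (int j = j0; j < j1; ++j) s += k[j] * in[base + (long)(p + j - c) * stride];
          out[base + (long)p * stride] = s;
        }
      }
}

// Separable zero-padded 3D convolution of a (Z,Y,X) array with 1D kernels
// per axis (odd lengths, centred).
// [[Rcpp::export]]
NumericVector sepconv3d(NumericVector x, NumericVector kz, NumericVector ky, NumericVector kx) {
  IntegerVector xd = x.attr("dim");
  int Z = xd[0], Y = xd[1], X = xd[2];
  long n = (long)Z * Y * X;
  std::vector<double> a(REAL(x), REAL(x) + n), b(n);
  sep_axis(a, b, Z, Y, X, 0, kz);
  sep_axis(b, a, Z, Y, X, 1, ky);
  sep_axis(a, b, Z, Y, X, 2, kx);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = xd;
  return out;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform.
static void dt1d(std::vector<double>& f, int n, std::vector<int>& v,
                 std::vector<double>& zb, std::vector<double>& d) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact 3D Euclidean distance transform: distance from each nonzero voxel of
// `mask` to the nearest zero voxel (background voxels get 0).
// [[Rcpp::export]]
NumericVector edt3d(NumericVector mask) {
  IntegerVector xd = mask.attr("dim");
  int Z = xd[0], Y = xd[1], X = xd[2];
  long n = (long)Z * Y * X, plane = (long)Z * Y;
  const double INF = 1e20;
  std::vector<double> g(n);
  double *pm = REAL(mask);
  for (long i = 0; i < n; ++i) g[i] = (pm[i] != 0.0) ? INF : 0.0;
  int nmax = std::max(Z, std::max(Y, X));
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1), d(nmax), line(nmax);
  // along z
  for (int xc = 0; xc < X; ++xc)
    for (int y = 0; y < Y; ++y) {
      long base = (long)xc * plane + (long)y * Z;
      for (int z = 0; z < Z; ++z) line[z] = g[base + z];
      dt1d(line, Z, v, zb, d);
      for (int z = 0; z < Z; ++z) g[base + z] = line[z];
    }
  // along y
  for (int xc = 0; xc < X; ++xc)
    for (int z = 0; z < Z; ++z) {
      long base = (long)xc * plane + z;
      for (int y = 0; y < Y; ++y) line[y] = g[base + (long)y * Z];
      dt1d(line, Y, v, zb, d);
      for (int y = 0; y < Y; ++y) g[base + (long)y * Z] = line[y];
    }
  // along x
  for (int y = 0; y < Y; ++y)
    for (int z = 0; z < Z; ++z) {
      long base = (long)y * Z + z;
      for (int xc = 0; xc < X; ++xc) line[xc] = g[base + (long)xc * plane];
      dt1d(line, X, v, zb, d);
      for (int xc = 0; xc < X; ++xc) g[base + (long)xc * plane] = line[xc];
    }
  NumericVector out(n);
  out.attr("dim") = xd;
  double *po = REAL(out);
  for (long i = 0; i < n; ++i) po[i] = std::sqrt(g[i]);
  return out;
}

struct WsNode {
  double prio;
  long order;
  long idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio; // min-heap on priority
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Seeded watershed by priority flooding with 6-connectivity: voxels inside
// `mask` are claimed by the seed region that reaches them first along
// increasing `priority` (use the negative distance transform for the classic
// topographic flooding).
// [[Rcpp::export]]
IntegerVector watershed3d(NumericVector priority, IntegerVector seeds, NumericVector mask) {
  IntegerVector xd = priority.attr("dim");
  int Z = xd[0], Y = xd[1], X = xd[2];
  long n = (long)Z * Y * X, plane = (long)Z * Y;
  IntegerVector lab(n);
  lab.attr("dim") = xd;
  double *pp = REAL(priority), *pm = REAL(mask);
  int *ps = INTEGER(seeds), *pl = INTEGER(lab);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> q;
  long order = 0;
  for (long i = 0; i < n; ++i) {
    pl[i] = 0;
    if (ps[i] > 0 && pm[i] != 0.0) {
      pl[i] = ps[i];
      q.push({pp[i], order++, i});
    }
  }
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    WsNode nd = q.top();
    q.pop();
    long i = nd.idx;
    int z = (int)(i % Z), y = (int)((i / Z) % Y), xc = (int)(i / plane);
    int L = pl[i];
    for (int k = 0; k < 6; ++k) {
      int z2 = z + dz[k], y2 = y + dy[k], x2 = xc + dx[k];
      if (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y || x2 < 0 || x2 >= X) continue;
      long j = (long)x2 * plane + (long)y2 * Z + z2;
      if (pm[j] == 0.0 || pl[j] != 0) continue;
      pl[j] = L;
      q.push({pp[j], order++, j});
    }
  }
  return lab;
}

static void max_axis(std::vector<double>& a, std::vector<double>& b,
                     int Z, int Y, int X, int axis, int r) {
  long plane = (long)Z * Y;
  int n = (axis == 0) ? Z : (axis == 1) ? Y : X;
  long stride = (axis == 0) ? 1 : (axis == 1) ? Z : plane;
  for (int xc = 0; xc < (axis == 2 ? 1 : X); ++xc)
    for (int y = 0; y < (axis == 1 ? 1 : Y); ++y)
      for (int z = 0; z < (axis == 0 ? 1 : Z); ++z) {
        long base;
        if (axis == 0) base = (long)xc * plane + (long)y * Z;
        else if (axis == 1) base = (long)xc * plane + z;
        else base = (long)y * Z + z;
        for (int p = 0; p < n; ++p) {
          double m = -std::numeric_limits<double>::infinity();
          int j0 = std::max(0, p - r), j1 = std::min(n - 1, p + r);
          for (int j = j0; j <= j1; ++j) {
            double v = a[base + (long)j * stride];
            if (v > m) m = v;
          }
          b[base + (long)p * stride] = m;
        }
      }
  a.swap(b);
}

// Separable (box-neighbourhood) maximum filter with radius r per axis.
// [[Rcpp::export]]
NumericVector maxfilter3d(NumericVector x, int r) {
  IntegerVector xd = x.attr("dim");
  int Z = xd[0], Y = xd[1], X = xd[2];
  long n = (long)Z * Y * X;
  std::vector<double> a(REAL(x), REAL(x) + n), b(n);
  max_axis(a, b, Z, Y, X, 0, r);
  max_axis(a, b, Z, Y, X, 1, r);
  max_axis(a, b, Z, Y, X, 2, r);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = xd;
  return out;
}
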