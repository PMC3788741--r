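// Periodic Stokeslet kernels and boundary-integral quadrature helpers.
//
// Conventions: the "A-kernel" is 8 pi mu times the Stokes Green's function,
// i.e. free space A(r) = I/r + r rT / r^3.  The triply periodic kernel uses
// the Hasimoto/Ewald split
//   A_per(r) = sum_p A_R(r + p L)  +  (1/V) sum_{k != 0} B(k) cos(k . r)
//   A_R(r) = 2 (xi e^{-xi^2 r^2}/sqrt(pi) + erfc(xi r)/(2 r)) (I + rh rhT)
//            - (4 xi / sqrt(pi)) e^{-xi^2 r^2} I
//   B(k)  = 8 pi (1 + k^2/(4 xi^2)) e^{-k^2/(4 xi^2)} / k^2 (I - kh khT)
// The solver path evaluates A_per(r) = A_free(r_mi) + T(r_mi) where T is a
// smooth periodic correction tabulated on a regular grid (Fourier part via
// FFT in R, real-space part from ewald_realcorr_grid) and interpolated with
// periodic Catmull-Rom tricubic interpolation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SQRT_PI = 1.7724538509055160273;

struct Mat3 {
  double m[9];  // row-major
  Mat3() { for (int i = 0; i < 9; ++i) m[i] = 0.0; }
  void add(const Mat3 &o) { for (int i = 0; i < 9; ++i) m[i] += o.m[i]; }
};

// Real-space Ewald term for a single image vector r (must be nonzero).
static inline void ewald_real_term(const double *r, double xi, Mat3 &out) {
  double r2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
  double rn = std::sqrt(r2);
  double ex = std::exp(-xi * xi * r2);
  double c1 = 2.0 * (xi * ex / SQRT_PI + std::erfc(xi * rn) / (2.0 * rn));
  double c2 = 4.0 * xi * ex / SQRT_PI;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      double v = c1 * ((a == b ? 1.0 : 0.0) + r[a] * r[b] / r2);
      if (a == b) v -= c2;
      out.m[3 * a + b] += v;
    }
}

static inline void free_space_A(const double *r, Mat3 &out) {
  double r2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
  double rn = std::sqrt(r2);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      out.m[3 * a + b] += (a == b ? 1.0 : 0.0) / rn + r[a] * r[b] / (r2 * rn);
}

// Smooth radial blend: 1 below 0.35 Lmin, 0 above 0.48 Lmin (before any
// minimum-image cut plane at 0.5 L).  The explicit free-space term of the
// pair evaluation is multiplied by chi; the remainder lives in the smooth
// periodic table, which keeps the tabulated function free of the
// minimum-image discontinuity in the off-diagonal components.
static inline double chi_blend(double d, double lmin) {
  double d0 = 0.28 * lmin, d1 = 0.48 * lmin;
  if (d <= d0) return 1.0;
  if (d >= d1) return 0.0;
  double s = (d - d0) / (d1 - d0);
  return 1.0 - s * s * s * (10.0 - 15.0 * s + 6.0 * s * s);
}

// [[Rcpp::export]]
NumericMatrix ewald_stokeslet_cpp(NumericVector rvec, NumericVector box,
                                  double xi, double tol) {
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double rcut = std::sqrt(std::log(1.0 / tol)) / xi + 1e-12;
  double kcut = 2.0 * xi * std::sqrt(std::log(1.0 / tol));
  Mat3 acc;
  int nx = (int)std::ceil((rcut + std::fabs(rvec[0])) / Lx) + 1;
  int ny = (int)std::ceil((rcut + std::fabs(rvec[1])) / Ly) + 1;
  int nz = (int)std::ceil((rcut + std::fabs(rvec[2])) / Lz) + 1;
  for (int ix = -nx; ix <= nx; ++ix)
    for (int iy = -ny; iy <= ny; ++iy)
      for (int iz = -nz; iz <= nz; ++iz) {
        double rr[3] = {rvec[0] + ix * Lx, rvec[1] + iy * Ly,
                        rvec[2] + iz * Lz};
        double rn = std::sqrt(rr[0] * rr[0] + rr[1] * rr[1] + rr[2] * rr[2]);
        if (rn < 1e-12) stop("ewald_stokeslet: r is a lattice vector");
        if (rn > rcut + 1e-12) continue;
        ewald_real_term(rr, xi, acc);
      }
  // Fourier sum
  double V = Lx * Ly * Lz;
  double dkx = 2.0 * M_PI / Lx, dky = 2.0 * M_PI / Ly, dkz = 2.0 * M_PI / Lz;
  int mx = (int)std::ceil(kcut / dkx), my = (int)std::ceil(kcut / dky),
      mz = (int)std::ceil(kcut / dkz);
  for (int ix = -mx; ix <= mx; ++ix)
    for (int iy = -my; iy <= my; ++iy)
      for (int iz = -mz; iz <= mz; ++iz) {
        if (ix == 0 && iy == 0 && iz == 0) continue;
        double kx = ix * dkx, ky = iy * dky, kz = iz * dkz;
        double k2 = kx * kx + ky * ky + kz * kz;
        if (k2 > kcut * kcut) continue;
        double g = 8.0 * M_PI * (1.0 + k2 / (4.0 * xi * xi)) *
                   std::exp(-k2 / (4.0 * xi * xi)) / k2;
        double cosk = std::cos(kx * rvec[0] + ky * rvec[1] + kz * rvec[2]);
        double kh[3] = {kx, ky, kz};
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            acc.m[3 * a + b] += (g * cosk / V) *
              ((a == b ? 1.0 : 0.0) - kh[a] * kh[b] / k2);
      }
  NumericMatrix out(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) out(a, b) = acc.m[3 * a + b];
  return out;
}

// Real-space part of the periodic correction on a regular grid covering
// [0,Lx) x [0,Ly) x [0,Lz): sum of A_R over images within the cutoff minus
// the free-space kernel at the minimum image.  Column order
// xx, xy, xz, yy, yz, zz; grid index ix fastest.
// [[Rcpp::export]]
NumericMatrix ewald_realcorr_grid_cpp(IntegerVector dims, NumericVector box,
                                      double xi, double tol) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double rcut = std::sqrt(std::log(1.0 / tol)) / xi;
  int px = (int)std::ceil(rcut / Lx) + 1, py = (int)std::ceil(rcut / Ly) + 1,
      pz = (int)std::ceil(rcut / Lz) + 1;
  NumericMatrix out((R_xlen_t)nx * ny * nz, 6);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        double r0[3] = {ix * Lx / nx, iy * Ly / ny, iz * Lz / nz};
        double rmi[3] = {r0[0] - Lx * std::round(r0[0] / Lx),
                         r0[1] - Ly * std::round(r0[1] / Ly),
                         r0[2] - Lz * std::round(r0[2] / Lz)};
        double rmin = std::sqrt(rmi[0] * rmi[0] + rmi[1] * rmi[1] +
                                rmi[2] * rmi[2]);
        Mat3 acc;
        for (int jx = -px; jx <= px; ++jx)
          for (int jy = -py; jy <= py; ++jy)
            for (int jz = -pz; jz <= pz; ++jz) {
              double rr[3] = {r0[0] + jx * Lx, r0[1] + jy * Ly,
                              r0[2] + jz * Lz};
              double rn = std::sqrt(rr[0] * rr[0] + rr[1] * rr[1] +
                                    rr[2] * rr[2]);
              if (rn > rcut) continue;
              if (rn < 1e-10) {
                // singular image coincides with the min image: the
                // difference A_R - A_free has the finite limit -4 xi/sqrt(pi) I
                for (int a = 0; a < 3; ++a)
                  acc.m[3 * a + a] += -4.0 * xi / SQRT_PI;
                continue;
              }
              ewald_real_term(rr, xi, acc);
            }
        if (rmin >= 1e-10) {
          double lmin = std::min(Lx, std::min(Ly, Lz));
          double ch = chi_blend(rmin, lmin);
          if (ch > 0) {
            Mat3 fs;
            free_space_A(rmi, fs);
            for (int i = 0; i < 9; ++i) acc.m[i] -= ch * fs.m[i];
          }
        }
        R_xlen_t g = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        out(g, 0) = acc.m[0]; out(g, 1) = acc.m[1]; out(g, 2) = acc.m[2];
        out(g, 3) = acc.m[4]; out(g, 4) = acc.m[5]; out(g, 5) = acc.m[8];
      }
  return out;
}

// ---- periodic Catmull-Rom tricubic interpolation of the 6-component table
struct Table {
  const double *data;  // column-major (npts x 6)
  int nx, ny, nz;
  double Lx, Ly, Lz;
  R_xlen_t npts;
};

static inline void cr_weights(double t, double *w) {
  w[0] = -0.5 * t + t * t - 0.5 * t * t * t;
  w[1] = 1.0 - 2.5 * t * t + 1.5 * t * t * t;
  w[2] = 0.5 * t + 2.0 * t * t - 1.5 * t * t * t;
  w[3] = -0.5 * t * t + 0.5 * t * t * t;
}

static inline void table_eval(const Table &tb, const double *r, double *six) {
  double u = r[0] / (tb.Lx / tb.nx);
  double v = r[1] / (tb.Ly / tb.ny);
  double w = r[2] / (tb.Lz / tb.nz);
  u -= tb.nx * std::floor(u / tb.nx);
  v -= tb.ny * std::floor(v / tb.ny);
  w -= tb.nz * std::floor(w / tb.nz);
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
  double wu[4], wv[4], ww[4];
  cr_weights(u - i0, wu); cr_weights(v - j0, wv); cr_weights(w - k0, ww);
  int ii[4], jj[4], kk[4];
  for (int s = 0; s < 4; ++s) {
    ii[s] = (i0 - 1 + s + 4 * tb.nx) % tb.nx;
    jj[s] = (j0 - 1 + s + 4 * tb.ny) % tb.ny;
    kk[s] = (k0 - 1 + s + 4 * tb.nz) % tb.nz;
  }
  for (int c = 0; c < 6; ++c) six[c] = 0.0;
  for (int sz = 0; sz < 4; ++sz)
    for (int sy = 0; sy < 4; ++sy) {
      double wyz = wv[sy] * ww[sz];
      R_xlen_t base = (R_xlen_t)tb.nx * (jj[sy] + (R_xlen_t)tb.ny * kk[sz]);
      for (int sx = 0; sx < 4; ++sx) {
        double wt = wu[sx] * wyz;
        R_xlen_t g = base + ii[sx];
        const double *d = tb.data;
        six[0] += wt * d[g];
        six[1] += wt * d[g + tb.npts];
        six[2] += wt * d[g + 2 * tb.npts];
        six[3] += wt * d[g + 3 * tb.npts];
        six[4] += wt * d[g + 4 * tb.npts];
        six[5] += wt * d[g + 5 * tb.npts];
      }
    }
}

static Table make_table(NumericMatrix table, IntegerVector dims,
                        NumericVector box) {
  Table tb;
  tb.data = REAL(table);
  tb.nx = dims[0]; tb.ny = dims[1]; tb.nz = dims[2];
  tb.Lx = box[0]; tb.Ly = box[1]; tb.Lz = box[2];
  tb.npts = (R_xlen_t)tb.nx * tb.ny * tb.nz;
  return tb;
}

// Periodic kernel at separation r (min image applied internally):
// A_per = A_free(r_mi) + T(r).  skip_free suppresses the free-space part
// (used for coincident points whose singular part is handled elsewhere).
static inline void kernel_eval(const Table &tb, const double *rraw,
                               bool skip_free, double *blk) {
  double r[3] = {rraw[0], rraw[1], rraw[2]};
  double six[6];
  table_eval(tb, r, six);
  double rmi[3] = {r[0] - tb.Lx * std::round(r[0] / tb.Lx),
                   r[1] - tb.Ly * std::round(r[1] / tb.Ly),
                   r[2] - tb.Lz * std::round(r[2] / tb.Lz)};
  Mat3 a;
  a.m[0] = six[0]; a.m[1] = six[1]; a.m[2] = six[2];
  a.m[3] = six[1]; a.m[4] = six[3]; a.m[5] = six[4];
  a.m[6] = six[2]; a.m[7] = six[4]; a.m[8] = six[5];
  double rn2 = rmi[0] * rmi[0] + rmi[1] * rmi[1] + rmi[2] * rmi[2];
  if (!skip_free && rn2 > 1e-20) {
    double lmin = std::min(tb.Lx, std::min(tb.Ly, tb.Lz));
    double ch = chi_blend(std::sqrt(rn2), lmin);
    if (ch > 0) {
      Mat3 fs;
      free_space_A(rmi, fs);
      for (int i = 0; i < 9; ++i) a.m[i] += ch * fs.m[i];
    }
  }
  for (int i = 0; i < 9; ++i) blk[i] = a.m[i];
}

// Dense single-layer matrix: velocities at targets from per-vertex density
// at sources with lumped quadrature weights.  Output (3 nt) x (3 ns), row
// blocks per target.  same_mesh: diagonal free-space part omitted.
// [[Rcpp::export]]
NumericMatrix sl_matrix_cpp(NumericMatrix tgt, NumericMatrix src,
                            NumericVector wsrc, NumericVector box,
                            NumericMatrix table, IntegerVector dims,
                            double mu, bool same_mesh) {
  Table tb = make_table(table, dims, box);
  int nt = tgt.nrow(), ns = src.nrow();
  NumericMatrix out(3 * nt, 3 * ns);
  double pref = 1.0 / (8.0 * M_PI * mu);
  for (int j = 0; j < ns; ++j) {
    double wj = wsrc[j] * pref;
    for (int i = 0; i < nt; ++i) {
      double r[3] = {tgt(i, 0) - src(j, 0), tgt(i, 1) - src(j, 1),
                     tgt(i, 2) - src(j, 2)};
      bool self = same_mesh && (i == j);
      double blk[9];
      kernel_eval(tb, r, self, blk);
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          out(3 * i + a, 3 * j + b) = blk[3 * a + b] * wj;
    }
  }
  return out;
}

// Matrix-free apply of the same operator: f is (ns x 3) density; returns
// (nt x 3) velocities.
// [[Rcpp::export]]
NumericMatrix sl_apply_cpp(NumericMatrix tgt, NumericMatrix src,
                           NumericVector wsrc, NumericMatrix fdens,
                           NumericVector box, NumericMatrix table,
                           IntegerVector dims, double mu, bool same_mesh) {
  Table tb = make_table(table, dims, box);
  int nt = tgt.nrow(), ns = src.nrow();
  NumericMatrix out(nt, 3);
  double pref = 1.0 / (8.0 * M_PI * mu);
  for (int i = 0; i < nt; ++i) {
    double acc[3] = {0, 0, 0};
    for (int j = 0; j < ns; ++j) {
      double r[3] = {tgt(i, 0) - src(j, 0), tgt(i, 1) - src(j, 1),
                     tgt(i, 2) - src(j, 2)};
      bool self = same_mesh && (i == j);
      double blk[9];
      kernel_eval(tb, r, self, blk);
      double wj = wsrc[j] * pref;
      double fj[3] = {fdens(j, 0), fdens(j, 1), fdens(j, 2)};
      for (int a = 0; a < 3; ++a)
        acc[a] += wj * (blk[3 * a] * fj[0] + blk[3 * a + 1] * fj[1] +
                        blk[3 * a + 2] * fj[2]);
    }
    out(i, 0) = acc[0]; out(i, 1) = acc[1]; out(i, 2) = acc[2];
  }
  return out;
}

// ---- singular / near-singular corrections --------------------------------
// The base matrix uses lumped vertex quadrature of the free-space part.
// For (target, triangle) pairs that are close, that is replaced by a proper
// integral of A_free times the linear shape functions: Duffy-type polar
// quadrature when the target is a vertex of the triangle, adaptive
// subdivision otherwise.  Returned as triplets
// (target index, source vertex index, 3x3 block of *added* correction,
// already including removal of the lumped share), scaled by 1/(8 pi mu).

struct Trip { int i, j; double blk[9]; };

static void add_trip(std::vector<Trip> &trips, int i, int j,
                     const double *blk) {
  Trip t; t.i = i; t.j = j;
  for (int c = 0; c < 9; ++c) t.blk[c] = blk[c];
  trips.push_back(t);
}

// 8-point Gauss-Legendre nodes/weights on [0,1]
static const double GL8X[8] = {0.0198550717512319, 0.1016667612931866,
  0.2372337950418355, 0.4082826787521751, 0.5917173212478249,
  0.7627662049581645, 0.8983332387068134, 0.9801449282487681};
static const double GL8W[8] = {0.0506142681451881, 0.1111905172266872,
  0.1568533229389437, 0.1813418916891810, 0.1813418916891810,
  0.1568533229389437, 0.1111905172266872, 0.0506142681451881};

// Singular integral over triangle (P0 singular vertex): returns 3 blocks
// (for shape functions of P0, P1, P2), each 3x3, NOT weight-scaled.
static void duffy_integral(const double *x, const double *P0,
                           const double *P1, const double *P2,
                           double blk0[9], double blk1[9], double blk2[9]) {
  double e1[3] = {P1[0] - P0[0], P1[1] - P0[1], P1[2] - P0[2]};
  double e2[3] = {P2[0] - P0[0], P2[1] - P0[1], P2[2] - P0[2]};
  double cr[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                  e1[2] * e2[0] - e1[0] * e2[2],
                  e1[0] * e2[1] - e1[1] * e2[0]};
  double twoA = std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
  for (int c = 0; c < 9; ++c) { blk0[c] = 0; blk1[c] = 0; blk2[c] = 0; }
  for (int a = 0; a < 8; ++a) {
    double rho = GL8X[a];
    for (int b = 0; b < 8; ++b) {
      double s = GL8X[b];
      double u = rho * (1.0 - s), v = rho * s;
      double y[3] = {P0[0] + u * e1[0] + v * e2[0],
                     P0[1] + u * e1[1] + v * e2[1],
                     P0[2] + u * e1[2] + v * e2[2]};
      double r[3] = {x[0] - y[0], x[1] - y[1], x[2] - y[2]};
      Mat3 g;
      free_space_A(r, g);
      double wq = GL8W[a] * GL8W[b] * twoA * rho;
      double n0 = 1.0 - rho, n1 = u, n2 = v;
      for (int c = 0; c < 9; ++c) {
        blk0[c] += wq * n0 * g.m[c];
        blk1[c] += wq * n1 * g.m[c];
        blk2[c] += wq * n2 * g.m[c];
      }
    }
  }
}

// 6-point degree-4 rule in barycentric coordinates
static const double TRI6[6][3] = {
  {0.10810301816807, 0.44594849091597, 0.44594849091597},
  {0.44594849091597, 0.10810301816807, 0.44594849091597},
  {0.44594849091597, 0.44594849091597, 0.10810301816807},
  {0.81684757298046, 0.09157621350977, 0.09157621350977},
  {0.09157621350977, 0.81684757298046, 0.09157621350977},
  {0.09157621350977, 0.09157621350977, 0.81684757298046}};
static const double TRI6W[6] = {0.22338158967801, 0.22338158967801,
  0.22338158967801, 0.10995174365532, 0.10995174365532, 0.10995174365532};

// Adaptive near-singular quadrature; bary rows are the barycentric coords
// (w.r.t. the ORIGINAL triangle) of the current subtriangle corners.
static void near_quad(const double *x, const double P[3][3],
                      const double bary[3][3], int depth, int max_depth,
                      double blk[3][9]) {
  double c0[3], c1[3], c2[3];
  for (int d = 0; d < 3; ++d) {
    c0[d] = bary[0][0] * P[0][d] + bary[0][1] * P[1][d] + bary[0][2] * P[2][d];
    c1[d] = bary[1][0] * P[0][d] + bary[1][1] * P[1][d] + bary[1][2] * P[2][d];
    c2[d] = bary[2][0] * P[0][d] + bary[2][1] * P[1][d] + bary[2][2] * P[2][d];
  }
  double cen[3] = {(c0[0] + c1[0] + c2[0]) / 3, (c0[1] + c1[1] + c2[1]) / 3,
                   (c0[2] + c1[2] + c2[2]) / 3};
  double dx = x[0] - cen[0], dy = x[1] - cen[1], dz = x[2] - cen[2];
  double dist2 = dx * dx + dy * dy + dz * dz;
  double e01 = 0, e12 = 0, e02 = 0;
  for (int d = 0; d < 3; ++d) {
    e01 += (c1[d] - c0[d]) * (c1[d] - c0[d]);
    e12 += (c2[d] - c1[d]) * (c2[d] - c1[d]);
    e02 += (c2[d] - c0[d]) * (c2[d] - c0[d]);
  }
  double size2 = std::max(e01, std::max(e12, e02));
  if (depth < max_depth && size2 > 0.5625 * dist2) {  // size > 0.75 dist
    double m01[3], m12[3], m02[3];
    for (int c = 0; c < 3; ++c) {
      m01[c] = 0.5 * (bary[0][c] + bary[1][c]);
      m12[c] = 0.5 * (bary[1][c] + bary[2][c]);
      m02[c] = 0.5 * (bary[0][c] + bary[2][c]);
    }
    double sub[4][3][3];
    for (int c = 0; c < 3; ++c) {
      sub[0][0][c] = bary[0][c]; sub[0][1][c] = m01[c]; sub[0][2][c] = m02[c];
      sub[1][0][c] = m01[c]; sub[1][1][c] = bary[1][c]; sub[1][2][c] = m12[c];
      sub[2][0][c] = m02[c]; sub[2][1][c] = m12[c]; sub[2][2][c] = bary[2][c];
      sub[3][0][c] = m01[c]; sub[3][1][c] = m12[c]; sub[3][2][c] = m02[c];
    }
    for (int ssub = 0; ssub < 4; ++ssub)
      near_quad(x, P, sub[ssub], depth + 1, max_depth, blk);
    return;
  }
  double u1[3] = {c1[0] - c0[0], c1[1] - c0[1], c1[2] - c0[2]};
  double u2[3] = {c2[0] - c0[0], c2[1] - c0[1], c2[2] - c0[2]};
  double cr[3] = {u1[1] * u2[2] - u1[2] * u2[1],
                  u1[2] * u2[0] - u1[0] * u2[2],
                  u1[0] * u2[1] - u1[1] * u2[0]};
  double area = 0.5 * std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
  for (int q = 0; q < 6; ++q) {
    double l0 = TRI6[q][0], l1 = TRI6[q][1], l2 = TRI6[q][2];
    double borig[3], y[3];
    for (int c = 0; c < 3; ++c)
      borig[c] = l0 * bary[0][c] + l1 * bary[1][c] + l2 * bary[2][c];
    for (int d = 0; d < 3; ++d)
      y[d] = borig[0] * P[0][d] + borig[1] * P[1][d] + borig[2] * P[2][d];
    double r[3] = {x[0] - y[0], x[1] - y[1], x[2] - y[2]};
    Mat3 g;
    free_space_A(r, g);
    double wq = TRI6W[q] * area;
    for (int vtx = 0; vtx < 3; ++vtx)
      for (int c = 0; c < 9; ++c)
        blk[vtx][c] += wq * borig[vtx] * g.m[c];
  }
}

// Near/singular corrections for single-layer quadrature.
// tgt: targets; verts/tris: source mesh; tgt_vertex: for each target, the
// 1-based index of the coincident source vertex (0 if none).  box gives the
// periodic cell (triangles are shifted to the target's minimum image).
// near_factor: triangles with centroid distance < near_factor * longest
// edge get the accurate treatment.  Output: (i, j, 9 block entries) rows,
// block scaled by 1/(8 pi mu) and *including* subtraction of the lumped
// free-space term the base matrix carries.
// [[Rcpp::export]]
NumericMatrix near_corr_cpp(NumericMatrix tgt, IntegerVector tgt_vertex,
                            NumericMatrix verts, IntegerMatrix tris,
                            NumericVector box, double mu,
                            double near_factor, int max_depth) {
  int nt = tgt.nrow(), nf = tris.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double pref = 1.0 / (8.0 * M_PI * mu);
  std::vector<Trip> trips;
  for (int f = 0; f < nf; ++f) {
    int v0 = tris(f, 0) - 1, v1 = tris(f, 1) - 1, v2 = tris(f, 2) - 1;
    double P[3][3];
    for (int d = 0; d < 3; ++d) {
      P[0][d] = verts(v0, d); P[1][d] = verts(v1, d); P[2][d] = verts(v2, d);
    }
    // unwrap the triangle about its first vertex (periodic meshes)
    for (int k = 1; k < 3; ++k) {
      P[k][0] -= Lx * std::round((P[k][0] - P[0][0]) / Lx);
      P[k][1] -= Ly * std::round((P[k][1] - P[0][1]) / Ly);
      P[k][2] -= Lz * std::round((P[k][2] - P[0][2]) / Lz);
    }
    double cen[3] = {(P[0][0] + P[1][0] + P[2][0]) / 3,
                     (P[0][1] + P[1][1] + P[2][1]) / 3,
                     (P[0][2] + P[1][2] + P[2][2]) / 3};
    double e2 = 0;
    for (int a = 0; a < 3; ++a)
      for (int bnd = a + 1; bnd < 3; ++bnd) {
        double s = 0;
        for (int d = 0; d < 3; ++d)
          s += (P[a][d] - P[bnd][d]) * (P[a][d] - P[bnd][d]);
        if (s > e2) e2 = s;
      }
    double rad2 = near_factor * near_factor * e2;
    double u1[3] = {P[1][0] - P[0][0], P[1][1] - P[0][1], P[1][2] - P[0][2]};
    double u2[3] = {P[2][0] - P[0][0], P[2][1] - P[0][1], P[2][2] - P[0][2]};
    double crx[3] = {u1[1] * u2[2] - u1[2] * u2[1],
                     u1[2] * u2[0] - u1[0] * u2[2],
                     u1[0] * u2[1] - u1[1] * u2[0]};
    double area = 0.5 * std::sqrt(crx[0] * crx[0] + crx[1] * crx[1] +
                                  crx[2] * crx[2]);
    int vidx[3] = {v0, v1, v2};
    for (int i = 0; i < nt; ++i) {
      // shift triangle to the target's minimum image
      double sh[3];
      sh[0] = Lx * std::round((tgt(i, 0) - cen[0]) / Lx);
      sh[1] = Ly * std::round((tgt(i, 1) - cen[1]) / Ly);
      sh[2] = Lz * std::round((tgt(i, 2) - cen[2]) / Lz);
      double dx = tgt(i, 0) - (cen[0] + sh[0]);
      double dy = tgt(i, 1) - (cen[1] + sh[1]);
      double dz = tgt(i, 2) - (cen[2] + sh[2]);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > rad2) continue;
      double Ps[3][3];
      for (int k = 0; k < 3; ++k)
        for (int d = 0; d < 3; ++d) Ps[k][d] = P[k][d] + sh[d];
      double x[3] = {tgt(i, 0), tgt(i, 1), tgt(i, 2)};
      int tv = tgt_vertex[i] - 1;  // coincident source vertex, or -1
      int sing = -1;
      for (int k = 0; k < 3; ++k) if (vidx[k] == tv) sing = k;
      double blk[3][9];
      for (int k = 0; k < 3; ++k)
        for (int c = 0; c < 9; ++c) blk[k][c] = 0;
      if (sing >= 0) {
        int o1 = (sing + 1) % 3, o2 = (sing + 2) % 3;
        double b0[9], b1[9], b2[9];
        duffy_integral(x, Ps[sing], Ps[o1], Ps[o2], b0, b1, b2);
        for (int c = 0; c < 9; ++c) {
          blk[sing][c] = b0[c]; blk[o1][c] = b1[c]; blk[o2][c] = b2[c];
        }
      } else {
        double bary0[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        near_quad(x, Ps, bary0, 0, max_depth, blk);
      }
      // subtract the lumped share already present in the base matrix
      for (int k = 0; k < 3; ++k) {
        if (vidx[k] != tv) {
          double r[3] = {x[0] - Ps[k][0], x[1] - Ps[k][1], x[2] - Ps[k][2]};
          Mat3 g;
          free_space_A(r, g);
          for (int c = 0; c < 9; ++c) blk[k][c] -= (area / 3.0) * g.m[c];
        }
        double scaled[9];
        for (int c = 0; c < 9; ++c) scaled[c] = blk[k][c] * pref;
        add_trip(trips, i, vidx[k], scaled);
      }
    }
  }
  NumericMatrix out((int)trips.size(), 11);
  for (size_t t = 0; t < trips.size(); ++t) {
    out(t, 0) = trips[t].i + 1;
    out(t, 1) = trips[t].j + 1;
    for (int c = 0; c < 9; ++c) out(t, 2 + c) = trips[t].blk[c];
  }
  return out;
}

// ---- point-to-mesh distances ---------------------------------------------

static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double best[3];
  if (d1 <= 0 && d2 <= 0) { best[0] = a[0]; best[1] = a[1]; best[2] = a[2]; }
  else {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) { best[0] = b[0]; best[1] = b[1]; best[2] = b[2]; }
    else {
      double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
      double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
      double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
      double vc = d1 * d4 - d3 * d2;
      double vb = d5 * d2 - d1 * d6;
      double va = d3 * d6 - d5 * d4;
      if (d6 >= 0 && d5 <= d6) { best[0] = c[0]; best[1] = c[1]; best[2] = c[2]; }
      else if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double t = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) best[k] = a[k] + t * ab[k];
      } else if (vb <= 0 && d2 >= 0 && d6 <= 0) {
        double t = d2 / (d2 - d6);
        for (int k = 0; k < 3; ++k) best[k] = a[k] + t * ac[k];
      } else if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
        double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int k = 0; k < 3; ++k) best[k] = b[k] + t * (c[k] - b[k]);
      } else {
        double denom = 1.0 / (va + vb + vc);
        double v = vb * denom, wq = vc * denom;
        for (int k = 0; k < 3; ++k)
          best[k] = a[k] + ab[k] * v + ac[k] * wq;
      }
    }
  }
  double dx = p[0] - best[0], dy = p[1] - best[1], dz = p[2] - best[2];
  return dx * dx + dy * dy + dz * dz;
}

// Minimum distance from each point to a triangulated surface; if period_z
// > 0 the mesh is treated as z-periodic.
// [[Rcpp::export]]
NumericVector point_mesh_distance_cpp(NumericMatrix pts, NumericMatrix verts,
                                      IntegerMatrix tris, double period_z) {
  int np = pts.nrow(), nf = tris.nrow();
  NumericVector out(np);
  std::vector<double> tv(9 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int v = tris(f, k) - 1;
      for (int d = 0; d < 3; ++d) tv[9 * f + 3 * k + d] = verts(v, d);
    }
    if (period_z > 0) {  // unwrap about first vertex
      for (int k = 1; k < 3; ++k) {
        double &z = tv[9 * f + 3 * k + 2];
        z -= period_z * std::round((z - tv[9 * f + 2]) / period_z);
      }
    }
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const double *a = &tv[9 * f], *b = &tv[9 * f + 3], *c = &tv[9 * f + 6];
      if (period_z > 0) {
        double cenz = (a[2] + b[2] + c[2]) / 3.0;
        double sh = period_z * std::round((p[2] - cenz) / period_z);
        double as[3] = {a[0], a[1], a[2] + sh};
        double bs[3] = {b[0], b[1], b[2] + sh};
        double cs[3] = {c[0], c[1], c[2] + sh};
        double d2 = point_tri_dist2(p, as, bs, cs);
        if (d2 < best) best = d2;
      } else {
        double d2 = point_tri_dist2(p, a, b, c);
        if (d2 < best) best = d2;
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
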