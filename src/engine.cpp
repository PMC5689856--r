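// Computational kernels of the dose engine: trilinear sampling, Siddon
// radiological path integrals, TERMA ray casting, collapsed-cone
// superposition, and gamma-index search. Geometry convention everywhere:
// mm, voxel centers at origin + index * spacing, x-fastest storage.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

struct Geom {
  int nx, ny, nz;
  double sx, sy, sz;   // spacing
  double ox, oy, oz;   // first voxel center
};

static Geom make_geom(const NumericVector& vals, const NumericVector& spacing,
                      const NumericVector& origin) {
  IntegerVector d = vals.attr("dim");
  Geom g;
  g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  return g;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// trilinear sample; returns NA outside unless clamp
static double trilinear(const double* v, const Geom& g,
                        double x, double y, double z, bool clamp) {
  double fx = (x - g.ox) / g.sx, fy = (y - g.oy) / g.sy,
         fz = (z - g.oz) / g.sz;
  if (!clamp && (fx < 0 || fy < 0 || fz < 0 ||
                 fx > g.nx - 1 || fy > g.ny - 1 || fz > g.nz - 1))
    return NA_REAL;
  fx = std::min(std::max(fx, 0.0), (double)(g.nx - 1));
  fy = std::min(std::max(fy, 0.0), (double)(g.ny - 1));
  fz = std::min(std::max(fz, 0.0), (double)(g.nz - 1));
  int i0 = std::min((int)fx, g.nx - 2 >= 0 ? g.nx - 2 : 0);
  int j0 = std::min((int)fy, g.ny - 2 >= 0 ? g.ny - 2 : 0);
  int k0 = std::min((int)fz, g.nz - 2 >= 0 ? g.nz - 2 : 0);
  if (g.nx == 1) i0 = 0;
  if (g.ny == 1) j0 = 0;
  if (g.nz == 1) k0 = 0;
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  int i1 = clampi(i0 + 1, 0, g.nx - 1), j1 = clampi(j0 + 1, 0, g.ny - 1),
      k1 = clampi(k0 + 1, 0, g.nz - 1);
  auto at = [&](int i, int j, int k) {
    return v[i + g.nx * (j + (long)g.ny * k)];
  };
  double c00 = at(i0, j0, k0) * (1 - tx) + at(i1, j0, k0) * tx;
  double c10 = at(i0, j1, k0) * (1 - tx) + at(i1, j1, k0) * tx;
  double c01 = at(i0, j0, k1) * (1 - tx) + at(i1, j0, k1) * tx;
  double c11 = at(i0, j1, k1) * (1 - tx) + at(i1, j1, k1) * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, NumericVector spacing,
                            NumericVector origin, NumericMatrix points,
                            bool clamp) {
  Geom g = make_geom(values, spacing, origin);
  int n = points.nrow();
  NumericVector out(n);
  const double* v = values.begin();
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(v, g, points(i, 0), points(i, 1), points(i, 2), clamp);
  return out;
}

// intersection of ray p + t*d (t in mm, d unit) with the voxel-boundary box
static bool box_clip(const Geom& g, const double p[3], const double d[3],
                     double& t0, double& t1) {
  double lo[3] = {g.ox - 0.5 * g.sx, g.oy - 0.5 * g.sy, g.oz - 0.5 * g.sz};
  double hi[3] = {g.ox + (g.nx - 0.5) * g.sx, g.oy + (g.ny - 0.5) * g.sy,
                  g.oz + (g.nz - 0.5) * g.sz};
  t0 = 0.0; t1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] < lo[a] || p[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - p[a]) / d[a], tb = (hi[a] - p[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  return t1 > t0;
}

// Siddon-style exact traversal: calls f(voxel_index, seg_len, t_mid) per
// crossed voxel
template <typename F>
static void siddon_walk(const Geom& g, const double p[3], const double d[3],
                        double t0, double t1, F&& f) {
  double t = t0;
  double pos[3] = {p[0] + t * d[0], p[1] + t * d[1], p[2] + t * d[2]};
  double sp[3] = {g.sx, g.sy, g.sz};
  double org[3] = {g.ox, g.oy, g.oz};
  int n[3] = {g.nx, g.ny, g.nz};
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    idx[a] = (int)std::floor((pos[a] - (org[a] - 0.5 * sp[a])) / sp[a]);
    idx[a] = clampi(idx[a], 0, n[a] - 1);
  }
  double tnext[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 1e-12) {
      step[a] = 1;
      double bound = org[a] + (idx[a] + 0.5) * sp[a];
      tnext[a] = t + (bound - pos[a]) / d[a];
    } else if (d[a] < -1e-12) {
      step[a] = -1;
      double bound = org[a] + (idx[a] - 0.5) * sp[a];
      tnext[a] = t + (bound - pos[a]) / d[a];
    } else {
      step[a] = 0;
      tnext[a] = std::numeric_limits<double>::infinity();
    }
  }
  while (t < t1 - 1e-9) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    double tstop = std::min(tnext[a], t1);
    double len = tstop - t;
    if (len > 1e-12) {
      long vi = idx[0] + (long)g.nx * (idx[1] + (long)g.ny * idx[2]);
      f(vi, len, 0.5 * (t + tstop));
    }
    if (tstop >= t1 - 1e-9) break;
    t = tnext[a];
    tnext[a] += sp[a] / std::fabs(d[a]);
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= n[a]) break;
  }
}

// [[Rcpp::export]]
double cpp_radiological_path(NumericVector density, NumericVector spacing,
                             NumericVector origin, NumericVector src,
                             NumericVector dst) {
  Geom g = make_geom(density, spacing, origin);
  double p[3] = {src[0], src[1], src[2]};
  double dvec[3] = {dst[0] - src[0], dst[1] - src[1], dst[2] - src[2]};
  double L = std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] +
                       dvec[2] * dvec[2]);
  if (L < 1e-12) return 0.0;
  double d[3] = {dvec[0] / L, dvec[1] / L, dvec[2] / L};
  double t0, t1;
  if (!box_clip(g, p, d, t0, t1)) return 0.0;
  t1 = std::min(t1, L);
  if (t1 <= t0) return 0.0;
  const double* rho = density.begin();
  double acc = 0.0;
  siddon_walk(g, p, d, t0, t1, [&](long vi, double len, double) {
    acc += rho[vi] * len;
  });
  return acc;
}

// Polyenergetic TERMA ray casting from a fluence plane.
// rays: n x 3 world positions of fluence pixels (on the isocenter plane);
// wp/we/wc: per-ray primary/extrafocal/contamination channel weights;
// pw/ew: 16-bin spectrum weights; eb: bin energies (MeV); mu_mm: water
// attenuation per mm at unit ED per bin; rel: ED-lookup table
// (n_lut x 16) of mass attenuation (release) coefficients; ed_lut_max:
// ED of the last LUT row. Deposits path-length-weighted point TERMA,
// TERMA-weighted mean energy, and the contamination surface channel.
// [[Rcpp::export]]
List cpp_terma_raycast(NumericVector density, NumericVector spacing,
                       NumericVector origin, NumericMatrix rays,
                       NumericVector wp, NumericVector we, NumericVector wc,
                       NumericVector pw, NumericVector ew, NumericVector eb,
                       NumericVector mu_mm, NumericMatrix rel,
                       double ed_lut_max, NumericVector source,
                       bool parallel, NumericVector beam_dir, double sad,
                       bool inv_sq, double contam_tau) {
  Geom g = make_geom(density, spacing, origin);
  const double* rho = density.begin();
  long nvox = (long)g.nx * g.ny * g.nz;
  std::vector<double> num(nvox, 0.0), den(nvox, 0.0), nume(nvox, 0.0),
      cont(nvox, 0.0);
  int nb = pw.size();
  int n_lut = rel.nrow();
  int nray = rays.nrow();

  for (int r = 0; r < nray; ++r) {
    double wpr = wp[r], wer = we[r], wcr = wc[r];
    if (wpr <= 0 && wer <= 0 && wcr <= 0) continue;
    double p[3], d[3];
    if (parallel) {
      d[0] = beam_dir[0]; d[1] = beam_dir[1]; d[2] = beam_dir[2];
      p[0] = rays(r, 0) - 2000.0 * d[0];
      p[1] = rays(r, 1) - 2000.0 * d[1];
      p[2] = rays(r, 2) - 2000.0 * d[2];
    } else {
      p[0] = source[0]; p[1] = source[1]; p[2] = source[2];
      double v[3] = {rays(r, 0) - p[0], rays(r, 1) - p[1], rays(r, 2) - p[2]};
      double L = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
      d[0] = v[0] / L; d[1] = v[1] / L; d[2] = v[2] / L;
    }
    double t0, t1;
    if (!box_clip(g, p, d, t0, t1)) continue;
    double dwe = 0.0;
    siddon_walk(g, p, d, t0, t1, [&](long vi, double len, double tmid) {
      double ed = rho[vi];
      double dmid = dwe + 0.5 * ed * len;
      double isq = 1.0;
      if (inv_sq && !parallel) {
        double ratio = sad / tmid;
        isq = ratio * ratio;
      }
      // release coefficients by ED lookup (row 1..n_lut spans 0..ed_lut_max)
      double f = ed / ed_lut_max * (n_lut - 1);
      int li = clampi((int)f, 0, n_lut - 2);
      double lw = std::min(std::max(f - li, 0.0), 1.0);
      if (n_lut == 1) { li = 0; lw = 0.0; }
      double sumc = 0.0, sumce = 0.0;
      if (wpr > 0 || wer > 0) {
        for (int b = 0; b < nb; ++b) {
          double w = wpr * pw[b] + wer * ew[b];
          if (w <= 0) continue;
          double relb = (n_lut == 1) ? rel(0, b)
            : rel(li, b) * (1 - lw) + rel(li + 1, b) * lw;
          double c = w * std::exp(-mu_mm[b] * dmid) * relb * eb[b];
          sumc += c;
          sumce += c * eb[b];
        }
      }
      num[vi] += sumc * isq * len;
      nume[vi] += sumce * isq * len;
      den[vi] += len;
      if (wcr > 0)
        cont[vi] += wcr * std::exp(-dmid / contam_tau) * isq * len;
      dwe += ed * len;
    });
  }

  NumericVector terma(nvox), meane(nvox), contam(nvox);
  for (long i = 0; i < nvox; ++i) {
    if (den[i] > 0) {
      terma[i] = num[i] / den[i];
      contam[i] = cont[i] / den[i];
      meane[i] = num[i] > 0 ? nume[i] / num[i] : 0.0;
    }
  }
  IntegerVector dim = IntegerVector::create(g.nx, g.ny, g.nz);
  terma.attr("dim") = dim; meane.attr("dim") = dim; contam.attr("dim") = dim;
  return List::create(_["terma"] = terma, _["mean_energy"] = meane,
                      _["contamination"] = contam);
}

// rotation taking +z to unit vector d (Rodrigues); columns of R
static void rot_z_to(const double d[3], double R[9]) {
  double c = d[2];
  if (c > 1.0 - 1e-12) {           // identity
    R[0] = 1; R[1] = 0; R[2] = 0; R[3] = 0; R[4] = 1; R[5] = 0;
    R[6] = 0; R[7] = 0; R[8] = 1;
    return;
  }
  if (c < -1.0 + 1e-12) {          // 180 deg about x
    R[0] = 1; R[1] = 0; R[2] = 0; R[3] = 0; R[4] = -1; R[5] = 0;
    R[6] = 0; R[7] = 0; R[8] = -1;
    return;
  }
  double vx = -d[1], vy = d[0];    // v = z x d
  double k = 1.0 / (1.0 + c);
  // R = I + [v]x + [v]x^2 * k   (vz = 0)
  R[0] = 1 - vy * vy * k; R[1] = vx * vy * k;     R[2] = vy;
  R[3] = vx * vy * k;     R[4] = 1 - vx * vx * k; R[5] = -vx;
  R[6] = -vy;             R[7] = vx;              R[8] = 1 - (vx * vx + vy * vy) * k;
}

// minimal rotation taking unit a to unit b (well conditioned for nearly
// parallel a, b; falls back to identity when anti-parallel, which cannot
// occur for voxels downstream of the source)
static void rot_a_to_b(const double a[3], const double b[3], double R[9]) {
  double v0 = a[1] * b[2] - a[2] * b[1];
  double v1 = a[2] * b[0] - a[0] * b[2];
  double v2 = a[0] * b[1] - a[1] * b[0];
  double c = a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
  if (c < -1.0 + 1e-12) {
    R[0] = 1; R[1] = 0; R[2] = 0; R[3] = 0; R[4] = 1; R[5] = 0;
    R[6] = 0; R[7] = 0; R[8] = 1;
    return;
  }
  double k = 1.0 / (1.0 + c);
  R[0] = 1 + k * (-v2 * v2 - v1 * v1);
  R[1] = -v2 + k * v0 * v1;
  R[2] = v1 + k * v0 * v2;
  R[3] = v2 + k * v0 * v1;
  R[4] = 1 + k * (-v2 * v2 - v0 * v0);
  R[5] = -v0 + k * v1 * v2;
  R[6] = -v1 + k * v0 * v2;
  R[7] = v0 + k * v1 * v2;
  R[8] = 1 + k * (-v1 * v1 - v0 * v0);
}

static void mat_mult(const double A[9], const double B[9], double C[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i + 0] * B[0 + j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}

// Collapsed-cone collection superposition.
// ck: (n_kern * n_cones) x n_edges matrix of cumulative kernels (CK at
// radii edges, uniform spacing dr); kern_idx: per-voxel kernel index
// (0-based); cone_dirs: n_cones x 3 in the kernel frame (+z forward);
// mask: per-voxel compute flag. Walks each cone ray upstream in steps of
// step_mm, accumulating TERMA weighted by CK differences over the
// radiological interval of each step.
// [[Rcpp::export]]
NumericVector cpp_superpose(NumericVector terma, NumericVector density,
                            NumericVector spacing, NumericVector origin,
                            IntegerVector kern_idx, NumericVector kern_w,
                            NumericMatrix ck,
                            int n_cones, double dr, double r_max,
                            NumericMatrix cone_dirs, NumericVector source,
                            NumericVector beam_dir, bool parallel, bool tilt,
                            double step_mm, LogicalVector mask) {
  Geom g = make_geom(terma, spacing, origin);
  const double* T = terma.begin();
  const double* rho = density.begin();
  long nvox = (long)g.nx * g.ny * g.nz;
  NumericVector dose(nvox);
  int n_edges = ck.ncol();
  double lo[3] = {g.ox - 0.5 * g.sx, g.oy - 0.5 * g.sy, g.oz - 0.5 * g.sz};
  double hi[3] = {g.ox + (g.nx - 0.5) * g.sx, g.oy + (g.ny - 0.5) * g.sy,
                  g.oz + (g.nz - 0.5) * g.sz};

  auto ck_at = [&](int row, double r) -> double {
    if (r <= 0) return 0.0;
    double f = r / dr;
    int i = (int)f;
    if (i >= n_edges - 1) return ck(row, n_edges - 1);
    double w = f - i;
    return ck(row, i) * (1 - w) + ck(row, i + 1) * w;
  };

  double base_axis[3] = {beam_dir[0], beam_dir[1], beam_dir[2]};
  double Rbase[9];
  rot_z_to(base_axis, Rbase);
  double geom_cap = 4.0 * (hi[0] - lo[0] + hi[1] - lo[1] + hi[2] - lo[2]);

  for (int kz = 0; kz < g.nz; ++kz)
    for (int jy = 0; jy < g.ny; ++jy)
      for (int ix = 0; ix < g.nx; ++ix) {
        long vi = ix + (long)g.nx * (jy + (long)g.ny * kz);
        if (!mask[vi]) continue;
        double x[3] = {g.ox + ix * g.sx, g.oy + jy * g.sy, g.oz + kz * g.sz};
        const double* Rm = Rbase;
        double Rv[9];
        if (tilt && !parallel) {
          // compose the base beam rotation with the small tilt from the
          // beam axis to the local source-voxel axis; this stays well
          // conditioned and mirror-equivariant for any gantry angle
          double a[3] = {x[0] - source[0], x[1] - source[1], x[2] - source[2]};
          double L = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
          a[0] /= L; a[1] /= L; a[2] /= L;
          double Rt[9];
          rot_a_to_b(base_axis, a, Rt);
          mat_mult(Rt, Rbase, Rv);
          Rm = Rv;
        }
        int krow0 = kern_idx[vi] * n_cones;
        // voxel kernel = linear blend of the two bracketing energies
        double kw = kern_w[vi];
        int krow1 = kw > 0 ? krow0 + n_cones : krow0;
        double acc = 0.0;
        for (int m = 0; m < n_cones; ++m) {
          double u[3];
          for (int a = 0; a < 3; ++a)
            u[a] = Rm[3 * a + 0] * cone_dirs(m, 0) +
                   Rm[3 * a + 1] * cone_dirs(m, 1) +
                   Rm[3 * a + 2] * cone_dirs(m, 2);
          int row = krow0 + m, row1 = krow1 + m;
          double racc = 0.0, ck_prev = 0.0;
          double s = 0.0;
          while (racc < r_max && s < geom_cap) {
            double smid = s + 0.5 * step_mm;
            double px = x[0] - smid * u[0], py = x[1] - smid * u[1],
                   pz = x[2] - smid * u[2];
            if (px < lo[0] || px > hi[0] || py < lo[1] || py > hi[1] ||
                pz < lo[2] || pz > hi[2])
              break;
            int i = clampi((int)std::floor((px - lo[0]) / g.sx), 0, g.nx - 1);
            int j = clampi((int)std::floor((py - lo[1]) / g.sy), 0, g.ny - 1);
            int k = clampi((int)std::floor((pz - lo[2]) / g.sz), 0, g.nz - 1);
            long si = i + (long)g.nx * (j + (long)g.ny * k);
            double ed = rho[si];
            double rnew = racc + ed * step_mm;
            if (ed > 0) {
              double ck_new = kw > 0
                ? (1 - kw) * ck_at(row, rnew) + kw * ck_at(row1, rnew)
                : ck_at(row, rnew);
              double w = ck_new - ck_prev;
              if (w > 0) acc += T[si] * w;
              ck_prev = ck_new;
            }
            racc = rnew;
            s += step_mm;
          }
        }
        dose[vi] = acc;
      }
  dose.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  return dose;
}

// gamma-index search on a precomputed offset lattice.
// delta: per-reference-voxel dose criterion (Gy); eval_mask: reference
// voxels to evaluate. mode 0 = optimized (radius-sorted offsets, early
// break); mode 1 = brute force (raw triple-loop order, lossless dominance
// prune at gamma0).
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector refv, NumericVector rsp,
                        NumericVector rorg, NumericVector evalv,
                        NumericVector esp, NumericVector eorg,
                        NumericVector delta, LogicalVector eval_mask,
                        double dta, double cap_factor, double step_frac,
                        int mode) {
  Geom gr = make_geom(refv, rsp, rorg);
  Geom ge = make_geom(evalv, esp, eorg);
  const double* ev = evalv.begin();
  long nvox = (long)gr.nx * gr.ny * gr.nz;
  NumericVector gamma(nvox, NA_REAL);

  double step = dta * step_frac;
  double cap = dta * cap_factor;
  int h = (int)std::floor(cap / step);
  struct Off { double x, y, z, r2; };
  std::vector<Off> offs;
  offs.reserve((2 * h + 1) * (2 * h + 1) * (2 * h + 1) / 2);
  for (int i = -h; i <= h; ++i)
    for (int j = -h; j <= h; ++j)
      for (int k = -h; k <= h; ++k) {
        double x = i * step, y = j * step, z = k * step;
        double r2 = x * x + y * y + z * z;
        if (r2 <= cap * cap + 1e-12) offs.push_back({x, y, z, r2});
      }
  if (mode == 0)
    std::sort(offs.begin(), offs.end(),
              [](const Off& a, const Off& b) { return a.r2 < b.r2; });

  double dta2 = dta * dta;
  for (int kz = 0; kz < gr.nz; ++kz)
    for (int jy = 0; jy < gr.ny; ++jy)
      for (int ix = 0; ix < gr.nx; ++ix) {
        long vi = ix + (long)gr.nx * (jy + (long)gr.ny * kz);
        if (!eval_mask[vi]) continue;
        double px = gr.ox + ix * gr.sx, py = gr.oy + jy * gr.sy,
               pz = gr.oz + kz * gr.sz;
        double dref = refv[vi], del = delta[vi];
        double best = std::numeric_limits<double>::infinity();
        if (mode == 0) {
          for (const Off& o : offs) {
            double sp2 = o.r2 / dta2;
            if (sp2 >= best) break;
            double de = trilinear(ev, ge, px + o.x, py + o.y, pz + o.z, false);
            if (ISNAN(de)) continue;
            double dd = (de - dref) / del;
            double g2 = sp2 + dd * dd;
            if (g2 < best) best = g2;
          }
        } else {
          // brute force: gamma0 bounds the useful search radius exactly
          double g0 = std::numeric_limits<double>::infinity();
          double de0 = trilinear(ev, ge, px, py, pz, false);
          if (!ISNAN(de0)) {
            double dd0 = (de0 - dref) / del;
            g0 = dd0 * dd0;
          }
          double rcap2 = std::min(cap * cap, g0 * dta2);
          best = g0;
          for (const Off& o : offs) {
            if (o.r2 > rcap2 + 1e-12) continue;
            double de = trilinear(ev, ge, px + o.x, py + o.y, pz + o.z, false);
            if (ISNAN(de)) continue;
            double dd = (de - dref) / del;
            double g2 = o.r2 / dta2 + dd * dd;
            if (g2 < best) best = g2;
          }
        }
        if (std::isfinite(best)) gamma[vi] = std::sqrt(best);
      }
  gamma.attr("dim") = IntegerVector::create(gr.nx, gr.ny, gr.nz);
  return gamma;
}

// ball erosion of a logical mask with grid-metric radius (mm)
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, NumericVector spacing,
                        double radius_mm) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int hx = (int)std::floor(radius_mm / spacing[0]);
  int hy = (int)std::floor(radius_mm / spacing[1]);
  int hz = (int)std::floor(radius_mm / spacing[2]);
  std::vector<std::array<int, 3>> offs;
  for (int i = -hx; i <= hx; ++i)
    for (int j = -hy; j <= hy; ++j)
      for (int k = -hz; k <= hz; ++k) {
        double r2 = i * spacing[0] * i * spacing[0] +
                    j * spacing[1] * j * spacing[1] +
                    k * spacing[2] * k * spacing[2];
        if (r2 <= radius_mm * radius_mm + 1e-9)
          offs.push_back({i, j, k});
      }
  LogicalVector out(mask.size());
  for (int kz = 0; kz < nz; ++kz)
    for (int jy = 0; jy < ny; ++jy)
      for (int ix = 0; ix < nx; ++ix) {
        long vi = ix + (long)nx * (jy + (long)ny * kz);
        bool keep = mask[vi] != 0;
        if (keep) {
          for (const auto& o : offs) {
            int i = ix + o[0], j = jy + o[1], k = kz + o[2];
            if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz ||
                mask[i + (long)nx * (j + (long)ny * k)] == 0) {
              keep = false;
              break;
            }
          }
        }
        out[vi] = keep;
      }
  out.attr("dim") = d;
  return out;
}
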