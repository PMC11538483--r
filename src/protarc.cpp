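#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3-D scalar fields are passed as flat numeric vectors in R array order
// (x fastest), with dims/spacing/origin alongside.  Coordinates are mm,
// voxel-center based: world = origin + index * spacing (0-based index).

static inline double trilin(const double *v, const int *d,
                            const double *sp, const double *orig,
                            double x, double y, double z) {
  double fx = (x - orig[0]) / sp[0];
  double fy = (y - orig[1]) / sp[1];
  double fz = (z - orig[2]) / sp[2];
  if (fx < -0.5 || fy < -0.5 || fz < -0.5 ||
      fx > d[0] - 0.5 || fy > d[1] - 0.5 || fz > d[2] - 0.5)
    return 0.0;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  // clamp so border voxels extrapolate as nearest (half-voxel shell)
  if (ix < 0) { ix = 0; wx = 0.0; }
  if (iy < 0) { iy = 0; wy = 0.0; }
  if (iz < 0) { iz = 0; wz = 0.0; }
  if (ix >= d[0] - 1) { ix = d[0] - 2; wx = (ix < 0 ? 0.0 : 1.0); if (d[0]==1){ix=0;wx=0;} }
  if (iy >= d[1] - 1) { iy = d[1] - 2; wy = (iy < 0 ? 0.0 : 1.0); if (d[1]==1){iy=0;wy=0;} }
  if (iz >= d[2] - 1) { iz = d[2] - 2; wz = (iz < 0 ? 0.0 : 1.0); if (d[2]==1){iz=0;wz=0;} }
  const int sx = 1, sy = d[0], sz = d[0] * d[1];
  const double *p = v + ix + iy * sy + iz * sz;
  int dx = (d[0] > 1) ? sx : 0, dy = (d[1] > 1) ? sy : 0, dz = (d[2] > 1) ? sz : 0;
  double c00 = p[0] * (1 - wx) + p[dx] * wx;
  double c10 = p[dy] * (1 - wx) + p[dx + dy] * wx;
  double c01 = p[dz] * (1 - wx) + p[dx + dz] * wx;
  double c11 = p[dy + dz] * (1 - wx) + p[dx + dy + dz] * wx;
  double c0 = c00 * (1 - wy) + c10 * wy;
  double c1 = c01 * (1 - wy) + c11 * wy;
  return c0 * (1 - wz) + c1 * wz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = values.begin();
  const int d[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double orig[3] = {origin[0], origin[1], origin[2]};
  for (int i = 0; i < n; ++i)
    out[i] = trilin(v, d, sp, orig, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Binary dilation by an explicit voxel-offset structuring element.
// [[Rcpp::export]]
LogicalVector cpp_dilate_mask(LogicalVector mask, IntegerVector dims,
                              IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, m = offsets.nrow();
  LogicalVector out(n, false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx = i + nx * (j + ny * k);
        if (!mask[idx]) continue;
        for (int o = 0; o < m; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          out[ii + nx * (jj + ny * kk)] = true;
        }
      }
  return out;
}

// Ray/axis-aligned-box intersection; box is the voxel-center grid padded by
// half a voxel.  Returns false when the ray misses.
static bool ray_box(const double *o, const double *u, const int *d,
                    const double *sp, const double *orig,
                    double &t0, double &t1) {
  t0 = -1e30; t1 = 1e30;
  for (int a = 0; a < 3; ++a) {
    double lo = orig[a] - 0.5 * sp[a];
    double hi = orig[a] + (d[a] - 0.5) * sp[a];
    if (std::fabs(u[a]) < 1e-12) {
      if (o[a] < lo || o[a] > hi) return false;
    } else {
      double ta = (lo - o[a]) / u[a], tb = (hi - o[a]) / u[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// Analytic Bragg-like depth-dose: flat entrance ramp blended into a
// Gaussian peak with a sharp distal falloff; the nominal range R is the
// distal 80% point.  pars: p0 (entrance/peak ratio), dist_sigma_frac,
// dist_sigma_min (mm), prox_ratio.
static inline double bragg(double z, double R, double p0,
                           double dfrac, double dmin, double pratio) {
  double sd = dfrac * R + dmin;
  double sp = pratio * sd;
  double zp = R - 0.6680472308365775 * sd; // sqrt(2*log(1.25))
  if (z < 0) return 0.0;
  if (z <= zp) {
    double e = (z - zp) / sp;
    return p0 + (1.0 - p0) * std::exp(-0.5 * e * e);
  }
  double e = (z - zp) / sd;
  if (e > 5.0) return 0.0;
  return std::exp(-0.5 * e * e);
}

// [[Rcpp::export]]
NumericVector cpp_bragg(NumericVector z, double R, List pars) {
  double p0 = pars["p0"], dfrac = pars["dist_sigma_frac"],
         dmin = pars["dist_sigma_min"], pratio = pars["prox_ratio"];
  NumericVector out(z.size());
  for (int i = 0; i < z.size(); ++i)
    out[i] = bragg(z[i], R, p0, dfrac, dmin, pratio);
  return out;
}

// WEPL from grid entry to each point, marching along direction u.
// [[Rcpp::export]]
NumericVector cpp_wepl_points(NumericVector density, IntegerVector dims,
                              NumericVector spacing, NumericVector origin,
                              NumericVector u, NumericMatrix pts,
                              double step) {
  const double *v = density.begin();
  const int d[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double orig[3] = {origin[0], origin[1], origin[2]};
  const double uu[3] = {u[0], u[1], u[2]};
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double t0, t1;
    if (!ray_box(p, uu, d, sp, orig, t0, t1) || t0 > 0) { out[i] = 0.0; continue; }
    // entry is at parameter t0 (<= 0), point at 0
    double L = -t0;
    int ns = (int)std::ceil(L / step);
    double h = (ns > 0) ? L / ns : 0.0;
    double acc = 0.0, prev = trilin(v, d, sp, orig,
                                    p[0] + t0 * uu[0], p[1] + t0 * uu[1], p[2] + t0 * uu[2]);
    for (int s = 1; s <= ns; ++s) {
      double t = t0 + s * h;
      double cur = trilin(v, d, sp, orig,
                          p[0] + t * uu[0], p[1] + t * uu[1], p[2] + t * uu[2]);
      acc += 0.5 * (prev + cur) * h;
      prev = cur;
    }
    out[i] = acc;
  }
  return out;
}

// Pencil-beam dose at arbitrary points.
// spots: matrix with columns ox,oy,oz (ray origin), ux,uy,uz (unit dir),
//        range_mm, weight.  pars adds lateral sigma0 (mm), sigma_slope
//        (mm per mm WEPL), step_mm, lateral cutoff (sigmas) and the Bragg
//        parameters.  range_scale multiplies the nominal range (±3% range
//        error scenarios).  If `want_matrix`, returns n_points x n_spots
//        influence; otherwise the weighted sum as a vector.
// [[Rcpp::export]]
SEXP cpp_dose_points(NumericVector density, IntegerVector dims,
                     NumericVector spacing, NumericVector origin,
                     NumericMatrix spots, NumericMatrix pts,
                     double range_scale, List pars, bool want_matrix) {
  const double *v = density.begin();
  const int d[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double orig[3] = {origin[0], origin[1], origin[2]};
  const int np = pts.nrow(), nsp = spots.nrow();
  const double p0 = pars["p0"], dfrac = pars["dist_sigma_frac"],
               dmin = pars["dist_sigma_min"], pratio = pars["prox_ratio"],
               sig0 = pars["sigma0"], sslope = pars["sigma_slope"],
               step = pars["step_mm"], cutoff = pars["lateral_cutoff"];

  NumericMatrix infl;
  NumericVector dose;
  if (want_matrix) infl = NumericMatrix(np, nsp); else dose = NumericVector(np);

  std::vector<double> wtab; // cumulative WEPL along the ray, per step
  for (int s = 0; s < nsp; ++s) {
    double o[3] = {spots(s, 0), spots(s, 1), spots(s, 2)};
    double u[3] = {spots(s, 3), spots(s, 4), spots(s, 5)};
    double R = spots(s, 6) * range_scale;
    double w = spots(s, 7);
    double t0, t1;
    if (!ray_box(o, u, d, sp, orig, t0, t1)) continue; // ray misses: zero dose
    int ns = (int)std::ceil((t1 - t0) / step) + 1;
    double h = (t1 - t0) / (ns - 1);
    wtab.assign(ns, 0.0);
    double prev = trilin(v, d, sp, orig, o[0] + t0 * u[0], o[1] + t0 * u[1],
                         o[2] + t0 * u[2]);
    for (int k = 1; k < ns; ++k) {
      double t = t0 + k * h;
      double cur = trilin(v, d, sp, orig, o[0] + t * u[0], o[1] + t * u[1],
                          o[2] + t * u[2]);
      wtab[k] = wtab[k - 1] + 0.5 * (prev + cur) * h;
      prev = cur;
    }
    double sd = dfrac * R + dmin;
    double zmax = R - 0.6680472308365775 * sd + 5.0 * sd; // distal cutoff in WEPL
    for (int i = 0; i < np; ++i) {
      double rx = pts(i, 0) - o[0], ry = pts(i, 1) - o[1], rz = pts(i, 2) - o[2];
      double t = rx * u[0] + ry * u[1] + rz * u[2];
      if (t < t0 || t > t1) continue;
      double f = (t - t0) / h;
      int k = (int)std::floor(f);
      if (k >= ns - 1) k = ns - 2;
      double z = wtab[k] + (f - k) * (wtab[k + 1] - wtab[k]);
      if (z > zmax) continue;
      double sig = sig0 + sslope * z;
      double lx = rx - t * u[0], ly = ry - t * u[1], lz = rz - t * u[2];
      double r2 = lx * lx + ly * ly + lz * lz;
      if (r2 > cutoff * cutoff * sig * sig) continue;
      double dd = bragg(z, R, p0, dfrac, dmin, pratio) *
                  std::exp(-0.5 * r2 / (sig * sig));
      if (want_matrix) infl(i, s) = dd;
      else dose[i] += w * dd;
    }
  }
  if (want_matrix) return infl;
  return dose;
}
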