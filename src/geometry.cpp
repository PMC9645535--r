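#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Volumes are (nx, ny, nz) arrays, column-major. Voxel indices are 0-based
// here; world = origin + index * spacing (per axis).

static inline double samp_nearest(const double* x, int nx, int ny, int nz,
                                  double fx, double fy, double fz) {
  int i = (int)std::lround(fx), j = (int)std::lround(fy), k = (int)std::lround(fz);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return x[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

static inline double samp_linear(const double* x, int nx, int ny, int nz,
                                 double fx, double fy, double fz) {
  if (fx < -0.5 || fy < -0.5 || fz < -0.5 ||
      fx > nx - 0.5 || fy > ny - 0.5 || fz > nz - 0.5) return 0.0;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int i = std::min(std::max(i0 + di, 0), nx - 1);
        int j = std::min(std::max(j0 + dj, 0), ny - 1);
        int k = std::min(std::max(k0 + dk, 0), nz - 1);
        double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
        acc += w * x[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      }
  return acc;
}

// [[Rcpp::export]]
NumericVector resample_grid_cpp(NumericVector x,
                                NumericVector spacing_in, NumericVector origin_in,
                                IntegerVector dims_out,
                                NumericVector spacing_out, NumericVector origin_out,
                                bool nearest) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int mx = dims_out[0], my = dims_out[1], mz = dims_out[2];
  NumericVector y((R_xlen_t)mx * my * mz);
  y.attr("dim") = dims_out;
  const double* xp = x.begin();
  double* yp = y.begin();
  R_xlen_t r = 0;
  for (int k = 0; k < mz; ++k) {
    double wz = origin_out[2] + k * spacing_out[2];
    double fz = (wz - origin_in[2]) / spacing_in[2];
    for (int j = 0; j < my; ++j) {
      double wy = origin_out[1] + j * spacing_out[1];
      double fy = (wy - origin_in[1]) / spacing_in[1];
      for (int i = 0; i < mx; ++i, ++r) {
        double wx = origin_out[0] + i * spacing_out[0];
        double fx = (wx - origin_in[0]) / spacing_in[0];
        yp[r] = nearest ? samp_nearest(xp, nx, ny, nz, fx, fy, fz)
                        : samp_linear(xp, nx, ny, nz, fx, fy, fz);
      }
    }
  }
  return y;
}

// Backward affine warp: source_world = M %*% out_world + off
// [[Rcpp::export]]
NumericVector affine_warp_cpp(NumericVector x, NumericVector spacing,
                              NumericVector origin, const arma::mat& M,
                              const arma::vec& off, bool nearest) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  R_xlen_t r = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++r) {
        double wx = origin[0] + i * spacing[0];
        double wy = origin[1] + j * spacing[1];
        double wz = origin[2] + k * spacing[2];
        double sx = M(0,0)*wx + M(0,1)*wy + M(0,2)*wz + off(0);
        double sy = M(1,0)*wx + M(1,1)*wy + M(1,2)*wz + off(1);
        double sz = M(2,0)*wx + M(2,1)*wy + M(2,2)*wz + off(2);
        double fx = (sx - origin[0]) / spacing[0];
        double fy = (sy - origin[1]) / spacing[1];
        double fz = (sz - origin[2]) / spacing[2];
        yp[r] = nearest ? samp_nearest(xp, nx, ny, nz, fx, fy, fz)
                        : samp_linear(xp, nx, ny, nz, fx, fy, fz);
      }
  return y;
}

// Backward divergence warp: out(x) = in(x - u(x)) with
// u(x) = sum_k m_k * (x - c_k)/||x - c_k|| * exp(-||x - c_k||^2 / (2 s_k^2))
// [[Rcpp::export]]
NumericVector divergence_warp_cpp(NumericVector x, NumericVector spacing,
                                  NumericVector origin, const arma::mat& centers,
                                  NumericVector mags, NumericVector sigmas,
                                  bool nearest) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int m = centers.n_rows;
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  R_xlen_t r = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++r) {
        double wx = origin[0] + i * spacing[0];
        double wy = origin[1] + j * spacing[1];
        double wz = origin[2] + k * spacing[2];
        double ux = 0, uy = 0, uz = 0;
        for (int q = 0; q < m; ++q) {
          double vx = wx - centers(q,0), vy = wy - centers(q,1), vz = wz - centers(q,2);
          double r2 = vx*vx + vy*vy + vz*vz;
          double rr = std::sqrt(r2);
          if (rr < 1e-9) continue;
          double w = mags[q] * std::exp(-r2 / (2.0 * sigmas[q] * sigmas[q])) / rr;
          ux += w * vx; uy += w * vy; uz += w * vz;
        }
        double fx = (wx - ux - origin[0]) / spacing[0];
        double fy = (wy - uy - origin[1]) / spacing[1];
        double fz = (wz - uz - origin[2]) / spacing[2];
        yp[r] = nearest ? samp_nearest(xp, nx, ny, nz, fx, fy, fz)
                        : samp_linear(xp, nx, ny, nz, fx, fy, fz);
      }
  return y;
}

// Sample a volume at arbitrary world points (q x 3); outside -> 0.
// [[Rcpp::export]]
NumericVector sample_points_cpp(NumericVector x, NumericVector spacing,
                                NumericVector origin, const arma::mat& Q,
                                bool nearest) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int q = Q.n_rows;
  NumericVector y(q);
  const double* xp = x.begin();
  for (int r = 0; r < q; ++r) {
    double fx = (Q(r,0) - origin[0]) / spacing[0];
    double fy = (Q(r,1) - origin[1]) / spacing[1];
    double fz = (Q(r,2) - origin[2]) / spacing[2];
    y[r] = nearest ? samp_nearest(xp, nx, ny, nz, fx, fy, fz)
                   : samp_linear(xp, nx, ny, nz, fx, fy, fz);
  }
  return y;
}

// ---------------------------------------------------------------------------
// Euclidean distance transform (Felzenszwalb-Huttenlocher, per axis), with
// anisotropic spacing. Distance of foreground voxels to the nearest
// background voxel; the volume border is not treated as background.

static void dt1d(std::vector<double>& f, std::vector<double>& d, double w2) {
  int n = f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0; z[0] = -HUGE_VAL; z[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w2*q*q) - (f[p] + w2*p*p)) / (2.0*w2*q - 2.0*w2*p);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk; v[kk] = q; z[kk] = s; z[kk+1] = HUGE_VAL;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk+1] < q) ++kk;
    int p = v[kk];
    d[q] = w2*(q-p)*(q-p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector edt_cpp(IntegerVector mask, NumericVector spacing) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> dist(n);
  for (R_xlen_t r = 0; r < n; ++r) dist[r] = mask[r] ? 1e20 : 0.0;
  std::vector<double> f, o;
  // x axis
  f.resize(nx); o.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = dist[base + i];
      dt1d(f, o, spacing[0]*spacing[0]);
      for (int i = 0; i < nx; ++i) dist[base + i] = o[i];
    }
  // y axis
  f.resize(ny); o.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = dist[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, o, spacing[1]*spacing[1]);
      for (int j = 0; j < ny; ++j) dist[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = o[j];
    }
  // z axis
  f.resize(nz); o.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = dist[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, o, spacing[2]*spacing[2]);
      for (int k = 0; k < nz; ++k) dist[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = std::sqrt(o[k]);
    }
  NumericVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) out[r] = dist[r];
  out.attr("dim") = d;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6 or 26 connectivity).

// [[Rcpp::export]]
IntegerVector cc_label_cpp(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  lab.attr("dim") = d;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && man != 1) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz) continue;
            R_xlen_t w = i2 + (R_xlen_t)nx * (j2 + (R_xlen_t)ny * k2);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Phantom rasterization: a tube of varying radius around a polyline,
// with wall and an angular thrombus crescent thickening the wall inward.
// Internal label codes: 0 background, 1 lumen, 2 wall, 3 thrombus.

struct CurveGeom {
  const arma::mat* P;   // n x 3 curve samples (world mm)
  const arma::mat* T;   // n x 3 unit tangents
  const arma::vec* radii;
  const arma::vec* depth;  // max inward thrombus depth per sample (mm)
  double wall, theta0, halfang;
  arma::vec ref;        // reference direction for the angular frame
};

static int classify_point(const CurveGeom& g, int j, double dist,
                          double wx, double wy, double wz) {
  double r = (*g.radii)[j];
  double rin = r;
  bool in_crescent = false;
  if (g.halfang > 0 && (*g.depth)[j] > 1e-9) {
    double tx = (*g.T)(j,0), ty = (*g.T)(j,1), tz = (*g.T)(j,2);
    double vx = wx - (*g.P)(j,0), vy = wy - (*g.P)(j,1), vz = wz - (*g.P)(j,2);
    double vt = vx*tx + vy*ty + vz*tz;
    vx -= vt*tx; vy -= vt*ty; vz -= vt*tz;
    double vn = std::sqrt(vx*vx + vy*vy + vz*vz);
    if (vn > 1e-9) {
      double ex = g.ref(0), ey = g.ref(1), ez = g.ref(2);
      double et = ex*tx + ey*ty + ez*tz;
      ex -= et*tx; ey -= et*ty; ez -= et*tz;
      double en = std::sqrt(ex*ex + ey*ey + ez*ez);
      if (en > 1e-9) {
        ex /= en; ey /= en; ez /= en;
        double fx = ty*ez - tz*ey, fy = tz*ex - tx*ez, fz = tx*ey - ty*ex;
        double th = std::atan2(vx*fx + vy*fy + vz*fz, vx*ex + vy*ey + vz*ez);
        double dth = th - g.theta0;
        while (dth > M_PI) dth -= 2*M_PI;
        while (dth < -M_PI) dth += 2*M_PI;
        if (std::fabs(dth) < g.halfang) {
          rin = r - (*g.depth)[j] * std::cos(M_PI_2 * dth / g.halfang);
          in_crescent = true;
        }
      }
    }
  }
  if (dist <= rin) return 1;
  if (dist <= r) return in_crescent ? 3 : 2;  // inside nominal lumen radius
  if (dist <= r + g.wall) return 2;
  return 0;
}

// [[Rcpp::export]]
List rasterize_phantom_cpp(IntegerVector dims, NumericVector spacing,
                           NumericVector origin, const arma::mat& P,
                           const arma::mat& Tn, const arma::vec& radii,
                           double wall, double theta0, double halfang,
                           const arma::vec& depth, NumericVector ref,
                           int subdiv) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  int n = P.n_rows;
  CurveGeom g;
  g.P = &P; g.T = &Tn; g.radii = &radii; g.depth = &depth;
  g.wall = wall; g.theta0 = theta0; g.halfang = halfang;
  g.ref = arma::vec(3);
  for (int a = 0; a < 3; ++a) g.ref(a) = ref[a];

  double maxsp = std::max(spacing[0], std::max(spacing[1], spacing[2]));
  // mean arc step between consecutive samples
  double step = 0.5;
  if (n > 1) {
    arma::rowvec d0 = P.row(1) - P.row(0);
    step = arma::norm(d0);
  }
  double R = radii.max() + wall + step + 2.0 * maxsp;

  std::vector<float> best(nvox, 1e30f);
  std::vector<int> bidx(nvox, -1);
  for (int q = 0; q < n; ++q) {
    double cx = P(q,0), cy = P(q,1), cz = P(q,2);
    int i0 = std::max(0, (int)std::ceil((cx - R - origin[0]) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::floor((cx + R - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::ceil((cy - R - origin[1]) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor((cy + R - origin[1]) / spacing[1]));
    int k0 = std::max(0, (int)std::ceil((cz - R - origin[2]) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::floor((cz + R - origin[2]) / spacing[2]));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * spacing[2] - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing[1] - cy;
        double dyz = dy*dy + dz*dz;
        if (dyz > R*R) continue;
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * spacing[0] - cx;
          float d2 = (float)(dx*dx + dyz);
          if (d2 < best[base + i]) { best[base + i] = d2; bidx[base + i] = q; }
        }
      }
    }
  }

  IntegerVector labels(nvox);
  labels.attr("dim") = dims;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (bidx[v] < 0) continue;
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    double wx = origin[0] + i * spacing[0];
    double wy = origin[1] + j * spacing[1];
    double wz = origin[2] + k * spacing[2];
    labels[v] = classify_point(g, bidx[v], std::sqrt((double)best[v]), wx, wy, wz);
  }

  NumericVector counts(4);
  if (subdiv <= 1) {
    for (R_xlen_t v = 0; v < nvox; ++v) counts[labels[v]] += 1.0;
  } else {
    // sub-voxel oracle: classify subdiv^3 sub-centres per voxel, searching
    // for the nearest curve sample in a window around the voxel's own
    int K = (int)std::ceil((2.0 * maxsp + step) / std::max(step, 1e-6)) + 2;
    double inv = 1.0 / subdiv;
    double w3 = inv * inv * inv;
    for (R_xlen_t v = 0; v < nvox; ++v) {
      if (bidx[v] < 0) { counts[0] += 1.0; continue; }
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      double wx0 = origin[0] + i * spacing[0];
      double wy0 = origin[1] + j * spacing[1];
      double wz0 = origin[2] + k * spacing[2];
      int lo = std::max(0, bidx[v] - K), hi = std::min(n - 1, bidx[v] + K);
      for (int sk = 0; sk < subdiv; ++sk)
        for (int sj = 0; sj < subdiv; ++sj)
          for (int si = 0; si < subdiv; ++si) {
            double wx = wx0 + ((si + 0.5) * inv - 0.5) * spacing[0];
            double wy = wy0 + ((sj + 0.5) * inv - 0.5) * spacing[1];
            double wz = wz0 + ((sk + 0.5) * inv - 0.5) * spacing[2];
            double bd = 1e30; int bq = lo;
            for (int q = lo; q <= hi; ++q) {
              double dx = wx - P(q,0), dy = wy - P(q,1), dz = wz - P(q,2);
              double d2 = dx*dx + dy*dy + dz*dz;
              if (d2 < bd) { bd = d2; bq = q; }
            }
            counts[classify_point(g, bq, std::sqrt(bd), wx, wy, wz)] += w3;
          }
    }
  }
  return List::create(_["labels"] = labels, _["counts"] = counts);
}

// Classify arbitrary world points against the phantom geometry
// (brute-force nearest curve sample); used as an analytic oracle.
// [[Rcpp::export]]
IntegerVector classify_points_cpp(const arma::mat& Q, const arma::mat& P,
                                  const arma::mat& Tn, const arma::vec& radii,
                                  double wall, double theta0, double halfang,
                                  const arma::vec& depth, NumericVector ref) {
  CurveGeom g;
  g.P = &P; g.T = &Tn; g.radii = &radii; g.depth = &depth;
  g.wall = wall; g.theta0 = theta0; g.halfang = halfang;
  g.ref = arma::vec(3);
  for (int a = 0; a < 3; ++a) g.ref(a) = ref[a];
  int nq = Q.n_rows, n = P.n_rows;
  IntegerVector out(nq);
  for (int r = 0; r < nq; ++r) {
    double wx = Q(r,0), wy = Q(r,1), wz = Q(r,2);
    double bd = 1e30; int bq = 0;
    for (int q = 0; q < n; ++q) {
      double dx = wx - P(q,0), dy = wy - P(q,1), dz = wz - P(q,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < bd) { bd = d2; bq = q; }
    }
    out[r] = classify_point(g, bq, std::sqrt(bd), wx, wy, wz);
  }
  return out;
}
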