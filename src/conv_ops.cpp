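#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature arrays are R arrays of dim (nx, ny, nz, nc), column-major.
// All convolutions are 3x3x3, stride 1, zero padding 1.
// Weight matrices are (nc_in * 27) x nc_out; patch column order is
// c * 27 + o with o = (dx+1) + 3*(dy+1) + 9*(dz+1).

static void build_patches(const double* xp, int nx, int ny, int nz, int ci,
                          int k0, int Tz, arma::mat& P) {
  P.zeros();
  for (int c = 0; c < ci; ++c) {
    const double* xc = xp + (R_xlen_t)nx * ny * nz * c;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          double* pc = P.colptr(c * 27 + o);
          int i_lo = std::max(0, -dx), i_hi = std::min(nx, nx - dx);
          for (int kk = 0; kk < Tz; ++kk) {
            int k2 = k0 + kk + dz;
            if (k2 < 0 || k2 >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              int j2 = j + dy;
              if (j2 < 0 || j2 >= ny) continue;
              double* dst = pc + (R_xlen_t)nx * (j + (R_xlen_t)ny * kk);
              const double* src = xc + (R_xlen_t)nx * (j2 + (R_xlen_t)ny * k2) + dx;
              for (int i = i_lo; i < i_hi; ++i) dst[i] = src[i];
            }
          }
        }
  }
}

static int slab_size(int nx, int ny, int ci, int nz) {
  // keep the patch matrix around ~32 MB
  int s = (int)(4.0e6 / ((double)nx * ny * ci * 27.0));
  if (s < 1) s = 1;
  if (s > nz) s = nz;
  return s;
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, const arma::mat& W, const arma::vec& b) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], ci = d[3];
  int co = W.n_cols;
  if ((int)W.n_rows != ci * 27) stop("conv3d_fw: weight/input channel mismatch");
  NumericVector y((R_xlen_t)nx * ny * nz * co);
  y.attr("dim") = IntegerVector::create(nx, ny, nz, co);
  const double* xp = x.begin();
  double* yp = y.begin();
  int slab = slab_size(nx, ny, ci, nz);
  arma::mat P((R_xlen_t)nx * ny * slab, ci * 27);
  for (int k0 = 0; k0 < nz; k0 += slab) {
    int Tz = std::min(slab, nz - k0);
    R_xlen_t Ns = (R_xlen_t)nx * ny * Tz;
    if (Tz != slab) P.set_size(Ns, ci * 27);
    build_patches(xp, nx, ny, nz, ci, k0, Tz, P);
    arma::mat Y = P * W;
    Y.each_row() += b.t();
    for (int o = 0; o < co; ++o) {
      double* dst = yp + (R_xlen_t)nx * ny * (k0 + (R_xlen_t)nz * o);
      std::memcpy(dst, Y.colptr(o), sizeof(double) * Ns);
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, const arma::mat& W, NumericVector gy) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], ci = d[3];
  int co = W.n_cols;
  NumericVector gx((R_xlen_t)nx * ny * nz * ci);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  arma::mat gW(ci * 27, co, arma::fill::zeros);
  arma::vec gb(co, arma::fill::zeros);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  int slab = slab_size(nx, ny, ci, nz);
  arma::mat P((R_xlen_t)nx * ny * slab, ci * 27);
  for (int k0 = 0; k0 < nz; k0 += slab) {
    int Tz = std::min(slab, nz - k0);
    R_xlen_t Ns = (R_xlen_t)nx * ny * Tz;
    if (Tz != slab) P.set_size(Ns, ci * 27);
    build_patches(xp, nx, ny, nz, ci, k0, Tz, P);
    arma::mat G(Ns, co);
    for (int o = 0; o < co; ++o) {
      const double* src = gyp + (R_xlen_t)nx * ny * (k0 + (R_xlen_t)nz * o);
      std::memcpy(G.colptr(o), src, sizeof(double) * Ns);
    }
    gW += P.t() * G;
    gb += arma::sum(G, 0).t();
    arma::mat gP = G * W.t();
    // scatter-add (col2im)
    for (int c = 0; c < ci; ++c) {
      double* gxc = gxp + (R_xlen_t)nx * ny * nz * c;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
            const double* pc = gP.colptr(c * 27 + o);
            int i_lo = std::max(0, -dx), i_hi = std::min(nx, nx - dx);
            for (int kk = 0; kk < Tz; ++kk) {
              int k2 = k0 + kk + dz;
              if (k2 < 0 || k2 >= nz) continue;
              for (int j = 0; j < ny; ++j) {
                int j2 = j + dy;
                if (j2 < 0 || j2 >= ny) continue;
                const double* src = pc + (R_xlen_t)nx * (j + (R_xlen_t)ny * kk);
                double* dst = gxc + (R_xlen_t)nx * (j2 + (R_xlen_t)ny * k2) + dx;
                for (int i = i_lo; i < i_hi; ++i) dst[i] += src[i];
              }
            }
          }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2; input dims must be even.
// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], nc = d[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool3d_fw: dims must be even");
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector y((R_xlen_t)mx * my * mz * nc);
  y.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  R_xlen_t r = 0;
  for (int c = 0; c < nc; ++c) {
    R_xlen_t off = (R_xlen_t)nx * ny * nz * c;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i, ++r) {
          double best = -HUGE_VAL;
          R_xlen_t bl = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                R_xlen_t l = off + (2 * i + di) +
                  (R_xlen_t)nx * ((2 * j + dj) + (R_xlen_t)ny * (2 * k + dk));
                if (xp[l] > best) { best = xp[l]; bl = l; }
              }
          yp[r] = best;
          ip[r] = (int)bl;  // safe: feature tensors stay < 2^31 elements
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(NumericVector gy, IntegerVector idx, IntegerVector dims_in) {
  NumericVector gx((R_xlen_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3]);
  gx.attr("dim") = dims_in;
  double* gxp = gx.begin();
  const double* gyp = gy.begin();
  const int* ip = idx.begin();
  for (R_xlen_t r = 0; r < gy.size(); ++r) gxp[ip[r]] += gyp[r];
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
NumericVector upsample3d_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], nc = d[3];
  int ux = 2 * nx, uy = 2 * ny, uz = 2 * nz;
  NumericVector y((R_xlen_t)ux * uy * uz * nc);
  y.attr("dim") = IntegerVector::create(ux, uy, uz, nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < nc; ++c) {
    R_xlen_t xo = (R_xlen_t)nx * ny * nz * c;
    R_xlen_t yo = (R_xlen_t)ux * uy * uz * c;
    for (int k = 0; k < uz; ++k)
      for (int j = 0; j < uy; ++j) {
        const double* src = xp + xo + (R_xlen_t)nx * ((j / 2) + (R_xlen_t)ny * (k / 2));
        double* dst = yp + yo + (R_xlen_t)ux * (j + (R_xlen_t)uy * k);
        for (int i = 0; i < ux; ++i) dst[i] = src[i / 2];
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample3d_bw(NumericVector gy) {
  IntegerVector d = gy.attr("dim");
  int ux = d[0], uy = d[1], uz = d[2], nc = d[3];
  int nx = ux / 2, ny = uy / 2, nz = uz / 2;
  NumericVector gx((R_xlen_t)nx * ny * nz * nc);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < nc; ++c) {
    R_xlen_t xo = (R_xlen_t)nx * ny * nz * c;
    R_xlen_t yo = (R_xlen_t)ux * uy * uz * c;
    for (int k = 0; k < uz; ++k)
      for (int j = 0; j < uy; ++j) {
        double* dst = gxp + xo + (R_xlen_t)nx * ((j / 2) + (R_xlen_t)ny * (k / 2));
        const double* src = gyp + yo + (R_xlen_t)ux * (j + (R_xlen_t)uy * k);
        for (int i = 0; i < ux; ++i) dst[i / 2] += src[i];
      }
  }
  return gx;
}
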