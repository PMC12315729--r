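// Hot numerical kernels: batch 3-D interpolation, symmetric 3x3 eigen
// decompositions, tensor log/exp, PPD reorientation, finite-strain rotations.
// All voxel coordinates are 0-based continuous indices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Catmull-Rom cubic kernel weights for fractional offset t in [0,1).
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

// Interpolate a 3-D volume at arbitrary continuous voxel coordinates.
// order: 0 nearest, 1 trilinear, 3 cubic (Catmull-Rom).
// oob_mode: 0 -> fill with `fill` outside, 1 -> clamp to boundary.
// Returns list(values, oob) where oob flags points outside the volume.
// [[Rcpp::export]]
List interp3_cpp(NumericVector vol, IntegerVector dim,
                 NumericMatrix pts, int order, int oob_mode, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  LogicalVector oob(n);
  const double *v = REAL(vol);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    bool outside = (x < 0 || y < 0 || z < 0 ||
                    x > nx - 1 || y > ny - 1 || z > nz - 1);
    oob[p] = outside;
    if (outside && oob_mode == 0) { out[p] = fill; continue; }
    x = clampd(x, 0, nx - 1); y = clampd(y, 0, ny - 1); z = clampd(z, 0, nz - 1);
    if (order == 0) {
      int ix = (int)std::lround(x), iy = (int)std::lround(y), iz = (int)std::lround(z);
      out[p] = v[ix * sx + iy * sy + iz * sz];
    } else if (order == 1) {
      int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
      if (ix >= nx - 1) ix = nx - 2; if (iy >= ny - 1) iy = ny - 2; if (iz >= nz - 1) iz = nz - 2;
      if (ix < 0) ix = 0; if (iy < 0) iy = 0; if (iz < 0) iz = 0;
      double fx = x - ix, fy = y - iy, fz = z - iz;
      double acc = 0.0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
            acc += w * v[(ix + dx) * sx + (iy + dy) * sy + (iz + dz) * sz];
          }
      out[p] = acc;
    } else { // cubic
      int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
      double wx[4], wy[4], wz[4];
      cr_weights(x - ix, wx); cr_weights(y - iy, wy); cr_weights(z - iz, wz);
      double acc = 0.0;
      for (int dz = -1; dz <= 2; ++dz) {
        int kz = iz + dz; if (kz < 0) kz = 0; if (kz > nz - 1) kz = nz - 1;
        for (int dy = -1; dy <= 2; ++dy) {
          int ky = iy + dy; if (ky < 0) ky = 0; if (ky > ny - 1) ky = ny - 1;
          double wyz = wy[dy + 1] * wz[dz + 1];
          for (int dx = -1; dx <= 2; ++dx) {
            int kx = ix + dx; if (kx < 0) kx = 0; if (kx > nx - 1) kx = nx - 1;
            acc += wx[dx + 1] * wyz * v[kx * sx + ky * sy + kz * sz];
          }
        }
      }
      out[p] = acc;
    }
  }
  return List::create(_["values"] = out, _["oob"] = oob);
}

static inline arma::mat33 unpack6(const double *t) {
  arma::mat33 D;
  D(0,0) = t[0]; D(0,1) = t[1]; D(0,2) = t[2];
  D(1,0) = t[1]; D(1,1) = t[3]; D(1,2) = t[4];
  D(2,0) = t[2]; D(2,1) = t[4]; D(2,2) = t[5];
  return D;
}

static inline void pack6(const arma::mat33 &D, double *t) {
  t[0] = D(0,0); t[1] = D(0,1); t[2] = D(0,2);
  t[3] = D(1,1); t[4] = D(1,2); t[5] = D(2,2);
}

// Eigen decomposition of N symmetric 3x3 matrices given as N x 6 rows
// (xx, xy, xz, yy, yz, zz). Eigenvalues returned in descending order.
// [[Rcpp::export]]
List eig_sym3_batch(NumericMatrix tens) {
  const R_xlen_t n = tens.nrow();
  NumericMatrix vals(n, 3), vecs(n, 9);
  arma::vec3 ev; arma::mat33 V;
  double row[6];
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int k = 0; k < 6; ++k) row[k] = tens(i, k);
    arma::mat33 D = unpack6(row);
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, D); // ascending
    for (int k = 0; k < 3; ++k) {
      vals(i, k) = eval(2 - k);
      for (int j = 0; j < 3; ++j) vecs(i, 3 * k + j) = evec(j, 2 - k);
    }
  }
  return List::create(_["values"] = vals, _["vectors"] = vecs);
}

// Matrix log of N symmetric 3x3 tensors. Eigenvalues below
// clamp_frac * lambda_max are clamped up before taking logs; rows whose
// largest eigenvalue is <= 0 are flagged invalid and zero-filled.
// [[Rcpp::export]]
List logm_sym3_batch(NumericMatrix tens, double clamp_frac) {
  const R_xlen_t n = tens.nrow();
  NumericMatrix out(n, 6);
  LogicalVector valid(n);
  double row[6], packed[6];
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int k = 0; k < 6; ++k) row[k] = tens(i, k);
    arma::mat33 D = unpack6(row);
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, D);
    double lmax = eval(2);
    if (!(lmax > 0.0)) { valid[i] = false; continue; }
    double floorv = clamp_frac * lmax;
    arma::vec3 lg;
    for (int k = 0; k < 3; ++k) lg(k) = std::log(std::max(eval(k), floorv));
    arma::mat33 L = evec * arma::diagmat(lg) * evec.t();
    pack6(L, packed);
    for (int k = 0; k < 6; ++k) out(i, k) = packed[k];
    valid[i] = true;
  }
  return List::create(_["log"] = out, _["valid"] = valid);
}

// Matrix exponential of N symmetric 3x3 matrices (rows as above).
// [[Rcpp::export]]
NumericMatrix expm_sym3_batch(NumericMatrix logs) {
  const R_xlen_t n = logs.nrow();
  NumericMatrix out(n, 6);
  double row[6], packed[6];
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int k = 0; k < 6; ++k) row[k] = logs(i, k);
    arma::mat33 L = unpack6(row);
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, L);
    arma::vec3 ex;
    for (int k = 0; k < 3; ++k) ex(k) = std::exp(eval(k));
    arma::mat33 D = evec * arma::diagmat(ex) * evec.t();
    pack6(D, packed);
    for (int k = 0; k < 6; ++k) out(i, k) = packed[k];
  }
  return out;
}

// Preservation-of-principal-directions reorientation. tens: N x 6 tensors,
// mats: N x 9 local affine matrices M (column-major 3x3 rows), applied as
// the anatomical transformation carrying source-frame directions into the
// output frame. Rows with singular M are flagged invalid.
// [[Rcpp::export]]
List ppd_reorient_batch(NumericMatrix tens, NumericMatrix mats) {
  const R_xlen_t n = tens.nrow();
  NumericMatrix out(n, 6);
  LogicalVector valid(n);
  double row[6], packed[6];
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int k = 0; k < 6; ++k) row[k] = tens(i, k);
    arma::mat33 D = unpack6(row);
    arma::mat33 M;
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) M(r, c) = mats(i, 3 * c + r);
    if (std::abs(arma::det(M)) < 1e-12) { valid[i] = false; continue; }
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, D); // ascending
    arma::vec3 e1 = evec.col(2), e2 = evec.col(1), e3 = evec.col(0);
    arma::vec3 n1 = M * e1;
    double n1n = arma::norm(n1);
    if (n1n < 1e-14) { valid[i] = false; continue; }
    n1 /= n1n;
    arma::vec3 v2 = M * e2;
    v2 -= arma::dot(v2, n1) * n1;
    double v2n = arma::norm(v2);
    arma::vec3 n2;
    if (v2n < 1e-14) {
      // degenerate secondary direction: pick any unit vector orthogonal to n1
      arma::vec3 a = {1, 0, 0};
      if (std::abs(n1(0)) > 0.9) a = {0, 1, 0};
      n2 = arma::cross(n1, a); n2 /= arma::norm(n2);
    } else n2 = v2 / v2n;
    arma::vec3 n3 = arma::cross(n1, n2);
    arma::mat33 E, Nm;
    E.col(0) = e1; E.col(1) = e2; E.col(2) = e3;
    Nm.col(0) = n1; Nm.col(1) = n2; Nm.col(2) = n3;
    arma::mat33 R = Nm * E.t();
    arma::mat33 Dp = R * D * R.t();
    Dp = 0.5 * (Dp + Dp.t());
    pack6(Dp, packed);
    for (int k = 0; k < 6; ++k) out(i, k) = packed[k];
    valid[i] = true;
  }
  return List::create(_["tensors"] = out, _["valid"] = valid);
}

// Finite-strain rotation R = J (J^T J)^{-1/2} for N 3x3 Jacobians
// (rows hold column-major 3x3). Singular rows flagged.
// [[Rcpp::export]]
List finite_strain_batch(NumericMatrix jacs) {
  const R_xlen_t n = jacs.nrow();
  NumericMatrix out(n, 9);
  LogicalVector valid(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    arma::mat33 J;
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) J(r, c) = jacs(i, 3 * c + r);
    arma::mat U, V; arma::vec s;
    bool ok = arma::svd(U, s, V, J);
    if (!ok || s(2) < 1e-12) { valid[i] = false; continue; }
    arma::mat33 R = U * V.t();
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) out(i, 3 * c + r) = R(r, c);
    valid[i] = true;
  }
  return List::create(_["rot"] = out, _["valid"] = valid);
}

// Interpolate K volumes (columns of vols, each nx*ny*nz long) at the same
// points, trilinear only, sharing the corner weights across volumes.
// oob_mode: 0 zero-fill, 1 clamp.
// [[Rcpp::export]]
NumericMatrix interp3_multi_cpp(NumericMatrix vols, IntegerVector dim,
                                NumericMatrix pts, int oob_mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  const int K = vols.ncol();
  NumericMatrix out(n, K);
  const double *v0 = REAL(vols);
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    bool outside = (x < 0 || y < 0 || z < 0 ||
                    x > nx - 1 || y > ny - 1 || z > nz - 1);
    if (outside && oob_mode == 0) continue; // zeros already
    x = clampd(x, 0, nx - 1); y = clampd(y, 0, ny - 1); z = clampd(z, 0, nz - 1);
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    if (ix >= nx - 1) ix = nx - 2; if (iy >= ny - 1) iy = ny - 2; if (iz >= nz - 1) iz = nz - 2;
    if (ix < 0) ix = 0; if (iy < 0) iy = 0; if (iz < 0) iz = 0;
    double fx = x - ix, fy = y - iy, fz = z - iz;
    double w[8];
    R_xlen_t off[8];
    int c = 0;
    for (int dz2 = 0; dz2 < 2; ++dz2)
      for (int dy2 = 0; dy2 < 2; ++dy2)
        for (int dx2 = 0; dx2 < 2; ++dx2) {
          w[c] = (dx2 ? fx : 1 - fx) * (dy2 ? fy : 1 - fy) * (dz2 ? fz : 1 - fz);
          off[c] = (ix + dx2) + (iy + dy2) * sy + (iz + dz2) * sz;
          ++c;
        }
    for (int k = 0; k < K; ++k) {
      const double *v = v0 + (R_xlen_t)k * nv;
      double acc = 0;
      for (int j = 0; j < 8; ++j) acc += w[j] * v[off[j]];
      out(p, k) = acc;
    }
  }
  return out;
}

// Scatter-add dense per-voxel gradients (N x 3) onto a knot grid via the
// transpose of the trilinear basis. vox: N x 3 continuous knot-grid
// coordinates; kdim: knot grid dims. Returns nk x 3.
// [[Rcpp::export]]
NumericMatrix scatter_grad_knots_cpp(NumericMatrix vox, IntegerVector kdim,
                                     NumericMatrix gdense) {
  const int nx = kdim[0], ny = kdim[1], nz = kdim[2];
  const R_xlen_t n = vox.nrow();
  NumericMatrix out((R_xlen_t)nx * ny * nz, 3);
  double *o0 = REAL(out);
  const R_xlen_t nk = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = clampd(vox(p, 0), 0, nx - 1);
    double y = clampd(vox(p, 1), 0, ny - 1);
    double z = clampd(vox(p, 2), 0, nz - 1);
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    if (ix >= nx - 1) ix = nx - 2; if (iy >= ny - 1) iy = ny - 2; if (iz >= nz - 1) iz = nz - 2;
    double fx = x - ix, fy = y - iy, fz = z - iz;
    for (int dz2 = 0; dz2 < 2; ++dz2)
      for (int dy2 = 0; dy2 < 2; ++dy2)
        for (int dx2 = 0; dx2 < 2; ++dx2) {
          double w = (dx2 ? fx : 1 - fx) * (dy2 ? fy : 1 - fy) * (dz2 ? fz : 1 - fz);
          R_xlen_t idx = (ix + dx2) + (R_xlen_t)(iy + dy2) * nx +
            (R_xlen_t)(iz + dz2) * nx * ny;
          for (int k = 0; k < 3; ++k)
            o0[idx + k * nk] += w * gdense(p, k);
        }
  }
  return out;
}
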