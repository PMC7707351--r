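#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3-D field at fractional voxel coordinates (0-based).
// Corners falling outside the lattice contribute `outside`; an NA corner with
// nonzero weight makes the whole sample NA (used to flag out-of-field voxels
// when resampling onto a reference lattice).
static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double ix, double iy, double iz,
                                double outside) {
  double fx = std::floor(ix), fy = std::floor(iy), fz = std::floor(iz);
  int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
  double dx = ix - fx, dy = iy - fy, dz = iz - fz;
  double wx[2] = {1.0 - dx, dx}, wy[2] = {1.0 - dy, dy}, wz[2] = {1.0 - dz, dz};
  double acc = 0.0;
  for (int cz = 0; cz < 2; ++cz) {
    int zz = z0 + cz;
    for (int cy = 0; cy < 2; ++cy) {
      int yy = y0 + cy;
      for (int cx = 0; cx < 2; ++cx) {
        double w = wx[cx] * wy[cy] * wz[cz];
        if (w == 0.0) continue;  // exact-integer shifts never touch OOB corners
        int xx = x0 + cx;
        double val;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          val = outside;
        else
          val = v[(size_t)xx + (size_t)nx * ((size_t)yy + (size_t)ny * (size_t)zz)];
        if (ISNAN(val)) return NA_REAL;
        acc += w * val;
      }
    }
  }
  return acc;
}

// Resample `values` (on lattice dim/spacing/origin, world mm) onto an output
// lattice. Each output voxel's world position w is mapped to a source world
// position M %*% w + b before sampling. M/b are the *output-to-source* map.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector values, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  IntegerVector out_dim, NumericVector out_spacing,
                                  NumericVector out_origin, NumericMatrix M,
                                  NumericVector b, double outside) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *v = REAL(values);
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  size_t p = 0;
  for (int k = 0; k < oz; ++k) {
    double wz = out_origin[2] + k * out_spacing[2];
    for (int j = 0; j < oy; ++j) {
      double wy = out_origin[1] + j * out_spacing[1];
      for (int i = 0; i < ox; ++i, ++p) {
        double wx = out_origin[0] + i * out_spacing[0];
        double sx = m00 * wx + m01 * wy + m02 * wz + b[0];
        double sy = m10 * wx + m11 * wy + m12 * wz + b[1];
        double sz = m20 * wx + m21 * wy + m22 * wz + b[2];
        out[p] = tri_sample(v, nx, ny, nz, (sx - origin[0]) / spacing[0],
                            (sy - origin[1]) / spacing[1],
                            (sz - origin[2]) / spacing[2], outside);
      }
    }
  }
  return out;
}

// Ellipsoid indicator on the lattice: ((x-c)/a)^2 summed <= 1.
// [[Rcpp::export]]
LogicalVector ellipsoid_mask_cpp(IntegerVector dim, NumericVector spacing,
                                 NumericVector origin, NumericVector centre,
                                 NumericVector semiaxes) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((size_t)nx * ny * nz);
  size_t p = 0;
  for (int k = 0; k < nz; ++k) {
    double uz = (origin[2] + k * spacing[2] - centre[2]) / semiaxes[2];
    double z2 = uz * uz;
    for (int j = 0; j < ny; ++j) {
      double uy = (origin[1] + j * spacing[1] - centre[1]) / semiaxes[1];
      double yz2 = z2 + uy * uy;
      for (int i = 0; i < nx; ++i, ++p) {
        double ux = (origin[0] + i * spacing[0] - centre[0]) / semiaxes[0];
        out[p] = ux * ux + yz2 <= 1.0;
      }
    }
  }
  return out;
}

// Superposed flat-top/Gaussian-penumbra beam profiles with an axial
// envelope, attenuated outside the body ellipsoid. One pass over the grid;
// the caller normalises to the prescription.
// [[Rcpp::export]]
NumericVector beam_dose_cpp(IntegerVector dim, NumericVector spacing,
                            NumericVector origin, NumericVector gtv_c,
                            double r_field, double penumbra_sigma,
                            double axial_sigma, NumericMatrix dirs,
                            NumericVector weights, NumericVector body_c,
                            NumericVector body_a, double floor_frac) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nb = dirs.nrow();
  NumericVector out((size_t)nx * ny * nz);
  double inv2sp = 1.0 / (2.0 * penumbra_sigma * penumbra_sigma);
  double inv2ax = 1.0 / (2.0 * axial_sigma * axial_sigma);
  size_t p = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2] - gtv_c[2];
    double bz = (origin[2] + k * spacing[2] - body_c[2]) / body_a[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1] - gtv_c[1];
      double by = (origin[1] + j * spacing[1] - body_c[1]) / body_a[1];
      double byz = bz * bz + by * by;
      for (int i = 0; i < nx; ++i, ++p) {
        double px = origin[0] + i * spacing[0] - gtv_c[0];
        double p2 = px * px + py * py + pz * pz;
        double dose = 0.0;
        for (int b = 0; b < nb; ++b) {
          double a = px * dirs(b, 0) + py * dirs(b, 1) + pz * dirs(b, 2);
          double d2 = p2 - a * a;
          double d = d2 > 0.0 ? std::sqrt(d2) : 0.0;
          double over = d - r_field;
          if (over < 0.0) over = 0.0;
          dose += weights[b] *
            std::exp(-over * over * inv2sp) * std::exp(-a * a * inv2ax);
        }
        double bx = (origin[0] + i * spacing[0] - body_c[0]) / body_a[0];
        bool body = bx * bx + byz <= 1.0;
        out[p] = dose * (floor_frac + (body ? 1.0 - floor_frac : 0.0));
      }
    }
  }
  return out;
}

// Separable convolution of a 3-D field with per-axis kernels (NULL = skip),
// reflecting boundary. Any NA inside a kernel window makes the output NA.
// Tap order matches the naive sum, so results are bit-identical to a
// straightforward R implementation.
// [[Rcpp::export]]
NumericVector blur3_cpp(NumericVector values, IntegerVector dim, List kernels) {
  int nd[3] = {dim[0], dim[1], dim[2]};
  size_t n = (size_t)nd[0] * nd[1] * nd[2];
  std::vector<double> cur(REAL(values), REAL(values) + n), nxt(n);
  ptrdiff_t strides[3] = {1, nd[0], (ptrdiff_t)nd[0] * nd[1]};
  for (int ax = 0; ax < 3; ++ax) {
    if (Rf_isNull(kernels[ax])) continue;
    NumericVector k = kernels[ax];
    int r = ((int)k.size() - 1) / 2;
    int nax = nd[ax];
    ptrdiff_t st = strides[ax];
    size_t p = 0;
    for (int kz = 0; kz < nd[2]; ++kz)
      for (int j = 0; j < nd[1]; ++j)
        for (int i = 0; i < nd[0]; ++i, ++p) {
          int c = ax == 0 ? i : (ax == 1 ? j : kz);
          double acc = 0.0;
          bool na = false;
          for (int t = -r; t <= r; ++t) {
            int cc = c + t;
            while (cc < 0 || cc >= nax) {
              if (cc < 0) cc = -cc;            // 1-based: 2 - idx
              if (cc >= nax) cc = 2 * nax - 2 - cc;  // 1-based: 2n - idx
            }
            double val = cur[(ptrdiff_t)p + (ptrdiff_t)(cc - c) * st];
            if (ISNAN(val)) { na = true; break; }
            acc += k[t + r] * val;
          }
          nxt[p] = na ? NA_REAL : acc;
        }
    cur.swap(nxt);
  }
  NumericVector out(n);
  std::copy(cur.begin(), cur.end(), REAL(out));
  return out;
}

// Mean over fractions of the planned dose sampled at x + shift_f (shifts in
// mm, rows of `shifts`). Out-of-grid contributions are 0 Gy.
//
// A per-fraction shift is constant over the grid, so trilinear sampling
// reduces to 8 weighted integer-offset copies of the array; each copy is a
// sequential pass over memory, which is far faster than per-voxel gathers.
// [[Rcpp::export]]
NumericVector accumulate_cpp(NumericVector values, IntegerVector dim,
                             NumericVector spacing, NumericMatrix shifts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nf = shifts.nrow();
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  double *o = REAL(out);
  const double *v = REAL(values);
  // group identical shifts so that e.g. an all-zero residual course is the
  // exact identity (weight 1.0) rather than a sum of rounded 1/n terms
  std::vector<int> mult;
  std::vector<double> ux, uy, uz;
  for (int f = 0; f < nf; ++f) {
    bool found = false;
    for (size_t u = 0; u < ux.size(); ++u) {
      if (shifts(f, 0) == ux[u] && shifts(f, 1) == uy[u] &&
          shifts(f, 2) == uz[u]) {
        ++mult[u];
        found = true;
        break;
      }
    }
    if (!found) {
      ux.push_back(shifts(f, 0));
      uy.push_back(shifts(f, 1));
      uz.push_back(shifts(f, 2));
      mult.push_back(1);
    }
  }
  for (size_t u = 0; u < ux.size(); ++u) {
    double wf = (double)mult[u] / nf;
    // voxel-unit shift split into integer base + fractional part
    double sh[3] = {ux[u], uy[u], uz[u]};
    double sv[3], fr[3];
    int base[3];
    for (int a = 0; a < 3; ++a) {
      sv[a] = sh[a] / spacing[a];
      base[a] = (int)std::floor(sv[a]);
      fr[a] = sv[a] - base[a];
    }
    for (int cz = 0; cz < 2; ++cz) {
      double wz = cz ? fr[2] : 1.0 - fr[2];
      if (wz == 0.0) continue;
      int oz = base[2] + cz;
      int k0 = std::max(0, -oz), k1 = std::min(nz - 1, nz - 1 - oz);
      for (int cy = 0; cy < 2; ++cy) {
        double wy = cy ? fr[1] : 1.0 - fr[1];
        if (wy == 0.0) continue;
        int oy = base[1] + cy;
        int j0 = std::max(0, -oy), j1 = std::min(ny - 1, ny - 1 - oy);
        for (int cx = 0; cx < 2; ++cx) {
          double w = wf * wz * wy * (cx ? fr[0] : 1.0 - fr[0]);
          if (w == 0.0) continue;
          int ox = base[0] + cx;
          int i0 = std::max(0, -ox), i1 = std::min(nx - 1, nx - 1 - ox);
          if (i0 > i1 || j0 > j1 || k0 > k1) continue;
          ptrdiff_t src_off = (ptrdiff_t)ox + (ptrdiff_t)nx * (oy + (ptrdiff_t)ny * oz);
          for (int k = k0; k <= k1; ++k)
            for (int j = j0; j <= j1; ++j) {
              size_t row = (size_t)nx * (j + (size_t)ny * k);
              const double *src = v + row + src_off + i0;
              double *dst = o + row + i0;
              for (int i = i0; i <= i1; ++i)
                *dst++ += w * *src++;
            }
        }
      }
    }
  }
  return out;
}
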