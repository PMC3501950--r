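#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major linear index for a (nx, ny, nz) array, 0-based.
static inline R_xlen_t lin3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)j * nx + (R_xlen_t)k * (R_xlen_t)nx * ny;
}

// Deposit isotropic Gaussians (one per particle) onto a grid of voxel
// centers. `sigma` parametrizes the covariance sigma * I3 in voxel^2 units,
// i.e. the standard deviation is sqrt(sigma) voxels per axis. The kernel is
// truncated per axis at trunc_sd standard deviations (no renormalization).
// Positions in mm; returned values are densities per mm^3.
// [[Rcpp::export]]
NumericVector cpp_deposit_gaussian(NumericMatrix pos, double sigma,
                                   double trunc_sd, IntegerVector dims,
                                   NumericVector spacing,
                                   NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const int np = pos.nrow();
  const double sd_vox = std::sqrt(sigma);
  double sd_mm[3], nc[3];
  for (int a = 0; a < 3; ++a) {
    sd_mm[a] = sd_vox * spacing[a];
    nc[a] = 1.0 / (std::sqrt(2.0 * M_PI) * sd_mm[a]);
  }
  const double r_vox = trunc_sd * sd_vox;
  std::vector<double> wx(64), wy(64), wz(64);
  const int wmax = 63;
  for (int p = 0; p < np; ++p) {
    double c[3];
    int lo[3], hi[3];
    bool any = true;
    for (int a = 0; a < 3; ++a) {
      c[a] = (pos(p, a) - origin[a]) / spacing[a];
      lo[a] = std::max(0, (int)std::ceil(c[a] - r_vox));
      hi[a] = std::min(dims[a] - 1, (int)std::floor(c[a] + r_vox));
      if (lo[a] > hi[a]) any = false;
      if (hi[a] - lo[a] > wmax) {  // very wide kernels fall back to resize
        wx.resize(hi[a] - lo[a] + 1); wy.resize(hi[a] - lo[a] + 1);
        wz.resize(hi[a] - lo[a] + 1);
      }
    }
    if (!any) continue;
    for (int i = lo[0]; i <= hi[0]; ++i) {
      double d = (i - c[0]) * spacing[0];
      wx[i - lo[0]] = nc[0] * std::exp(-0.5 * d * d / (sd_mm[0] * sd_mm[0]));
    }
    for (int j = lo[1]; j <= hi[1]; ++j) {
      double d = (j - c[1]) * spacing[1];
      wy[j - lo[1]] = nc[1] * std::exp(-0.5 * d * d / (sd_mm[1] * sd_mm[1]));
    }
    for (int k = lo[2]; k <= hi[2]; ++k) {
      double d = (k - c[2]) * spacing[2];
      wz[k - lo[2]] = nc[2] * std::exp(-0.5 * d * d / (sd_mm[2] * sd_mm[2]));
    }
    for (int k = lo[2]; k <= hi[2]; ++k) {
      for (int j = lo[1]; j <= hi[1]; ++j) {
        const double wyz = wy[j - lo[1]] * wz[k - lo[2]];
        double *col = REAL(out) + lin3(lo[0], j, k, nx, ny);
        const double *wxp = wx.data();
        for (int i = lo[0]; i <= hi[0]; ++i)
          col[i - lo[0]] += wxp[i - lo[0]] * wyz;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Second-order central differences (one-sided at grid faces), per mm.
// Returns an (nx*ny*nz) x 3 matrix of gradient components.
// [[Rcpp::export]]
NumericMatrix cpp_gradient3(NumericVector values, IntegerVector dims,
                            NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix g(n, 3);
  const double *v = REAL(values);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin3(i, j, k, nx, ny);
        // x
        if (nx == 1) g(id, 0) = 0.0;
        else if (i == 0)
          g(id, 0) = (v[lin3(1, j, k, nx, ny)] - v[id]) / spacing[0];
        else if (i == nx - 1)
          g(id, 0) = (v[id] - v[lin3(nx - 2, j, k, nx, ny)]) / spacing[0];
        else
          g(id, 0) = (v[lin3(i + 1, j, k, nx, ny)] -
                      v[lin3(i - 1, j, k, nx, ny)]) / (2.0 * spacing[0]);
        // y
        if (ny == 1) g(id, 1) = 0.0;
        else if (j == 0)
          g(id, 1) = (v[lin3(i, 1, k, nx, ny)] - v[id]) / spacing[1];
        else if (j == ny - 1)
          g(id, 1) = (v[id] - v[lin3(i, ny - 2, k, nx, ny)]) / spacing[1];
        else
          g(id, 1) = (v[lin3(i, j + 1, k, nx, ny)] -
                      v[lin3(i, j - 1, k, nx, ny)]) / (2.0 * spacing[1]);
        // z
        if (nz == 1) g(id, 2) = 0.0;
        else if (k == 0)
          g(id, 2) = (v[lin3(i, j, 1, nx, ny)] - v[id]) / spacing[2];
        else if (k == nz - 1)
          g(id, 2) = (v[id] - v[lin3(i, j, nz - 2, nx, ny)]) / spacing[2];
        else
          g(id, 2) = (v[lin3(i, j, k + 1, nx, ny)] -
                      v[lin3(i, j, k - 1, nx, ny)]) / (2.0 * spacing[2]);
      }
  return g;
}

// central-difference gradient component of a volume at voxel (i,j,k)
static inline double grad_at(const double *v, const int *dims,
                             const double *spacing, int i, int j, int k,
                             int axis) {
  const int nx = dims[0], ny = dims[1];
  int c[3] = { i, j, k };
  const int n = dims[axis];
  if (n == 1) return 0.0;
  int cm[3] = { i, j, k }, cp[3] = { i, j, k };
  double denom = 2.0 * spacing[axis];
  if (c[axis] == 0) { cp[axis] = 1; denom = spacing[axis]; }
  else if (c[axis] == n - 1) { cm[axis] = n - 2; denom = spacing[axis]; }
  else { cm[axis] -= 1; cp[axis] += 1; }
  return (v[lin3(cp[0], cp[1], cp[2], nx, ny)] -
          v[lin3(cm[0], cm[1], cm[2], nx, ny)]) / denom;
}

// Trilinear interpolation, at arbitrary points, of the central-difference
// gradient field of a volume (equivalent to materializing the gradient on
// the grid and interpolating it, without the intermediate volume).
// Points are clamped into the voxel-center box. Returns an n x 3 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_gradient_interp(NumericVector values, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(values);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; ++p) {
    double c[3];
    c[0] = (pts(p, 0) - origin[0]) / spacing[0];
    c[1] = (pts(p, 1) - origin[1]) / spacing[1];
    c[2] = (pts(p, 2) - origin[2]) / spacing[2];
    c[0] = std::min(std::max(c[0], 0.0), (double)(nx - 1));
    c[1] = std::min(std::max(c[1], 0.0), (double)(ny - 1));
    c[2] = std::min(std::max(c[2], 0.0), (double)(nz - 1));
    int i0 = std::max(0, std::min((int)std::floor(c[0]), nx - 2));
    int j0 = std::max(0, std::min((int)std::floor(c[1]), ny - 2));
    int k0 = std::max(0, std::min((int)std::floor(c[2]), nz - 2));
    const double fx = c[0] - i0, fy = c[1] - j0, fz = c[2] - k0;
    const int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
              k1 = std::min(k0 + 1, nz - 1);
    for (int a = 0; a < 3; ++a) {
      const double g000 = grad_at(v, INTEGER(dims), REAL(spacing), i0, j0, k0, a),
                   g100 = grad_at(v, INTEGER(dims), REAL(spacing), i1, j0, k0, a),
                   g010 = grad_at(v, INTEGER(dims), REAL(spacing), i0, j1, k0, a),
                   g110 = grad_at(v, INTEGER(dims), REAL(spacing), i1, j1, k0, a),
                   g001 = grad_at(v, INTEGER(dims), REAL(spacing), i0, j0, k1, a),
                   g101 = grad_at(v, INTEGER(dims), REAL(spacing), i1, j0, k1, a),
                   g011 = grad_at(v, INTEGER(dims), REAL(spacing), i0, j1, k1, a),
                   g111 = grad_at(v, INTEGER(dims), REAL(spacing), i1, j1, k1, a);
      const double c00 = g000 * (1 - fx) + g100 * fx;
      const double c10 = g010 * (1 - fx) + g110 * fx;
      const double c01 = g001 * (1 - fx) + g101 * fx;
      const double c11 = g011 * (1 - fx) + g111 * fx;
      out(p, a) = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                  (c01 * (1 - fy) + c11 * fy) * fz;
    }
  }
  return out;
}

static inline double trilinear_one(const double *v, const int *dims,
                                   const double *spacing, const double *origin,
                                   double x, double y, double z,
                                   bool outside_zero) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double c[3] = { (x - origin[0]) / spacing[0],
                  (y - origin[1]) / spacing[1],
                  (z - origin[2]) / spacing[2] };
  if (outside_zero) {
    if (c[0] < 0 || c[0] > nx - 1 || c[1] < 0 || c[1] > ny - 1 ||
        c[2] < 0 || c[2] > nz - 1)
      return 0.0;
  } else {
    c[0] = std::min(std::max(c[0], 0.0), (double)(nx - 1));
    c[1] = std::min(std::max(c[1], 0.0), (double)(ny - 1));
    c[2] = std::min(std::max(c[2], 0.0), (double)(nz - 1));
  }
  int i0 = std::min((int)std::floor(c[0]), nx - 2); if (nx == 1) i0 = 0;
  int j0 = std::min((int)std::floor(c[1]), ny - 2); if (ny == 1) j0 = 0;
  int k0 = std::min((int)std::floor(c[2]), nz - 2); if (nz == 1) k0 = 0;
  i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
  const double fx = c[0] - i0, fy = c[1] - j0, fz = c[2] - k0;
  const int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
            k1 = std::min(k0 + 1, nz - 1);
  const double v000 = v[lin3(i0, j0, k0, nx, ny)],
               v100 = v[lin3(i1, j0, k0, nx, ny)],
               v010 = v[lin3(i0, j1, k0, nx, ny)],
               v110 = v[lin3(i1, j1, k0, nx, ny)],
               v001 = v[lin3(i0, j0, k1, nx, ny)],
               v101 = v[lin3(i1, j0, k1, nx, ny)],
               v011 = v[lin3(i0, j1, k1, nx, ny)],
               v111 = v[lin3(i1, j1, k1, nx, ny)];
  const double c00 = v000 * (1 - fx) + v100 * fx;
  const double c10 = v010 * (1 - fx) + v110 * fx;
  const double c01 = v001 * (1 - fx) + v101 * fx;
  const double c11 = v011 * (1 - fx) + v111 * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Trilinear interpolation of a scalar volume at arbitrary points (mm).
// outside_zero = TRUE returns 0 beyond the voxel-center bounding box,
// otherwise coordinates are clamped to the box.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts, bool outside_zero) {
  const int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p)
    out[p] = trilinear_one(REAL(values), INTEGER(dims), REAL(spacing),
                           REAL(origin), pts(p, 0), pts(p, 1), pts(p, 2),
                           outside_zero);
  return out;
}

// Exact nearest inside-voxel map by brute force: for every voxel, the
// 1-based linear index of the nearest voxel with inside == TRUE (itself if
// inside). Sites are scanned in ascending linear index with strict-<
// updates, so ties resolve to the lowest linear index.
// [[Rcpp::export]]
IntegerVector cpp_nearest_inside_map(LogicalVector inside, IntegerVector dims,
                                     NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> si, sj, sk;
  std::vector<R_xlen_t> sidx;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin3(i, j, k, nx, ny);
        if (inside[id]) { si.push_back(i); sj.push_back(j); sk.push_back(k);
                          sidx.push_back(id); }
      }
  if (sidx.empty()) stop("geometry has no inside voxel");
  IntegerVector out(n);
  const double sx2 = spacing[0] * spacing[0], sy2 = spacing[1] * spacing[1],
               sz2 = spacing[2] * spacing[2];
  const size_t ns = sidx.size();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin3(i, j, k, nx, ny);
        if (inside[id]) { out[id] = (int)(id + 1); continue; }
        double best = R_PosInf; R_xlen_t bidx = sidx[0];
        for (size_t s = 0; s < ns; ++s) {
          const double dx = i - si[s], dy = j - sj[s], dz = k - sk[s];
          const double d2 = dx * dx * sx2 + dy * dy * sy2 + dz * dz * sz2;
          if (d2 < best) { best = d2; bidx = sidx[s]; }
        }
        out[id] = (int)(bidx + 1);
      }
  out.attr("dim") = dims;
  return out;
}

// Cone-beam ray casting: for each detector pixel, sum equidistant trilinear
// samples of the volume along the ray from the source through the pixel
// center, times the step length (line-integral approximation).
// [[Rcpp::export]]
NumericMatrix cpp_raycast(NumericVector values, IntegerVector dims,
                          NumericVector spacing, NumericVector origin,
                          NumericVector src, NumericVector det00,
                          NumericVector du, NumericVector dv,
                          int nu, int nv, double step) {
  NumericMatrix img(nv, nu);  // row = v, col = u
  const double *vol = REAL(values);
  const int *d = INTEGER(dims);
  const double *sp = REAL(spacing), *org = REAL(origin);
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = org[a];
    hi[a] = org[a] + (d[a] - 1) * sp[a];
  }
  for (int iu = 0; iu < nu; ++iu) {
    for (int iv = 0; iv < nv; ++iv) {
      double dir[3], p[3], len = 0.0;
      for (int a = 0; a < 3; ++a) {
        p[a] = det00[a] + iu * du[a] + iv * dv[a];
        dir[a] = p[a] - src[a];
        len += dir[a] * dir[a];
      }
      len = std::sqrt(len);
      for (int a = 0; a < 3; ++a) dir[a] /= len;
      // slab intersection with the voxel-center bounding box
      double tn = 0.0, tf = len;
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(dir[a]) < 1e-12) {
          if (src[a] < lo[a] || src[a] > hi[a]) { miss = true; break; }
        } else {
          double t1 = (lo[a] - src[a]) / dir[a];
          double t2 = (hi[a] - src[a]) / dir[a];
          if (t1 > t2) std::swap(t1, t2);
          tn = std::max(tn, t1);
          tf = std::min(tf, t2);
        }
      }
      double acc = 0.0;
      if (!miss && tf > tn) {
        const int nsamp = (int)std::ceil((tf - tn) / step);
        for (int s = 0; s < nsamp; ++s) {
          const double t = tn + (s + 0.5) * step;
          if (t > tf) break;
          acc += trilinear_one(vol, d, sp, org,
                               src[0] + t * dir[0], src[1] + t * dir[1],
                               src[2] + t * dir[2], true);
        }
        acc *= step;
      }
      img(iv, iu) = acc;
    }
  }
  return img;
}
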