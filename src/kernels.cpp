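#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian spreading and the analytic gradient of the real-space correlation
// coefficient. All lengths here are in Angstrom (the map frame); callers
// convert model coordinates (nm) at the boundary. Kernels are unnormalized
// Gaussians truncated on a sphere of radius cutoff*sigma; voxels outside
// every atom's sphere are exactly zero.

static inline void patch_range(double x, double r, double origin, double vox,
                               int dim, int &lo, int &hi) {
  lo = (int)std::ceil((x - r - origin) / vox);
  hi = (int)std::floor((x + r - origin) / vox);
  if (lo < 0) lo = 0;
  if (hi > dim - 1) hi = dim - 1;
}

// [[Rcpp::export]]
NumericVector spread_density_cpp(NumericMatrix coords, NumericVector weights,
                                 IntegerVector dims, NumericVector voxel,
                                 NumericVector origin, double sigma,
                                 double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int natom = coords.nrow();
  NumericVector rho(nx * ny * nz);
  const double r = cutoff * sigma, r2 = r * r;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int a = 0; a < natom; ++a) {
    const double w = weights[a];
    if (w == 0.0) continue;
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    int i0, i1, j0, j1, k0, k1;
    patch_range(xa, r, origin[0], voxel[0], nx, i0, i1);
    patch_range(ya, r, origin[1], voxel[1], ny, j0, j1);
    patch_range(za, r, origin[2], voxel[2], nz, k0, k1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - za, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - ya, dyz2 = dy * dy + dz2;
        if (dyz2 > r2) continue;
        const size_t base = (size_t)(k * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - xa;
          const double d2 = dx * dx + dyz2;
          if (d2 <= r2) rho[base + i] += w * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return rho;
}

// One-call spread + gradient accumulation: computes the simulated density
// and, reusing the cached kernel values from the spreading pass, the
// per-atom vectors A_a = sum_v exp(v) g_a(v) (x_v - x_a) and
// B_a = sum_v sim(v) g_a(v) (x_v - x_a). Arithmetic is identical to
// calling spread_density_cpp followed by cc_gradient_terms_cpp; the
// Gaussians are simply not evaluated twice.
// [[Rcpp::export]]
List fit_kernel_cpp(NumericMatrix coords, NumericVector weights,
                    NumericVector exp_map, IntegerVector dims,
                    NumericVector voxel, NumericVector origin, double sigma,
                    double cutoff, bool want_grad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int natom = coords.nrow();
  NumericVector rho(nx * ny * nz);
  NumericMatrix A(natom, 3), B(natom, 3);
  const double r = cutoff * sigma, r2 = r * r;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector< std::vector<double> > gcache(natom);
  std::vector< std::vector<size_t> > vcache(natom);
  for (int a = 0; a < natom; ++a) {
    const double w = weights[a];
    if (w == 0.0) continue;
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    int i0, i1, j0, j1, k0, k1;
    patch_range(xa, r, origin[0], voxel[0], nx, i0, i1);
    patch_range(ya, r, origin[1], voxel[1], ny, j0, j1);
    patch_range(za, r, origin[2], voxel[2], nz, k0, k1);
    std::vector<double> &gv = gcache[a];
    std::vector<size_t> &vv = vcache[a];
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - za, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - ya, dyz2 = dy * dy + dz2;
        if (dyz2 > r2) continue;
        const size_t base = (size_t)(k * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - xa;
          const double d2 = dx * dx + dyz2;
          if (d2 <= r2) {
            const double g = w * std::exp(-d2 * inv2s2);
            rho[base + i] += g;
            if (want_grad) { gv.push_back(g); vv.push_back(base + i); }
          }
        }
      }
    }
  }
  if (want_grad) {
    for (int a = 0; a < natom; ++a) {
      if (weights[a] == 0.0) continue;
      const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
      double Ax = 0, Ay = 0, Az = 0, Bx = 0, By = 0, Bz = 0;
      const std::vector<double> &gv = gcache[a];
      const std::vector<size_t> &vv = vcache[a];
      for (size_t t = 0; t < vv.size(); ++t) {
        const size_t v = vv[t];
        const double g = gv[t];
        const size_t i = v % nx, j = (v / nx) % ny, k = v / ((size_t)nx * ny);
        const double dx = origin[0] + i * voxel[0] - xa;
        const double dy = origin[1] + j * voxel[1] - ya;
        const double dz = origin[2] + k * voxel[2] - za;
        const double ge = g * exp_map[v], gs = g * rho[v];
        Ax += ge * dx; Ay += ge * dy; Az += ge * dz;
        Bx += gs * dx; By += gs * dy; Bz += gs * dz;
      }
      A(a, 0) = Ax; A(a, 1) = Ay; A(a, 2) = Az;
      B(a, 0) = Bx; B(a, 1) = By; B(a, 2) = Bz;
    }
  }
  return List::create(_["sim"] = rho, _["A"] = A, _["B"] = B);
}

// Returns, for each atom, the accumulated vectors
//   A_a = sum_v exp(v) g_a(v) (x_v - x_a)   and
//   B_a = sum_v sim(v) g_a(v) (x_v - x_a)
// from which the gradient of c.c. = S_ab / sqrt(S_aa S_bb) follows as
//   d cc / d x_a = (A_a / sigma^2) / sqrt(S_aa S_bb) - cc (B_a / sigma^2) / S_bb.
// exp_map and sim share the grid; sim must be the spread of the same coords.
// [[Rcpp::export]]
List cc_gradient_terms_cpp(NumericMatrix coords, NumericVector weights,
                           NumericVector exp_map, NumericVector sim,
                           IntegerVector dims, NumericVector voxel,
                           NumericVector origin, double sigma, double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int natom = coords.nrow();
  NumericMatrix A(natom, 3), B(natom, 3);
  const double r = cutoff * sigma, r2 = r * r;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int a = 0; a < natom; ++a) {
    const double w = weights[a];
    if (w == 0.0) continue;
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    int i0, i1, j0, j1, k0, k1;
    patch_range(xa, r, origin[0], voxel[0], nx, i0, i1);
    patch_range(ya, r, origin[1], voxel[1], ny, j0, j1);
    patch_range(za, r, origin[2], voxel[2], nz, k0, k1);
    double Ax = 0, Ay = 0, Az = 0, Bx = 0, By = 0, Bz = 0;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - za, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - ya, dyz2 = dy * dy + dz2;
        if (dyz2 > r2) continue;
        const size_t base = (size_t)(k * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - xa;
          const double d2 = dx * dx + dyz2;
          if (d2 > r2) continue;
          const double g = w * std::exp(-d2 * inv2s2);
          const double ge = g * exp_map[base + i], gs = g * sim[base + i];
          Ax += ge * dx; Ay += ge * dy; Az += ge * dz;
          Bx += gs * dx; By += gs * dy; Bz += gs * dz;
        }
      }
    }
    A(a, 0) = Ax; A(a, 1) = Ay; A(a, 2) = Az;
    B(a, 0) = Bx; B(a, 1) = By; B(a, 2) = Bz;
  }
  return List::create(_["A"] = A, _["B"] = B);
}
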