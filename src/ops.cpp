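// Low-level numerical kernels: trilinear/nearest resampling, displacement
// field algebra (composition, scaling-and-squaring exponential), the
// stationary-velocity demons iteration loop, separable Gaussian smoothing,
// an exact anisotropic Euclidean distance transform that also propagates
// the label of the nearest site, tube voxelization for phantoms, and
// geodesic paths over the 26-connected foreground graph.
//
// Conventions: volumes are R arrays in column-major order with dims
// (nx, ny, nz); voxel coordinates are 0-based doubles; displacement fields
// are 4D arrays (nx, ny, nz, 3) in voxel units on the grid they act on.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double sample_trilinear(const double* vol, int nx, int ny, int nz,
                                      double x, double y, double z) {
  // outside the grid -> 0 (background); border handled by clamping the
  // interpolation cell after the outside test
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return 0.0;
  int x0 = clampi((int)std::floor(x), 0, nx - 1);
  int y0 = clampi((int)std::floor(y), 0, ny - 1);
  int z0 = clampi((int)std::floor(z), 0, nz - 1);
  int x1 = clampi(x0 + 1, 0, nx - 1);
  int y1 = clampi(y0 + 1, 0, ny - 1);
  int z1 = clampi(z0 + 1, 0, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (fx < 0) fx = 0; if (fx > 1) fx = 1;
  if (fy < 0) fy = 0; if (fy > 1) fy = 1;
  if (fz < 0) fz = 0; if (fz > 1) fz = 1;
  size_t sxy = (size_t)nx * ny;
  #define V(i,j,k) vol[(size_t)(i) + (size_t)nx * (j) + sxy * (k)]
  double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
  double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
  double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
  double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
  #undef V
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

static inline double sample_nearest(const double* vol, int nx, int ny, int nz,
                                    double x, double y, double z) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return vol[(size_t)i + (size_t)nx * j + (size_t)nx * ny * k];
}

// [[Rcpp::export]]
NumericVector c_sample_points(NumericVector vol, NumericMatrix pts, int interp) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int i = 0; i < n; ++i) {
    if (interp == 0)
      out[i] = sample_trilinear(v, nx, ny, nz, pts(i,0), pts(i,1), pts(i,2));
    else
      out[i] = sample_nearest(v, nx, ny, nz, pts(i,0), pts(i,1), pts(i,2));
  }
  return out;
}

// Resample through an affine voxel->voxel map: src voxel = A %*% (i,j,k,1).
// A is 3x4, out grid dims odim. interp 0 = trilinear, 1 = nearest.
// [[Rcpp::export]]
NumericVector c_resample_affine(NumericVector vol, NumericMatrix A,
                                IntegerVector odim, int interp) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((size_t)ox * oy * oz);
  out.attr("dim") = odim;
  const double* v = REAL(vol);
  double* o = REAL(out);
  size_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        double sx = A(0,0)*i + A(0,1)*j + A(0,2)*k + A(0,3);
        double sy = A(1,0)*i + A(1,1)*j + A(1,2)*k + A(1,3);
        double sz = A(2,0)*i + A(2,1)*j + A(2,2)*k + A(2,3);
        o[idx] = (interp == 0)
          ? sample_trilinear(v, nx, ny, nz, sx, sy, sz)
          : sample_nearest(v, nx, ny, nz, sx, sy, sz);
      }
  return out;
}

// Warp a volume living on the same grid as the displacement field:
// out(x) = vol(x + u(x)); u in voxel units, dims (nx,ny,nz,3).
// [[Rcpp::export]]
NumericVector c_warp(NumericVector vol, NumericVector disp, int interp) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = d;
  const double* v = REAL(vol);
  const double* u = REAL(disp);
  double* o = REAL(out);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + u[idx];
        double y = j + u[idx + nvox];
        double z = k + u[idx + 2 * nvox];
        o[idx] = (interp == 0)
          ? sample_trilinear(v, nx, ny, nz, x, y, z)
          : sample_nearest(v, nx, ny, nz, x, y, z);
      }
  return out;
}

// Composition w = v followed by u on the same grid:
// x + w(x) = (x + v(x)) + u(x + v(x)).  Samples of u outside the grid are 0.
static void compose_disp(const double* u, const double* v, double* w,
                         int nx, int ny, int nz) {
  size_t nvox = (size_t)nx * ny * nz;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + v[idx];
        double y = j + v[idx + nvox];
        double z = k + v[idx + 2 * nvox];
        w[idx]          = v[idx]          + sample_trilinear(u,          nx, ny, nz, x, y, z);
        w[idx + nvox]   = v[idx + nvox]   + sample_trilinear(u + nvox,   nx, ny, nz, x, y, z);
        w[idx + 2*nvox] = v[idx + 2*nvox] + sample_trilinear(u + 2*nvox, nx, ny, nz, x, y, z);
      }
}

// [[Rcpp::export]]
NumericVector c_compose(NumericVector u, NumericVector v) {
  IntegerVector d = u.attr("dim");
  NumericVector w(u.size());
  w.attr("dim") = d;
  compose_disp(REAL(u), REAL(v), REAL(w), d[0], d[1], d[2]);
  return w;
}

// Exponential of a stationary velocity field by scaling and squaring.
// [[Rcpp::export]]
NumericVector c_exp_field(NumericVector vel, int n_squarings) {
  IntegerVector d = vel.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t n3 = (size_t)nx * ny * nz * 3;
  std::vector<double> a(n3), b(n3);
  const double* v = REAL(vel);
  double scale = std::ldexp(1.0, -n_squarings);  // 2^-n
  for (size_t i = 0; i < n3; ++i) a[i] = v[i] * scale;
  for (int s = 0; s < n_squarings; ++s) {
    compose_disp(a.data(), a.data(), b.data(), nx, ny, nz);
    std::swap(a, b);
  }
  NumericVector out(n3);
  out.attr("dim") = d;
  std::copy(a.begin(), a.end(), REAL(out));
  return out;
}

// Separable Gaussian smoothing, sigma in voxels, kernel truncated at 3 sigma,
// renormalized at borders (no flux from outside).
static void gauss1d(std::vector<double>& buf, std::vector<double>& tmp,
                    const std::vector<double>& ker, int n, int stride,
                    double* data, size_t offset) {
  int r = (int)ker.size() - 1;  // ker holds [w0, w1, ..., wr]
  for (int i = 0; i < n; ++i) buf[i] = data[offset + (size_t)i * stride];
  for (int i = 0; i < n; ++i) {
    double acc = ker[0] * buf[i], wsum = ker[0];
    for (int t = 1; t <= r; ++t) {
      if (i - t >= 0) { acc += ker[t] * buf[i - t]; wsum += ker[t]; }
      if (i + t < n)  { acc += ker[t] * buf[i + t]; wsum += ker[t]; }
    }
    tmp[i] = acc / wsum;
  }
  for (int i = 0; i < n; ++i) data[offset + (size_t)i * stride] = tmp[i];
}

static void gauss3_inplace(double* v, int nx, int ny, int nz, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(r + 1);
  for (int t = 0; t <= r; ++t) ker[t] = std::exp(-0.5 * t * t / (sigma * sigma));
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> buf(nmax), tmp(nmax);
  size_t sxy = (size_t)nx * ny;
  // x lines
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      gauss1d(buf, tmp, ker, nx, 1, v, (size_t)j * nx + sxy * k);
  // y lines
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      gauss1d(buf, tmp, ker, ny, nx, v, (size_t)i + sxy * k);
  // z lines
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      gauss1d(buf, tmp, ker, nz, (int)sxy, v, (size_t)i + (size_t)j * nx);
}

// [[Rcpp::export]]
NumericVector c_gauss3(NumericVector vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  NumericVector out = clone(vol);
  int ncomp = (d.size() == 4) ? d[3] : 1;
  size_t nvox = (size_t)d[0] * d[1] * d[2];
  for (int c = 0; c < ncomp; ++c)
    gauss3_inplace(REAL(out) + (size_t)c * nvox, d[0], d[1], d[2], sigma);
  return out;
}

// Demons iteration loop at a single resolution level.
// F, M: fixed and moving (already smoothed), same grid. vel: initial velocity
// (voxel units) or empty. Returns list(vel, iterations, mse, converged).
// Update rule: Thirion force with the warped-moving gradient,
// d = (F - Mw) * grad(Mw) / (|grad|^2 + (F - Mw)^2), fluid-smoothed, added to
// the velocity, which is then elastic-smoothed (log-demons additive
// approximation). Convergence: relative MSE change < tol for 5 consecutive
// iterations.
// [[Rcpp::export]]
List c_demons_level(NumericVector F, NumericVector M, NumericVector vel,
                    int max_iter, double sigma_fluid, double sigma_elastic,
                    int n_squarings, double tol) {
  IntegerVector d = F.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector d4 = IntegerVector::create(nx, ny, nz, 3);

  NumericVector v(nvox * 3);
  v.attr("dim") = d4;
  if (vel.size() == (R_xlen_t)(nvox * 3)) std::copy(vel.begin(), vel.end(), v.begin());

  const double* f = REAL(F);
  double prev_mse = std::numeric_limits<double>::infinity();
  double mse = prev_mse;
  int still = 0, it = 0;
  bool converged = false;
  NumericVector upd(nvox * 3);
  upd.attr("dim") = d4;

  for (it = 0; it < max_iter; ++it) {
    NumericVector phi = c_exp_field(v, n_squarings);
    NumericVector Mw = c_warp(M, phi, 0);
    const double* mw = REAL(Mw);
    // gradient of warped moving by central differences + demons force
    double* u = REAL(upd);
    mse = 0.0;
    size_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          double diff = f[idx] - mw[idx];
          mse += diff * diff;
          int ip = i < nx-1 ? i+1 : i, im = i > 0 ? i-1 : i;
          int jp = j < ny-1 ? j+1 : j, jm = j > 0 ? j-1 : j;
          int kp = k < nz-1 ? k+1 : k, km = k > 0 ? k-1 : k;
          size_t sxy = (size_t)nx * ny;
          double gx = (mw[(size_t)ip + (size_t)nx*j + sxy*k] -
                       mw[(size_t)im + (size_t)nx*j + sxy*k]) / (ip - im);
          double gy = (mw[(size_t)i + (size_t)nx*jp + sxy*k] -
                       mw[(size_t)i + (size_t)nx*jm + sxy*k]) / (jp - jm);
          double gz = (mw[(size_t)i + (size_t)nx*j + sxy*kp] -
                       mw[(size_t)i + (size_t)nx*j + sxy*km]) / (kp - km);
          double g2 = gx*gx + gy*gy + gz*gz;
          double denom = g2 + diff * diff;
          double s = (denom > 1e-12) ? diff / denom : 0.0;
          u[idx]          = s * gx;
          u[idx + nvox]   = s * gy;
          u[idx + 2*nvox] = s * gz;
        }
    mse /= (double)nvox;
    if (prev_mse < std::numeric_limits<double>::infinity()) {
      double rel = std::fabs(prev_mse - mse) / (prev_mse > 1e-300 ? prev_mse : 1.0);
      still = (rel < tol) ? still + 1 : 0;
      if (still >= 5) { converged = true; break; }
    }
    prev_mse = mse;
    if (mse == 0.0) { converged = true; break; }
    NumericVector us = c_gauss3(upd, sigma_fluid);
    double* vv = REAL(v);
    const double* usp = REAL(us);
    for (size_t q = 0; q < nvox * 3; ++q) vv[q] += usp[q];
    gauss3_inplace(vv,            nx, ny, nz, sigma_elastic);
    gauss3_inplace(vv + nvox,     nx, ny, nz, sigma_elastic);
    gauss3_inplace(vv + 2*nvox,   nx, ny, nz, sigma_elastic);
  }
  return List::create(_["vel"] = v, _["iterations"] = it,
                      _["mse"] = mse, _["converged"] = converged);
}

// Jacobian determinant of x -> x + u(x), central differences, voxel units.
// [[Rcpp::export]]
NumericVector c_jacobian_det(NumericVector disp) {
  IntegerVector d = disp.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* u = REAL(disp);
  double* o = REAL(out);
  size_t sxy = (size_t)nx * ny;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int ip = i < nx-1 ? i+1 : i, im = i > 0 ? i-1 : i;
        int jp = j < ny-1 ? j+1 : j, jm = j > 0 ? j-1 : j;
        int kp = k < nz-1 ? k+1 : k, km = k > 0 ? k-1 : k;
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          const double* uc = u + (size_t)c * nvox;
          J[c][0] = (uc[(size_t)ip + (size_t)nx*j + sxy*k] -
                     uc[(size_t)im + (size_t)nx*j + sxy*k]) / (ip - im);
          J[c][1] = (uc[(size_t)i + (size_t)nx*jp + sxy*k] -
                     uc[(size_t)i + (size_t)nx*jm + sxy*k]) / (jp - jm);
          J[c][2] = (uc[(size_t)i + (size_t)nx*j + sxy*kp] -
                     uc[(size_t)i + (size_t)nx*j + sxy*km]) / (kp - km);
        }
        J[0][0] += 1.0; J[1][1] += 1.0; J[2][2] += 1.0;
        o[idx] = J[0][0]*(J[1][1]*J[2][2]-J[1][2]*J[2][1])
               - J[0][1]*(J[1][0]*J[2][2]-J[1][2]*J[2][0])
               + J[0][2]*(J[1][0]*J[2][1]-J[1][1]*J[2][0]);
      }
  return out;
}

// ---- exact anisotropic EDT with nearest-site label propagation ----------
// Felzenszwalb & Huttenlocher lower envelope of parabolas, generalized to
// arbitrary per-axis sample spacing; carries the label of the argmin site.

static void edt_pass(std::vector<double>& f, std::vector<int>& lab,
                     int n, double sp) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> vtx(n);
  std::vector<double> z(n + 1);
  std::vector<double> fout(n);
  std::vector<int> lout(n);
  int k = 0;
  int first = -1;
  for (int q = 0; q < n; ++q) if (f[q] < INF) { first = q; break; }
  if (first < 0) return;  // whole line empty
  vtx[0] = first; z[0] = -INF; z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double qq = q * sp;
    while (true) {
      int p = vtx[k];
      double pp = p * sp;
      double s = ((f[q] + qq*qq) - (f[p] + pp*pp)) / (2*qq - 2*pp);
      if (s <= z[k]) { --k; }
      else { ++k; vtx[k] = q; z[k] = s; z[k+1] = INF; break; }
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * sp;
    while (z[kk + 1] < qq) ++kk;
    int p = vtx[kk];
    double pp = p * sp;
    fout[q] = (qq - pp) * (qq - pp) + f[p];
    lout[q] = lab[p];
  }
  f = fout; lab = lout;
}

// sites: integer volume, >0 at labeled sites. Returns list(dist2, label):
// squared distance in mm^2 to the nearest site and that site's label.
// [[Rcpp::export]]
List c_edt_labels(IntegerVector sites, NumericVector spacing) {
  IntegerVector d = sites.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(nvox);
  std::vector<int> lab(nvox);
  const int* s = INTEGER(sites);
  for (size_t i = 0; i < nvox; ++i) {
    dist[i] = (s[i] > 0) ? 0.0 : INF;
    lab[i] = s[i];
  }
  size_t sxy = (size_t)nx * ny;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> fline(nmax);
  std::vector<int> lline(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t off = (size_t)j * nx + sxy * k;
      for (int i = 0; i < nx; ++i) { fline[i] = dist[off + i]; lline[i] = lab[off + i]; }
      fline.resize(nx); lline.resize(nx);
      edt_pass(fline, lline, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) { dist[off + i] = fline[i]; lab[off + i] = lline[i]; }
      fline.resize(nmax); lline.resize(nmax);
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t off = (size_t)i + sxy * k;
      for (int j = 0; j < ny; ++j) { fline[j] = dist[off + (size_t)j * nx]; lline[j] = lab[off + (size_t)j * nx]; }
      fline.resize(ny); lline.resize(ny);
      edt_pass(fline, lline, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) { dist[off + (size_t)j * nx] = fline[j]; lab[off + (size_t)j * nx] = lline[j]; }
      fline.resize(nmax); lline.resize(nmax);
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t off = (size_t)i + (size_t)j * nx;
      for (int k = 0; k < nz; ++k) { fline[k] = dist[off + sxy * k]; lline[k] = lab[off + sxy * k]; }
      fline.resize(nz); lline.resize(nz);
      edt_pass(fline, lline, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) { dist[off + sxy * k] = fline[k]; lab[off + sxy * k] = lline[k]; }
      fline.resize(nmax); lline.resize(nmax);
    }
  NumericVector dd(nvox); IntegerVector ll(nvox);
  std::copy(dist.begin(), dist.end(), dd.begin());
  std::copy(lab.begin(), lab.end(), ll.begin());
  dd.attr("dim") = d; ll.attr("dim") = d;
  return List::create(_["dist2"] = dd, _["label"] = ll);
}

// ---- phantom tube voxelization ------------------------------------------
// Axis-aligned grid: world = origin + index * spacing. pts: dense centerline
// polyline (n x 3, world mm) with per-sample radius. A voxel is foreground
// iff its distance to the nearest polyline sample is < that sample's radius.
// Returns mask and 1-based index of the nearest sample (0 outside).
// [[Rcpp::export]]
List c_tube_voxelize(IntegerVector dim, NumericVector spacing,
                     NumericVector origin, NumericMatrix pts,
                     NumericVector radii) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector mask(nvox), nearest(nvox);
  mask.attr("dim") = dim; nearest.attr("dim") = dim;
  int n = pts.nrow();
  double rmax = 0;
  for (int t = 0; t < n; ++t) rmax = std::max(rmax, radii[t]);
  // bounding box of the tube in voxel coords
  double lo[3] = {1e300,1e300,1e300}, hi[3] = {-1e300,-1e300,-1e300};
  for (int t = 0; t < n; ++t)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], pts(t,c));
      hi[c] = std::max(hi[c], pts(t,c));
    }
  int ilo[3], ihi[3];
  int nd[3] = {nx, ny, nz};
  for (int c = 0; c < 3; ++c) {
    ilo[c] = clampi((int)std::floor((lo[c] - rmax - origin[c]) / spacing[c]) - 1, 0, nd[c]-1);
    ihi[c] = clampi((int)std::ceil((hi[c] + rmax - origin[c]) / spacing[c]) + 1, 0, nd[c]-1);
  }
  std::vector<double> px(n), py(n), pz(n);
  for (int t = 0; t < n; ++t) { px[t]=pts(t,0); py[t]=pts(t,1); pz[t]=pts(t,2); }
  for (int k = ilo[2]; k <= ihi[2]; ++k) {
    double wz = origin[2] + k * spacing[2];
    for (int j = ilo[1]; j <= ihi[1]; ++j) {
      double wy = origin[1] + j * spacing[1];
      for (int i = ilo[0]; i <= ihi[0]; ++i) {
        double wx = origin[0] + i * spacing[0];
        double best = 1e300; int bt = -1;
        for (int t = 0; t < n; ++t) {
          double dx = wx - px[t], dy = wy - py[t], dz = wz - pz[t];
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 < best) { best = d2; bt = t; }
        }
        size_t idx = (size_t)i + (size_t)nx * j + (size_t)nx * ny * k;
        if (bt >= 0 && best < radii[bt] * radii[bt]) {
          mask[idx] = 1;
          nearest[idx] = bt + 1;
        }
      }
    }
  }
  return List::create(_["mask"] = mask, _["nearest"] = nearest);
}

// ---- connected components (26-connectivity) -----------------------------
// [[Rcpp::export]]
IntegerVector c_cc26(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector comp(nvox);
  comp.attr("dim") = d;
  const int* m = INTEGER(mask);
  int* c = INTEGER(comp);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s0 = 0; s0 < nvox; ++s0) {
    if (m[s0] == 0 || c[s0] != 0) continue;
    ++cur;
    stack.push_back(s0);
    c[s0] = cur;
    while (!stack.empty()) {
      size_t s = stack.back(); stack.pop_back();
      int i = (int)(s % nx), j = (int)((s / nx) % ny), k = (int)(s / ((size_t)nx*ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i+di, jj = j+dj, kk = k+dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            size_t t = (size_t)ii + (size_t)nx*jj + (size_t)nx*ny*kk;
            if (m[t] != 0 && c[t] == 0) { c[t] = cur; stack.push_back(t); }
          }
    }
  }
  return comp;
}

// ---- geodesic paths over the foreground graph ---------------------------
// Dijkstra over 26-connected foreground voxels. Edge cost = Euclidean step
// (mm) divided by pow(0.5*(depth[a]+depth[b]) + eps, depth_power): with
// depth_power 0 this is the plain geodesic distance; with > 0 the path is
// pulled toward the interior (medial) axis.
// Returns list(dist = mm distances from source (NA outside reachable set),
//              path = 1-based voxel indices source..target) ; target < 0
// means "farthest voxel" and path is traced to it.
// [[Rcpp::export]]
List c_geodesic(IntegerVector mask, NumericVector spacing, NumericVector depth,
                int source, int target, double depth_power) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  const int* m = INTEGER(mask);
  const double* dep = REAL(depth);
  std::vector<double> dist(nvox, std::numeric_limits<double>::infinity());
  std::vector<int> prev(nvox, -1);
  typedef std::pair<double, size_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  size_t src = (size_t)(source - 1);
  dist[src] = 0.0;
  pq.push(QE(0.0, src));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double dd = top.first; size_t s = top.second;
    if (dd > dist[s]) continue;
    int i = (int)(s % nx), j = (int)((s / nx) % ny), k = (int)(s / ((size_t)nx*ny));
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i+di, jj = j+dj, kk = k+dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          size_t t = (size_t)ii + (size_t)nx*jj + (size_t)nx*ny*kk;
          if (m[t] == 0) continue;
          double step = std::sqrt(di*di*spacing[0]*spacing[0] +
                                  dj*dj*spacing[1]*spacing[1] +
                                  dk*dk*spacing[2]*spacing[2]);
          double w = step;
          if (depth_power > 0) {
            double md = 0.5 * (dep[s] + dep[t]) + 0.1;
            w = step / std::pow(md, depth_power);
          }
          if (dist[s] + w < dist[t]) {
            dist[t] = dist[s] + w;
            prev[t] = (int)s;
            pq.push(QE(dist[t], t));
          }
        }
  }
  size_t tgt;
  if (target < 0) {
    tgt = src; double best = -1;
    for (size_t q = 0; q < nvox; ++q)
      if (m[q] && std::isfinite(dist[q]) && dist[q] > best) { best = dist[q]; tgt = q; }
  } else tgt = (size_t)(target - 1);
  std::vector<int> path;
  if (std::isfinite(dist[tgt])) {
    for (int cur = (int)tgt; cur != -1; cur = prev[cur]) path.push_back(cur + 1);
    std::reverse(path.begin(), path.end());
  }
  NumericVector dv(nvox);
  for (size_t q = 0; q < nvox; ++q)
    dv[q] = std::isfinite(dist[q]) ? dist[q] : NA_REAL;
  dv.attr("dim") = d;
  return List::create(_["dist"] = dv, _["path"] = IntegerVector(path.begin(), path.end()),
                      _["target"] = (double)(tgt + 1));
}
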