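#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---- 1D squared distance transform (Felzenszwalb & Huttenlocher) ----------
// f: squared distances at sample points spaced `s` apart; in-place result.
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double sq = qs * qs;
    while (true) {
      double vs = v[k] * s;
      double denom = 2.0 * qs - 2.0 * vs;
      double sec = (f[q] + sq - f[v[k]] - vs * vs) / denom;
      if (sec <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = sec;
        z[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (z[k + 1] < qs) ++k;
    double diff = qs - v[k] * s;
    d[q] = diff * diff + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Euclidean distance transform of a 3D logical array (distance from each
// foreground voxel to the nearest background voxel, in physical units).
// [[Rcpp::export]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims, NumericVector voxel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  // large finite stand-in for "no background seen yet": the parabola
  // envelope arithmetic must stay finite (infinities break the envelope
  // invariants and the stack index)
  const double INF = 1e15;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> line;
  // along x
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = out[base + x];
      dt1d(line, dx);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }
  // along y
  line.assign(ny, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)y * nx];
      dt1d(line, dy);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = line[y];
    }
  // along z
  line.assign(nz, 0.0);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(line, dz);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = line[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---- separable Gaussian blur ----------------------------------------------
static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-(double)(i * i) / s2);
    sum += k[i + r];
  }
  for (auto& v : k) v /= sum;
  return k;
}

static void blur_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
  std::vector<double> buf(len);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)j * nx * ny + (R_xlen_t)i * nx;
      else if (axis == 1) base = (R_xlen_t)j * nx * ny + i;
      else base = (R_xlen_t)j * nx + i;
      for (int t = 0; t < len; ++t) buf[t] = a[base + t * stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        for (int u = -r; u <= r; ++u) {
          int tt = t + u;
          if (tt < 0) tt = -tt;                    // reflect
          if (tt >= len) tt = 2 * len - 2 - tt;
          if (tt < 0) tt = 0;
          acc += k[u + r] * buf[tt];
        }
        a[base + t * stride] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector gauss_blur3d(NumericVector img, IntegerVector dims,
                           NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(img.begin(), img.end());
  blur_axis(a, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(a, nx, ny, nz, 1, sigma_vox[1]);
  if (nz > 1) blur_axis(a, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(img.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// ---- tube / sphere rasterization -------------------------------------------
// Voxel value = local chord thickness (µm) of the brightest structure covering
// it: 2*sqrt(r^2 - d^2) for a cylinder of radius r at axis distance d, same
// form for spheres. Voxel centers at origin + index * voxel. The axial (z)
// distance is taken from the voxel's z slab (centre ± z/2), not its centre:
// an optical section integrates light over its thickness, so a structure
// anywhere within the slab contributes. Lateral distances use the pixel
// centre (lateral sampling is fine relative to structure size).
// segs: columns x1 y1 z1 x2 y2 z2 r;  spheres: columns x y z r.
// [[Rcpp::export]]
NumericVector draw_structures(IntegerVector dims, NumericVector voxel,
                              NumericVector origin, NumericMatrix segs,
                              NumericMatrix spheres) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  NumericVector out((R_xlen_t)nx * ny * nz);

  auto clampi = [](int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); };

  for (int s = 0; s < segs.nrow(); ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5), r = segs(s, 6);
    double lx = x2 - x1, ly = y2 - y1, lz = z2 - z1;
    double L2 = lx * lx + ly * ly + lz * lz;
    int i0 = clampi((int)std::floor((std::min(x1, x2) - r - ox) / dx), 0, nx - 1);
    int i1 = clampi((int)std::ceil((std::max(x1, x2) + r - ox) / dx), 0, nx - 1);
    int j0 = clampi((int)std::floor((std::min(y1, y2) - r - oy) / dy), 0, ny - 1);
    int j1 = clampi((int)std::ceil((std::max(y1, y2) + r - oy) / dy), 0, ny - 1);
    int k0 = clampi((int)std::floor((std::min(z1, z2) - r - oz) / dz), 0, nz - 1);
    int k1 = clampi((int)std::ceil((std::max(z1, z2) + r - oz) / dz), 0, nz - 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double px = ox + i * dx, py = oy + j * dy, pz = oz + k * dz;
          double t = 0.0;
          if (L2 > 0) {
            t = ((px - x1) * lx + (py - y1) * ly + (pz - z1) * lz) / L2;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double qx = x1 + t * lx - px, qy = y1 + t * ly - py, qz = z1 + t * lz - pz;
          double qza = std::fabs(qz) - 0.5 * dz;
          if (qza < 0) qza = 0;
          double d2 = qx * qx + qy * qy + qza * qza;
          if (d2 <= r * r) {
            double val = 2.0 * std::sqrt(r * r - d2);
            R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
            if (val > out[idx]) out[idx] = val;
          }
        }
  }

  for (int s = 0; s < spheres.nrow(); ++s) {
    double cx = spheres(s, 0), cy = spheres(s, 1), cz = spheres(s, 2), r = spheres(s, 3);
    int i0 = clampi((int)std::floor((cx - r - ox) / dx), 0, nx - 1);
    int i1 = clampi((int)std::ceil((cx + r - ox) / dx), 0, nx - 1);
    int j0 = clampi((int)std::floor((cy - r - oy) / dy), 0, ny - 1);
    int j1 = clampi((int)std::ceil((cy + r - oy) / dy), 0, ny - 1);
    int k0 = clampi((int)std::floor((cz - r - oz) / dz), 0, nz - 1);
    int k1 = clampi((int)std::ceil((cz + r - oz) / dz), 0, nz - 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double px = ox + i * dx - cx, py = oy + j * dy - cy, pz = oz + k * dz - cz;
          double pza = std::fabs(pz) - 0.5 * dz;
          if (pza < 0) pza = 0;
          double d2 = px * px + py * py + pza * pza;
          if (d2 <= r * r) {
            double val = 2.0 * std::sqrt(r * r - d2);
            R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
            if (val > out[idx]) out[idx] = val;
          }
        }
  }

  out.attr("dim") = dims;
  return out;
}
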