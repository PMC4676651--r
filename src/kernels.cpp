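// Voxel-level kernels. All volumes are R arrays with dim = (nz, ny, nx),
// column-major, so linear index = z + nz * (y + ny * x), 0-based here.
// Spacing/origin vectors are ordered (z, y, x) in mm.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// reflect index into [0, n-1]
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// ---------------------------------------------------------------- smoothing

static void convolve_axis(const std::vector<double> &in, std::vector<double> &out,
                          int nz, int ny, int nx, int axis,
                          const std::vector<double> &kernel) {
  int half = (int)kernel.size() / 2;
  int n[3] = {nz, ny, nx};
  int len = n[axis];
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int pos[3] = {z, y, x};
        double acc = 0.0;
        for (int k = -half; k <= half; ++k) {
          int p[3] = {pos[0], pos[1], pos[2]};
          p[axis] = reflect(pos[axis] + k, len);
          acc += kernel[k + half] * in[idx3(p[0], p[1], p[2], nz, ny)];
        }
        out[idx3(z, y, x, nz, ny)] = acc;
      }
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int half = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * half + 1);
  double s = 0.0;
  for (int i = -half; i <= half; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + half] = v;
    s += v;
  }
  for (auto &v : k) v /= s;
  return k;
}

// [[Rcpp::export(name = ".cpp_gaussian_smooth3")]]
NumericVector cpp_gaussian_smooth3(NumericVector vol, IntegerVector dim,
                                   NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    std::vector<double> k = gauss_kernel(s);
    convolve_axis(a, b, nz, ny, nx, axis, k);
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------- Hessian eigenvalues

// analytic eigenvalues of a symmetric 3x3, ascending order
static void eig_sym3(double a00, double a11, double a22,
                     double a01, double a02, double a12,
                     double eig[3]) {
  double p1 = a01 * a01 + a02 * a02 + a12 * a12;
  if (p1 == 0.0) {
    eig[0] = a00; eig[1] = a11; eig[2] = a22;
  } else {
    double q = (a00 + a11 + a22) / 3.0;
    double p2 = (a00 - q) * (a00 - q) + (a11 - q) * (a11 - q) +
                (a22 - q) * (a22 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b00 = (a00 - q) / p, b11 = (a11 - q) / p, b22 = (a22 - q) / p;
    double b01 = a01 / p, b02 = a02 / p, b12 = a12 / p;
    double detB = b00 * (b11 * b22 - b12 * b12) -
                  b01 * (b01 * b22 - b12 * b02) +
                  b02 * (b01 * b12 - b11 * b02);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    double e1 = q + 2.0 * p * std::cos(phi);
    double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    double e2 = 3.0 * q - e1 - e3;
    eig[0] = e3; eig[1] = e2; eig[2] = e1; // ascending
  }
  // sort ascending (paranoia)
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2 - i; ++j)
      if (eig[j] > eig[j + 1]) std::swap(eig[j], eig[j + 1]);
}

// Multi-scale tube-likeness for dark tubes (lumen darker than surroundings).
// Response is the maximum over scales of a Frangi-type measure computed on
// the sign-flipped, gamma-normalised Hessian of the Gaussian-smoothed volume.
// [[Rcpp::export(name = ".cpp_tube_response")]]
NumericVector cpp_tube_response(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector scales_mm,
                                double alpha, double beta, double cpar) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> best(n, 0.0);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];

  for (int si = 0; si < scales_mm.size(); ++si) {
    double sc = scales_mm[si];
    NumericVector sig = NumericVector::create(sc / sz, sc / sy, sc / sx);
    NumericVector sm = cpp_gaussian_smooth3(vol, dim, sig);
    double g2 = sc * sc; // gamma-normalisation, gamma = 2
    // reflect padding hallucinates dark valleys near the border; keep only
    // the region at least one smoothing scale away from it
    int mz = std::max(1, (int)std::ceil(sc / sz));
    int my = std::max(1, (int)std::ceil(sc / sy));
    int mx = std::max(1, (int)std::ceil(sc / sx));
    for (int x = mx; x < nx - mx; ++x) {
      for (int y = my; y < ny - my; ++y) {
        for (int z = mz; z < nz - mz; ++z) {
          double c = sm[idx3(z, y, x, nz, ny)];
          double hzz = (sm[idx3(z + 1, y, x, nz, ny)] - 2 * c + sm[idx3(z - 1, y, x, nz, ny)]) / (sz * sz);
          double hyy = (sm[idx3(z, y + 1, x, nz, ny)] - 2 * c + sm[idx3(z, y - 1, x, nz, ny)]) / (sy * sy);
          double hxx = (sm[idx3(z, y, x + 1, nz, ny)] - 2 * c + sm[idx3(z, y, x - 1, nz, ny)]) / (sx * sx);
          double hzy = (sm[idx3(z + 1, y + 1, x, nz, ny)] - sm[idx3(z + 1, y - 1, x, nz, ny)] -
                        sm[idx3(z - 1, y + 1, x, nz, ny)] + sm[idx3(z - 1, y - 1, x, nz, ny)]) / (4 * sz * sy);
          double hzx = (sm[idx3(z + 1, y, x + 1, nz, ny)] - sm[idx3(z + 1, y, x - 1, nz, ny)] -
                        sm[idx3(z - 1, y, x + 1, nz, ny)] + sm[idx3(z - 1, y, x - 1, nz, ny)]) / (4 * sz * sx);
          double hyx = (sm[idx3(z, y + 1, x + 1, nz, ny)] - sm[idx3(z, y + 1, x - 1, nz, ny)] -
                        sm[idx3(z, y - 1, x + 1, nz, ny)] + sm[idx3(z, y - 1, x - 1, nz, ny)]) / (4 * sy * sx);
          // dark tube: flip sign so bright-tube conditions apply
          double eig[3];
          eig_sym3(-g2 * hzz, -g2 * hyy, -g2 * hxx,
                   -g2 * hzy, -g2 * hzx, -g2 * hyx, eig);
          // order by absolute value: l1 smallest
          double l[3] = {eig[0], eig[1], eig[2]};
          for (int i = 0; i < 2; ++i)
            for (int j = 0; j < 2 - i; ++j)
              if (std::fabs(l[j]) > std::fabs(l[j + 1])) std::swap(l[j], l[j + 1]);
          double l1 = l[0], l2 = l[1], l3 = l[2];
          if (l2 >= 0.0 || l3 >= 0.0) continue; // bright-tube condition on flipped Hessian
          double ra = std::fabs(l2) / std::fabs(l3);
          double rb = std::fabs(l1) / std::sqrt(std::fabs(l2 * l3));
          double s2 = l1 * l1 + l2 * l2 + l3 * l3;
          double v = (1.0 - std::exp(-ra * ra / (2 * alpha * alpha))) *
                     std::exp(-rb * rb / (2 * beta * beta)) *
                     (1.0 - std::exp(-s2 / (2 * cpar * cpar)));
          size_t id = (size_t)idx3(z, y, x, nz, ny);
          if (v > best[id]) best[id] = v;
        }
      }
    }
  }
  NumericVector out(best.begin(), best.end());
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------------------ gradient

// [[Rcpp::export(name = ".cpp_gradient_magnitude3")]]
NumericVector cpp_gradient_magnitude3(NumericVector vol, IntegerVector dim,
                                      NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out((size_t)nz * ny * nx);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int zp = std::min(z + 1, nz - 1), zm = std::max(z - 1, 0);
        int yp = std::min(y + 1, ny - 1), ym = std::max(y - 1, 0);
        int xp = std::min(x + 1, nx - 1), xm = std::max(x - 1, 0);
        double gz = (vol[idx3(zp, y, x, nz, ny)] - vol[idx3(zm, y, x, nz, ny)]) / ((zp - zm) * sz);
        double gy = (vol[idx3(z, yp, x, nz, ny)] - vol[idx3(z, ym, x, nz, ny)]) / ((yp - ym) * sy);
        double gx = (vol[idx3(z, y, xp, nz, ny)] - vol[idx3(z, y, xm, nz, ny)]) / ((xp - xm) * sx);
        out[idx3(z, y, x, nz, ny)] = std::sqrt(gz * gz + gy * gy + gx * gx);
      }
  out.attr("dim") = dim;
  return out;
}

// Steepest one-sided difference over the 26-neighbourhood, mm-scaled.
// Unlike central differences this cannot be blinded by a symmetric wall on
// both sides of a one-voxel channel, which is exactly the leakage geometry
// the growth gate has to stop.
// [[Rcpp::export(name = ".cpp_local_gradient3")]]
NumericVector cpp_local_gradient3(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out((size_t)nz * ny * nx);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  static int OFFL[26][3];
  static double DIST[26];
  {
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          OFFL[k][0] = dz; OFFL[k][1] = dy; OFFL[k][2] = dx;
          DIST[k] = std::sqrt(dz * dz * sz * sz + dy * dy * sy * sy +
                              dx * dx * sx * sx);
          ++k;
        }
  }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double v = vol[idx3(z, y, x, nz, ny)], g = 0.0;
        for (int k = 0; k < 26; ++k) {
          int zz = z + OFFL[k][0], yy = y + OFFL[k][1], xx = x + OFFL[k][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          double d = std::fabs(vol[idx3(zz, yy, xx, nz, ny)] - v) / DIST[k];
          if (d > g) g = d;
        }
        out[idx3(z, y, x, nz, ny)] = g;
      }
  out.attr("dim") = dim;
  return out;
}

// -------------------------------------------------------- connected labeling

static const int OFF26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},{-1,1,-1},{-1,1,0},{-1,1,1},
  {0,-1,-1},{0,-1,0},{0,-1,1},{0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},
  {1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},{1,1,0},{1,1,1}};
static const int OFF6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  const int (*off)[3] = (connectivity == 6) ? OFF6 : OFF26;
  int noff = (connectivity == 6) ? 6 : 26;
  int cur = 0;
  std::queue<int> q;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    q.push((int)i);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
      for (int k = 0; k < noff; ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int pp = idx3(zz, yy, xx, nz, ny);
        if (mask[pp] && lab[pp] == 0) { lab[pp] = cur; q.push(pp); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ------------------------------------------------------------ region growing

// [[Rcpp::export(name = ".cpp_region_grow_range")]]
LogicalVector cpp_region_grow_range(NumericVector vol, IntegerVector dim,
                                    IntegerVector seed0, double lower,
                                    double upper, int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out((size_t)nz * ny * nx, false);
  const int (*off)[3] = (connectivity == 6) ? OFF6 : OFF26;
  int noff = (connectivity == 6) ? 6 : 26;
  int s = idx3(seed0[0], seed0[1], seed0[2], nz, ny);
  std::queue<int> q;
  out[s] = true;
  q.push(s);
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
    for (int k = 0; k < noff; ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int pp = idx3(zz, yy, xx, nz, ny);
      if (!out[pp] && vol[pp] >= lower && vol[pp] <= upper) {
        out[pp] = true; q.push(pp);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Gradient-gated growth from a seed mask (26-connected, FIFO order), then one
// conditional dilation of the growth-accepted set restricted to eligible HU.
// [[Rcpp::export(name = ".cpp_grow_gradient_gate")]]
LogicalVector cpp_grow_gradient_gate(NumericVector vol, NumericVector gradmag,
                                     IntegerVector dim, LogicalVector seeds,
                                     double hu_ceiling, double grad_thresh) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  LogicalVector out(n, false);
  std::vector<char> grown(n, 0);
  std::queue<int> q;
  for (size_t i = 0; i < n; ++i)
    if (seeds[i]) { out[i] = true; q.push((int)i); }
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
    for (int k = 0; k < 26; ++k) {
      int zz = z + OFF26[k][0], yy = y + OFF26[k][1], xx = x + OFF26[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int pp = idx3(zz, yy, xx, nz, ny);
      if (!out[pp] && vol[pp] < hu_ceiling && gradmag[pp] < grad_thresh) {
        out[pp] = true; grown[pp] = 1; q.push(pp);
      }
    }
  }
  // conditional dilation: eligible neighbours of growth-accepted voxels;
  // restores the wall-adjacent rind the gradient gate rejects by design
  std::vector<int> add;
  for (size_t i = 0; i < n; ++i) {
    if (!grown[i]) continue;
    int p = (int)i;
    int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
    for (int k = 0; k < 26; ++k) {
      int zz = z + OFF26[k][0], yy = y + OFF26[k][1], xx = x + OFF26[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int pp = idx3(zz, yy, xx, nz, ny);
      if (!out[pp] && vol[pp] < hu_ceiling) add.push_back(pp);
    }
  }
  for (int pp : add) out[pp] = true;
  out.attr("dim") = dim;
  return out;
}

// ----------------------------------------------------------------- dilation

// [[Rcpp::export(name = ".cpp_dilate26")]]
LogicalVector cpp_dilate26(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  LogicalVector out(n, false);
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int p = (int)i;
    int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
    out[p] = true;
    for (int k = 0; k < 26; ++k) {
      int zz = z + OFF26[k][0], yy = y + OFF26[k][1], xx = x + OFF26[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      out[idx3(zz, yy, xx, nz, ny)] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}

// voxels whose centre lies within radius_mm of any of the given world points
// [[Rcpp::export(name = ".cpp_stamp_balls")]]
LogicalVector cpp_stamp_balls(IntegerVector dim, NumericVector spacing,
                              NumericVector origin, NumericMatrix pts,
                              double radius_mm) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out((size_t)nz * ny * nx, false);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  for (int i = 0; i < pts.nrow(); ++i) {
    double pz = pts(i, 0) - origin[0], py = pts(i, 1) - origin[1],
           px = pts(i, 2) - origin[2];
    // the voxel containing the point is always included
    int cz = (int)std::lround(pz / sz), cy = (int)std::lround(py / sy),
        cx = (int)std::lround(px / sx);
    if (cz >= 0 && cz < nz && cy >= 0 && cy < ny && cx >= 0 && cx < nx)
      out[idx3(cz, cy, cx, nz, ny)] = true;
    if (radius_mm <= 0) continue;
    int z0 = std::max(0, (int)std::floor((pz - radius_mm) / sz));
    int z1 = std::min(nz - 1, (int)std::ceil((pz + radius_mm) / sz));
    int y0 = std::max(0, (int)std::floor((py - radius_mm) / sy));
    int y1 = std::min(ny - 1, (int)std::ceil((py + radius_mm) / sy));
    int x0 = std::max(0, (int)std::floor((px - radius_mm) / sx));
    int x1 = std::min(nx - 1, (int)std::ceil((px + radius_mm) / sx));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double dz = z * sz - pz, dy = y * sy - py, dx = x * sx - px;
          if (dz * dz + dy * dy + dx * dx <= radius_mm * radius_mm)
            out[idx3(z, y, x, nz, ny)] = true;
        }
  }
  out.attr("dim") = dim;
  return out;
}

// --------------------------------------------------------- phantom rendering

static inline double dist_point_segment(double pz, double py, double px,
                                        double az, double ay, double ax,
                                        double bz, double by, double bx) {
  double vz = bz - az, vy = by - ay, vx = bx - ax;
  double wz = pz - az, wy = py - ay, wx = px - ax;
  double vv = vz * vz + vy * vy + vx * vx;
  double t = (vv > 0) ? (wz * vz + wy * vy + wx * vx) / vv : 0.0;
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  double dz = pz - (az + t * vz), dy = py - (ay + t * vy), dx = px - (ax + t * vx);
  return std::sqrt(dz * dz + dy * dy + dx * dx);
}

// segs: n x 8 matrix (z0,y0,x0,z1,y1,x1,radius,wall_thickness), world mm.
// Two passes: wall capsules first, lumen capsules override, so junction lumens
// stay connected. branch_id assigned by smallest distance/radius ratio.
// [[Rcpp::export(name = ".cpp_render_tree")]]
List cpp_render_tree(IntegerVector dim, NumericVector spacing,
                     NumericVector origin, NumericMatrix segs,
                     IntegerVector seg_branch, double hu_lumen,
                     double hu_wall, double hu_parenchyma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  NumericVector vol(n, hu_parenchyma);
  LogicalVector lumen(n, false);
  IntegerVector bid(n, 0);
  std::vector<double> best(n, 1e30);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];

  for (int pass = 0; pass < 2; ++pass) {
    for (int i = 0; i < segs.nrow(); ++i) {
      double az = segs(i, 0) - origin[0], ay = segs(i, 1) - origin[1], ax = segs(i, 2) - origin[2];
      double bz = segs(i, 3) - origin[0], by = segs(i, 4) - origin[1], bx = segs(i, 5) - origin[2];
      double r = segs(i, 6), wall = segs(i, 7);
      if (pass == 1 && r <= 0) continue; // wall-only capsule (e.g. septum)
      double reach = (pass == 0) ? r + wall : r;
      int z0 = std::max(0, (int)std::floor((std::min(az, bz) - reach) / sz));
      int z1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + reach) / sz));
      int y0 = std::max(0, (int)std::floor((std::min(ay, by) - reach) / sy));
      int y1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + reach) / sy));
      int x0 = std::max(0, (int)std::floor((std::min(ax, bx) - reach) / sx));
      int x1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + reach) / sx));
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y)
          for (int z = z0; z <= z1; ++z) {
            double d = dist_point_segment(z * sz, y * sy, x * sx,
                                          az, ay, ax, bz, by, bx);
            size_t id = (size_t)idx3(z, y, x, nz, ny);
            if (pass == 0) {
              if (d <= r + wall) vol[id] = hu_wall;
            } else if (d <= r) {
              vol[id] = hu_lumen;
              lumen[id] = true;
              double ratio = d / r;
              if (ratio < best[id]) { best[id] = ratio; bid[id] = seg_branch[i]; }
            }
          }
    }
  }
  vol.attr("dim") = dim;
  lumen.attr("dim") = dim;
  bid.attr("dim") = dim;
  return List::create(_["volume"] = vol, _["lumen"] = lumen,
                      _["branch_id"] = bid);
}

// ------------------------------------------------------------------ thinning

// Simple-point test after Malandain & Bertrand: p is simple iff the foreground
// has exactly one 26-component in N26*(p) and the background has exactly one
// 6-component in N18(p) that is 6-adjacent to p.
static bool is_simple(const std::vector<char> &m, int z, int y, int x,
                      int nz, int ny, int nx) {
  char cube[27]; // local 3x3x3, index (dz+1) + 3*((dy+1) + 3*(dx+1))
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        char v = 0;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          v = m[idx3(zz, yy, xx, nz, ny)];
        cube[(dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1))] = v;
      }
  const int C = 13; // centre
  // T26: foreground 26-components among the 26 neighbours
  {
    char vis[27]; std::memset(vis, 0, 27);
    int ncomp = 0;
    for (int i = 0; i < 27; ++i) {
      if (i == C || !cube[i] || vis[i]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      std::queue<int> q; q.push(i); vis[i] = 1;
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pz = p % 3, pr = p / 3, py = pr % 3, px = pr / 3;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = pz + dz, yy = py + dy, xx = px + dx;
              if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
              int pp = zz + 3 * (yy + 3 * xx);
              if (pp == C || !cube[pp] || vis[pp]) continue;
              vis[pp] = 1; q.push(pp);
            }
      }
    }
    if (ncomp != 1) return false;
  }
  // T6: background 6-components within N18 that touch a 6-neighbour of centre
  {
    char vis[27]; std::memset(vis, 0, 27);
    int ncomp = 0;
    static const int six[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
    for (int s = 0; s < 6; ++s) {
      int i = six[s];
      if (cube[i] || vis[i]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      std::queue<int> q; q.push(i); vis[i] = 1;
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pz = p % 3, pr = p / 3, py = pr % 3, px = pr / 3;
        static const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
        for (int k = 0; k < 6; ++k) {
          int zz = pz + d6[k][0], yy = py + d6[k][1], xx = px + d6[k][2];
          if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
          int pp = zz + 3 * (yy + 3 * xx);
          // stay in N18: exclude centre and the 8 corners
          int nd = (zz != 1) + (yy != 1) + (xx != 1);
          if (pp == C || nd == 3) continue;
          if (cube[pp] || vis[pp]) continue;
          vis[pp] = 1; q.push(pp);
        }
      }
    }
    if (ncomp != 1) return false;
  }
  return true;
}

static int count_fg26(const std::vector<char> &m, int z, int y, int x,
                      int nz, int ny, int nx) {
  int c = 0;
  for (int k = 0; k < 26; ++k) {
    int zz = z + OFF26[k][0], yy = y + OFF26[k][1], xx = x + OFF26[k][2];
    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
    if (m[idx3(zz, yy, xx, nz, ny)]) ++c;
  }
  return c;
}

// Topology-preserving sequential thinning with 6 directional sub-iterations.
// Deterministic: candidates scanned and deleted in raster order; endpoints
// (<= 1 foreground neighbour) are never removed.
// [[Rcpp::export(name = ".cpp_thin3d")]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<char> m(n, 0);
  std::vector<int> fg;
  for (size_t i = 0; i < n; ++i)
    if (mask[i]) { m[i] = 1; fg.push_back((int)i); }

  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<int> cand;
      for (int p : fg) {
        if (!m[p]) continue;
        int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
        int zz = z + OFF6[dir][0], yy = y + OFF6[dir][1], xx = x + OFF6[dir][2];
        bool border = (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) ||
                      !m[idx3(zz, yy, xx, nz, ny)];
        if (!border) continue;
        if (count_fg26(m, z, y, x, nz, ny, nx) <= 1) continue; // endpoint
        cand.push_back(p);
      }
      for (int p : cand) { // sequential recheck keeps topology exact
        if (!m[p]) continue;
        int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
        if (count_fg26(m, z, y, x, nz, ny, nx) <= 1) continue;
        if (!is_simple(m, z, y, x, nz, ny, nx)) continue;
        m[p] = 0;
        changed = true;
      }
    }
    // compact live list occasionally
    std::vector<int> live;
    live.reserve(fg.size());
    for (int p : fg) if (m[p]) live.push_back(p);
    fg.swap(live);
  }
  LogicalVector out(n, false);
  for (int p : fg) out[p] = true;
  out.attr("dim") = dim;
  return out;
}
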