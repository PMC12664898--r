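// 3D voxel kernels: separable Gaussian filtering, connected-component
// labelling, Euclidean distance transform, greyscale reconstruction,
// regional maxima and marker-controlled watershed. All arrays are R
// column-major 3D volumes passed as flat vectors with an explicit dim.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline long long vidx(int x, int y, int z, int nx, int ny) {
  return (long long)x + (long long)nx * ((long long)y + (long long)ny * z);
}

// Neighbour offsets for 6/18/26 connectivity.
static void neighbour_offsets(int connectivity,
                              std::vector<int>& dx, std::vector<int>& dy,
                              std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur(clone(vol));
  const int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double tot = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); tot += k[i + r]; }
    for (double& w : k) w /= tot;
    NumericVector out(cur.size());
    const int len = n[axis];
    // iterate over lines along `axis`
    for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
      for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
        for (int x = 0; x < (axis == 0 ? 1 : nx); ++x)
          for (int t = 0; t < len; ++t) {
            int px = (axis == 0) ? t : x, py = (axis == 1) ? t : y, pz = (axis == 2) ? t : z;
            double acc = 0;
            for (int i = -r; i <= r; ++i) {
              int u = t + i;
              if (u < 0) u = -u;                 // reflect
              if (u >= len) u = 2 * len - 2 - u;
              if (u < 0) u = 0;
              int qx = (axis == 0) ? u : px, qy = (axis == 1) ? u : py, qz = (axis == 2) ? u : pz;
              acc += k[i + r] * cur[vidx(qx, qy, qz, nx, ny)];
            }
            out[vidx(px, py, pz, nx, ny)] = acc;
          }
    cur = out;
  }
  return cur;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<long long> stack;
  for (long long p = 0; p < n; ++p) {
    if (mask[p] == 0 || lab[p] != 0) continue;
    ++next;
    lab[p] = next;
    stack.push_back(p);
    while (!stack.empty()) {
      long long q = stack.back(); stack.pop_back();
      int qx = (int)(q % nx), qy = (int)((q / nx) % ny), qz = (int)(q / ((long long)nx * ny));
      for (size_t i = 0; i < dx.size(); ++i) {
        int ax = qx + dx[i], ay = qy + dy[i], az = qz + dz[i];
        if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz) continue;
        long long a = vidx(ax, ay, az, nx, ny);
        if (mask[a] != 0 && lab[a] == 0) { lab[a] = next; stack.push_back(a); }
      }
    }
  }
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing s; f holds squared distances, positions are i*s.
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zbuf(n + 1), d(n);
  int k = 0;
  v[0] = 0; zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sint = (f[q] + xq * xq - f[v[k]] - xv * xv) / (2 * xq - 2 * xv);
      if (sint <= zbuf[k]) { --k; }
      else {
        ++k; v[k] = q; zbuf[k] = sint;
        zbuf[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zbuf[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  f = d;
}

// Euclidean distance (physical units) from each foreground voxel to the
// nearest background voxel centre; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  const double INF = 1e30;
  NumericVector g(n);
  for (long long p = 0; p < n; ++p) g[p] = mask[p] ? INF : 0.0;
  std::vector<double> line;
  // axis 0
  line.resize(nx);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) line[x] = g[vidx(x, y, z, nx, ny)];
    dt1d(line, spacing[0]);
    for (int x = 0; x < nx; ++x) g[vidx(x, y, z, nx, ny)] = line[x];
  }
  line.assign(ny, 0.0);
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) line[y] = g[vidx(x, y, z, nx, ny)];
    dt1d(line, spacing[1]);
    for (int y = 0; y < ny; ++y) g[vidx(x, y, z, nx, ny)] = line[y];
  }
  line.assign(nz, 0.0);
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) line[z] = g[vidx(x, y, z, nx, ny)];
    dt1d(line, spacing[2]);
    for (int z = 0; z < nz; ++z) g[vidx(x, y, z, nx, ny)] = line[z];
  }
  for (long long p = 0; p < n; ++p) g[p] = std::sqrt(g[p]);
  return g;
}

// Greyscale reconstruction by dilation of `marker` under `ceiling`
// (Vincent's hybrid raster + FIFO algorithm). marker <= ceiling required.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector ceiling,
                              IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  NumericVector J(clone(marker));
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  std::vector<size_t> plus, minus;
  for (size_t i = 0; i < dx.size(); ++i) {
    bool earlier = (dz[i] < 0) || (dz[i] == 0 && dy[i] < 0) ||
                   (dz[i] == 0 && dy[i] == 0 && dx[i] < 0);
    if (earlier) plus.push_back(i); else minus.push_back(i);
  }
  // forward pass
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    long long p = vidx(x, y, z, nx, ny);
    double m = J[p];
    for (size_t ii : plus) {
      int ax = x + dx[ii], ay = y + dy[ii], az = z + dz[ii];
      if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz) continue;
      double v = J[vidx(ax, ay, az, nx, ny)];
      if (v > m) m = v;
    }
    J[p] = std::min(m, ceiling[p]);
  }
  // backward pass + queue init
  std::queue<long long> fifo;
  for (int z = nz - 1; z >= 0; --z) for (int y = ny - 1; y >= 0; --y) for (int x = nx - 1; x >= 0; --x) {
    long long p = vidx(x, y, z, nx, ny);
    double m = J[p];
    for (size_t ii : minus) {
      int ax = x + dx[ii], ay = y + dy[ii], az = z + dz[ii];
      if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz) continue;
      double v = J[vidx(ax, ay, az, nx, ny)];
      if (v > m) m = v;
    }
    J[p] = std::min(m, ceiling[p]);
    for (size_t ii : minus) {
      int ax = x + dx[ii], ay = y + dy[ii], az = z + dz[ii];
      if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz) continue;
      long long q = vidx(ax, ay, az, nx, ny);
      if (J[q] < J[p] && J[q] < ceiling[q]) { fifo.push(p); break; }
    }
  }
  while (!fifo.empty()) {
    long long p = fifo.front(); fifo.pop();
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((long long)nx * ny));
    for (size_t i = 0; i < dx.size(); ++i) {
      int ax = x + dx[i], ay = y + dy[i], az = z + dz[i];
      if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz) continue;
      long long q = vidx(ax, ay, az, nx, ny);
      if (J[q] < J[p] && ceiling[q] != J[q]) {
        J[q] = std::min(J[p], ceiling[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

// Regional maxima of `img` restricted to mask>0: plateaus with no strictly
// greater neighbour inside the mask support. Returns 0/1.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector img, IntegerVector mask,
                                  IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  IntegerVector out(n, 0);
  std::vector<char> state(n, 0); // 0 unvisited, 1 processed
  std::vector<long long> plateau, stack;
  for (long long p = 0; p < n; ++p) {
    if (mask[p] == 0 || state[p]) continue;
    double v = img[p];
    plateau.clear(); stack.clear();
    stack.push_back(p);
    state[p] = 1;
    bool is_max = true;
    while (!stack.empty()) {
      long long q = stack.back(); stack.pop_back();
      plateau.push_back(q);
      int qx = (int)(q % nx), qy = (int)((q / nx) % ny), qz = (int)(q / ((long long)nx * ny));
      for (size_t i = 0; i < dx.size(); ++i) {
        int ax = qx + dx[i], ay = qy + dy[i], az = qz + dz[i];
        if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz) continue;
        long long a = vidx(ax, ay, az, nx, ny);
        if (mask[a] == 0) continue;
        if (img[a] > v) { is_max = false; continue; }
        if (img[a] == v && !state[a]) { state[a] = 1; stack.push_back(a); }
      }
    }
    if (is_max) for (long long q : plateau) out[q] = 1;
  }
  return out;
}

struct WsNode {
  double prio; long long order; long long p;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // max-heap on priority
    return a.order > b.order;                      // FIFO among ties
  }
};

// Marker-controlled watershed by priority flooding: voxels with the highest
// `priority` (e.g. distance-transform value) are claimed first.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            IntegerVector mask, IntegerVector dim,
                            int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;
  for (long long p = 0; p < n; ++p)
    if (markers[p] > 0 && mask[p] != 0) {
      lab[p] = markers[p];
      pq.push({priority[p], counter++, p});
    }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    long long p = nd.p;
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((long long)nx * ny));
    for (size_t i = 0; i < dx.size(); ++i) {
      int ax = x + dx[i], ay = y + dy[i], az = z + dz[i];
      if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz) continue;
      long long q = vidx(ax, ay, az, nx, ny);
      if (mask[q] == 0 || lab[q] != 0) continue;
      lab[q] = lab[p];
      pq.push({priority[q], counter++, q});
    }
  }
  return lab;
}

// Trilinear sampling of a 3D volume at continuous voxel-centre coordinates
// (0-based: coordinate k lies at the centre of R voxel k+1). Coordinates are
// clamped to the grid edge.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim, NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double cx = pts(i, 0), cy = pts(i, 1), cz = pts(i, 2);
    if (cx < 0) cx = 0; if (cx > nx - 1) cx = nx - 1;
    if (cy < 0) cy = 0; if (cy > ny - 1) cy = ny - 1;
    if (cz < 0) cz = 0; if (cz > nz - 1) cz = nz - 1;
    int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
    if (x0 > nx - 2) x0 = std::max(0, nx - 2);
    if (y0 > ny - 2) y0 = std::max(0, ny - 2);
    if (z0 > nz - 2) z0 = std::max(0, nz - 2);
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
    double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    double c000 = vol[vidx(x0, y0, z0, nx, ny)], c100 = vol[vidx(x1, y0, z0, nx, ny)];
    double c010 = vol[vidx(x0, y1, z0, nx, ny)], c110 = vol[vidx(x1, y1, z0, nx, ny)];
    double c001 = vol[vidx(x0, y0, z1, nx, ny)], c101 = vol[vidx(x1, y0, z1, nx, ny)];
    double c011 = vol[vidx(x0, y1, z1, nx, ny)], c111 = vol[vidx(x1, y1, z1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Trilinear upsampling of a 3D volume by integer factor f (fine voxel
// centres at (i+0.5)/f - 0.5 in coarse 0-based voxel-centre coordinates).
// [[Rcpp::export]]
NumericVector cpp_upsample(NumericVector vol, IntegerVector dim, int f) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int fx = nx * f, fy = ny * f, fz = nz * f;
  NumericVector out((long long)fx * fy * fz);
  for (int z = 0; z < fz; ++z) {
    double cz = (z + 0.5) / f - 0.5;
    int z0 = (int)std::floor(cz);
    double wz = cz - z0;
    int za = std::min(std::max(z0, 0), nz - 1);
    int zb = std::min(std::max(z0 + 1, 0), nz - 1);
    for (int y = 0; y < fy; ++y) {
      double cy = (y + 0.5) / f - 0.5;
      int y0 = (int)std::floor(cy);
      double wy = cy - y0;
      int ya = std::min(std::max(y0, 0), ny - 1);
      int yb = std::min(std::max(y0 + 1, 0), ny - 1);
      for (int x = 0; x < fx; ++x) {
        double cx = (x + 0.5) / f - 0.5;
        int x0 = (int)std::floor(cx);
        double wx = cx - x0;
        int xa = std::min(std::max(x0, 0), nx - 1);
        int xb = std::min(std::max(x0 + 1, 0), nx - 1);
        double c00 = vol[vidx(xa, ya, za, nx, ny)] * (1 - wx) + vol[vidx(xb, ya, za, nx, ny)] * wx;
        double c10 = vol[vidx(xa, yb, za, nx, ny)] * (1 - wx) + vol[vidx(xb, yb, za, nx, ny)] * wx;
        double c01 = vol[vidx(xa, ya, zb, nx, ny)] * (1 - wx) + vol[vidx(xb, ya, zb, nx, ny)] * wx;
        double c11 = vol[vidx(xa, yb, zb, nx, ny)] * (1 - wx) + vol[vidx(xb, yb, zb, nx, ny)] * wx;
        out[vidx(x, y, z, fx, fy)] = (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
                                     (c01 * (1 - wy) + c11 * wy) * wz;
      }
    }
  }
  return out;
}

// Per-group maximum: for each voxel with group[i] > 0, track max of val.
// Returns a vector of length ngroups (1-based groups).
// [[Rcpp::export]]
NumericVector cpp_group_max(NumericVector val, IntegerVector group, int ngroups) {
  NumericVector out(ngroups, R_NegInf);
  const long long n = val.size();
  for (long long i = 0; i < n; ++i) {
    int g = group[i];
    if (g > 0 && val[i] > out[g - 1]) out[g - 1] = val[i];
  }
  return out;
}

// Nearest-neighbour (block) upsampling of an integer volume by factor f.
// [[Rcpp::export]]
IntegerVector cpp_upsample_int(IntegerVector vol, IntegerVector dim, int f) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int fx = nx * f, fy = ny * f, fz = nz * f;
  IntegerVector out((long long)fx * fy * fz);
  for (int z = 0; z < fz; ++z)
    for (int y = 0; y < fy; ++y)
      for (int x = 0; x < fx; ++x)
        out[vidx(x, y, z, fx, fy)] = vol[vidx(x / f, y / f, z / f, nx, ny)];
  return out;
}
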