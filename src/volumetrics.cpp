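// 3D volumetric primitives on column-major (nx, ny, nz) arrays with
// anisotropic voxel spacing (nm). All distances returned in nm.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---- separable Gaussian blur, reflecting boundaries ----------------------

static void blur_axis(std::vector<double> &v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &kk : k) kk /= s;

  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(n);
  // iterate over all lines along `axis`
  int d1 = (axis == 0) ? ny : nx;
  int d2 = (axis == 2) ? ny : nz;
  for (int a = 0; a < d1; ++a) {
    for (int b = 0; b < d2; ++b) {
      for (int i = 0; i < n; ++i) {
        int x, y, z;
        if (axis == 0) { x = i; y = a; z = b; }
        else if (axis == 1) { x = a; y = i; z = b; }
        else { x = a; y = b; z = i; }
        line[i] = v[idx3(x, y, z, nx, ny)];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int p = i + j;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= n) p = 2 * n - p - 1;
          if (p < 0) p = 0;
          if (p >= n) p = n - 1;
          acc += k[j + r] * line[p];
        }
        int x, y, z;
        if (axis == 0) { x = i; y = a; z = b; }
        else if (axis == 1) { x = a; y = i; z = b; }
        else { x = a; y = b; z = i; }
        v[idx3(x, y, z, nx, ny)] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector vol, IntegerVector dim,
                         NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(v, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(v, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---- 3D connected components (6 or 26 connectivity) -----------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity = 26) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back((int)start);
    lab[start] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (ad == 0) continue;
            if (connectivity == 6 && ad != 1) continue;
            int ni = idx3(xx, yy, zz, nx, ny);
            if (mask[ni] && lab[ni] == 0) {
              lab[ni] = next;
              stack.push_back(ni);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- anisotropic squared Euclidean distance transform ---------------------
// Felzenszwalb & Huttenlocher 1D lower envelope, grid positions i*spacing.

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double s) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * s;
    while (true) {
      double vv = (double)v[k] * s;
      double sint = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (sint <= zb[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        zb[k] = sint;
        zb[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * s;
    while (zb[k + 1] < qq) ++k;
    double vv = (double)v[k] * s;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// distance (nm) from every voxel to the nearest feature voxel
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector feature, IntegerVector dim,
                        NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// ---- marker-controlled watershed on the distance transform ----------------
// Splits one binary component: markers are distance-transform maxima with a
// minimum pairwise physical separation; voxels are flooded in order of
// decreasing interior distance.

// [[Rcpp::export]]
IntegerVector cpp_watershed_split(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing, double min_sep_nm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;

  // interior distance = distance to nearest background voxel (or border)
  LogicalVector bg(n);
  for (R_xlen_t i = 0; i < n; ++i) bg[i] = !mask[i];
  NumericVector dist = cpp_edt3d(bg, dim, spacing);
  // treat the volume border as background too
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[idx3(x, y, z, nx, ny)]) continue;
        double bx = std::min(x + 1, nx - x) * spacing[0];
        double by = std::min(y + 1, ny - y) * spacing[1];
        double bz = std::min(z + 1, nz - z) * spacing[2];
        double bd = std::min(bx, std::min(by, bz));
        int i = idx3(x, y, z, nx, ny);
        if (bd < dist[i]) dist[i] = bd;
      }

  // local maxima (26-neighborhood, >=)
  std::vector<int> maxima;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              int j = idx3(xx, yy, zz, nx, ny);
              if (mask[j] && dist[j] > dist[i]) ismax = false;
            }
        if (ismax) maxima.push_back(i);
      }
  // order maxima by decreasing distance, suppress within min_sep
  std::sort(maxima.begin(), maxima.end(),
            [&](int a, int b) { return dist[a] > dist[b]; });
  std::vector<int> markers;
  std::vector<double> mx, my, mz;
  for (int i : maxima) {
    int z = i / (nx * ny);
    int rem = i - z * nx * ny;
    int y = rem / nx;
    int x = rem - y * nx;
    double px = x * spacing[0], py = y * spacing[1], pz = z * spacing[2];
    bool ok = true;
    for (size_t k = 0; k < markers.size(); ++k) {
      double dx = px - mx[k], dy = py - my[k], dzp = pz - mz[k];
      if (dx * dx + dy * dy + dzp * dzp < min_sep_nm * min_sep_nm) {
        ok = false;
        break;
      }
    }
    if (ok) {
      markers.push_back(i);
      mx.push_back(px);
      my.push_back(py);
      mz.push_back(pz);
    }
  }

  IntegerVector lab(n, 0);
  typedef std::pair<double, std::pair<int, int> > QE; // (dist, (idx, label))
  std::priority_queue<QE> q;
  for (size_t k = 0; k < markers.size(); ++k) {
    lab[markers[k]] = (int)k + 1;
    q.push(QE(dist[markers[k]], std::make_pair(markers[k], (int)k + 1)));
  }
  while (!q.empty()) {
    QE top = q.top();
    q.pop();
    int cur = top.second.first;
    int l = top.second.second;
    int z = cur / (nx * ny);
    int rem = cur - z * nx * ny;
    int y = rem / nx;
    int x = rem - y * nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (mask[j] && lab[j] == 0) {
            lab[j] = l;
            q.push(QE(dist[j], std::make_pair(j, l)));
          }
        }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- boundary voxels (6-connectivity exposure to background/border) -------

// [[Rcpp::export]]
LogicalVector cpp_boundary3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        bool bnd = false;
        for (int k = 0; k < 6 && !bnd; ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            bnd = true;
          else if (!mask[idx3(xx, yy, zz, nx, ny)])
            bnd = true;
        }
        out[i] = bnd;
      }
  out.attr("dim") = dim;
  return out;
}

// ---- point-to-surface distances and shell neighbor counts -----------------

// min Euclidean distance from each point (nm) to a point set (nm)
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_set(NumericMatrix points, NumericMatrix set) {
  int np = points.nrow(), ns = set.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    for (int j = 0; j < ns; ++j) {
      double dx = px - set(j, 0), dy = py - set(j, 1), dz = pz - set(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each of k surfaces (concatenated rows of surf, surfaces delimited by
// surf_start/surf_len, 0-based start), count points with min distance to that
// surface <= each radius. bounds: per-surface centroid x,y,z and max radius
// used as a bounding-sphere prefilter. exclude: 1-based point index to skip
// per surface (0 = none). Returns k x length(radii) counts.
// [[Rcpp::export]]
IntegerMatrix cpp_count_within(NumericMatrix points, NumericMatrix surf,
                               IntegerVector surf_start, IntegerVector surf_len,
                               NumericMatrix bounds, NumericVector radii,
                               IntegerVector exclude) {
  int k = surf_start.size(), np = points.nrow(), nr = radii.size();
  double rmax = 0.0, rmin = R_PosInf;
  for (int r = 0; r < nr; ++r) {
    rmax = std::max(rmax, radii[r]);
    rmin = std::min(rmin, radii[r]);
  }
  IntegerMatrix out(k, nr);
  for (int s = 0; s < k; ++s) {
    double cx = bounds(s, 0), cy = bounds(s, 1), cz = bounds(s, 2);
    double br = bounds(s, 3);
    int st = surf_start[s], ln = surf_len[s];
    int ex = exclude[s] - 1;
    for (int i = 0; i < np; ++i) {
      if (i == ex) continue;
      double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
      double dx = px - cx, dy = py - cy, dz = pz - cz;
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dc - br > rmax) continue;
      double best = R_PosInf;
      for (int j = st; j < st + ln; ++j) {
        double ddx = px - surf(j, 0), ddy = py - surf(j, 1),
               ddz = pz - surf(j, 2);
        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (d2 < best) {
          best = d2;
          if (best <= rmin * rmin) break;
        }
      }
      best = std::sqrt(best);
      for (int r = 0; r < nr; ++r)
        if (best <= radii[r]) out(s, r) += 1;
    }
  }
  return out;
}

// ---- in-place patch stamping ----------------------------------------------
// vol[lo..lo+pdim-1] = max(vol, patch). Writes through to the caller's array;
// callers own the array exclusively (renderer-internal use).

// [[Rcpp::export]]
void cpp_patch_max(NumericVector vol, IntegerVector dim, IntegerVector lo,
                   NumericVector patch, IntegerVector pdim) {
  int nx = dim[0], ny = dim[1];
  int px = pdim[0], py = pdim[1], pz = pdim[2];
  int x0 = lo[0] - 1, y0 = lo[1] - 1, z0 = lo[2] - 1;
  for (int z = 0; z < pz; ++z)
    for (int y = 0; y < py; ++y)
      for (int x = 0; x < px; ++x) {
        double v = patch[x + px * (y + py * z)];
        if (v > 0) {
          int i = idx3(x0 + x, y0 + y, z0 + z, nx, ny);
          if (v > vol[i]) vol[i] = v;
        }
      }
}
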