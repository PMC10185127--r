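// Low-level volumetric kernels: tube rasterization, exact Euclidean distance
// transform, Dijkstra shortest paths on the voxel graph, separable Gaussian
// smoothing, affine resampling, spherical Hough voting, connected components,
// surface extraction and marching tetrahedra.  All grids are column-major
// (nx, ny, nz) with 0-based flat index i + nx*(j + ny*k); world coordinates
// are voxel centers: origin + index * spacing (axis-aligned RAS).
#include <RcppArmadillo.h>
#include <queue>
#include <unordered_map>
#include <cstring>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Tube rasterization support: windowed distance to a densely sampled curve.
// For every voxel within `win[p]` mm of curve sample p, track the minimal
// distance and the arc length of the closest sample.
// [[Rcpp::export]]
List cpp_tube_distance(IntegerVector dims, NumericVector spacing,
                       NumericVector origin, NumericMatrix pts,
                       NumericVector svals, NumericVector win) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dmin(nvox, R_PosInf);
  NumericVector smin(nvox, NA_REAL);
  IntegerVector pmin(nvox, NA_INTEGER);
  const int np = pts.nrow();
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    const double w = win[p];
    int i0 = (int)std::ceil((px - w - origin[0]) / spacing[0]);
    int i1 = (int)std::floor((px + w - origin[0]) / spacing[0]);
    int j0 = (int)std::ceil((py - w - origin[1]) / spacing[1]);
    int j1 = (int)std::floor((py + w - origin[1]) / spacing[1]);
    int k0 = (int)std::ceil((pz - w - origin[2]) / spacing[2]);
    int k1 = (int)std::floor((pz + w - origin[2]) / spacing[2]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing[2] - pz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing[1] - py;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > w * w) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing[0] - px;
          const double d2 = dx * dx + dyz2;
          const R_xlen_t v = idx3(i, j, k, nx, ny);
          if (d2 < dmin[v] * dmin[v]) {
            dmin[v] = std::sqrt(d2);
            smin[v] = svals[p];
            pmin[v] = p + 1;  // 1-based for R
          }
        }
      }
    }
  }
  return List::create(_["dmin"] = dmin, _["smin"] = smin, _["pmin"] = pmin);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing.  Foreground voxels receive the squared distance (mm^2)
// to the nearest background voxel center; background voxels get 0.
static void dt1d(const double *f, double *d, int n, double w2,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double INF = 1e30;
  for (R_xlen_t v = 0; v < nvox; ++v) out[v] = fg[v] ? INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> vv(nmax);
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double *col = &out[idx3(0, j, k, nx, ny)];
      dt1d(col, f.data(), nx, spacing[0] * spacing[0], vv, z);
      std::memcpy(col, f.data(), nx * sizeof(double));
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[idx3(i, j, k, nx, ny)];
      dt1d(f.data(), d.data(), ny, spacing[1] * spacing[1], vv, z);
      for (int j = 0; j < ny; ++j) out[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[idx3(i, j, k, nx, ny)];
      dt1d(f.data(), d.data(), nz, spacing[2] * spacing[2], vv, z);
      for (int k = 0; k < nz; ++k) out[idx3(i, j, k, nx, ny)] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Dijkstra over the 26-connected voxel graph restricted to `mask`.
// Edge weight = Euclidean step length (mm) * mean of the node costs.
// source/target are 0-based flat indices; target = -1 runs a full sweep.
// [[Rcpp::export]]
List cpp_dijkstra(IntegerVector dims, NumericVector spacing, LogicalVector mask,
                  NumericVector node_cost, int source, int target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dist(nvox, R_PosInf);
  IntegerVector parent(nvox, -1);
  if (!mask[source]) stop("source voxel is outside the mask");
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist[source] = 0.0;
  pq.push(QE(0.0, source));
  int off[26][3];
  double slen[26];
  int no = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        off[no][0] = di; off[no][1] = dj; off[no][2] = dk;
        slen[no] = std::sqrt(di * di * spacing[0] * spacing[0] +
                             dj * dj * spacing[1] * spacing[1] +
                             dk * dk * spacing[2] * spacing[2]);
        ++no;
      }
  while (!pq.empty()) {
    const QE top = pq.top(); pq.pop();
    const int u = top.second;
    if (top.first > dist[u]) continue;
    if (u == target) break;
    const int ui = u % nx, uj = (u / nx) % ny, uk = u / (nx * ny);
    for (int o = 0; o < no; ++o) {
      const int vi = ui + off[o][0], vj = uj + off[o][1], vk = uk + off[o][2];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz)
        continue;
      const int v = idx3(vi, vj, vk, nx, ny);
      if (!mask[v]) continue;
      const double w = slen[o] * 0.5 * (node_cost[u] + node_cost[v]);
      const double nd = dist[u] + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        parent[v] = u;
        pq.push(QE(nd, v));
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, sigma in voxels per axis, replicate border.
static void gauss1d(std::vector<double> &buf, std::vector<double> &tmp, int n,
                    const std::vector<double> &ker, int r) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = -r; t <= r; ++t) {
      int s = i + t;
      if (s < 0) s = 0;
      if (s >= n) s = n - 1;
      acc += ker[t + r] * buf[s];
    }
    tmp[i] = acc;
  }
  std::copy(tmp.begin(), tmp.begin() + n, buf.begin());
}

static std::vector<double> gauss_kernel(double sigma, int &r) {
  r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double sum = 0.0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    sum += ker[t + r];
  }
  for (double &k : ker) k /= sum;
  return ker;
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dims,
                         NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(vol);
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> buf(nmax), tmp(nmax);
  if (sigma_vox[0] > 0) {
    int r; std::vector<double> ker = gauss_kernel(sigma_vox[0], r);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) buf[i] = out[idx3(i, j, k, nx, ny)];
        gauss1d(buf, tmp, nx, ker, r);
        for (int i = 0; i < nx; ++i) out[idx3(i, j, k, nx, ny)] = buf[i];
      }
  }
  if (sigma_vox[1] > 0) {
    int r; std::vector<double> ker = gauss_kernel(sigma_vox[1], r);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) buf[j] = out[idx3(i, j, k, nx, ny)];
        gauss1d(buf, tmp, ny, ker, r);
        for (int j = 0; j < ny; ++j) out[idx3(i, j, k, nx, ny)] = buf[j];
      }
  }
  if (sigma_vox[2] > 0) {
    int r; std::vector<double> ker = gauss_kernel(sigma_vox[2], r);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) buf[k] = out[idx3(i, j, k, nx, ny)];
        gauss1d(buf, tmp, nz, ker, r);
        for (int k = 0; k < nz; ++k) out[idx3(i, j, k, nx, ny)] = buf[k];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Resample onto a new grid through an affine map: for each output voxel with
// world coordinate x_out, sample the input at world_in = M * x_out + t.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           IntegerVector odims, NumericVector ospacing,
                           NumericVector oorigin, NumericMatrix M,
                           NumericVector t, bool nearest, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    const double wz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < oy; ++j) {
      const double wy = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < ox; ++i) {
        const double wx = oorigin[0] + i * ospacing[0];
        const double xi = M(0, 0) * wx + M(0, 1) * wy + M(0, 2) * wz + t[0];
        const double yi = M(1, 0) * wx + M(1, 1) * wy + M(1, 2) * wz + t[1];
        const double zi = M(2, 0) * wx + M(2, 1) * wy + M(2, 2) * wz + t[2];
        const double ci = (xi - origin[0]) / spacing[0];
        const double cj = (yi - origin[1]) / spacing[1];
        const double ck = (zi - origin[2]) / spacing[2];
        double val = fill;
        if (nearest) {
          const int ri = (int)std::lround(ci), rj = (int)std::lround(cj),
                    rk = (int)std::lround(ck);
          if (ri >= 0 && ri < nx && rj >= 0 && rj < ny && rk >= 0 && rk < nz)
            val = vol[idx3(ri, rj, rk, nx, ny)];
        } else {
          const int fi = (int)std::floor(ci), fj = (int)std::floor(cj),
                    fk = (int)std::floor(ck);
          if (fi >= 0 && fi + 1 < nx && fj >= 0 && fj + 1 < ny && fk >= 0 &&
              fk + 1 < nz) {
            const double ax = ci - fi, ay = cj - fj, az = ck - fk;
            double acc = 0.0;
            for (int dz = 0; dz <= 1; ++dz)
              for (int dy = 0; dy <= 1; ++dy)
                for (int dx = 0; dx <= 1; ++dx) {
                  const double w = (dx ? ax : 1 - ax) * (dy ? ay : 1 - ay) *
                                   (dz ? az : 1 - az);
                  acc += w * vol[idx3(fi + dx, fj + dy, fk + dz, nx, ny)];
                }
            val = acc;
          } else if (ci > -0.5 && ci < nx - 0.5 && cj > -0.5 && cj < ny - 0.5 &&
                     ck > -0.5 && ck < nz - 0.5) {
            // border: fall back to nearest so edge voxels are preserved
            const int ri = (int)std::lround(ci), rj = (int)std::lround(cj),
                      rk = (int)std::lround(ck);
            val = vol[idx3(std::min(std::max(ri, 0), nx - 1),
                           std::min(std::max(rj, 0), ny - 1),
                           std::min(std::max(rk, 0), nz - 1), nx, ny)];
          }
        }
        out[idx3(i, j, k, ox, oy)] = val;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Spherical Hough voting for bright spheres: edge voxels (gradient magnitude
// above `gthresh`) vote along the negative gradient direction (towards the
// bright interior) at radii rmin..rmax.  The accumulator lives on a coarse
// grid of cell size `acc_mm`.
// [[Rcpp::export]]
List cpp_hough_votes(NumericVector vol, IntegerVector dims,
                     NumericVector spacing, NumericVector origin, double rmin,
                     double rmax, double gthresh, double acc_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ax = (int)std::ceil(nx * spacing[0] / acc_mm) + 1;
  const int ay = (int)std::ceil(ny * spacing[1] / acc_mm) + 1;
  const int az = (int)std::ceil(nz * spacing[2] / acc_mm) + 1;
  NumericVector acc((R_xlen_t)ax * ay * az);
  const double rstep = std::min(acc_mm, (rmax - rmin) / 4.0 + 1e-9);
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const double gx = (vol[idx3(i + 1, j, k, nx, ny)] -
                           vol[idx3(i - 1, j, k, nx, ny)]) / (2 * spacing[0]);
        const double gy = (vol[idx3(i, j + 1, k, nx, ny)] -
                           vol[idx3(i, j - 1, k, nx, ny)]) / (2 * spacing[1]);
        const double gz = (vol[idx3(i, j, k + 1, nx, ny)] -
                           vol[idx3(i, j, k - 1, nx, ny)]) / (2 * spacing[2]);
        const double gm = std::sqrt(gx * gx + gy * gy + gz * gz);
        if (gm < gthresh) continue;
        const double ux = gx / gm, uy = gy / gm, uz = gz / gm;
        const double wx = origin[0] + i * spacing[0];
        const double wy = origin[1] + j * spacing[1];
        const double wz = origin[2] + k * spacing[2];
        for (double r = rmin; r <= rmax + 1e-9; r += rstep) {
          // bright sphere on dark background: gradient at the edge points
          // inward, so the center lies along +g
          const double cx = wx + r * ux, cy = wy + r * uy, cz = wz + r * uz;
          const int ai = (int)std::lround((cx - origin[0]) / acc_mm);
          const int aj = (int)std::lround((cy - origin[1]) / acc_mm);
          const int ak = (int)std::lround((cz - origin[2]) / acc_mm);
          if (ai < 0 || ai >= ax || aj < 0 || aj >= ay || ak < 0 || ak >= az)
            continue;
          acc[idx3(ai, aj, ak, ax, ay)] += gm;
        }
      }
  return List::create(_["acc"] = acc,
                      _["dims"] = IntegerVector::create(ax, ay, az),
                      _["cell"] = acc_mm);
}

// ---------------------------------------------------------------------------
// 26-connected component labelling (0 = background), labels start at 1 and
// are assigned in raster-scan order of each component's first (seed) voxel,
// which makes the equal-size tie-break lexicographic and deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      const int u = stack.back();
      stack.pop_back();
      const int ui = u % nx, uj = (u / nx) % ny, uk = u / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int vi = ui + di, vj = uj + dj, vk = uk + dk;
            if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz)
              continue;
            const int v = idx3(vi, vj, vk, nx, ny);
            if (mask[v] && !lab[v]) {
              lab[v] = next;
              stack.push_back(v);
            }
          }
    }
  }
  return lab;
}

// Surface voxels: mask voxels with at least one face-adjacent background
// neighbour; voxels on the grid border count as surface.
// [[Rcpp::export]]
LogicalVector cpp_surface6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = idx3(i, j, k, nx, ny);
        if (!mask[v]) continue;
        bool surf = false;
        for (int o = 0; o < 6 && !surf; ++o) {
          const int vi = i + d6[o][0], vj = j + d6[o][1], vk = k + d6[o][2];
          if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz)
            surf = true;
          else if (!mask[idx3(vi, vj, vk, nx, ny)])
            surf = true;
        }
        if (surf) out[v] = true;
      }
  return out;
}

// Directed nearest-neighbour distances: for each row of A, min distance to B.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int a = 0; a < na; ++a) {
    double best = R_PosInf;
    const double ax = A(a, 0), ay = A(a, 1), az = A(a, 2);
    for (int b = 0; b < nb; ++b) {
      const double dx = ax - B(b, 0), dy = ay - B(b, 1), dz = az - B(b, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the voxel-center lattice (Kuhn 6-tet split, face
// consistent across cubes).  Field values outside the grid are 0, so masks
// touching the border still yield closed surfaces.  Vertices are deduplicated
// per lattice edge, giving a watertight mesh.
struct MTCtx {
  const double *field;
  int nx, ny, nz;
  double sp[3], org[3];
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> verts;  // x,y,z triplets
  std::vector<int> tris;      // 1-based vertex index triples
  double level;
  uint64_t nn;                // extended node count base

  double fval(int i, int j, int k) const {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0.0;
    return field[idx3(i, j, k, nx, ny)];
  }
  uint64_t nodeid(int i, int j, int k) const {
    return (uint64_t)(i + 1) +
           (uint64_t)(nx + 2) *
               ((uint64_t)(j + 1) + (uint64_t)(ny + 2) * (uint64_t)(k + 1));
  }
  int edge_vertex(const int a[3], const int b[3]) {
    uint64_t ia = nodeid(a[0], a[1], a[2]), ib = nodeid(b[0], b[1], b[2]);
    uint64_t key = (ia < ib) ? ia * nn + ib : ib * nn + ia;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    const double fa = fval(a[0], a[1], a[2]), fb = fval(b[0], b[1], b[2]);
    double t = (level - fa) / (fb - fa);
    if (t < 1e-6) t = 1e-6;
    if (t > 1 - 1e-6) t = 1 - 1e-6;
    for (int d = 0; d < 3; ++d) {
      const double pa = org[d] + a[d] * sp[d], pb = org[d] + b[d] * sp[d];
      verts.push_back(pa + t * (pb - pa));
    }
    const int id = (int)(verts.size() / 3);
    vmap[key] = id;
    return id;
  }
};

static void do_tet(MTCtx &C, const int v[4][3]) {
  double f[4];
  bool in[4];
  int nin = 0;
  for (int a = 0; a < 4; ++a) {
    f[a] = C.fval(v[a][0], v[a][1], v[a][2]);
    in[a] = f[a] > C.level;
    if (in[a]) ++nin;
  }
  if (nin == 0 || nin == 4) return;
  if (nin == 1 || nin == 3) {
    int solo = -1;
    for (int a = 0; a < 4; ++a)
      if (in[a] == (nin == 1)) solo = a;
    int others[3], m = 0;
    for (int a = 0; a < 4; ++a)
      if (a != solo) others[m++] = a;
    const int p1 = C.edge_vertex(v[solo], v[others[0]]);
    const int p2 = C.edge_vertex(v[solo], v[others[1]]);
    const int p3 = C.edge_vertex(v[solo], v[others[2]]);
    C.tris.push_back(p1); C.tris.push_back(p2); C.tris.push_back(p3);
  } else {
    int A[2], B[2], na = 0, nb2 = 0;
    for (int a = 0; a < 4; ++a)
      if (in[a]) A[na++] = a; else B[nb2++] = a;
    // quad perimeter: (A0,B0) (A0,B1) (A1,B1) (A1,B0)
    const int q1 = C.edge_vertex(v[A[0]], v[B[0]]);
    const int q2 = C.edge_vertex(v[A[0]], v[B[1]]);
    const int q3 = C.edge_vertex(v[A[1]], v[B[1]]);
    const int q4 = C.edge_vertex(v[A[1]], v[B[0]]);
    C.tris.push_back(q1); C.tris.push_back(q2); C.tris.push_back(q3);
    C.tris.push_back(q1); C.tris.push_back(q3); C.tris.push_back(q4);
  }
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims,
                    NumericVector spacing, NumericVector origin, double level) {
  MTCtx C;
  C.field = field.begin();
  C.nx = dims[0]; C.ny = dims[1]; C.nz = dims[2];
  for (int d = 0; d < 3; ++d) { C.sp[d] = spacing[d]; C.org[d] = origin[d]; }
  C.level = level;
  C.nn = (uint64_t)(C.nx + 2) * (C.ny + 2) * (C.nz + 2) + 1;
  // Kuhn split: 6 tets sharing the main diagonal c0 -> c7 of each cube,
  // corners c = x + 2y + 4z.  Paths 0 -> e1 -> e1+e2 -> 7 over axis perms.
  const int perms[6][3] = {{1,2,4},{1,4,2},{2,1,4},{2,4,1},{4,1,2},{4,2,1}};
  for (int k = -1; k < C.nz; ++k)
    for (int j = -1; j < C.ny; ++j)
      for (int i = -1; i < C.nx; ++i) {
        // skip cubes with uniform field quickly
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const double f = C.fval(i + (c & 1), j + ((c >> 1) & 1),
                                  k + ((c >> 2) & 1));
          if (f > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          const int c1 = perms[p][0], c2 = c1 + perms[p][1];
          const int corners[4] = {0, c1, c2, 7};
          int v[4][3];
          for (int a = 0; a < 4; ++a) {
            v[a][0] = i + (corners[a] & 1);
            v[a][1] = j + ((corners[a] >> 1) & 1);
            v[a][2] = k + ((corners[a] >> 2) & 1);
          }
          do_tet(C, v);
        }
      }
  const int nv = (int)(C.verts.size() / 3);
  NumericMatrix V(nv, 3);
  for (int a = 0; a < nv; ++a)
    for (int d = 0; d < 3; ++d) V(a, d) = C.verts[3 * a + d];
  const int nt = (int)(C.tris.size() / 3);
  IntegerMatrix F(nt, 3);
  for (int a = 0; a < nt; ++a)
    for (int d = 0; d < 3; ++d) F(a, d) = C.tris[3 * a + d];
  return List::create(_["vertices"] = V, _["triangles"] = F);
}
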