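#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// ---- 3D curve-skeleton thinning -------------------------------------------
//
// Sequential directional thinning of a 26-connected object over a 6-connected
// background. A border voxel is deletable when it is a simple point (removal
// preserves topology, Malandain-Bertrand characterisation: exactly one
// 26-component of object voxels in N26 and exactly one 6-component of
// background voxels in N18 touching the centre) and not a curve endpoint
// (more than one object neighbour). Deterministic: voxels are visited in
// lexicographic order within each of the six directional subiterations.

static const int DX26[26] = {-1,0,1,-1,0,1,-1,0,1, -1,0,1,-1,1,-1,0,1, -1,0,1,-1,0,1,-1,0,1};
static const int DY26[26] = {-1,-1,-1,0,0,0,1,1,1, -1,-1,-1,0,0,1,1,1, -1,-1,-1,0,0,0,1,1,1};
static const int DZ26[26] = {-1,-1,-1,-1,-1,-1,-1,-1,-1, 0,0,0,0,0,0,0,0, 1,1,1,1,1,1,1,1,1};

struct Grid {
  const int* m; int nx, ny, nz;
  inline bool obj(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
    return m[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] != 0;
  }
};

// neighbourhood cube index 0..26 for offsets in {-1,0,1}^3
static inline int cidx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

static int n26_object_count(const Grid& g, int x, int y, int z) {
  int n = 0;
  for (int k = 0; k < 26; ++k)
    if (g.obj(x + DX26[k], y + DY26[k], z + DZ26[k])) ++n;
  return n;
}

static bool is_simple(const Grid& g, int x, int y, int z) {
  bool occ[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        occ[cidx(dx, dy, dz)] = g.obj(x + dx, y + dy, z + dz);

  // (a) exactly one 26-connected component of object voxels in N26
  bool seen[27]; std::memset(seen, 0, sizeof(seen));
  int comp = 0;
  int stack[27], top;
  for (int k = 0; k < 26; ++k) {
    const int c = cidx(DX26[k], DY26[k], DZ26[k]);
    if (!occ[c] || seen[c]) continue;
    if (++comp > 1) return false;
    top = 0; stack[top++] = c; seen[c] = true;
    while (top) {
      const int cur = stack[--top];
      const int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      for (int j = 0; j < 26; ++j) {
        const int ax = cx + DX26[j], ay = cy + DY26[j], az = cz + DZ26[j];
        if (ax < -1 || ax > 1 || ay < -1 || ay > 1 || az < -1 || az > 1) continue;
        if (ax == 0 && ay == 0 && az == 0) continue;
        const int cc = cidx(ax, ay, az);
        if (occ[cc] && !seen[cc]) { seen[cc] = true; stack[top++] = cc; }
      }
    }
  }
  if (comp != 1) return false;

  // (b) exactly one 6-connected component of background voxels in N18
  //     that touches the centre through a face
  static const int F6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool bseen[27]; std::memset(bseen, 0, sizeof(bseen));
  comp = 0;
  for (int k = 0; k < 6; ++k) {
    const int c = cidx(F6[k][0], F6[k][1], F6[k][2]);
    if (occ[c] || bseen[c]) continue;
    if (++comp > 1) return false;
    top = 0; stack[top++] = c; bseen[c] = true;
    while (top) {
      const int cur = stack[--top];
      const int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      for (int j = 0; j < 6; ++j) {
        const int ax = cx + F6[j][0], ay = cy + F6[j][1], az = cz + F6[j][2];
        if (ax < -1 || ax > 1 || ay < -1 || ay > 1 || az < -1 || az > 1) continue;
        if (std::abs(ax) + std::abs(ay) + std::abs(az) > 2) continue; // stay in N18
        if (ax == 0 && ay == 0 && az == 0) continue;
        const int cc = cidx(ax, ay, az);
        if (!occ[cc] && !bseen[cc]) { bseen[cc] = true; stack[top++] = cc; }
      }
    }
  }
  return comp == 1;
}

// [[Rcpp::export]]
IntegerVector thin3d_cpp(IntegerVector mask, int nx, int ny, int nz) {
  IntegerVector out = clone(mask);
  Grid g; g.m = out.begin(); g.nx = nx; g.ny = ny; g.nz = nz;
  int* M = out.begin();
  const size_t n = (size_t)nx * ny * nz;

  std::vector<int> objs;
  objs.reserve(1024);
  for (size_t i = 0; i < n; ++i) if (M[i]) objs.push_back((int)i);

  static const int DIRS[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (size_t ii = 0; ii < objs.size(); ++ii) {
        const int idx = objs[ii];
        if (!M[idx]) continue;
        const int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
        if (g.obj(x + DIRS[d][0], y + DIRS[d][1], z + DIRS[d][2])) continue; // not border in d
        if (n26_object_count(g, x, y, z) <= 1) continue;                      // endpoint
        if (is_simple(g, x, y, z)) cand.push_back(idx);
      }
      // sequential re-check so earlier deletions cannot break topology
      for (size_t ii = 0; ii < cand.size(); ++ii) {
        const int idx = cand[ii];
        const int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
        if (n26_object_count(g, x, y, z) <= 1) continue;
        if (!is_simple(g, x, y, z)) continue;
        M[idx] = 0;
        changed = true;
      }
    }
  }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) --------

static void dt1d(const double* f, double* d, int n, int* v, double* zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -R_PosInf; zbuf[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    if (f[q] == R_PosInf) continue;
    double s;
    while (true) {
      if (k < 0) break;
      if (f[v[k]] == R_PosInf) { --k; continue; }
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    if (k < 0) { k = 0; v[0] = q; zbuf[0] = -R_PosInf; zbuf[1] = R_PosInf; }
    else { ++k; v[k] = q; zbuf[k] = s; zbuf[k + 1] = R_PosInf; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Distance (in voxels) from each voxel to the nearest zero voxel of mask.
// Voxels outside the volume are not treated as background.
// [[Rcpp::export]]
NumericVector edt3d_cpp(IntegerVector mask, int nx, int ny, int nz) {
  const size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  double* D = out.begin();
  const int* M = mask.begin();
  for (size_t i = 0; i < n; ++i) D[i] = M[i] ? R_PosInf : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double* row = D + (size_t)nx * ((size_t)y + (size_t)ny * z);
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = row[x]; if (row[x] < R_PosInf) any = true; }
      if (!any) continue;
      dt1d(f.data(), dd.data(), nx, v.data(), zbuf.data());
      for (int x = 0; x < nx; ++x) row[x] = dd[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      bool any = false;
      for (int y = 0; y < ny; ++y) {
        f[y] = D[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
        if (f[y] < R_PosInf) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), dd.data(), ny, v.data(), zbuf.data());
      for (int y = 0; y < ny; ++y)
        D[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] = dd[y];
    }
  // along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      bool any = false;
      for (int z = 0; z < nz; ++z) {
        f[z] = D[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
        if (f[z] < R_PosInf) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), dd.data(), nz, v.data(), zbuf.data());
      for (int z = 0; z < nz; ++z)
        D[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] = dd[z];
    }

  for (size_t i = 0; i < n; ++i)
    D[i] = (D[i] == R_PosInf) ? R_PosInf : std::sqrt(D[i]);
  return out;
}

// ---- 26-connected component labelling --------------------------------------

// Labels assigned in lexicographic first-encounter order (deterministic).
// [[Rcpp::export]]
IntegerVector label3d_cpp(IntegerVector mask, int nx, int ny, int nz) {
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector out(n);
  int* L = out.begin();
  const int* M = mask.begin();
  std::vector<int> stack;
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (!M[i] || L[i]) continue;
    ++next;
    stack.clear();
    stack.push_back((int)i);
    L[i] = next;
    while (!stack.empty()) {
      const int cur = stack.back(); stack.pop_back();
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (int k = 0; k < 26; ++k) {
        const int ax = x + DX26[k], ay = y + DY26[k], az = z + DZ26[k];
        if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz) continue;
        const size_t idx = (size_t)ax + (size_t)nx * ((size_t)ay + (size_t)ny * az);
        if (M[idx] && !L[idx]) { L[idx] = next; stack.push_back((int)idx); }
      }
    }
  }
  return out;
}
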