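#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Voxel grids are flattened R arrays with dim = (nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x), all 0-based here.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  if ((R_xlen_t)nz * ny * nx != mask.size())
    stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets for the requested connectivity
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nn = std::abs(a) + std::abs(b) + std::abs(c);
        if (nn == 0) continue;
        if ((connectivity == 6 && nn > 1) || (connectivity == 18 && nn > 2)) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int noff = (int)dz.size();

  IntegerVector labels((R_xlen_t)nz * ny * nx, 0);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!mask[i] || labels[i]) continue;
        ++next;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int cz = cur % nz, rest = cur / nz;
          int cy = rest % ny, cx = rest / ny;
          for (int k = 0; k < noff; ++k) {
            int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && !labels[j]) { labels[j] = next; stack.push_back(j); }
          }
        }
      }
  labels.attr("dim") = dims;
  return labels;
}

// ---- (26, 6) simple-point machinery for homotopic thinning --------------

// neighborhood cube index: p = (dz+1) + 3*(dy+1) + 9*(dx+1), p in 0..26, center 13
static inline int cube(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// C1: object voxels of the 26-neighborhood form exactly one 26-connected
// component (and there is at least one).
static bool one_object_component(const bool *nb) {
  int seen[27] = {0};
  int first = -1, count = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13) continue;
    if (nb[p]) { ++count; if (first < 0) first = p; }
  }
  if (count == 0) return false;
  std::vector<int> stack;
  stack.push_back(first);
  seen[first] = 1;
  int reached = 1;
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int dz = p % 3 - 1, dy = (p / 3) % 3 - 1, dx = p / 9 - 1;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (!a && !b && !c) continue;
          int zz = dz + a, yy = dy + b, xx = dx + c;
          if (zz < -1 || zz > 1 || yy < -1 || yy > 1 || xx < -1 || xx > 1) continue;
          int q = cube(zz, yy, xx);
          if (q == 13 || !nb[q] || seen[q]) continue;
          seen[q] = 1; ++reached;
          stack.push_back(q);
        }
  }
  return reached == count;
}

// C2: background voxels of the 18-neighborhood, 6-connected within it, form
// exactly one component that touches a face neighbor of the center.
static bool one_background_component(const bool *nb) {
  // positions in the 18-neighborhood: offsets with at most two nonzero coords
  bool in18[27] = {false};
  for (int p = 0; p < 27; ++p) {
    if (p == 13) continue;
    int dz = p % 3 - 1, dy = (p / 3) % 3 - 1, dx = p / 9 - 1;
    if (std::abs(dz) + std::abs(dy) + std::abs(dx) <= 2) in18[p] = true;
  }
  int face[6] = { cube(-1,0,0), cube(1,0,0), cube(0,-1,0),
                  cube(0,1,0),  cube(0,0,-1), cube(0,0,1) };
  int seen[27] = {0};
  int ncomp = 0;
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (nb[s] || seen[s]) continue;   // must be background, unvisited
    ++ncomp;
    if (ncomp > 1) return false;
    std::vector<int> stack;
    stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int dz = p % 3 - 1, dy = (p / 3) % 3 - 1, dx = p / 9 - 1;
      const int steps[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int zz = dz + steps[k][0], yy = dy + steps[k][1], xx = dx + steps[k][2];
        if (zz < -1 || zz > 1 || yy < -1 || yy > 1 || xx < -1 || xx > 1) continue;
        int q = cube(zz, yy, xx);
        if (q == 13 || !in18[q] || nb[q] || seen[q]) continue;
        seen[q] = 1;
        stack.push_back(q);
      }
    }
  }
  return ncomp == 1;
}

static void fill_neighborhood(const std::vector<char> &m, int z, int y, int x,
                              int nz, int ny, int nx, bool *nb) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int zz = z + a, yy = y + b, xx = x + c;
        bool v = (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
                   ? (m[lin(zz, yy, xx, nz, ny)] != 0) : false;
        nb[cube(a, b, c)] = v;
      }
}

static inline int count_object_neighbors(const bool *nb) {
  int n = 0;
  for (int p = 0; p < 27; ++p) if (p != 13 && nb[p]) ++n;
  return n;
}

// Homotopic thinning to a one-voxel-wide medial skeleton. Directional
// subiterations (U/D/N/S/E/W borders) with sequential re-checking preserve
// topology; curve endpoints (<= 1 object neighbor) are never removed.
// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  if ((R_xlen_t)nz * ny * nx != mask.size())
    stop("mask length does not match dims");
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // collect candidates on this border
      std::vector<int> cand;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            int i = lin(z, y, x, nz, ny);
            if (!m[i]) continue;
            int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
            bool border = !(zz >= 0 && zz < nz && yy >= 0 && yy < ny &&
                            xx >= 0 && xx < nx) ||
                          !m[lin(zz, yy, xx, nz, ny)];
            if (!border) continue;
            fill_neighborhood(m, z, y, x, nz, ny, nx, nb);
            if (count_object_neighbors(nb) <= 1) continue;  // endpoint
            if (one_object_component(nb) && one_background_component(nb))
              cand.push_back(i);
          }
      // sequential deletion with re-check keeps the result homotopic
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        int z = i % nz, rest = i / nz;
        int y = rest % ny, x = rest / ny;
        fill_neighborhood(m, z, y, x, nz, ny, nx, nb);
        if (count_object_neighbors(nb) <= 1) continue;
        if (one_object_component(nb) && one_background_component(nb)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// Separable 1D convolution along the first array dimension with replicate
// padding; used by the 3D Gaussian filter.
// [[Rcpp::export(name = ".convolve_dim1")]]
NumericVector convolve_dim1(NumericVector x, IntegerVector dims, NumericVector kernel) {
  const int n1 = dims[0];
  R_xlen_t ncol = x.size() / n1;
  const int kl = kernel.size();
  const int half = kl / 2;
  NumericVector out(x.size());
  for (R_xlen_t c = 0; c < ncol; ++c) {
    const double *col = &x[c * n1];
    double *o = &out[c * n1];
    for (int i = 0; i < n1; ++i) {
      double acc = 0.0;
      for (int k = 0; k < kl; ++k) {
        int j = i + k - half;
        if (j < 0) j = 0;
        if (j >= n1) j = n1 - 1;
        acc += col[j] * kernel[k];
      }
      o[i] = acc;
    }
  }
  out.attr("dim") = dims;
  return out;
}
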