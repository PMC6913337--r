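#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// The 13 unique 3D directions (half of the 26-neighbourhood); pairs are
// counted in both orders where symmetry is required.
static const int DIRS[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// levels: flattened 3D integer array, 0 = outside mask, 1..n_gray inside.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dims, int n_gray) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(n_gray, n_gray);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = levels[idx3(i, j, k, nx, ny)];
        if (a <= 0) continue;
        for (int d = 0; d < 13; ++d) {
          int ii = i + DIRS[d][0], jj = j + DIRS[d][1], kk = k + DIRS[d][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          int b = levels[idx3(ii, jj, kk, nx, ny)];
          if (b <= 0) continue;
          M(a - 1, b - 1) += 1.0;
          M(b - 1, a - 1) += 1.0;
        }
      }
  return M;
}

// Run-length counts aggregated over the 13 directions. A run is a maximal
// collinear sequence of in-mask voxels sharing one gray level.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dims, int n_gray) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericMatrix M(n_gray, maxlen);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = levels[idx3(i, j, k, nx, ny)];
          if (a <= 0) continue;
          // run start: predecessor along d is out of grid, out of mask, or a
          // different level
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (pi >= 0 && pi < nx && pj >= 0 && pj < ny && pk >= 0 && pk < nz &&
              levels[idx3(pi, pj, pk, nx, ny)] == a)
            continue;
          int len = 1;
          int ci = i + dx, cj = j + dy, ck = k + dz;
          while (ci >= 0 && ci < nx && cj >= 0 && cj < ny && ck >= 0 &&
                 ck < nz && levels[idx3(ci, cj, ck, nx, ny)] == a) {
            ++len; ci += dx; cj += dy; ck += dz;
          }
          M(a - 1, len - 1) += 1.0;
        }
  }
  return M;
}

// Connected constant-level zones (26-connectivity). Returns one (level, size)
// row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] <= 0) continue;
    int lev = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++size;
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            int w = idx3(ii, jj, kk, nx, ny);
            if (!seen[w] && levels[w] == lev) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zl.push_back(lev);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) { out(r, 0) = zl[r]; out(r, 1) = zs[r]; }
  return out;
}

// Neighbourhood gray-tone difference accumulators: for each level, the summed
// absolute deviation from the 26-neighbourhood in-mask mean, and the count of
// valid (>= 1 in-mask neighbour) voxels.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, IntegerVector dims, int n_gray) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector s(n_gray);
  IntegerVector cnt(n_gray);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = levels[idx3(i, j, k, nx, ny)];
        if (a <= 0) continue;
        double sum = 0.0; int nn = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              int b = levels[idx3(ii, jj, kk, nx, ny)];
              if (b > 0) { sum += b; ++nn; }
            }
        if (nn > 0) {
          s[a - 1] += std::fabs((double)a - sum / nn);
          cnt[a - 1] += 1;
        }
      }
  return List::create(_["s"] = s, _["n"] = cnt);
}
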