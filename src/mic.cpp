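#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Maximal information coefficient.
//
// For each admissible grid size (k, l) with k * l <= max(4, n^alpha), one
// axis is split into l equal-probability bins (ties kept together) and the
// partition of the other axis into at most k bins is optimized exactly by
// dynamic programming over tie-group ("clump") boundaries. Both orientations
// are searched; each entry of the characteristic matrix is normalized by
// log2(min(k, l_achieved)) and the maximum is returned.

static inline double xlogx(double p) { return p > 0.0 ? p * std::log(p) : 0.0; }

// Equal-probability bin assignment: bin = ceil(l * maxrank / n) with maxrank
// the largest rank within a tie group, then compressed to consecutive ids.
static std::vector<int> equip_bins(const NumericVector& v, int l, int& nbins) {
  int n = v.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  std::vector<int> bin(n, 0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    int b = (int)std::ceil((double)l * (j + 1) / n);
    if (b < 1) b = 1;
    if (b > l) b = l;
    for (int t = i; t <= j; ++t) bin[ord[t]] = b;
    i = j + 1;
  }
  std::vector<int> remap(l + 1, -1);
  nbins = 0;
  for (int b = 1; b <= l; ++b) {
    for (int p = 0; p < n; ++p)
      if (bin[p] == b) { remap[b] = nbins++; break; }
  }
  std::vector<int> out(n);
  for (int p = 0; p < n; ++p) out[p] = remap[bin[p]];
  return out;
}

// Max I (in nats) over partitions of the free axis into exactly t = 1..kmax
// columns, given fixed row assignment. Returns best[t] = max_t' <= t.
static std::vector<double> max_mi_dp(const NumericVector& xf,
                                     const std::vector<int>& row, int nr,
                                     int kmax, double& h_rows) {
  int n = xf.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return xf[a] < xf[b]; });
  // clump boundaries: cuts allowed only between distinct xf values
  std::vector<int> clump_end; // exclusive end index in ord for each clump
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && xf[ord[j + 1]] == xf[ord[i]]) ++j;
    clump_end.push_back(j + 1);
    i = j + 1;
  }
  int m = (int)clump_end.size();
  // cumulative per-row counts over clumps
  std::vector<double> cum((m + 1) * nr, 0.0), cumtot(m + 1, 0.0);
  int pos = 0;
  for (int c = 0; c < m; ++c) {
    for (int q = 0; q < nr; ++q) cum[(c + 1) * nr + q] = cum[c * nr + q];
    cumtot[c + 1] = cumtot[c];
    while (pos < clump_end[c]) {
      cum[(c + 1) * nr + row[ord[pos]]] += 1.0;
      cumtot[c + 1] += 1.0;
      ++pos;
    }
  }
  h_rows = 0.0;
  for (int q = 0; q < nr; ++q) h_rows -= xlogx(cum[m * nr + q] / n);
  // precompute column contributions F(a, b) for clumps a+1..b forming one
  // column, incrementally over b for each a
  std::vector<double> F((m + 1) * (m + 1), 0.0);
  std::vector<double> colq(nr);
  for (int a = 0; a < m; ++a) {
    std::fill(colq.begin(), colq.end(), 0.0);
    double tot = 0.0, sumq = 0.0;
    for (int b = a + 1; b <= m; ++b) {
      for (int q = 0; q < nr; ++q) {
        double add = cum[b * nr + q] - cum[(b - 1) * nr + q];
        if (add > 0.0) {
          sumq -= xlogx(colq[q] / n);
          colq[q] += add;
          sumq += xlogx(colq[q] / n);
        }
      }
      tot += cumtot[b] - cumtot[b - 1];
      F[a * (m + 1) + b] = -xlogx(tot / n) + sumq;
    }
  }
  int tmax = std::min(kmax, m);
  const double NEG = -1e100;
  std::vector<double> Dprev(m + 1, NEG), Dcur(m + 1, NEG);
  std::vector<double> best(kmax + 1, NEG);
  for (int r = 1; r <= m; ++r) Dprev[r] = F[r];
  best[1] = Dprev[m];
  for (int t = 2; t <= tmax; ++t) {
    for (int r = 1; r <= m; ++r) {
      Dcur[r] = NEG;
      const double* Fr = &F[0];
      for (int j = t - 1; j <= r - 1; ++j) {
        double v = Dprev[j] + Fr[j * (m + 1) + r];
        if (v > Dcur[r]) Dcur[r] = v;
      }
    }
    best[t] = Dcur[m];
    std::swap(Dprev, Dcur);
  }
  for (int t = 2; t <= kmax; ++t)
    if (best[t] < best[t - 1]) best[t] = best[t - 1];
  return best;
}

// [[Rcpp::export]]
double cpp_mic(NumericVector x, NumericVector y, double alpha = 0.6) {
  int n = x.size();
  double B = std::max(4.0, std::pow((double)n, alpha));
  double mic = 0.0;
  const double LN2 = std::log(2.0);
  for (int orient = 0; orient < 2; ++orient) {
    const NumericVector& vfix = orient == 0 ? y : x;  // equipartitioned axis
    const NumericVector& vfree = orient == 0 ? x : y; // optimized axis
    int lmax = (int)std::floor(B / 2.0);
    for (int l = 2; l <= lmax; ++l) {
      int nr = 0;
      std::vector<int> row = equip_bins(vfix, l, nr);
      if (nr < 2) continue;
      int kmax = (int)std::floor(B / nr);
      if (kmax < 2) continue;
      double h_rows = 0.0;
      std::vector<double> best = max_mi_dp(vfree, row, nr, kmax, h_rows);
      for (int k = 2; k <= kmax; ++k) {
        if (best[k] <= -1e99) continue;
        double Ibits = (h_rows + best[k]) / LN2;
        double denom = std::log2((double)std::min(k, nr));
        if (denom <= 0.0) continue;
        double val = Ibits / denom;
        if (val > mic) mic = val;
      }
    }
  }
  if (mic > 1.0) mic = 1.0;
  if (mic < 0.0) mic = 0.0;
  return mic;
}
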