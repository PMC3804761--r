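#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Grid-partition search for the maximal information coefficient.
//
// The heuristic follows the ApproxMaxMI scheme: one axis is equipartitioned
// into ny rows on ranks (tied values are never separated), then a dynamic
// programme places column cuts at clump boundaries to maximise the plug-in
// mutual information of the induced grid.  Both axis orientations are
// evaluated.  All logarithms are base 2 (MI in bits).

static inline double log2_(double v) { return std::log(v) / M_LN2; }

// stable order of v (ascending); ties keep original order
static std::vector<int> order_of(const std::vector<double>& v) {
  std::vector<int> idx(v.size());
  for (size_t i = 0; i < v.size(); ++i) idx[i] = (int)i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// Assign sorted tie-groups (sizes gsz) greedily to <= nbins bins of near-equal
// mass; groups are never split.  Returns bin id per group (0-based).
static std::vector<int> equipartition_groups(const std::vector<int>& gsz,
                                             int nbins) {
  int ng = (int)gsz.size();
  int total = 0;
  for (int s : gsz) total += s;
  std::vector<int> bin(ng);
  int r = 0, curr = 0, rem_pts = total, rem_bins = nbins;
  for (int g = 0; g < ng; ++g) {
    double target = (double)rem_pts / rem_bins;
    if (curr > 0 && rem_bins > 1 &&
        std::fabs(curr + gsz[g] - target) > std::fabs(curr - target)) {
      ++r;
      --rem_bins;
      rem_pts -= curr;
      curr = 0;
    }
    bin[g] = r;
    curr += gsz[g];
  }
  return bin;
}

// Dynamic programme over candidate column boundaries.
// cum: (K+1) x ny cumulative row counts at each boundary (boundary 0 = empty,
// boundary K = all n points).  Returns best[l-1] = max over partitions into
// at most l columns of sum_cols sum_r (m_r/n) log2 m_r - (M/n) log2 M,
// for l = 1..lmax.  Adding H(Q) to best gives the grid MI.
static std::vector<double> dp_columns(const std::vector<double>& cum, int K,
                                      int ny, int lmax, double n) {
  if (lmax > K) lmax = K;
  // precompute g(s,t), the score of a single column spanning boundaries
  // (s, t], for all 0 <= s < t <= K
  // G[t * (K+1) + s]: score of a single column spanning boundaries (s, t],
  // stored so the dynamic programme reads contiguously over s
  std::vector<double> G((size_t)(K + 1) * (K + 1), 0.0);
  // counts are integers: table of i * log2(i) avoids log calls in the loop
  int ni = (int)n;
  std::vector<double> xlx(ni + 1, 0.0);
  for (int i = 2; i <= ni; ++i) xlx[i] = i * log2_((double)i);
  for (int t = 1; t <= K; ++t) {
    const double* ct = &cum[(size_t)t * ny];
    double* Gt = &G[(size_t)t * (K + 1)];
    for (int s = 0; s < t; ++s) {
      const double* cs = &cum[(size_t)s * ny];
      double sc = 0.0;
      int M = 0;
      for (int r = 0; r < ny; ++r) {
        int m = (int)(ct[r] - cs[r] + 0.5);
        sc += xlx[m];
        M += m;
      }
      sc -= xlx[M];
      Gt[s] = sc / n;
    }
  }
  // rolling DP over the number of columns l
  const double ninf = -std::numeric_limits<double>::infinity();
  std::vector<double> Fprev(K + 1, ninf), Fcurr(K + 1, ninf);
  std::vector<double> out(lmax);
  for (int t = 1; t <= K; ++t) Fprev[t] = G[(size_t)t * (K + 1)];
  out[0] = Fprev[K];
  for (int l = 2; l <= lmax; ++l) {
    for (int t = 1; t < l; ++t) Fcurr[t] = ninf;
    for (int t = l; t <= K; ++t) {
      const double* Gt = &G[(size_t)t * (K + 1)];
      double best = ninf;
      for (int s = l - 1; s < t; ++s) {
        double v = Fprev[s] + Gt[s];
        if (v > best) best = v;
      }
      Fcurr[t] = best;
    }
    out[l - 1] = std::max(out[l - 2], Fcurr[K]);
    std::swap(Fprev, Fcurr);
  }
  return out;
}

// entropy (bits) of row margin from cumulative counts at boundary K
static double row_entropy(const std::vector<double>& cum, int K, int ny,
                          double n) {
  double H = 0.0;
  for (int r = 0; r < ny; ++r) {
    double m = cum[(size_t)K * ny + r];
    if (m > 0) H -= (m / n) * log2_(m / n);
  }
  return H;
}

// One orientation: a = column axis, b = row axis.  Equipartitions b into ny
// rows, builds clump candidate boundaries on a (merged to <= kmax
// superclumps), and returns best MI over <= l columns for l = 1..lmax.
static std::vector<double> orient_scores(const std::vector<double>& a,
                                         const std::vector<double>& b, int ny,
                                         int lmax, int kmax) {
  int n = (int)a.size();
  // rows from b: sort, group ties, equipartition
  std::vector<int> ob = order_of(b);
  std::vector<int> row(n);
  {
    std::vector<int> gsz;
    std::vector<int> gstart;
    int i = 0;
    while (i < n) {
      int j = i;
      while (j < n && b[ob[j]] == b[ob[i]]) ++j;
      gstart.push_back(i);
      gsz.push_back(j - i);
      i = j;
    }
    std::vector<int> bin = equipartition_groups(gsz, ny);
    for (size_t g = 0; g < gsz.size(); ++g)
      for (int k = gstart[g]; k < gstart[g] + gsz[g]; ++k) row[ob[k]] = bin[g];
  }
  // order by a; rowid per sorted position
  std::vector<int> oa = order_of(a);
  std::vector<int> rid(n);
  for (int i = 0; i < n; ++i) rid[i] = row[oa[i]];
  // x-groups (ties in a stay together), then clumps: consecutive groups in
  // the same single row merge; groups spanning rows stand alone
  std::vector<int> csz;  // clump sizes
  std::vector<int> crow; // clump row if pure, -1 if mixed
  {
    int i = 0;
    while (i < n) {
      int j = i;
      bool pure = true;
      while (j < n && a[oa[j]] == a[oa[i]]) {
        if (rid[j] != rid[i]) pure = false;
        ++j;
      }
      int r = pure ? rid[i] : -1;
      if (!csz.empty() && r >= 0 && crow.back() == r)
        csz.back() += (j - i);
      else {
        csz.push_back(j - i);
        crow.push_back(r);
      }
      i = j;
    }
  }
  int K = (int)csz.size();
  // clump boundary positions (in sorted-a order)
  std::vector<int> bound(K + 1, 0);
  for (int k = 0; k < K; ++k) bound[k + 1] = bound[k] + csz[k];
  if (K > kmax) {
    // superclumps: equipartition clumps by size into kmax bins
    std::vector<int> bin = equipartition_groups(csz, kmax);
    std::vector<int> nb;
    nb.push_back(0);
    for (int k = 1; k <= K; ++k)
      if (k == K || bin[k] != bin[k - 1]) nb.push_back(bound[k]);
    bound = nb;
    K = (int)bound.size() - 1;
  }
  // cumulative row counts at boundaries
  std::vector<double> cum((size_t)(K + 1) * ny, 0.0);
  for (int k = 1; k <= K; ++k) {
    for (int r = 0; r < ny; ++r)
      cum[(size_t)k * ny + r] = cum[(size_t)(k - 1) * ny + r];
    for (int p = bound[k - 1]; p < bound[k]; ++p) cum[(size_t)k * ny + rid[p]] += 1.0;
  }
  double HQ = row_entropy(cum, K, ny, (double)n);
  std::vector<double> best = dp_columns(cum, K, ny, lmax, (double)n);
  for (double& v : best) v += HQ;
  return best; // length min(lmax, K)
}

// [[Rcpp::export]]
double cpp_mic(NumericVector x, NumericVector y, int B, double clump_factor) {
  int n = x.size();
  std::vector<double> a(x.begin(), x.end()), b(y.begin(), y.end());
  double best = 0.0;
  for (int orient = 0; orient < 2; ++orient) {
    const std::vector<double>& ca = orient == 0 ? a : b;
    const std::vector<double>& cb = orient == 0 ? b : a;
    for (int ny = 2; 2 * ny <= B; ++ny) {
      int lmax = B / ny;
      if (lmax < 2) break;
      int kmax;
      if (R_FINITE(clump_factor)) {
        double k = clump_factor * lmax;
        kmax = k > n ? n : (int)k;
        if (kmax < lmax) kmax = lmax;
      } else {
        kmax = n;
      }
      std::vector<double> I = orient_scores(ca, cb, ny, lmax, kmax);
      for (int nx = 2; nx <= (int)I.size(); ++nx) {
        double denom = log2_((double)std::min(nx, ny));
        double m = I[nx - 1] / denom;
        if (m > best) best = m;
      }
      // grids coarser than the data: I has length min(lmax, K); nominal
      // column counts beyond K add nothing (empty columns), but their
      // normalisation can differ, so score them with the K-column optimum
      for (int nx = (int)I.size() + 1; nx <= lmax; ++nx) {
        double m = I.back() / log2_((double)std::min(nx, ny));
        if (m > best) best = m;
      }
    }
  }
  if (best > 1.0 && best < 1.0 + 1e-9) best = 1.0; // clamp fp jitter
  return best;
}

// [[Rcpp::export]]
double cpp_grid_score(NumericVector x, NumericVector y, int nx, int ny,
                      double clump_factor) {
  std::vector<double> a(x.begin(), x.end()), b(y.begin(), y.end());
  int n = x.size();
  auto one = [&](const std::vector<double>& ca, const std::vector<double>& cb,
                 int cols, int rows) {
    int kmax;
    if (R_FINITE(clump_factor)) {
      double k = clump_factor * cols;
      kmax = k > n ? n : (int)k;
      if (kmax < cols) kmax = cols;
    } else {
      kmax = n;
    }
    std::vector<double> I = orient_scores(ca, cb, rows, cols, kmax);
    return I.back();
  };
  double I1 = one(a, b, nx, ny); // rows on y, optimise x columns
  double I2 = one(b, a, ny, nx); // rows on x, optimise y columns
  double m = std::max(I1, I2) / log2_((double)std::min(nx, ny));
  if (m > 1.0 && m < 1.0 + 1e-9) m = 1.0;
  return m;
}

// Exact column optimisation for an explicit row assignment: used by the
// exhaustive search, which enumerates row partitions in R and optimises
// columns here with every distinct-value gap as a candidate boundary.
// rowid: 0-based row per point *sorted by the column axis*; bounds: candidate
// cut positions as cumulative point counts (must end at n).
// [[Rcpp::export]]
NumericVector cpp_optimize_columns(IntegerVector rowid, IntegerVector bounds,
                                   int ny, int lmax) {
  int n = rowid.size();
  int K = bounds.size();
  std::vector<double> cum((size_t)(K + 1) * ny, 0.0);
  int pos = 0;
  for (int k = 1; k <= K; ++k) {
    for (int r = 0; r < ny; ++r)
      cum[(size_t)k * ny + r] = cum[(size_t)(k - 1) * ny + r];
    while (pos < bounds[k - 1]) {
      cum[(size_t)k * ny + rowid[pos]] += 1.0;
      ++pos;
    }
  }
  double HQ = row_entropy(cum, K, ny, (double)n);
  std::vector<double> best = dp_columns(cum, K, ny, lmax, (double)n);
  NumericVector out(best.size());
  for (size_t i = 0; i < best.size(); ++i) out[i] = best[i] + HQ;
  return out;
}
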