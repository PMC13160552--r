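#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---- refined incompatibility ------------------------------------------------
//
// For a pair of integer-coded sites (1..4 = A,C,G,T; 0 = gap/N, dropped
// pairwise), the refined incompatibility score is the minimum number of extra
// (homoplasic) steps any tree requires to fit both sites jointly.  It is
// computed from the partition intersection graph: vertices are the observed
// states of each site, edges the observed joint states; the minimum number of
// steps over all trees equals (#joint states) - (#vertices) + (#components),
// i.e. the cycle rank of that graph.  Zero iff the two sites are compatible
// (four-gamete-style); pairs with fewer than 4 complete taxa score 0.

static int find_root(std::vector<int> &par, int v) {
  while (par[v] != v) { par[v] = par[par[v]]; v = par[v]; }
  return v;
}

static double ri_pair(const int *x, const int *y, int n) {
  bool sx[5] = {false}, sy[5] = {false};
  bool joint[5][5] = {{false}};
  int complete = 0;
  for (int t = 0; t < n; ++t) {
    int a = x[t], b = y[t];
    if (a == 0 || b == 0) continue;
    ++complete;
    sx[a] = true; sy[b] = true; joint[a][b] = true;
  }
  if (complete < 4) return 0.0;
  int nx = 0, ny = 0, nj = 0;
  int idx[5], idy[5];
  for (int a = 1; a <= 4; ++a) if (sx[a]) idx[a] = nx++;
  for (int b = 1; b <= 4; ++b) if (sy[b]) idy[b] = ny++;
  std::vector<int> par(nx + ny);
  for (int i = 0; i < nx + ny; ++i) par[i] = i;
  int ncomp = nx + ny;
  for (int a = 1; a <= 4; ++a) {
    if (!sx[a]) continue;
    for (int b = 1; b <= 4; ++b) {
      if (!joint[a][b]) continue;
      ++nj;
      int ra = find_root(par, idx[a]);
      int rb = find_root(par, nx + idy[b]);
      if (ra != rb) { par[ra] = rb; --ncomp; }
    }
  }
  int extra = nj - (nx + ny) + ncomp;
  return extra > 0 ? (double)extra : 0.0;
}

// [[Rcpp::export(name = ".ri_pair_cpp")]]
double ri_pair_cpp(IntegerVector x, IntegerVector y) {
  if (x.size() != y.size()) stop("sites must cover the same taxa");
  return ri_pair(x.begin(), y.begin(), x.size());
}

// Full matrix of refined incompatibility scores between the given sites.
// M is taxa x sites, integer coded.
// [[Rcpp::export(name = ".ri_matrix_cpp")]]
NumericMatrix ri_matrix_cpp(IntegerMatrix M) {
  int n = M.nrow(), S = M.ncol();
  // column-major copy for cache-friendly pair access
  std::vector<std::vector<int> > cols(S, std::vector<int>(n));
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < n; ++i) cols[j][i] = M(i, j);
  NumericMatrix out(S, S);
  for (int i = 0; i < S; ++i)
    for (int j = i + 1; j < S; ++j) {
      double v = ri_pair(cols[i].data(), cols[j].data(), n);
      out(i, j) = v; out(j, i) = v;
    }
  return out;
}

// Mean score over site pairs whose physical distance is within w.
// [[Rcpp::export(name = ".phi_stat_cpp")]]
double phi_stat_cpp(NumericMatrix ri, NumericVector pos, double w) {
  int S = ri.nrow();
  double sum = 0.0; long cnt = 0;
  for (int i = 0; i < S; ++i)
    for (int j = i + 1; j < S; ++j) {
      double d = pos[j] - pos[i]; if (d < 0) d = -d;
      if (d <= w) { sum += ri(i, j); ++cnt; }
    }
  if (cnt == 0) return NA_REAL;
  return sum / (double)cnt;
}

// Permutation distribution of the windowed mean score: site contents are
// shuffled over the observed physical positions (uses R's RNG, so results
// are reproducible under set.seed()).
// [[Rcpp::export(name = ".phi_perm_cpp")]]
NumericVector phi_perm_cpp(NumericMatrix ri, NumericVector pos, double w,
                           int nperm) {
  int S = ri.nrow();
  NumericVector out(nperm);
  std::vector<int> perm(S);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < S; ++i) perm[i] = i;
    // Fisher-Yates with R's RNG
    for (int i = S - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double sum = 0.0; long cnt = 0;
    for (int i = 0; i < S; ++i)
      for (int j = i + 1; j < S; ++j) {
        double d = pos[j] - pos[i]; if (d < 0) d = -d;
        if (d <= w) { sum += ri(perm[i], perm[j]); ++cnt; }
      }
    out[p] = cnt ? sum / (double)cnt : NA_REAL;
  }
  return out;
}

// ---- maximum-descent exact p-value ------------------------------------------
//
// P(maximum descent >= k) for a uniformly random arrangement of m up-steps
// (+1) and n down-steps (-1), where the descent at a point is the drop from
// the running maximum.  Exact dynamic programming over (ups used, downs used,
// current drop capped at k); hitting drop == k is absorbing.

// [[Rcpp::export(name = ".descent_pvalue_cpp")]]
double descent_pvalue_cpp(int m, int n, int k) {
  if (k <= 0) return 1.0;
  if (k > n) return 0.0;
  // dp[a][b][d]: probability of having used a ups, b downs, current drop d
  // (< k), not yet having hit k
  double need = (double)(m + 1) * (double)(n + 1) * (double)k;
  if (need > 6e7) stop("state space too large for the exact descent DP");
  std::vector<double> dp((size_t)(m + 1) * (n + 1) * k, 0.0);
  std::vector<double> nxt((size_t)(m + 1) * (n + 1) * k, 0.0);
  size_t strideA = (size_t)(n + 1) * k;
  size_t strideB = (size_t)k;
  dp[0] = 1.0;
  double hit = 0.0;
  int total = m + n;
  for (int t = 0; t < total; ++t) {
    std::fill(nxt.begin(), nxt.end(), 0.0);
    int alo = std::max(0, t - n), ahi = std::min(m, t);
    for (int a = alo; a <= ahi; ++a) {
      int b = t - a;
      double remU = m - a, remD = n - b, rem = remU + remD;
      for (int d = 0; d < k; ++d) {
        double pr = dp[a * strideA + b * strideB + d];
        if (pr == 0.0) continue;
        if (remU > 0) {
          int d2 = d > 0 ? d - 1 : 0;
          nxt[(a + 1) * strideA + b * strideB + d2] += pr * remU / rem;
        }
        if (remD > 0) {
          int d2 = d + 1;
          double q = pr * remD / rem;
          if (d2 >= k) hit += q;
          else nxt[a * strideA + (b + 1) * strideB + d2] += q;
        }
      }
    }
    std::swap(dp, nxt);
  }
  return hit;
}
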