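#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic SMC sweep over one block.
//
// X: m x n integer matrix, 0 = gap, 1..4 = A,C,G,T (already masked and
// restricted to heterozygous, connected sites).  K: particle budget.
// e: per-base error rate.  logcomp: log composition probabilities (length 4).
//
// Particles are partial haplotype-pair paths; extension weights follow the
// gap-aware recursion: each covering read is chained to hap 1 or hap 2 via
// its base at its nearest informative position left of t, or contributes the
// averaged emission when unanchored.  Extensions are enumerated parent-major
// / candidate-minor and ties in the top-K selection are broken by that
// index, so the sweep is fully deterministic.
// [[Rcpp::export(name = "dsmc_sweep_cpp")]]
List dsmc_sweep_cpp(IntegerMatrix X, int K, double e, NumericVector logcomp) {
  const int m = X.nrow(), n = X.ncol();
  if (n < 1) stop("empty block");
  if (K < 1) stop("K must be >= 1");

  const double lmatch = std::log(1.0 - e);
  const double lmis = std::log(e / 3.0);
  // averaged branch: log((p(x|s1)+p(x|s2))/2) for x matching one of s1,s2
  // (they are distinct) or neither
  const double lavg_one = std::log(((1.0 - e) + e / 3.0) / 2.0);
  const double lavg_none = lmis;  // (e/3 + e/3)/2 = e/3

  // per-column distinct observed alleles (candidate alphabet)
  std::vector<std::vector<int> > alleles(n);
  for (int j = 0; j < n; ++j) {
    bool seen[5] = {false, false, false, false, false};
    for (int i = 0; i < m; ++i) seen[X(i, j)] = true;
    for (int b = 1; b <= 4; ++b)
      if (seen[b]) alleles[j].push_back(b);
    if (alleles[j].size() < 2)
      stop("column %d has fewer than two observed alleles", j + 1);
  }

  // particle storage: paths as flat vectors (hap1, hap2), one per particle
  std::vector<std::vector<int> > h1, h2;
  std::vector<double> logw;

  // initialization at t = 1: canonical pairs s1 < s2 (mirror paths carry
  // identical weights); weight = column likelihood only, every read
  // unanchored => averaged branch
  {
    const std::vector<int> &al = alleles[0];
    for (size_t a = 0; a < al.size(); ++a) {
      for (size_t b = a + 1; b < al.size(); ++b) {
        double w = 0.0;
        for (int i = 0; i < m; ++i) {
          int x = X(i, 0);
          if (x == 0) continue;
          w += (x == al[a] || x == al[b]) ? lavg_one : lavg_none;
        }
        h1.push_back(std::vector<int>(1, al[a]));
        h2.push_back(std::vector<int>(1, al[b]));
        logw.push_back(w);
      }
    }
  }

  // select + normalize helper (stable: weight desc, index asc)
  std::vector<int> ord;
  auto select_normalize = [&](int budget) {
    ord.resize(logw.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return logw[a] > logw[b]; });
    int keep = std::min<int>(budget, (int)ord.size());
    while (keep > 0 && !std::isfinite(logw[ord[keep - 1]])) --keep;
    if (keep == 0) stop("all candidate extensions have zero weight");
    std::vector<std::vector<int> > nh1(keep), nh2(keep);
    std::vector<double> nw(keep);
    double mx = logw[ord[0]], s = 0.0;
    for (int i = 0; i < keep; ++i) s += std::exp(logw[ord[i]] - mx);
    const double lz = mx + std::log(s);
    for (int i = 0; i < keep; ++i) {
      nh1[i] = h1[ord[i]];
      nh2[i] = h2[ord[i]];
      nw[i] = logw[ord[i]] - lz;
    }
    h1.swap(nh1); h2.swap(nh2); logw.swap(nw);
  };
  select_normalize(K);

  // nearest informative position per read (0-based col + 1; 0 = none)
  std::vector<int> pos(m, 0);
  for (int i = 0; i < m; ++i)
    if (X(i, 0) != 0) pos[i] = 1;

  // reads covering each column (precomputed once)
  std::vector<std::vector<int> > cov(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i)
      if (X(i, j) != 0) cov[j].push_back(i);

  for (int t = 1; t < n; ++t) {
    const std::vector<int> &al = alleles[t];
    const int A = (int)al.size();
    const int L = A * (A - 1);
    const int Kcur = (int)logw.size();
    std::vector<std::vector<int> > e1, e2;
    std::vector<double> ew;
    e1.reserve(Kcur * L); e2.reserve(Kcur * L); ew.reserve(Kcur * L);
    for (int k = 0; k < Kcur; ++k) {
      for (int a = 0; a < A; ++a) {
        for (int b = 0; b < A; ++b) {
          if (a == b) continue;
          const int s1 = al[a], s2 = al[b];
          double w = logw[k] + logcomp[s1 - 1] + logcomp[s2 - 1];
          for (size_t ci = 0; ci < cov[t].size(); ++ci) {
            const int i = cov[t][ci];
            const int x = X(i, t);
            const int p = pos[i];
            if (p > 0) {
              const int xp = X(i, p - 1);
              if (xp == h1[k][p - 1])
                w += (x == s1) ? lmatch : lmis;
              else if (xp == h2[k][p - 1])
                w += (x == s2) ? lmatch : lmis;
              else
                w += (x == s1 || x == s2) ? lavg_one : lavg_none;
            } else {
              w += (x == s1 || x == s2) ? lavg_one : lavg_none;
            }
          }
          e1.push_back(h1[k]); e1.back().push_back(s1);
          e2.push_back(h2[k]); e2.back().push_back(s2);
          ew.push_back(w);
        }
      }
    }
    h1.swap(e1); h2.swap(e2); logw.swap(ew);
    select_normalize(K);
    for (size_t ci = 0; ci < cov[t].size(); ++ci) pos[cov[t][ci]] = t + 1;
  }

  // best particle is first after the final stable selection
  return List::create(_["h1"] = IntegerVector(h1[0].begin(), h1[0].end()),
                      _["h2"] = IntegerVector(h2[0].begin(), h2[0].end()),
                      _["log_weight"] = logw[0]);
}
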