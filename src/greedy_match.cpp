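#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Disjoint-set "next available" pointer with path compression.
static int find_ptr(std::vector<int> &f, int x) {
  while (f[x] != x) {
    f[x] = f[f[x]];
    x = f[x];
  }
  return x;
}

// Greedy 1:1 caliper matching on the propensity score, without replacement.
// Treated units are processed in descending propensity order (ties broken by
// ascending original index); each is paired with the nearest still-unused
// control whose |ps difference| <= caliper; distance ties are broken by the
// smallest original control index. Unmatched treated units are dropped.
//
// Returns a 2-column integer matrix of 1-based (treated, control) indices in
// processing order.
// [[Rcpp::export]]
IntegerMatrix greedy_match_cpp(NumericVector ps, IntegerVector treat,
                               double caliper) {
  const int n = ps.size();
  std::vector<int> tr, co;
  tr.reserve(n);
  co.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (treat[i] == 1)
      tr.push_back(i);
    else
      co.push_back(i);
  }
  const int m = static_cast<int>(co.size());
  if (tr.empty() || m == 0) return IntegerMatrix(0, 2);

  // Controls sorted by (ps, original index); equal-ps runs are in ascending
  // index order, so the first available position inside a run carries the
  // smallest index.
  std::sort(co.begin(), co.end(), [&](int a, int b) {
    if (ps[a] != ps[b]) return ps[a] < ps[b];
    return a < b;
  });
  std::vector<double> cps(m);
  for (int j = 0; j < m; ++j) cps[j] = ps[co[j]];

  std::sort(tr.begin(), tr.end(), [&](int a, int b) {
    if (ps[a] != ps[b]) return ps[a] > ps[b];
    return a < b;
  });

  // nxt[p]: first available sorted position >= p (m = none).
  // prv[k]: represents position k-1; query largest available <= p via
  // find(prv, p + 1) - 1 (-1 = none).
  std::vector<int> nxt(m + 1), prv(m + 2);
  for (int p = 0; p <= m; ++p) nxt[p] = p;
  for (int k = 0; k <= m + 1; ++k) prv[k] = k;

  std::vector<int> out_t, out_c;
  out_t.reserve(tr.size());
  out_c.reserve(tr.size());

  for (int ti : tr) {
    const double pt = ps[ti];
    const int pos = static_cast<int>(
        std::lower_bound(cps.begin(), cps.end(), pt) - cps.begin());
    const int R = find_ptr(nxt, pos);
    const int L = find_ptr(prv, pos) - 1;  // largest available <= pos - 1
    const double dR = (R < m) ? cps[R] - pt : R_PosInf;
    const double dL = (L >= 0) ? pt - cps[L] : R_PosInf;
    const double dbest = std::min(dL, dR);
    if (!(dbest <= caliper)) continue;

    // Candidate with the smallest original index at distance dbest: jump to
    // the start of the equal-ps run and take its first available position.
    int cand = -1;
    if (dR == dbest) {
      const int rs = static_cast<int>(
          std::lower_bound(cps.begin(), cps.end(), cps[R]) - cps.begin());
      cand = find_ptr(nxt, rs);
    }
    if (dL == dbest) {
      const int ls = static_cast<int>(
          std::lower_bound(cps.begin(), cps.end(), cps[L]) - cps.begin());
      const int candL = find_ptr(nxt, ls);
      if (cand < 0 || co[candL] < co[cand]) cand = candL;
    }

    out_t.push_back(ti + 1);
    out_c.push_back(co[cand] + 1);
    nxt[cand] = cand + 1;      // delete from "next available"
    prv[cand + 1] = cand;      // delete from "prev available"
  }

  IntegerMatrix res(out_t.size(), 2);
  for (size_t r = 0; r < out_t.size(); ++r) {
    res(r, 0) = out_t[r];
    res(r, 1) = out_c[r];
  }
  colnames(res) = CharacterVector::create("treated", "control");
  return res;
}
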