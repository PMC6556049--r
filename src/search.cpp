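#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exhaustive depth-first search over candidate assignments with three
// feasibility criteria: one-to-one use of template atoms, bond
// consistency against all previously placed atoms (equality of coded
// bond types in both directions), and dead-end elimination -- a branch
// is pruned when its cumulative squared distance plus an admissible
// lower bound (sum over unassigned query atoms of the minimum squared
// distance to any still-unclaimed candidate) cannot beat the best
// complete mapping found so far. Candidates at each node are tried in
// ascending squared-distance order; the first-found optimum is kept, so
// the result is deterministic.

namespace {

struct Search {
  int n;
  const IntegerVector &order;           // 0-based search order
  std::vector<std::vector<int>> cand;   // 0-based candidates per query atom
  const NumericMatrix &d2;
  const IntegerMatrix &qb, &tb;         // coded bond types, 0 = no bond
  bool use_dee;
  std::vector<int> map, best_map;
  std::vector<char> used;
  double best;
  double nodes;

  Search(const IntegerVector &ord, const List &cands, const NumericMatrix &d2_,
         const IntegerMatrix &qb_, const IntegerMatrix &tb_, bool dee)
      : n(ord.size()), order(ord), d2(d2_), qb(qb_), tb(tb_), use_dee(dee),
        map(n, -1), used(n, 0),
        best(std::numeric_limits<double>::infinity()), nodes(0.0) {
    cand.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector ci = cands[i];
      cand[i].assign(ci.begin(), ci.end());
    }
  }

  bool bond_ok(int a, int t, int k) const {
    for (int j = 0; j < k; ++j) {
      int p = order[j];
      if (qb(a, p) != tb(t, map[p])) return false;
    }
    return true;
  }

  void dfs(int k, double cum) {
    if (k == n) {
      if (cum < best) {
        best = cum;
        best_map = map;
      }
      return;
    }
    int a = order[k];

    std::vector<std::pair<double, int>> cs;
    cs.reserve(cand[a].size());
    for (int t : cand[a])
      if (!used[t] && bond_ok(a, t, k))
        cs.push_back(std::make_pair(d2(a, t), t));
    std::stable_sort(cs.begin(), cs.end());

    // Per remaining atom: the two smallest distances over unclaimed
    // candidates and the claimant of the smallest, so that the bound
    // excluding any particular template atom is O(1) per candidate.
    const double inf = std::numeric_limits<double>::infinity();
    double lb_base = 0.0;
    std::vector<double> min1, min2;
    std::vector<int> arg1;
    if (use_dee && best < inf) {
      int m = n - k - 1;
      min1.assign(m, inf);
      min2.assign(m, inf);
      arg1.assign(m, -1);
      for (int r = 0; r < m; ++r) {
        int u = order[k + 1 + r];
        for (int t : cand[u]) {
          if (used[t]) continue;
          double d = d2(u, t);
          if (d < min1[r]) {
            min2[r] = min1[r];
            min1[r] = d;
            arg1[r] = t;
          } else if (d < min2[r]) {
            min2[r] = d;
          }
        }
        lb_base += min1[r];
      }
    }

    for (size_t c = 0; c < cs.size(); ++c) {
      double d = cs[c].first;
      int t = cs[c].second;
      nodes += 1.0;
      if (use_dee && best < std::numeric_limits<double>::infinity()) {
        double lb = lb_base;
        if (std::isfinite(lb)) {
          for (size_t r = 0; r < arg1.size(); ++r)
            if (arg1[r] == t) lb += min2[r] - min1[r];
        }
        if (cum + d + lb >= best) continue;
      }
      map[a] = t;
      used[t] = 1;
      dfs(k + 1, cum + d);
      used[t] = 0;
      map[a] = -1;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_mapping_search(IntegerVector order0, List candidates0,
                        NumericMatrix d2, IntegerMatrix qbond,
                        IntegerMatrix tbond, bool use_dee) {
  Search s(order0, candidates0, d2, qbond, tbond, use_dee);
  s.dfs(0, 0.0);
  bool found = std::isfinite(s.best);
  IntegerVector mapping(s.n, NA_INTEGER);
  if (found)
    for (int i = 0; i < s.n; ++i) mapping[i] = s.best_map[i] + 1;
  return List::create(_["found"] = found, _["mapping"] = mapping,
                      _["total_sq"] = found ? s.best : NA_REAL,
                      _["nodes"] = s.nodes);
}
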