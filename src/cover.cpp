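// Greedy set cover engines: exact greedy with maintained residual sizes, and
// the bucketed disk-friendly greedy (DFG) with lazy residual re-evaluation.
//
// Both engines are templated over a set accessor so they run either on an
// explicit collection of candidate sets (the set cover API) or directly on a
// thresholded distance matrix (candidate set i = closed ball of radius r
// around point i), without materializing the balls.
//
// Fairness quotas enter as per-class demand tokens: while class j still has
// remaining demand, every unselected candidate of class j counts one extra
// unit of residual coverage, and selecting it consumes one unit of demand.
// All tie-breaking randomness comes from R's RNG (unif_rand), so set.seed()
// at the R level makes every run reproducible.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// uniform integer in [0, m)
inline int rand_below(int m) {
  int v = (int)(unif_rand() * m);
  if (v >= m) v = m - 1;
  return v;
}

// Fisher-Yates shuffle driven by R's RNG
inline void shuffle_vec(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rand_below(i + 1);
    std::swap(v[i], v[j]);
  }
}

// accessor over an explicit set system (plus inverted element->sets index,
// built on demand by the exact engine)
struct ExplicitSets {
  const std::vector<std::vector<int> >* sets;
  std::vector<std::vector<int> > containing;
  int n_sets_, n_univ_;

  int n_sets() const { return n_sets_; }
  int n_univ() const { return n_univ_; }
  int initial_size(int i) const { return (int)(*sets)[i].size(); }

  template <class F> void each_member(int i, F f) const {
    const std::vector<int>& s = (*sets)[i];
    for (size_t t = 0; t < s.size(); ++t) f(s[t]);
  }
  void build_inverted() {
    containing.assign(n_univ_, std::vector<int>());
    std::vector<int> cnt(n_univ_, 0);
    for (int i = 0; i < n_sets_; ++i)
      for (size_t t = 0; t < (*sets)[i].size(); ++t) ++cnt[(*sets)[i][t]];
    for (int e = 0; e < n_univ_; ++e) containing[e].reserve(cnt[e]);
    for (int i = 0; i < n_sets_; ++i)
      for (size_t t = 0; t < (*sets)[i].size(); ++t)
        containing[(*sets)[i][t]].push_back(i);
  }
  template <class F> void each_containing(int e, F f) const {
    const std::vector<int>& c = containing[e];
    for (size_t t = 0; t < c.size(); ++t) f(c[t]);
  }
};

// accessor over closed balls of a symmetric distance matrix: set i covers
// j iff D(j, i) <= r; element e is contained in set i iff D(e, i) <= r,
// which by symmetry is the same column scan
struct DistBalls {
  const double* D;
  double r;
  int n;

  int n_sets() const { return n; }
  int n_univ() const { return n; }
  int initial_size(int i) const {
    const double* col = D + (size_t)i * n;
    int c = 0;
    for (int j = 0; j < n; ++j)
      if (col[j] <= r) ++c;
    return c;
  }
  template <class F> void each_member(int i, F f) const {
    const double* col = D + (size_t)i * n;
    for (int j = 0; j < n; ++j)
      if (col[j] <= r) f(j);
  }
  void build_inverted() {}
  template <class F> void each_containing(int e, F f) const {
    each_member(e, f);  // symmetry
  }
};

// covering progress plus fairness demand bookkeeping
struct CoverState {
  std::vector<char> covered;
  int n_uncovered;
  std::vector<int> cls;     // per-set class id, empty = no fairness
  std::vector<int> demand;  // remaining demand per class
  int total_demand;

  void init(int n_univ, IntegerVector set_class, IntegerVector quota) {
    covered.assign(n_univ, 0);
    n_uncovered = n_univ;
    total_demand = 0;
    if (set_class.size() > 0) {
      cls.assign(set_class.begin(), set_class.end());
      demand.assign(quota.begin(), quota.end());
      for (size_t j = 0; j < demand.size(); ++j) total_demand += demand[j];
    }
  }
  bool fair() const { return !cls.empty(); }
  int fair_bonus(int s) const {
    return (fair() && demand[cls[s]] > 0) ? 1 : 0;
  }
  bool done() const { return n_uncovered == 0 && total_demand == 0; }
};

template <class Acc>
int lazy_residual(const Acc& acc, const CoverState& st, int i) {
  int r = 0;
  acc.each_member(i, [&](int e) { if (!st.covered[e]) ++r; });
  return r;
}

// Exact greedy: residual sizes are maintained exactly via the inverted
// index; ties among maximal residuals are broken uniformly at random.
template <class Acc>
std::vector<int> exact_greedy(Acc& acc, CoverState& st, int kmax,
                              bool& infeasible) {
  const int n_sets = acc.n_sets();
  acc.build_inverted();
  std::vector<int> resid(n_sets);
  for (int i = 0; i < n_sets; ++i) resid[i] = acc.initial_size(i);

  std::vector<char> selected(n_sets, 0);
  std::vector<int> order;
  std::vector<int> ties;

  while (!st.done()) {
    int best = -1;
    for (int i = 0; i < n_sets; ++i) {
      if (selected[i]) continue;
      int eff = resid[i] + st.fair_bonus(i);
      if (eff > best) {
        best = eff;
        ties.clear();
        ties.push_back(i);
      } else if (eff == best && eff > 0) {
        ties.push_back(i);
      }
    }
    if (best <= 0)
      stop("no candidate set can cover the remaining elements or quotas");
    int s = ties[rand_below((int)ties.size())];
    selected[s] = 1;
    // cover the new elements and decrement residuals of sets containing them
    acc.each_member(s, [&](int e) {
      if (!st.covered[e]) {
        st.covered[e] = 1;
        --st.n_uncovered;
        acc.each_containing(e, [&](int t) { --resid[t]; });
      }
    });
    if (st.fair() && st.demand[st.cls[s]] > 0) {
      --st.demand[st.cls[s]];
      --st.total_demand;
    }
    order.push_back(s);
    if (kmax >= 0 && (int)order.size() > kmax) {
      infeasible = true;
      return order;
    }
  }
  return order;
}

// DFG: sets are bucketed by (effective) size, bucket k holds sizes in
// [p^k, p^{k+1}); buckets are processed from the largest downward, each in a
// freshly shuffled order; at pop time the residual is recomputed lazily and
// the set is either selected (still in its bucket) or demoted.
template <class Acc>
std::vector<int> dfg_greedy(Acc& acc, CoverState& st, double p, int kmax,
                            bool& infeasible) {
  const int n_sets = acc.n_sets();
  const double lp = std::log(p);
  std::map<long long, std::vector<int> > buckets;
  std::vector<char> selected(n_sets, 0);
  std::vector<int> order;

  for (int i = 0; i < n_sets; ++i) {
    int sz = acc.initial_size(i) + st.fair_bonus(i);
    if (sz > 0) {
      long long k = (long long)std::floor(std::log((double)sz) / lp);
      buckets[k].push_back(i);
    }
  }

  while (!st.done()) {
    if (buckets.empty())
      stop("no candidate set can cover the remaining elements or quotas");
    std::map<long long, std::vector<int> >::reverse_iterator it = buckets.rbegin();
    long long kb = it->first;
    std::vector<int> cur;
    cur.swap(it->second);
    buckets.erase(kb);
    shuffle_vec(cur);
    for (size_t q = 0; q < cur.size(); ++q) {
      int s = cur[q];
      if (selected[s]) continue;
      int eff = lazy_residual(acc, st, s) + st.fair_bonus(s);
      if (eff <= 0) continue;  // nothing left to contribute; drop
      long long knew = (long long)std::floor(std::log((double)eff) / lp);
      if (knew >= kb) {
        selected[s] = 1;
        acc.each_member(s, [&](int e) {
          if (!st.covered[e]) {
            st.covered[e] = 1;
            --st.n_uncovered;
          }
        });
        if (st.fair() && st.demand[st.cls[s]] > 0) {
          --st.demand[st.cls[s]];
          --st.total_demand;
        }
        order.push_back(s);
        if (kmax >= 0 && (int)order.size() > kmax) {
          infeasible = true;
          return order;
        }
        if (st.done()) return order;
      } else {
        buckets[knew].push_back(s);
      }
    }
  }
  return order;
}

template <class Acc>
IntegerVector run_cover(Acc& acc, CoverState& st, int engine, double p,
                        int kmax) {
  bool infeasible = false;
  std::vector<int> order;
  if (engine == 1)
    order = dfg_greedy(acc, st, p, kmax, infeasible);
  else
    order = exact_greedy(acc, st, kmax, infeasible);
  IntegerVector out((int)order.size());
  for (size_t i = 0; i < order.size(); ++i) out[i] = order[i] + 1;  // 1-based
  out.attr("infeasible") = infeasible;
  return out;
}

}  // namespace

// Greedy cover over an explicit collection of candidate sets.
// sets: list of 1-based integer vectors over universe 1..n_univ;
// engine: 0 = exact greedy, 1 = DFG with bucket base p;
// set_class: per-set 0-based class ids (length 0 disables fairness);
// quota: remaining demand per class; kmax: abort once more than kmax sets
// are selected (kmax < 0 disables). Returns selected set indices (1-based)
// in selection order, with attribute "infeasible".
// [[Rcpp::export]]
IntegerVector cpp_greedy_cover(List sets, int n_univ, int engine, double p,
                               IntegerVector set_class, IntegerVector quota,
                               int kmax) {
  RNGScope rng;
  int n_sets = sets.size();
  std::vector<std::vector<int> > ss(n_sets);
  for (int i = 0; i < n_sets; ++i) {
    IntegerVector v = sets[i];
    ss[i].resize(v.size());
    for (int t = 0; t < v.size(); ++t) ss[i][t] = v[t] - 1;
  }
  ExplicitSets acc;
  acc.sets = &ss;
  acc.n_sets_ = n_sets;
  acc.n_univ_ = n_univ;
  CoverState st;
  st.init(n_univ, set_class, quota);
  return run_cover(acc, st, engine, p, kmax);
}

// Greedy ball cover directly from a symmetric distance matrix: candidate set
// i is the closed ball of radius r around point i.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cover_dist(NumericMatrix D, double r, int engine,
                                    double p, IntegerVector set_class,
                                    IntegerVector quota, int kmax) {
  RNGScope rng;
  DistBalls acc;
  acc.D = REAL(D);
  acc.r = r;
  acc.n = D.nrow();
  CoverState st;
  st.init(acc.n, set_class, quota);
  return run_cover(acc, st, engine, p, kmax);
}
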