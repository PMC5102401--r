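#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Self-contained counter RNG (splitmix64) so solver runs are reproducible
// from an integer seed and independent of R's RNG state.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int rint(int n) { return (int)(runif() * n); }
};

// Minimum-set objective: sum of selected costs plus, per feature, a species
// penalty factor times the normalised shortfall s_f / T_f.
struct State {
  int n, m;
  const double *cost;
  const int *pu_ptr;    // length n + 1, 0-based CSC by planning unit
  const int *feat_idx;  // feature index per entry, 0-based
  const double *amt;
  const double *target;
  const double *spf;
  std::vector<int> sel;
  std::vector<double> rep;
  double cost_tot, pen_tot;

  double pen_f(int f, double r) const {
    double s = target[f] - r;
    return s > 0 ? spf[f] * s / target[f] : 0.0;
  }

  void recompute() {
    cost_tot = 0.0;
    std::fill(rep.begin(), rep.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      if (!sel[i]) continue;
      cost_tot += cost[i];
      for (int k = pu_ptr[i]; k < pu_ptr[i + 1]; ++k) rep[feat_idx[k]] += amt[k];
    }
    pen_tot = 0.0;
    for (int f = 0; f < m; ++f) pen_tot += pen_f(f, rep[f]);
  }

  double objective() const { return cost_tot + pen_tot; }

  // change in objective from flipping unit i (without applying it)
  double delta(int i) const {
    double sgn = sel[i] ? -1.0 : 1.0;
    double d = sgn * cost[i];
    for (int k = pu_ptr[i]; k < pu_ptr[i + 1]; ++k) {
      int f = feat_idx[k];
      d += pen_f(f, rep[f] + sgn * amt[k]) - pen_f(f, rep[f]);
    }
    return d;
  }

  void flip(int i) {
    double sgn = sel[i] ? -1.0 : 1.0;
    cost_tot += sgn * cost[i];
    for (int k = pu_ptr[i]; k < pu_ptr[i + 1]; ++k) {
      int f = feat_idx[k];
      pen_tot -= pen_f(f, rep[f]);
      rep[f] += sgn * amt[k];
      pen_tot += pen_f(f, rep[f]);
    }
    sel[i] = 1 - sel[i];
  }
};

static void improve(State &st, Rng &rng, int max_passes) {
  int n = st.n;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int pass = 0; pass < max_passes; ++pass) {
    // Fisher-Yates shuffle of the sweep order
    for (int i = n - 1; i > 0; --i) std::swap(ord[i], ord[rng.rint(i + 1)]);
    bool changed = false;
    for (int j = 0; j < n; ++j) {
      int i = ord[j];
      if (st.delta(i) < -1e-12) { st.flip(i); changed = true; }
    }
    if (!changed) break;
  }
}

// [[Rcpp::export]]
List anneal_cpp(NumericVector cost, IntegerVector pu_ptr, IntegerVector feat_idx,
                NumericVector amt, NumericVector target, NumericVector spf,
                int n_iterations, double t_initial, double t_final,
                int improvement_passes, double init_prob, double seed) {
  State st;
  st.n = cost.size();
  st.m = target.size();
  st.cost = REAL(cost);
  st.pu_ptr = INTEGER(pu_ptr);
  st.feat_idx = INTEGER(feat_idx);
  st.amt = REAL(amt);
  st.target = REAL(target);
  st.spf = REAL(spf);
  st.sel.assign(st.n, 0);
  st.rep.assign(st.m, 0.0);

  Rng rng((uint64_t)seed);
  for (int i = 0; i < st.n; ++i) st.sel[i] = rng.runif() < init_prob ? 1 : 0;
  st.recompute();

  double alpha = std::pow(t_final / t_initial, 1.0 / std::max(1, n_iterations));
  double T = t_initial;
  // track the best state visited, as annealing can drift away from it late
  std::vector<int> best_sel = st.sel;
  double best_obj = st.objective();
  for (int it = 0; it < n_iterations; ++it) {
    int i = rng.rint(st.n);
    double d = st.delta(i);
    if (d < 0.0 || rng.runif() < std::exp(-d / T)) {
      st.flip(i);
      double obj = st.objective();
      if (obj < best_obj - 1e-12) { best_obj = obj; best_sel = st.sel; }
    }
    T *= alpha;
  }
  st.sel = best_sel;
  st.recompute();
  improve(st, rng, improvement_passes);

  st.recompute(); // guard against drift in incremental bookkeeping
  return List::create(
    _["selected"] = LogicalVector(st.sel.begin(), st.sel.end()),
    _["objective"] = st.objective(),
    _["cost"] = st.cost_tot,
    _["penalty"] = st.pen_tot,
    _["representation"] = NumericVector(st.rep.begin(), st.rep.end()));
}

// [[Rcpp::export]]
List brute_force_cpp(NumericVector cost, IntegerVector pu_ptr, IntegerVector feat_idx,
                     NumericVector amt, NumericVector target, NumericVector spf) {
  State st;
  st.n = cost.size();
  st.m = target.size();
  if (st.n > 25) stop("exhaustive search refused for more than 25 units");
  st.cost = REAL(cost);
  st.pu_ptr = INTEGER(pu_ptr);
  st.feat_idx = INTEGER(feat_idx);
  st.amt = REAL(amt);
  st.spf = REAL(spf);
  st.target = REAL(target);
  st.sel.assign(st.n, 0);
  st.rep.assign(st.m, 0.0);
  st.recompute();

  uint64_t total = 1ULL << st.n;
  double best = st.objective();
  uint64_t best_mask = 0, gray_prev = 0;
  int best_k = 0;
  // Gray-code walk: one flip per subset
  for (uint64_t s = 1; s < total; ++s) {
    uint64_t gray = s ^ (s >> 1);
    uint64_t bit = gray ^ gray_prev;
    int i = 0;
    while (!((bit >> i) & 1ULL)) ++i;
    st.flip(i);
    gray_prev = gray;
    double obj = st.objective();
    int k = __builtin_popcountll(gray);
    // ties broken toward fewer units, then lexicographically smaller id sets
    bool better = obj < best - 1e-12;
    if (!better && obj < best + 1e-12) {
      if (k < best_k) better = true;
      else if (k == best_k) {
        // lexicographic on sorted id lists == smaller lowest set bits first
        for (int b = 0; b < st.n; ++b) {
          bool in_g = (gray >> b) & 1ULL, in_b = (best_mask >> b) & 1ULL;
          if (in_g != in_b) { better = in_g; break; }
        }
      }
    }
    if (better) { best = obj; best_mask = gray; best_k = k; }
  }
  LogicalVector sel(st.n);
  for (int i = 0; i < st.n; ++i) sel[i] = (best_mask >> i) & 1ULL;
  return List::create(_["selected"] = sel, _["objective"] = best);
}
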