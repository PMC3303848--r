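#include "bnbmla_core.h"
#include <functional>
using namespace Rcpp;

// Exhaustive enumeration of labeled DAGs on small domains (n <= 6) by
// assigning each node's parent set in order, pruning as soon as a partial
// assignment contains a cycle (edges only accumulate, so pruning is sound).

static int popcnt(unsigned x) {
#ifdef __GNUC__
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { c += x & 1u; x >>= 1; } return c;
#endif
}

// Reach set of node k via edges assigned so far (parents chosen for nodes
// 0..assigned-1): edge k -> j exists iff k is in mask[j].
static unsigned reach_of(int k, int assigned, const std::vector<unsigned> &mask,
                         int n) {
  unsigned seen = 0;
  std::vector<int> stack(1, k);
  while (!stack.empty()) {
    int x = stack.back(); stack.pop_back();
    for (int j = 0; j < assigned; ++j) {
      if ((mask[j] >> x) & 1u) {
        if (!((seen >> j) & 1u)) { seen |= 1u << j; stack.push_back(j); }
      }
    }
  }
  return seen;
}

static void enumerate_rec(int k, int n, int maxpar, std::vector<unsigned> &mask,
                          const std::function<void(const std::vector<unsigned> &)> &leaf) {
  if (k == n) { leaf(mask); return; }
  unsigned forbidden = (1u << k) | reach_of(k, k, mask, n);
  unsigned allowed = ((n >= 32 ? ~0u : ((1u << n) - 1u))) & ~forbidden;
  unsigned sub = allowed;
  while (true) {
    if (popcnt(sub) <= maxpar) {
      mask[k] = sub;
      enumerate_rec(k + 1, n, maxpar, mask, leaf);
    }
    if (sub == 0) break;
    sub = (sub - 1) & allowed;
  }
  mask[k] = 0;
}

// [[Rcpp::export]]
double cpp_count_dags(int n, int maxpar) {
  if (n < 1 || n > 6) stop("DAG enumeration supports 1 <= n <= 6");
  double count = 0;
  std::vector<unsigned> mask(n, 0);
  enumerate_rec(0, n, maxpar, mask,
                [&](const std::vector<unsigned> &) { count += 1; });
  return count;
}

// Materialize every DAG as a list of 1-based parent-index vectors.
// [[Rcpp::export]]
List cpp_enumerate_dags(int n, int maxpar) {
  if (n < 1 || n > 5) stop("DAG materialization supports 1 <= n <= 5");
  std::vector<SEXP> out;
  std::vector<unsigned> mask(n, 0);
  enumerate_rec(0, n, maxpar, mask, [&](const std::vector<unsigned> &m) {
    List ps(n);
    for (int v = 0; v < n; ++v) {
      IntegerVector pv;
      for (int u = 0; u < n; ++u)
        if ((m[v] >> u) & 1u) pv.push_back(u + 1);
      ps[v] = pv;
    }
    out.push_back(ps);
  });
  return List(out.begin(), out.end());
}

// Exact feature and MBS posteriors by full enumeration: two passes, the
// first finds the maximum log score (for stable normalization), the second
// accumulates softmax-weighted feature indicators.
// [[Rcpp::export]]
List cpp_oracle_posteriors(IntegerMatrix data, IntegerVector arity,
                           IntegerVector targets1, IntegerVector preds1,
                           int maxpar, int prior, double ess) {
  const int n = arity.size();
  if (n < 1 || n > 6) stop("exact posteriors support 1 <= n_vars <= 6");
  std::vector<int> targets(targets1.begin(), targets1.end());
  std::vector<int> preds(preds1.begin(), preds1.end());
  for (int &t : targets) t -= 1;
  for (int &p : preds) p -= 1;

  // precompute family scores for every (child, parent mask)
  std::vector<std::vector<double>> fs(n, std::vector<double>(1u << n, 0.0));
  for (int v = 0; v < n; ++v) {
    for (unsigned m = 0; m < (1u << n); ++m) {
      if ((m >> v) & 1u) continue;
      if (popcnt(m) > maxpar) continue;
      std::vector<int> pa;
      for (int u = 0; u < n; ++u)
        if ((m >> u) & 1u) pa.push_back(u);
      fs[v][m] = family_log_marginal_core(data, arity, v, pa, prior, ess);
    }
  }
  auto dag_score = [&](const std::vector<unsigned> &m) {
    double s = 0;
    for (int v = 0; v < n; ++v) s += fs[v][m[v]];
    return s;
  };

  double max_score = -std::numeric_limits<double>::infinity();
  double n_dags = 0;
  std::vector<unsigned> mask(n, 0);
  enumerate_rec(0, n, maxpar, mask, [&](const std::vector<unsigned> &m) {
    double s = dag_score(m);
    if (s > max_score) max_score = s;
    n_dags += 1;
  });

  double z = 0;
  enumerate_rec(0, n, maxpar, mask, [&](const std::vector<unsigned> &m) {
    z += std::exp(dag_score(m) - max_score);
  });

  FeatureAccumulator acc((int)preds.size(), (int)targets.size());
  enumerate_rec(0, n, maxpar, mask, [&](const std::vector<unsigned> &m) {
    double w = std::exp(dag_score(m) - max_score) / z;
    Dag g(n);
    for (int v = 0; v < n; ++v)
      for (int u = 0; u < n; ++u)
        if ((m[v] >> u) & 1u) g.add(u, v);
    accumulate_features(g, targets, preds, acc, w,
                        (std::vector<unsigned char> *)0);
  });

  List out = accumulator_to_list(acc, targets, n);
  out["n_dags"] = n_dags;
  out["log_z"] = max_score + std::log(z);
  return out;
}
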