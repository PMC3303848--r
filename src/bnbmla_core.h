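#ifndef BNBMLA_CORE_H
#define BNBMLA_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <map>
#include <utility>

typedef std::vector<uint64_t> Bits;

inline int bits_nwords(int n) { return (n + 63) / 64; }
inline bool bits_get(const Bits &b, int i) { return (b[i >> 6] >> (i & 63)) & 1ULL; }
inline void bits_set(Bits &b, int i) { b[i >> 6] |= (1ULL << (i & 63)); }
inline void bits_clear(Bits &b, int i) { b[i >> 6] &= ~(1ULL << (i & 63)); }
inline bool bits_any(const Bits &b) {
  for (uint64_t w : b) if (w) return true;
  return false;
}
inline int bits_count(const Bits &b) {
  int c = 0;
  for (uint64_t w : b) {
#ifdef __GNUC__
    c += __builtin_popcountll(w);
#else
    while (w) { c += (int)(w & 1ULL); w >>= 1; }
#endif
  }
  return c;
}

// Directed graph with children/parents as bitsets; invariantly acyclic when
// used by the sampler (moves are validated before application).
struct Dag {
  int n, nw;
  std::vector<Bits> ch, pa;
  std::vector<int> npar;
  explicit Dag(int n_)
    : n(n_), nw(bits_nwords(n_)),
      ch(n_, Bits(bits_nwords(n_), 0)),
      pa(n_, Bits(bits_nwords(n_), 0)),
      npar(n_, 0) {}
  bool has(int u, int v) const { return bits_get(ch[u], v); }
  void add(int u, int v) { bits_set(ch[u], v); bits_set(pa[v], u); npar[v]++; }
  void del(int u, int v) { bits_clear(ch[u], v); bits_clear(pa[v], u); npar[v]--; }
  int n_edges() const {
    int e = 0;
    for (int i = 0; i < n; ++i) e += bits_count(ch[i]);
    return e;
  }
};

// Descendant sets (excluding self) for every node, by memoized DFS.
inline void dag_descendants(const Dag &g, std::vector<Bits> &desc) {
  const int n = g.n, nw = g.nw;
  desc.assign(n, Bits(nw, 0));
  std::vector<int> state(n, 0);  // 0 = new, 2 = done
  std::vector<int> stack;
  stack.reserve(n);
  for (int s = 0; s < n; ++s) {
    if (state[s] == 2) continue;
    stack.push_back(s);
    while (!stack.empty()) {
      int v = stack.back();
      if (state[v] == 0) {
        state[v] = 1;
        for (int u = 0; u < n; ++u)
          if (bits_get(g.ch[v], u) && state[u] == 0) stack.push_back(u);
      } else if (state[v] == 1) {
        stack.pop_back();
        state[v] = 2;
        for (int u = 0; u < n; ++u) {
          if (bits_get(g.ch[v], u)) {
            bits_set(desc[v], u);
            for (int w = 0; w < nw; ++w) desc[v][w] |= desc[u][w];
          }
        }
      } else {
        stack.pop_back();
      }
    }
  }
}

// Can u reach v if the direct edge u->v is ignored?  Used to validate edge
// reversal (a surviving u ~> v path would become a cycle).
inline bool dag_reaches_excluding(const Dag &g, int u, int v) {
  const int n = g.n;
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  for (int c = 0; c < n; ++c)
    if (bits_get(g.ch[u], c) && c != v) { stack.push_back(c); seen[c] = 1; }
  while (!stack.empty()) {
    int x = stack.back(); stack.pop_back();
    if (x == v) return true;
    for (int c = 0; c < n; ++c)
      if (bits_get(g.ch[x], c) && !seen[c]) { seen[c] = 1; stack.push_back(c); }
  }
  return false;
}

// ---------------------------------------------------------------------------
// Structural features of Table-2 type for one DAG.

struct FeatureAccumulator {
  int n_pred, n_tar, n_set_feats;
  // pairwise, flattened pred-major: [p * n_tar + t]
  std::vector<double> dcr, tcr, confr, assoc, pir, sr, med;
  // multi-target
  std::vector<double> mt_exist, mt_only, mt_other;   // per (pred, target)
  std::vector<double> mt_any, edge_any;              // per pred
  std::map<std::pair<int, Bits>, double> mbs;        // (target index, set) -> mass
  std::map<Bits, double> mbs_set;                    // joint-target blanket -> mass
  double total;

  FeatureAccumulator(int np, int nt)
    : n_pred(np), n_tar(nt),
      dcr(np * nt, 0), tcr(np * nt, 0), confr(np * nt, 0), assoc(np * nt, 0),
      pir(np * nt, 0), sr(np * nt, 0), med(np * nt, 0),
      mt_exist(np * nt, 0), mt_only(np * nt, 0), mt_other(np * nt, 0),
      mt_any(np, 0), edge_any(np, 0), total(0) {}
};

// Markov blanket of y: parents + children + other parents of children.
inline Bits markov_blanket_bits(const Dag &g, int y) {
  Bits mb = g.pa[y];
  for (int w = 0; w < g.nw; ++w) mb[w] |= g.ch[y][w];
  for (int c = 0; c < g.n; ++c)
    if (bits_get(g.ch[y], c))
      for (int w = 0; w < g.nw; ++w) mb[w] |= g.pa[c][w];
  bits_clear(mb, y);
  return mb;
}

// Evaluate all tracked features of g and add them to acc with weight wt.
inline void accumulate_features(const Dag &g,
                                const std::vector<int> &targets,
                                const std::vector<int> &preds,
                                FeatureAccumulator &acc,
                                double wt,
                                std::vector<unsigned char> *sr_series) {
  const int n = g.n, nw = g.nw;
  const int nt = (int)targets.size(), np = (int)preds.size();
  std::vector<Bits> desc;
  dag_descendants(g, desc);
  // ancestors as transpose of descendants
  std::vector<Bits> anc(n, Bits(nw, 0));
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      if (bits_get(desc[u], v)) bits_set(anc[v], u);

  // per-target Markov blanket sets
  for (int ti = 0; ti < nt; ++ti) {
    Bits mb = markov_blanket_bits(g, targets[ti]);
    acc.mbs[std::make_pair(ti, mb)] += wt;
  }
  if (nt > 1) {
    Bits mb(nw, 0);
    for (int t : targets) {
      Bits m = markov_blanket_bits(g, t);
      for (int w = 0; w < nw; ++w) mb[w] |= m[w];
    }
    for (int t : targets) bits_clear(mb, t);
    acc.mbs_set[mb] += wt;
  }

  for (int pi = 0; pi < np; ++pi) {
    int p = preds[pi];
    bool any_sr = false, any_edge = false;
    std::vector<char> sr_pt(nt, 0);
    for (int ti = 0; ti < nt; ++ti) {
      int t = targets[ti];
      bool e_dcr = g.has(p, t) || g.has(t, p);
      bool e_tcr = bits_get(desc[p], t) || bits_get(desc[t], p);
      bool e_confr = false;
      for (int w = 0; w < nw && !e_confr; ++w) {
        uint64_t common = anc[p][w] & anc[t][w];
        if (w == (p >> 6)) common &= ~(1ULL << (p & 63));
        if (w == (t >> 6)) common &= ~(1ULL << (t & 63));
        if (common) e_confr = true;
      }
      bool child_shared = false;
      for (int w = 0; w < nw && !child_shared; ++w)
        if (g.ch[p][w] & g.ch[t][w]) child_shared = true;
      bool e_pir = child_shared && !e_dcr;
      bool e_sr = e_dcr || e_pir;
      bool e_assoc = e_dcr || e_tcr || e_confr;
      int k = pi * nt + ti;
      if (e_dcr) acc.dcr[k] += wt;
      if (e_tcr) acc.tcr[k] += wt;
      if (e_confr) acc.confr[k] += wt;
      if (e_assoc) acc.assoc[k] += wt;
      if (e_pir) acc.pir[k] += wt;
      if (e_sr) acc.sr[k] += wt;
      if (e_tcr && !e_dcr) acc.med[k] += wt;
      if (e_sr) acc.mt_exist[k] += wt;
      sr_pt[ti] = e_sr ? 1 : 0;
      any_sr = any_sr || e_sr;
      any_edge = any_edge || e_dcr;
      if (sr_series) sr_series->push_back(sr_pt[ti]);
    }
    if (any_sr) acc.mt_any[pi] += wt;
    if (any_edge) acc.edge_any[pi] += wt;
    for (int ti = 0; ti < nt; ++ti) {
      bool others = false;
      for (int tj = 0; tj < nt; ++tj)
        if (tj != ti && sr_pt[tj]) { others = true; break; }
      if (sr_pt[ti] && !others) acc.mt_only[pi * nt + ti] += wt;
      if (others) acc.mt_other[pi * nt + ti] += wt;
    }
  }
  acc.total += wt;
}

// ---------------------------------------------------------------------------
// Closed-form Dirichlet-multinomial family score.

// prior: 0 = CH (every hyperparameter 1), 1 = BDeu (ess / (r * q)).
double family_log_marginal_core(const Rcpp::IntegerMatrix &data,
                                const Rcpp::IntegerVector &arity,
                                int child, const std::vector<int> &parents,
                                int prior, double ess);

struct ScoreCache {
  std::map<std::pair<int, Bits>, double> m;
};

double cached_family_score(const Rcpp::IntegerMatrix &data,
                           const Rcpp::IntegerVector &arity,
                           int child, const Bits &pa_bits, int n_vars,
                           int prior, double ess, ScoreCache &cache);

Rcpp::List accumulator_to_list(const FeatureAccumulator &acc,
                               const std::vector<int> &targets, int n_vars);

#endif
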