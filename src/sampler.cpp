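#include "bnbmla_core.h"
#include <random>
using namespace Rcpp;

// Deterministic, platform-stable RNG helpers on top of mt19937_64.
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { return (double)(eng() >> 11) * (1.0 / 9007199254740992.0); }
  int rint(int k) {  // uniform on 0..k-1
    int x = (int)(unif() * k);
    return x >= k ? k - 1 : x;
  }
};

struct Neigh {
  std::vector<std::pair<int, int>> adds, dels, revs;
};

// Full neighborhood of g under the three structure operators, respecting
// acyclicity and the parent limit.
static void neighborhoods(const Dag &g, int maxpar, Neigh &nb) {
  nb.adds.clear(); nb.dels.clear(); nb.revs.clear();
  std::vector<Bits> desc;
  dag_descendants(g, desc);
  for (int u = 0; u < g.n; ++u) {
    for (int v = 0; v < g.n; ++v) {
      if (u == v) continue;
      if (g.has(u, v)) {
        nb.dels.push_back(std::make_pair(u, v));
        if (g.npar[u] < maxpar && !dag_reaches_excluding(g, u, v))
          nb.revs.push_back(std::make_pair(u, v));
      } else if (!g.has(v, u)) {
        // adding u -> v is valid iff v does not already reach u
        if (g.npar[v] < maxpar && !bits_get(desc[v], u))
          nb.adds.push_back(std::make_pair(u, v));
      }
    }
  }
}

static void neighborhood_counts(const Dag &g, int maxpar,
                                int &na, int &nd, int &nr) {
  na = nd = nr = 0;
  std::vector<Bits> desc;
  dag_descendants(g, desc);
  for (int u = 0; u < g.n; ++u) {
    for (int v = 0; v < g.n; ++v) {
      if (u == v) continue;
      if (g.has(u, v)) {
        nd++;
        if (g.npar[u] < maxpar && !dag_reaches_excluding(g, u, v)) nr++;
      } else if (!g.has(v, u)) {
        if (g.npar[v] < maxpar && !bits_get(desc[v], u)) na++;
      }
    }
  }
}

struct ChainState {
  Dag g;
  double logscore;
  explicit ChainState(int n) : g(n), logscore(0.0) {}
};

struct MoveCtx {
  const IntegerMatrix &data;
  const IntegerVector &arity;
  int maxpar, prior;
  double ess;
  ScoreCache &cache;
};

// One Metropolis-Hastings step with operator-uniform proposals and exact
// neighborhood-size Hastings correction.  Returns 1 on acceptance.
static int mh_step(ChainState &st, double beta, MoveCtx &cx, Rng &rng,
                   long long &resamples) {
  Dag &g = st.g;
  Neigh nb;
  neighborhoods(g, cx.maxpar, nb);
  const int counts[3] = {(int)nb.adds.size(), (int)nb.dels.size(),
                         (int)nb.revs.size()};
  int avail = (counts[0] > 0) + (counts[1] > 0) + (counts[2] > 0);
  if (avail == 0) return 0;  // single-node domain
  int op = rng.rint(3);
  while (counts[op] == 0) { resamples++; op = rng.rint(3); }
  const std::vector<std::pair<int, int>> &pool =
    (op == 0) ? nb.adds : (op == 1) ? nb.dels : nb.revs;
  std::pair<int, int> mv = pool[rng.rint(counts[op])];
  const int u = mv.first, v = mv.second;

  double delta = 0.0;
  if (op == 0) {        // add u -> v
    Bits pb = g.pa[v];
    double s0 = cached_family_score(cx.data, cx.arity, v, pb, g.n, cx.prior,
                                    cx.ess, cx.cache);
    bits_set(pb, u);
    double s1 = cached_family_score(cx.data, cx.arity, v, pb, g.n, cx.prior,
                                    cx.ess, cx.cache);
    delta = s1 - s0;
  } else if (op == 1) { // delete u -> v
    Bits pb = g.pa[v];
    double s0 = cached_family_score(cx.data, cx.arity, v, pb, g.n, cx.prior,
                                    cx.ess, cx.cache);
    bits_clear(pb, u);
    double s1 = cached_family_score(cx.data, cx.arity, v, pb, g.n, cx.prior,
                                    cx.ess, cx.cache);
    delta = s1 - s0;
  } else {              // reverse u -> v
    Bits pbv = g.pa[v];
    double sv0 = cached_family_score(cx.data, cx.arity, v, pbv, g.n, cx.prior,
                                     cx.ess, cx.cache);
    bits_clear(pbv, u);
    double sv1 = cached_family_score(cx.data, cx.arity, v, pbv, g.n, cx.prior,
                                     cx.ess, cx.cache);
    Bits pbu = g.pa[u];
    double su0 = cached_family_score(cx.data, cx.arity, u, pbu, g.n, cx.prior,
                                     cx.ess, cx.cache);
    bits_set(pbu, v);
    double su1 = cached_family_score(cx.data, cx.arity, u, pbu, g.n, cx.prior,
                                     cx.ess, cx.cache);
    delta = (sv1 - sv0) + (su1 - su0);
  }

  double logq_fwd = -std::log((double)avail) - std::log((double)counts[op]);

  // apply move
  if (op == 0) g.add(u, v);
  else if (op == 1) g.del(u, v);
  else { g.del(u, v); g.add(v, u); }

  int na2, nd2, nr2;
  neighborhood_counts(g, cx.maxpar, na2, nd2, nr2);
  int avail2 = (na2 > 0) + (nd2 > 0) + (nr2 > 0);
  int rev_count = (op == 0) ? nd2 : (op == 1) ? na2 : nr2;
  double logq_rev = -std::log((double)avail2) - std::log((double)rev_count);

  double log_alpha = beta * delta + logq_rev - logq_fwd;
  if (log_alpha >= 0 || std::log(rng.unif()) < log_alpha) {
    st.logscore += delta;
    return 1;
  }
  // undo
  if (op == 0) g.del(u, v);
  else if (op == 1) g.add(u, v);
  else { g.del(v, u); g.add(u, v); }
  return 0;
}

// Metropolis-coupled MCMC over DAG structures.  Chain 0 is the cold chain
// (inverse temperature 1); only its states contribute to estimates.
// [[Rcpp::export]]
List cpp_mc3_run(IntegerMatrix data, IntegerVector arity, List cfg,
                 IntegerVector targets1, IntegerVector preds1) {
  const int n_vars = arity.size();
  const long long burn_in = (long long)as<double>(cfg["burn_in"]);
  const long long n_steps = (long long)as<double>(cfg["n_steps"]);
  const int n_chains = as<int>(cfg["n_chains"]);
  NumericVector betas = cfg["inverse_temperatures"];
  const long long swap_interval = (long long)as<double>(cfg["swap_interval"]);
  const long long feat_interval =
    (long long)as<double>(cfg["feature_eval_interval"]);
  const int maxpar = as<int>(cfg["max_parents"]);
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  const int prior = as<int>(cfg["prior"]);
  const double ess = as<double>(cfg["ess"]);
  const bool store_series = as<bool>(cfg["store_series"]);
  const bool store_dags = as<bool>(cfg["store_dags"]);

  std::vector<int> targets(targets1.begin(), targets1.end());
  std::vector<int> preds(preds1.begin(), preds1.end());
  for (int &t : targets) t -= 1;
  for (int &p : preds) p -= 1;

  Rng rng(seed);
  ScoreCache cache;
  MoveCtx cx{data, arity, maxpar, prior, ess, cache};

  std::vector<ChainState> chains;
  for (int c = 0; c < n_chains; ++c) chains.emplace_back(n_vars);
  // empty graph start: score = sum of no-parent family scores
  {
    double s0 = 0.0;
    Bits none(bits_nwords(n_vars), 0);
    for (int v = 0; v < n_vars; ++v)
      s0 += cached_family_score(data, arity, v, none, n_vars, prior, ess, cache);
    for (int c = 0; c < n_chains; ++c) chains[c].logscore = s0;
  }

  FeatureAccumulator acc((int)preds.size(), (int)targets.size());
  std::vector<unsigned char> series;
  std::vector<SEXP> dag_store;
  std::vector<double> score_trace;
  std::vector<long long> accepts(n_chains, 0);
  std::vector<long long> swap_att(std::max(n_chains - 1, 0), 0);
  std::vector<long long> swap_acc(std::max(n_chains - 1, 0), 0);
  long long resamples = 0;

  const long long total = burn_in + n_steps;
  for (long long step = 1; step <= total; ++step) {
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    for (int c = 0; c < n_chains; ++c)
      accepts[c] += mh_step(chains[c], betas[c], cx, rng, resamples);
    if (n_chains > 1 && swap_interval > 0 && step % swap_interval == 0) {
      int i = rng.rint(n_chains - 1);
      double lr = (betas[i] - betas[i + 1]) *
                  (chains[i + 1].logscore - chains[i].logscore);
      swap_att[i]++;
      if (lr >= 0 || std::log(rng.unif()) < lr) {
        std::swap(chains[i].g, chains[i + 1].g);
        std::swap(chains[i].logscore, chains[i + 1].logscore);
        swap_acc[i]++;
      }
    }
    if (step > burn_in && (step - burn_in) % feat_interval == 0) {
      accumulate_features(chains[0].g, targets, preds, acc, 1.0,
                          store_series ? &series : (std::vector<unsigned char> *)0);
      score_trace.push_back(chains[0].logscore);
      if (store_dags) {
        List ps(n_vars);
        for (int v = 0; v < n_vars; ++v) {
          IntegerVector pv;
          for (int u = 0; u < n_vars; ++u)
            if (chains[0].g.has(u, v)) pv.push_back(u + 1);
          ps[v] = pv;
        }
        dag_store.push_back(ps);
      }
    }
  }

  List out = accumulator_to_list(acc, targets, n_vars);
  NumericVector acc_rate(n_chains);
  for (int c = 0; c < n_chains; ++c) acc_rate[c] = (double)accepts[c] / total;
  out["acceptance_rate"] = acc_rate;
  out["swap_attempts"] =
    NumericVector(swap_att.begin(), swap_att.end());
  out["swap_accepts"] = NumericVector(swap_acc.begin(), swap_acc.end());
  out["operator_resamples"] = (double)resamples;
  out["score_trace"] = NumericVector(score_trace.begin(), score_trace.end());
  out["cache_size"] = (double)cache.m.size();
  if (store_series) {
    const int width = (int)(preds.size() * targets.size());
    const int nrec = width > 0 ? (int)(series.size() / width) : 0;
    RawMatrix sm(width, nrec);
    for (size_t i = 0; i < series.size(); ++i) sm[i] = series[i];
    out["sr_series"] = sm;
  }
  if (store_dags) out["dags"] = List(dag_store.begin(), dag_store.end());
  return out;
}
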