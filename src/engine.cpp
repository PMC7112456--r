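// Event-driven core for the SSFIR process plus the two random-graph samplers.
// All randomness flows through a private 64-bit generator so that results are
// reproducible from an integer seed independently of R's RNG state.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

class Rng {
public:
  Rng(uint64_t a, uint64_t b) {
    std::seed_seq ss{a, b};
    gen_.seed(ss);
  }
  // uniform in (0, 1): top 53 bits, offset to exclude exact 0
  double unif() {
    return ((gen_() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // uniform integer in [0, n)
  int below(int n) {
    return static_cast<int>(unif() * n) % n;
  }
private:
  std::mt19937_64 gen_;
};

// Fenwick tree over per-node event rates; supports O(log n) update and
// sampling of an index proportionally to its rate.
class Fenwick {
public:
  explicit Fenwick(int n) : n_(n), tree_(n + 1, 0.0), val_(n, 0.0) {}
  void set(int i, double v) {
    double d = v - val_[i];
    val_[i] = v;
    for (int j = i + 1; j <= n_; j += j & (-j)) tree_[j] += d;
  }
  double get(int i) const { return val_[i]; }
  double total() const {
    double s = 0.0;
    for (int j = n_; j > 0; j -= j & (-j)) s += tree_[j];
    return s;
  }
  // largest index i such that prefix_sum(i) < u; returns a node with val > 0
  int sample(double u) const {
    int pos = 0, logn = 1;
    while ((1 << logn) <= n_) ++logn;
    for (int k = logn; k >= 0; --k) {
      int next = pos + (1 << k);
      if (next <= n_ && tree_[next] < u) {
        pos = next;
        u -= tree_[next];
      }
    }
    // pos is 1-based count of skipped entries -> 0-based index pos
    int i = pos;
    if (i >= n_) i = n_ - 1;
    // guard against floating drift landing on a zero-rate node
    while (i > 0 && val_[i] <= 0.0) --i;
    while (i < n_ - 1 && val_[i] <= 0.0) ++i;
    return i;
  }
private:
  int n_;
  std::vector<double> tree_;
  std::vector<double> val_;
};

enum State : uint8_t { S = 0, SF = 1, I = 2, R = 3 };

struct RunResult {
  int n_s, n_sf, n_r;
  int peak_i;
  double t_end;
  int ev_inf_s, ev_alert, ev_inf_sf, ev_rec;
  int seed0;
  bool consistent;
};

RunResult run_one(int n, const IntegerVector& ptr, const IntegerVector& idx,
                  double beta, double beta_f, double gamma, double mu,
                  const std::vector<int>& seeds, Rng& rng) {
  std::vector<uint8_t> st(n, S);
  std::vector<int> nS(n, 0), nF(n, 0);  // tracked for infected nodes only
  Fenwick rates(n);

  int nI = 0, nR = 0, peak = 0;
  int evs = 0, eva = 0, evf = 0, evr = 0;
  double t = 0.0;

  auto node_rate = [&](int i) {
    return (beta + beta_f) * nS[i] + gamma * beta * nF[i] + mu;
  };
  auto refresh_counts = [&](int i) {
    int cs = 0, cf = 0;
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      uint8_t s2 = st[idx[e]];
      if (s2 == S) ++cs; else if (s2 == SF) ++cf;
    }
    nS[i] = cs; nF[i] = cf;
  };
  // make node j infected (from S or SF), updating neighbours' edge counts
  auto infect = [&](int j) {
    uint8_t was = st[j];
    st[j] = I;
    for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
      int nb = idx[e];
      if (st[nb] == I) {
        if (was == S) --nS[nb]; else --nF[nb];
        rates.set(nb, node_rate(nb));
      }
    }
    refresh_counts(j);
    rates.set(j, node_rate(j));
    ++nI;
    if (nI > peak) peak = nI;
  };

  for (int s0 : seeds) infect(s0);
  int n_seeded = nI;

  while (nI > 0) {
    double total = rates.total();
    t += -std::log(rng.unif()) / total;
    int i = rates.sample(rng.unif() * total);
    double ri = rates.get(i);
    double u = rng.unif() * ri;
    double r_inf = beta * nS[i];
    double r_alert = beta_f * nS[i];
    double r_inf_f = gamma * beta * nF[i];
    if (u < r_inf || u < r_inf + r_alert) {
      bool is_inf = (u < r_inf);
      // pick a uniformly random susceptible neighbour of i
      int target = rng.below(nS[i]), j = -1;
      for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
        if (st[idx[e]] == S && target-- == 0) { j = idx[e]; break; }
      }
      if (is_inf) {
        infect(j);
        ++evs;
      } else {
        st[j] = SF;
        for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
          int nb = idx[e];
          if (st[nb] == I) {
            --nS[nb]; ++nF[nb];
            rates.set(nb, node_rate(nb));
          }
        }
        ++eva;
      }
    } else if (u < r_inf + r_alert + r_inf_f) {
      int target = rng.below(nF[i]), j = -1;
      for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
        if (st[idx[e]] == SF && target-- == 0) { j = idx[e]; break; }
      }
      infect(j);
      ++evf;
    } else {
      st[i] = R;
      rates.set(i, 0.0);
      --nI; ++nR; ++evr;
    }
  }

  RunResult out;
  int cs = 0, cf = 0, ci = 0, cr = 0;
  for (int i = 0; i < n; ++i) {
    switch (st[i]) {
      case S: ++cs; break;
      case SF: ++cf; break;
      case I: ++ci; break;
      case R: ++cr; break;
    }
  }
  out.n_s = cs; out.n_sf = cf; out.n_r = cr;
  out.peak_i = peak;
  out.t_end = t;
  out.ev_inf_s = evs; out.ev_alert = eva; out.ev_inf_sf = evf; out.ev_rec = evr;
  out.seed0 = seeds.empty() ? -1 : seeds[0];
  out.consistent = (ci == 0) && (cs + cf + ci + cr == n) &&
                   (cr == n_seeded + evs + evf) && (evr == cr) && (cf == eva - evf);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_run_epidemic")]]
NumericVector cpp_run_epidemic(int n, IntegerVector ptr, IntegerVector idx,
                               double beta, double beta_f, double gamma, double mu,
                               IntegerVector seeds, int master_seed) {
  Rng rng(static_cast<uint64_t>(master_seed), 0x9e3779b9u);
  std::vector<int> sv(seeds.begin(), seeds.end());
  RunResult r = run_one(n, ptr, idx, beta, beta_f, gamma, mu, sv, rng);
  return NumericVector::create(
      _["n_s"] = r.n_s, _["n_sf"] = r.n_sf, _["n_r"] = r.n_r,
      _["peak_i"] = r.peak_i, _["t_end"] = r.t_end,
      _["ev_inf_s"] = r.ev_inf_s, _["ev_alert"] = r.ev_alert,
      _["ev_inf_sf"] = r.ev_inf_sf, _["ev_rec"] = r.ev_rec,
      _["consistent"] = r.consistent ? 1.0 : 0.0);
}

// [[Rcpp::export(name = ".cpp_run_ensemble")]]
NumericMatrix cpp_run_ensemble(int n, IntegerVector ptr, IntegerVector idx,
                               double beta, double beta_f, double gamma, double mu,
                               int n_realizations, int n_seeds,
                               IntegerVector fixed_seeds, int master_seed) {
  NumericMatrix out(n_realizations, 5);
  colnames(out) = CharacterVector::create("seed_node", "rho", "sf_frac",
                                          "peak_i_frac", "t_end");
  for (int r = 0; r < n_realizations; ++r) {
    Rng rng(static_cast<uint64_t>(master_seed), static_cast<uint64_t>(r) + 1);
    std::vector<int> seeds;
    if (fixed_seeds.size() > 0) {
      seeds.assign(fixed_seeds.begin(), fixed_seeds.end());
    } else {
      std::unordered_set<int> chosen;
      while (static_cast<int>(chosen.size()) < n_seeds) chosen.insert(rng.below(n));
      seeds.assign(chosen.begin(), chosen.end());
    }
    RunResult res = run_one(n, ptr, idx, beta, beta_f, gamma, mu, seeds, rng);
    if (!res.consistent) stop("internal state-conservation violation in realization %d", r + 1);
    out(r, 0) = res.seed0;
    out(r, 1) = static_cast<double>(res.n_r) / n;
    out(r, 2) = static_cast<double>(res.n_sf) / n;
    out(r, 3) = static_cast<double>(res.peak_i) / n;
    out(r, 4) = res.t_end;
  }
  return out;
}

// G(n, p) edge sampler (skip-based enumeration over the upper triangle).
// [[Rcpp::export(name = ".cpp_er_edges")]]
IntegerMatrix cpp_er_edges(int n, double p, int master_seed) {
  Rng rng(static_cast<uint64_t>(master_seed), 0x2545F491u);
  std::vector<int> from, to;
  if (p >= 1.0) {
    for (int v = 1; v < n; ++v)
      for (int w = 0; w < v; ++w) { from.push_back(w); to.push_back(v); }
  } else if (p > 0.0) {
    double lq = std::log(1.0 - p);
    long long v = 1, w = -1;
    while (v < n) {
      w += 1 + static_cast<long long>(std::floor(std::log(rng.unif()) / lq));
      while (w >= v && v < n) { w -= v; ++v; }
      if (v < n) { from.push_back(static_cast<int>(w)); to.push_back(static_cast<int>(v)); }
    }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t i = 0; i < from.size(); ++i) { out(i, 0) = from[i]; out(i, 1) = to[i]; }
  return out;
}

// Configuration-model stub matching with rejection of self-loops and
// multi-edges. Conflicting stub pairs are redrawn; a deadlock (only
// illegal pairings left) triggers a full re-matching, bounded.
// [[Rcpp::export(name = ".cpp_stub_match")]]
IntegerMatrix cpp_stub_match(IntegerVector degrees, int master_seed, int max_restarts) {
  int n = degrees.size();
  std::vector<int> base;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < degrees[i]; ++d) base.push_back(i);
  if (base.size() % 2 != 0) stop("degree sum must be even");
  long long m = static_cast<long long>(base.size()) / 2;

  Rng rng(static_cast<uint64_t>(master_seed), 0x853c49e6u);
  for (int attempt = 1; attempt <= max_restarts; ++attempt) {
    std::vector<int> stubs = base;
    std::unordered_set<long long> seen;
    seen.reserve(2 * m);
    std::vector<int> from, to;
    from.reserve(m); to.reserve(m);
    int remaining = static_cast<int>(stubs.size());
    long long fails = 0;
    const long long fail_limit = 10000 + 100LL * n;
    while (remaining >= 2 && fails < fail_limit) {
      int a = rng.below(remaining);
      int b = rng.below(remaining - 1);
      if (b >= a) ++b;
      int u = stubs[a], v = stubs[b];
      if (u == v) { ++fails; continue; }
      long long key = static_cast<long long>(std::min(u, v)) * n + std::max(u, v);
      if (seen.count(key)) { ++fails; continue; }
      seen.insert(key);
      from.push_back(std::min(u, v));
      to.push_back(std::max(u, v));
      if (a < b) std::swap(a, b);           // remove the larger index first
      stubs[a] = stubs[remaining - 1];
      stubs[b] = stubs[remaining - 2];
      remaining -= 2;
      fails = 0;
    }
    if (remaining == 0) {
      IntegerMatrix out(from.size(), 2);
      for (size_t i = 0; i < from.size(); ++i) { out(i, 0) = from[i]; out(i, 1) = to[i]; }
      return out;
    }
  }
  stop("stub matching failed to produce a simple graph after %d restarts", max_restarts);
  return IntegerMatrix(0, 2);  // unreachable
}
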