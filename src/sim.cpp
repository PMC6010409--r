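#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Agent-based core for syllable-type transmission. Individuals are slots in a
// fixed-size population; a year consists of simultaneous mortality draws
// followed by replacement of each dead slot with a juvenile that learns from
// the surviving adults. Randomness comes from a xoshiro256++ stream seeded
// from R's RNG at each entry point, so set.seed() in R gives bit-reproducible
// runs while keeping the per-event cost low.

struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  void seed_from_R() {
    // derive 256 bits of state from R's RNG; avoid an all-zero state
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo;
    }
    s[0] |= 1;
    for (int i = 0; i < 16; ++i) next();
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  int unif_int(int n) { // 0..n-1
    return (int)(unif() * n);
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() { // standard normal, Box-Muller with cached spare
    if (have_spare) { have_spare = false; return spare; }
    double u, v, ss;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      ss = u * u + v * v;
    } while (ss >= 1.0 || ss == 0.0);
    double m = std::sqrt(-2.0 * std::log(ss) / ss);
    spare = v * m; have_spare = true;
    return u * m;
  }
};

typedef std::vector<int> Rep;           // repertoire: distinct 1-based type ids

// repertoires stored flat (fixed stride) for cache locality
struct RepPool {
  std::vector<int> flat;
  std::vector<int> rsz;
  int stride;
  void init(int n, int stride_) {
    stride = stride_;
    flat.assign((size_t)n * stride, 0);
    rsz.assign(n, 0);
  }
  const int* begin(int i) const { return &flat[(size_t)i * stride]; }
  int size(int i) const { return rsz[i]; }
  void set(int i, const Rep& r) {
    rsz[i] = (int)r.size();
    for (size_t s = 0; s < r.size(); ++s) flat[(size_t)i * stride + s] = r[s];
  }
};

static inline bool contains(const Rep& r, int x) {
  for (size_t i = 0; i < r.size(); ++i) if (r[i] == x) return true;
  return false;
}

// reusable scratch space for one learning event; the per-type stamp
// array gives O(1) memory accumulation over the whole alphabet
struct Scratch {
  std::vector<int> type;
  std::vector<double> F, Tsum, base, G, w;
  std::vector<char> used;
  std::vector<int> stamp, pos;
  int gen = 0;
  Scratch() {
    type.reserve(512); F.reserve(512); Tsum.reserve(512);
    base.reserve(512); G.reserve(512); w.reserve(512); used.reserve(512);
  }
  void clear(int N_s) {
    type.clear(); F.clear(); Tsum.clear();
    if ((int)stamp.size() < N_s) { stamp.assign(N_s, 0); pos.assign(N_s, 0); }
    ++gen;
  }
  void add(int x, double t) {
    int idx = x - 1;
    if (stamp[idx] == gen) {
      F[pos[idx]] += 1.0; Tsum[pos[idx]] += t;
    } else {
      stamp[idx] = gen; pos[idx] = (int)type.size();
      type.push_back(x); F.push_back(1.0); Tsum.push_back(t);
    }
  }
};

// uniform mutation target: a type other than `selected` and not already in
// `rep`; falls back to `selected` only if the alphabet is exhausted
static int mutate_type(Xoshiro& rng, int selected, const Rep& rep, int N_s) {
  if ((int)rep.size() + 1 >= N_s) {
    for (int x = 1; x <= N_s; ++x)
      if (x != selected && !contains(rep, x)) return x;
    return selected;
  }
  for (int tries = 0; tries < 10000; ++tries) {
    int x = rng.unif_int(N_s) + 1;
    if (x != selected && !contains(rep, x)) return x;
  }
  return selected;
}

// weighted draw among indices with !used; returns index
static int weighted_pick(Xoshiro& rng, const std::vector<double>& w,
                         const std::vector<char>& used) {
  double tot = 0.0;
  for (size_t i = 0; i < w.size(); ++i) if (!used[i]) tot += w[i];
  if (tot <= 0.0) { // degenerate: uniform among unused
    int n = 0;
    for (size_t i = 0; i < w.size(); ++i) if (!used[i]) ++n;
    int k = rng.unif_int(n);
    for (size_t i = 0; i < w.size(); ++i)
      if (!used[i] && k-- == 0) return (int)i;
  }
  double u = rng.unif() * tot, acc = 0.0;
  int last = -1;
  for (size_t i = 0; i < w.size(); ++i) {
    if (used[i]) continue;
    last = (int)i;
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return last;
}

// index of the single item left unselected after a full weighted
// without-replacement draw (the last item of a Plackett-Luce ordering)
static int pl_last(Xoshiro& rng, const std::vector<double>& w,
                   std::vector<char>& used) {
  int n = (int)w.size();
  used.assign(n, 0);
  for (int k = 0; k < n - 1; ++k) used[weighted_pick(rng, w, used)] = 1;
  for (int i = 0; i < n; ++i) if (!used[i]) return i;
  return n - 1;
}

// partial Fisher-Yates: after the call, pool[0..k-1] is a uniform sample
// without replacement (contents preserved, order permuted)
static void sample_k(Xoshiro& rng, std::vector<int>& pool, int k) {
  int n = (int)pool.size();
  for (int j = 0; j < k; ++j) {
    int i = j + rng.unif_int(n - j);
    std::swap(pool[j], pool[i]);
  }
}

// Model 1: memorise N_T repertoires, choose r_m types with probability
// proportional to F^alpha * M * T, mutate each chosen syllable with prob mu
// powF is a lookup for f^alpha, f = 0..N_T (F is a demonstrator count)
static void learn_m1(Xoshiro& rng, Scratch& sc, const RepPool& reps,
                     const std::vector<double>& t_m, std::vector<int>& pool,
                     const std::vector<double>& M,
                     const std::vector<double>& powF, double mu,
                     int N_T, int N_s, int r_m, Rep& rep) {
  int k = std::min(N_T, (int)pool.size());
  sample_k(rng, pool, k);
  sc.clear(N_s);
  for (int j = 0; j < k; ++j) {
    int d = pool[j];
    const int* rj = reps.begin(d);
    for (int s = 0; s < reps.size(d); ++s)
      sc.add(rj[s], t_m[d]);
  }
  int m = (int)sc.type.size();
  sc.w.assign(m, 0.0);
  for (int i = 0; i < m; ++i)
    sc.w[i] = powF[(int)sc.F[i]] * M[sc.type[i] - 1] *
              (sc.Tsum[i] / sc.F[i]);
  rep.clear();
  sc.used.assign(m, 0);
  double tot = 0.0;
  for (int i = 0; i < m; ++i) tot += sc.w[i];
  int drawn = 0;
  while ((int)rep.size() < r_m && drawn < m) {
    int i;
    if (tot <= 0.0) {
      i = weighted_pick(rng, sc.w, sc.used);
    } else {
      double u = rng.unif() * tot, acc = 0.0;
      i = -1;
      for (int j = 0; j < m; ++j) {
        if (sc.used[j]) continue;
        i = j;
        acc += sc.w[j];
        if (u <= acc) break;
      }
    }
    sc.used[i] = 1; ++drawn;
    tot -= sc.w[i];
    int x = sc.type[i];
    if (rng.unif() < mu) x = mutate_type(rng, x, rep, N_s);
    if (!contains(rep, x)) rep.push_back(x);
  }
  // memory exhausted before reaching r_m: the remaining learning events
  // can only produce novelty through mutation (never when mu = 0)
  int remaining = r_m - (int)rep.size();
  for (int s2 = 0; s2 < remaining && (int)rep.size() < N_s; ++s2)
    if (rng.unif() < mu) {
      int x = mutate_type(rng, 0, rep, N_s);
      if (!contains(rep, x)) rep.push_back(x);
    }
}

// Model 2: memorise the union of N_T1 repertoires (truncated to 8 by
// attrition), tally support G from a second, disjoint sample of N_T2
// adults, then drop the least-supported type (weights (W+G)*M*T) until
// r_m remain
static void learn_m2(Xoshiro& rng, Scratch& sc, const RepPool& reps,
                     const std::vector<double>& t_m, std::vector<int>& pool,
                     const std::vector<double>& M, double mu, int N_T1,
                     int N_T2, double W, int N_s, int r_m, Rep& rep) {
  int P = (int)pool.size();
  int k1 = std::min(N_T1, P);
  int k2 = std::min(N_T2, P - k1);
  sample_k(rng, pool, k1 + k2);
  sc.clear(N_s);
  for (int j = 0; j < k1; ++j) {
    int d = pool[j];
    const int* rj = reps.begin(d);
    for (int s = 0; s < reps.size(d); ++s)
      sc.add(rj[s], t_m[d]);
  }
  size_t m = sc.type.size();
  sc.base.assign(m, 0.0); // M * T, fixed by phase 1
  for (size_t i = 0; i < m; ++i)
    sc.base[i] = M[sc.type[i] - 1] * (sc.Tsum[i] / sc.F[i]);

  // first reduction: no phase-2 evidence yet, weights (W + 0) * M * T
  while (sc.type.size() > 8) {
    sc.w.assign(sc.type.size(), 0.0);
    for (size_t i = 0; i < sc.type.size(); ++i) sc.w[i] = W * sc.base[i];
    int drop = pl_last(rng, sc.w, sc.used);
    sc.type.erase(sc.type.begin() + drop);
    sc.base.erase(sc.base.begin() + drop);
  }
  // phase 2: count repertoires containing each memorised type
  sc.G.assign(sc.type.size(), 0.0);
  for (int j = k1; j < k1 + k2; ++j) {
    int d = pool[j];
    const int* rj = reps.begin(d);
    for (int s = 0; s < reps.size(d); ++s)
      for (size_t i = 0; i < sc.type.size(); ++i)
        if (sc.type[i] == rj[s]) { sc.G[i] += 1.0; break; }
  }
  while ((int)sc.type.size() > r_m) {
    sc.w.assign(sc.type.size(), 0.0);
    for (size_t i = 0; i < sc.type.size(); ++i)
      sc.w[i] = (W + sc.G[i]) * sc.base[i];
    int drop = pl_last(rng, sc.w, sc.used);
    sc.type.erase(sc.type.begin() + drop);
    sc.base.erase(sc.base.begin() + drop);
    sc.G.erase(sc.G.begin() + drop);
  }
  rep.assign(sc.type.begin(), sc.type.end());
  for (size_t i = 0; i < rep.size(); ++i)
    if (rng.unif() < mu) rep[i] = mutate_type(rng, rep[i], rep, N_s);
}

static RepPool as_pool(List reps, int stride = 8) {
  RepPool out;
  int mx = 1;
  for (int i = 0; i < reps.size(); ++i)
    mx = std::max(mx, (int)Rf_length(reps[i]));
  out.init(reps.size(), std::max(stride, mx));
  for (int i = 0; i < reps.size(); ++i) {
    IntegerVector r = reps[i];
    out.rsz[i] = r.size();
    for (int s = 0; s < r.size(); ++s)
      out.flat[(size_t)i * out.stride + s] = r[s];
  }
  return out;
}

static std::vector<double> pow_table(double alpha, int N_T) {
  std::vector<double> powF(N_T + 1, 0.0);
  for (int f = 1; f <= N_T; ++f) powF[f] = std::pow((double)f, alpha);
  return powF;
}

static int sample_rep_size(Xoshiro& rng, const std::vector<double>& probs) {
  double u = rng.unif(), acc = 0.0;
  for (size_t i = 0; i < probs.size(); ++i) {
    acc += probs[i];
    if (u <= acc) return (int)i + 1;
  }
  return (int)probs.size();
}

// [[Rcpp::export(name = ".cpp_learn_m1")]]
IntegerVector cpp_learn_m1(List pool_reps, NumericVector pool_t,
                           NumericVector M, double alpha, double mu,
                           int N_T, int r_m) {
  Xoshiro rng; rng.seed_from_R();
  Scratch sc;
  RepPool reps = as_pool(pool_reps);
  std::vector<double> t(pool_t.begin(), pool_t.end());
  std::vector<double> Mv(M.begin(), M.end());
  std::vector<int> idx(pool_reps.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
  Rep r;
  std::vector<double> powF = pow_table(alpha, std::max(1, N_T));
  learn_m1(rng, sc, reps, t, idx, Mv, powF, mu, N_T, (int)M.size(), r_m, r);
  return IntegerVector(r.begin(), r.end());
}

// [[Rcpp::export(name = ".cpp_learn_m2")]]
IntegerVector cpp_learn_m2(List pool_reps, NumericVector pool_t,
                           NumericVector M, double mu, int N_T1, int N_T2,
                           double W, int r_m) {
  Xoshiro rng; rng.seed_from_R();
  Scratch sc;
  RepPool reps = as_pool(pool_reps);
  std::vector<double> t(pool_t.begin(), pool_t.end());
  std::vector<double> Mv(M.begin(), M.end());
  std::vector<int> idx(pool_reps.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
  Rep r;
  learn_m2(rng, sc, reps, t, idx, Mv, mu, N_T1, N_T2, W, (int)M.size(),
           r_m, r);
  return IntegerVector(r.begin(), r.end());
}

// [[Rcpp::export(name = ".cpp_pl_last")]]
IntegerVector cpp_pl_last(NumericVector w, int n) {
  Xoshiro rng; rng.seed_from_R();
  std::vector<double> wv(w.begin(), w.end());
  std::vector<char> used;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pl_last(rng, wv, used) + 1;
  return out;
}

// [[Rcpp::export(name = ".cpp_advance")]]
List cpp_advance(List reps_in, NumericVector t_in, IntegerVector birth_in,
                 NumericVector M, IntegerVector type_birth_in, int year,
                 int model, double mu, double v, double alpha, int N_T,
                 int N_T1, int N_T2, double W, double mortality,
                 NumericVector rep_probs, int nyears) {
  Xoshiro rng; rng.seed_from_R();
  Scratch sc;
  int N_p = reps_in.size();
  int N_s = M.size();
  RepPool reps = as_pool(reps_in);
  std::vector<double> t_m(t_in.begin(), t_in.end());
  std::vector<int> birth(birth_in.begin(), birth_in.end());
  std::vector<double> Mv(M.begin(), M.end());
  std::vector<int> type_birth(type_birth_in.begin(), type_birth_in.end());
  std::vector<double> rp(rep_probs.begin(), rep_probs.end());

  std::vector<double> powF = pow_table(alpha, std::max(1, N_T));
  std::vector<int> counts(N_s, 0);
  for (int i = 0; i < N_p; ++i)
    for (int s = 0; s < reps.size(i); ++s) counts[reps.begin(i)[s] - 1]++;

  std::vector<char> dead(N_p);
  std::vector<int> pool;
  pool.reserve(N_p);
  Rep r; r.reserve(16);

  for (int y = 0; y < nyears; ++y) {
    int newyear = year + y + 1;
    pool.clear();
    for (int i = 0; i < N_p; ++i) {
      dead[i] = rng.unif() < mortality;
      if (!dead[i]) pool.push_back(i);
    }
    if (pool.empty())
      stop("every individual died in year %d; no demonstrators remain",
           newyear);
    for (int i = 0; i < N_p; ++i)
      if (dead[i])
        for (int s = 0; s < reps.size(i); ++s) counts[reps.begin(i)[s] - 1]--;
    for (int i = 0; i < N_p; ++i) {
      if (!dead[i]) continue;
      int r_m = sample_rep_size(rng, rp);
      if (model == 1)
        learn_m1(rng, sc, reps, t_m, pool, Mv, powF, mu, N_T, N_s, r_m, r);
      else
        learn_m2(rng, sc, reps, t_m, pool, Mv, mu, N_T1, N_T2, W, N_s,
                 r_m, r);
      for (size_t s = 0; s < r.size(); ++s) {
        int x = r[s] - 1;
        if (counts[x] == 0) type_birth[x] = newyear; // (re-)innovation
        counts[x]++;
      }
      reps.set(i, r);
      t_m[i] = std::exp(rng.norm() * v);
      birth[i] = newyear;
    }
  }

  List reps_out(N_p);
  for (int i = 0; i < N_p; ++i)
    reps_out[i] = IntegerVector(reps.begin(i), reps.begin(i) + reps.size(i));
  return List::create(
    _["repertoires"] = reps_out,
    _["t_m"] = NumericVector(t_m.begin(), t_m.end()),
    _["birth_ind"] = IntegerVector(birth.begin(), birth.end()),
    _["type_birth"] = IntegerVector(type_birth.begin(), type_birth.end()),
    _["year"] = year + nyears);
}
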