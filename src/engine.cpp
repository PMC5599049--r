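// Event-level core of the transcription-factor branching process.
//
// A system is a set of cistromes; cistrome i has p[i] genome segments of
// which r[i] are producing.  Producing segments are indexed canonically:
//   [0, u[i])          own-only producing segments (u = r - sum of pool sizes)
//   [u[i], r[i])       blocks of shared-pool segments, one block per pool
// Absorbing segments occupy [r[i], p[i]) and are never tracked individually.
// A shared pool couples >= 2 cistromes; position t of the pool's block in one
// member is the counterpart of position t in every other member.
//
// Dynamics per timestep: every active segment of cistrome i emits m[i] TF
// units; each unit lands uniformly over the p[i] segments of i.  A segment
// active at t deactivates after emitting and may be re-activated by landings
// within the same step; multiple landings collapse to one activation.
//
// meanfield mode: a landing on a shared segment transfers to one partner
//   (uniform among the pool's other members) and activates the counterpart
//   there; the source segment is not activated by that unit.  The step
//   expectation then matches the infinite-limit recursion with own-activation
//   weight (r - sigma)/p and incoming weight sigma/p_partner.
// two_site mode: every segment has a primary site (own-cistrome TF) and one
//   secondary site (foreign TF).  Own landings occupy primaries; each
//   occupied primary on a shared segment then attempts one transfer to the
//   secondary site of a counterpart whose secondary is still free (uniform
//   among such members; at most one foreign TF accepted per segment per
//   step).  A segment with either site occupied is active at t+1.
//
// RNG: self-contained xoshiro256++ seeded via splitmix64.  Each (run,
// cistrome-name) pair gets its own substream, so with sigma = 0 a cistrome's
// trajectory is bit-identical whether it is simulated alone or inside a
// larger system.  Transfer-resolution randomness draws from a separate
// per-run substream that is never touched when there are no shared pools.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cstring>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // unbiased uniform draw on {0, ..., n-1} (Lemire rejection)
  inline uint32_t below(uint32_t n) {
    uint64_t m = (uint64_t)(uint32_t)next() * (uint64_t)n;
    uint32_t l = (uint32_t)m;
    if (l < n) {
      uint32_t t = (uint32_t)(-(int32_t)n) % n;
      while (l < t) {
        m = (uint64_t)(uint32_t)next() * (uint64_t)n;
        l = (uint32_t)m;
      }
    }
    return (uint32_t)(m >> 32);
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline uint64_t fnv1a64(const char* s) {
  uint64_t h = 1469598103934665603ULL;
  for (; *s; ++s) { h ^= (uint64_t)(unsigned char)(*s); h *= 1099511628211ULL; }
  return h;
}

// substream seed for (master, run, tag); tag is a cistrome-name hash or a
// reserved constant for the transfer stream
static inline uint64_t substream_seed(uint64_t master, uint64_t run, uint64_t tag) {
  uint64_t x = master ^ 0xD1B54A32D192ED03ULL;
  uint64_t a = splitmix64(x);
  uint64_t y = a ^ (run * 0x9E3779B97F4A7C15ULL) ^ tag;
  return splitmix64(y);
}

static const uint64_t TRANSFER_TAG = 0xC0FFEE5EED5EED5EULL;

struct Pool {
  std::vector<int> members;      // cistrome indices
  std::vector<int> block_start;  // producing-index block start per member
  int sigma;
};

struct SysDesc {
  int k;
  std::vector<int> p, r, u;
  std::vector<Pool> pools;
  // per cistrome: pools it belongs to, and its member slot in each
  std::vector<std::vector<int>> pool_of, slot_of;
  std::vector<uint64_t> name_hash;
};

static SysDesc parse_sys(const List& sys) {
  SysDesc d;
  IntegerVector p = sys["p"], r = sys["r"];
  CharacterVector nm = sys["names"];
  d.k = p.size();
  d.p.assign(p.begin(), p.end());
  d.r.assign(r.begin(), r.end());
  d.name_hash.resize(d.k);
  for (int i = 0; i < d.k; ++i) d.name_hash[i] = fnv1a64(CHAR(STRING_ELT(nm, 0 + i)));
  List pools = sys["pools"];
  d.pool_of.resize(d.k);
  d.slot_of.resize(d.k);
  std::vector<int> used(d.k, 0);  // producing indices consumed by pools so far
  for (int q = 0; q < pools.size(); ++q) {
    List pl = pools[q];
    IntegerVector mem = pl["members"];  // 0-based cistrome indices
    int sigma = as<int>(pl["sigma"]);
    Pool P;
    P.sigma = sigma;
    for (int j = 0; j < mem.size(); ++j) {
      P.members.push_back(mem[j]);
      d.pool_of[mem[j]].push_back(q);
      d.slot_of[mem[j]].push_back(j);
      used[mem[j]] += sigma;
    }
    d.pools.push_back(P);
  }
  d.u.resize(d.k);
  for (int i = 0; i < d.k; ++i) {
    d.u[i] = d.r[i] - used[i];
    if (d.u[i] < 0) stop("infeasible layout: shared counts exceed r");
  }
  // block starts: own-only first, then pool blocks in pool order
  std::vector<int> cursor(d.k);
  for (int i = 0; i < d.k; ++i) cursor[i] = d.u[i];
  for (size_t q = 0; q < d.pools.size(); ++q) {
    Pool& P = d.pools[q];
    P.block_start.resize(P.members.size());
    for (size_t j = 0; j < P.members.size(); ++j) {
      P.block_start[j] = cursor[P.members[j]];
      cursor[P.members[j]] += P.sigma;
    }
  }
  return d;
}

struct StepCounts {
  std::vector<long> emitted, own_hits, transferred, absorbed, collapsed;
  std::vector<std::vector<long>> trans_mat;  // [from][to]
  void init(int k) {
    emitted.assign(k, 0); own_hits.assign(k, 0); transferred.assign(k, 0);
    absorbed.assign(k, 0); collapsed.assign(k, 0);
    trans_mat.assign(k, std::vector<long>(k, 0));
  }
};

struct EngineState {
  std::vector<int> s;                        // active counts
  std::vector<std::vector<uint8_t>> mark;    // meanfield next-active / primary
  std::vector<std::vector<uint8_t>> sec;     // two_site secondary sites
};

// number of TF units emitted by cistrome i this step (integer m, with the
// fractional part realised as one extra unit per active segment w.p. frac)
static inline long n_emitted(int s, double m, Xoshiro256pp& rng) {
  long mf = (long)std::floor(m);
  double frac = m - (double)mf;
  long n = (long)s * mf;
  if (frac > 0) for (int j = 0; j < s; ++j) if (rng.unif() < frac) ++n;
  return n;
}

// one synchronous timestep; marks/sec are assumed zeroed and are left zeroed
static void do_step(const SysDesc& d, EngineState& st, const NumericVector& m,
                    int mode, std::vector<Xoshiro256pp>& rng, Xoshiro256pp& trng,
                    StepCounts* acc) {
  const int k = d.k;
  std::vector<long> N(k);
  for (int i = 0; i < k; ++i) N[i] = st.s[i] > 0 ? n_emitted(st.s[i], m[i], rng[i]) : 0;

  if (mode == 0) {  // meanfield
    for (int i = 0; i < k; ++i) {
      long own = 0, trans = 0, absd = 0, coll = 0;
      for (long n = 0; n < N[i]; ++n) {
        uint32_t j = rng[i].below((uint32_t)d.p[i]);
        if ((int)j < d.u[i]) {
          if (st.mark[i][j]) ++coll; else st.mark[i][j] = 1;
          ++own;
        } else if ((int)j < d.r[i]) {
          // locate the pool block containing j
          int off = (int)j - d.u[i];
          size_t b = 0;
          while (true) {
            int q = d.pool_of[i][b];
            if (off < d.pools[q].sigma) break;
            off -= d.pools[q].sigma; ++b;
          }
          const Pool& P = d.pools[d.pool_of[i][b]];
          int slot = d.slot_of[i][b];
          // partner: uniform among other members
          int nmem = (int)P.members.size();
          int pj;
          if (nmem == 2) pj = 1 - slot;
          else {
            int x = (int)trng.below((uint32_t)(nmem - 1));
            pj = (x >= slot) ? x + 1 : x;
          }
          int partner = P.members[pj];
          int cj = P.block_start[pj] + off;
          if (st.mark[partner][cj]) { if (acc) ++acc->collapsed[partner]; }
          else st.mark[partner][cj] = 1;
          ++trans;
          if (acc) ++acc->trans_mat[i][partner];
        } else {
          ++absd;
        }
      }
      if (acc) {
        acc->emitted[i] += N[i]; acc->own_hits[i] += own;
        acc->transferred[i] += trans; acc->absorbed[i] += absd;
        acc->collapsed[i] += coll;
      }
    }
    for (int i = 0; i < k; ++i) {
      int cnt = 0;
      for (int j = 0; j < d.r[i]; ++j) { cnt += st.mark[i][j]; st.mark[i][j] = 0; }
      st.s[i] = cnt;
    }
  } else {  // two_site
    // phase 1: own landings occupy primary sites
    for (int i = 0; i < k; ++i) {
      long own = 0, absd = 0, coll = 0;
      for (long n = 0; n < N[i]; ++n) {
        uint32_t j = rng[i].below((uint32_t)d.p[i]);
        if ((int)j < d.r[i]) {
          if (st.mark[i][j]) ++coll; else st.mark[i][j] = 1;
          ++own;
        } else ++absd;
      }
      if (acc) {
        acc->emitted[i] += N[i]; acc->own_hits[i] += own;
        acc->absorbed[i] += absd; acc->collapsed[i] += coll;
      }
    }
    // phase 2: occupied primaries on shared segments transfer one copy to a
    // free counterpart secondary; resolution order randomised per position
    for (size_t q = 0; q < d.pools.size(); ++q) {
      const Pool& P = d.pools[q];
      int nmem = (int)P.members.size();
      std::vector<int> order(nmem);
      for (int t = 0; t < P.sigma; ++t) {
        for (int j = 0; j < nmem; ++j) order[j] = j;
        if (nmem > 2)  // Fisher-Yates; trivial (and skipped) for 2 members
          for (int j = nmem - 1; j > 0; --j) {
            int x = (int)trng.below((uint32_t)(j + 1));
            std::swap(order[j], order[x]);
          }
        for (int oj = 0; oj < nmem; ++oj) {
          int j = order[oj];
          int i = P.members[j];
          if (!st.mark[i][P.block_start[j] + t]) continue;
          // candidate targets: other members with a free secondary
          int cand[8]; int nc = 0;
          for (int j2 = 0; j2 < nmem; ++j2) {
            if (j2 == j) continue;
            if (!st.sec[P.members[j2]][P.block_start[j2] + t]) cand[nc++] = j2;
          }
          if (nc == 0) continue;
          int pick = nc == 1 ? cand[0] : cand[(int)trng.below((uint32_t)nc)];
          int partner = P.members[pick];
          st.sec[partner][P.block_start[pick] + t] = 1;
          if (acc) { ++acc->transferred[i]; ++acc->trans_mat[i][partner]; }
        }
      }
    }
    for (int i = 0; i < k; ++i) {
      int cnt = 0;
      for (int j = 0; j < d.r[i]; ++j) {
        cnt += (st.mark[i][j] | st.sec[i][j]);
        st.mark[i][j] = 0; st.sec[i][j] = 0;
      }
      st.s[i] = cnt;
    }
  }
}

static void init_engine_state(const SysDesc& d, EngineState& st, const IntegerVector& s0) {
  st.s.assign(s0.begin(), s0.end());
  st.mark.resize(d.k);
  st.sec.resize(d.k);
  for (int i = 0; i < d.k; ++i) {
    st.mark[i].assign(d.r[i], 0);
    st.sec[i].assign(d.r[i], 0);
  }
}

static void seed_streams(const SysDesc& d, uint64_t master, uint64_t run,
                         std::vector<Xoshiro256pp>& rng, Xoshiro256pp& trng) {
  rng.resize(d.k);
  for (int i = 0; i < d.k; ++i) rng[i].seed(substream_seed(master, run, d.name_hash[i]));
  trng.seed(substream_seed(master, run, TRANSFER_TAG));
}

// [[Rcpp::export]]
List cpp_run(List sys, NumericVector m, IntegerVector s0, int T, int mode,
             double master_seed, double run_index, bool record_accounting,
             bool early_exit) {
  SysDesc d = parse_sys(sys);
  std::vector<Xoshiro256pp> rng;
  Xoshiro256pp trng;
  seed_streams(d, (uint64_t)master_seed, (uint64_t)run_index, rng, trng);

  EngineState st;
  init_engine_state(d, st, s0);

  IntegerMatrix smat(T + 1, d.k);
  for (int i = 0; i < d.k; ++i) smat(0, i) = st.s[i];

  StepCounts acc;
  IntegerMatrix em, oh, tr, ab, co;
  if (record_accounting) {
    em = IntegerMatrix(T, d.k); oh = IntegerMatrix(T, d.k);
    tr = IntegerMatrix(T, d.k); ab = IntegerMatrix(T, d.k);
    co = IntegerMatrix(T, d.k);
  }
  IntegerMatrix trans_total(d.k, d.k);

  for (int t = 0; t < T; ++t) {
    bool all0 = true;
    for (int i = 0; i < d.k; ++i) if (st.s[i] > 0) { all0 = false; break; }
    if (all0 && early_exit && !record_accounting) break;  // rows stay zero
    if (record_accounting) acc.init(d.k);
    do_step(d, st, m, mode, rng, trng, record_accounting ? &acc : nullptr);
    for (int i = 0; i < d.k; ++i) smat(t + 1, i) = st.s[i];
    if (record_accounting) {
      for (int i = 0; i < d.k; ++i) {
        em(t, i) = (int)acc.emitted[i]; oh(t, i) = (int)acc.own_hits[i];
        tr(t, i) = (int)acc.transferred[i]; ab(t, i) = (int)acc.absorbed[i];
        co(t, i) = (int)acc.collapsed[i];
        for (int j = 0; j < d.k; ++j) trans_total(i, j) += (int)acc.trans_mat[i][j];
      }
    }
  }

  List out = List::create(_["s"] = smat);
  if (record_accounting) {
    out["emitted"] = em; out["own_hits"] = oh; out["transferred"] = tr;
    out["absorbed"] = ab; out["collapsed"] = co; out["transfer_totals"] = trans_total;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ensemble(List sys, NumericVector m, IntegerVector s0, int T, int mode,
                  double master_seed, int n_runs, bool early_exit) {
  SysDesc d = parse_sys(sys);
  IntegerMatrix final_s(n_runs, d.k);
  IntegerMatrix first_active(n_runs, d.k);  // first t with s_t > 0, -1 if never
  std::vector<Xoshiro256pp> rng;
  Xoshiro256pp trng;
  for (int run = 1; run <= n_runs; ++run) {
    seed_streams(d, (uint64_t)master_seed, (uint64_t)run, rng, trng);
    EngineState st;
    init_engine_state(d, st, s0);
    std::vector<int> fa(d.k, -1);
    for (int i = 0; i < d.k; ++i) if (st.s[i] > 0) fa[i] = 0;
    for (int t = 0; t < T; ++t) {
      bool all0 = true;
      for (int i = 0; i < d.k; ++i) if (st.s[i] > 0) { all0 = false; break; }
      if (all0 && early_exit) break;
      do_step(d, st, m, mode, rng, trng, nullptr);
      for (int i = 0; i < d.k; ++i)
        if (fa[i] < 0 && st.s[i] > 0) fa[i] = t + 1;
    }
    for (int i = 0; i < d.k; ++i) {
      final_s(run - 1, i) = st.s[i];
      first_active(run - 1, i) = fa[i];
    }
    if (run % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["final_s"] = final_s, _["first_active"] = first_active);
}

// replicate a single step from a given active-count state (the step
// distribution depends on the state only through the counts)
// [[Rcpp::export]]
IntegerMatrix cpp_step_replicates(List sys, IntegerVector s_init, NumericVector m,
                                  int mode, int n_reps, double master_seed) {
  SysDesc d = parse_sys(sys);
  IntegerMatrix out(n_reps, d.k);
  std::vector<Xoshiro256pp> rng;
  Xoshiro256pp trng;
  for (int rep = 1; rep <= n_reps; ++rep) {
    seed_streams(d, (uint64_t)master_seed, (uint64_t)rep, rng, trng);
    EngineState st;
    init_engine_state(d, st, s_init);
    do_step(d, st, m, mode, rng, trng, nullptr);
    for (int i = 0; i < d.k; ++i) out(rep - 1, i) = st.s[i];
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
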