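// Discrete Petri-net execution engine.
//
// Semantics: a transition is enabled when every ordinary pre-place holds at
// least the arc weight in tokens and every read-arc place holds at least one
// token.  Firing subtracts/adds ordinary arc weights; read-arc places are
// untouched.  A source transition (no ordinary pre-places, no read arcs in)
// fires at most once per run.  The deterministic policy repeatedly fires the
// first enabled transition in the caller-supplied priority order; the random
// policy picks uniformly among enabled transitions with its own seeded
// generator so results are reproducible across platforms.
#include <Rcpp.h>
#include <map>
#include <set>
#include <vector>
using namespace Rcpp;

namespace {

struct CompiledNet {
  int nP, nT;
  // CSR over transitions, in firing-priority order
  std::vector<int> prePtr, preP, preW;
  std::vector<char> preRead;
  std::vector<int> postPtr, postP, postW;
  // transitions whose enabledness depends on each place
  std::vector<int> consPtr, consT;
  std::vector<char> isSource;
  // derived, for batched deterministic firing
  std::vector<std::vector<std::pair<int, long long> > > deltas;  // net/firing
  std::vector<std::vector<int> > earlier;  // earlier trans fed by t's posts
};

void derive_batching(CompiledNet& net) {
  std::vector<long long> delta(net.nP, 0);
  net.deltas.resize(net.nT);
  net.earlier.resize(net.nT);
  for (int t = 0; t < net.nT; ++t) {
    for (int a = net.prePtr[t]; a < net.prePtr[t + 1]; ++a)
      if (!net.preRead[a]) delta[net.preP[a]] -= net.preW[a];
    for (int a = net.postPtr[t]; a < net.postPtr[t + 1]; ++a)
      delta[net.postP[a]] += net.postW[a];
    std::set<int> ear;
    for (int a = net.postPtr[t]; a < net.postPtr[t + 1]; ++a) {
      int q = net.postP[a];
      if (delta[q] <= 0) continue;
      for (int c = net.consPtr[q]; c < net.consPtr[q + 1]; ++c)
        if (net.consT[c] < t) ear.insert(net.consT[c]);
    }
    net.earlier[t].assign(ear.begin(), ear.end());
    for (int a = net.prePtr[t]; a < net.prePtr[t + 1]; ++a) {
      int q = net.preP[a];
      if (delta[q] != 0)
        net.deltas[t].push_back(std::make_pair(q, delta[q]));
      delta[q] = 0;
    }
    for (int a = net.postPtr[t]; a < net.postPtr[t + 1]; ++a) {
      int q = net.postP[a];
      if (delta[q] != 0)
        net.deltas[t].push_back(std::make_pair(q, delta[q]));
      delta[q] = 0;
    }
  }
}

CompiledNet unpack(const List& cn) {
  CompiledNet net;
  net.nP = as<int>(cn["n_places"]);
  net.nT = as<int>(cn["n_trans"]);
  IntegerVector prePtr = cn["pre_ptr"], preP = cn["pre_place"],
                preW = cn["pre_w"], preRead = cn["pre_read"],
                postPtr = cn["post_ptr"], postP = cn["post_place"],
                postW = cn["post_w"], consPtr = cn["cons_ptr"],
                consT = cn["cons_trans"], isSrc = cn["is_source"];
  net.prePtr.assign(prePtr.begin(), prePtr.end());
  net.preP.assign(preP.begin(), preP.end());
  net.preW.assign(preW.begin(), preW.end());
  net.preRead.assign(preRead.begin(), preRead.end());
  net.postPtr.assign(postPtr.begin(), postPtr.end());
  net.postP.assign(postP.begin(), postP.end());
  net.postW.assign(postW.begin(), postW.end());
  net.consPtr.assign(consPtr.begin(), consPtr.end());
  net.consT.assign(consT.begin(), consT.end());
  net.isSource.resize(net.nT);
  for (int t = 0; t < net.nT; ++t) net.isSource[t] = (char)isSrc[t];
  derive_batching(net);
  return net;
}

// splitmix64: small, seedable, platform-independent
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  size_t below(size_t n) { return (size_t)(next() % (uint64_t)n); }
};

const long long INF = (long long)1 << 60;

// Token-margin tracker for exact period fast-forwarding.  While verifying a
// candidate firing period, every marking-dependent decision records how many
// tokens each involved place could gain (grow) or lose (shrink) without the
// decision's outcome changing.  A later shift of the whole marking by
// j * (period delta) then provably replays the period verbatim as long as
// j * |delta_q| stays within both margins of every place q.
struct Tracker {
  bool active;
  std::vector<long long> grow, shrink;
  explicit Tracker(int nP) : active(false), grow(nP, INF), shrink(nP, INF) {}
  void reset() {
    std::fill(grow.begin(), grow.end(), INF);
    std::fill(shrink.begin(), shrink.end(), INF);
  }
  inline void cmp_true(int q, long long slack) {   // v >= w held
    if (slack < shrink[q]) shrink[q] = slack;
  }
  inline void cmp_false(int q, long long slack) {  // v < w held
    if (slack < grow[q]) grow[q] = slack;
  }
  // value v sits in a floor bucket [lo_v, hi_v]; keep it there
  inline void bucket(int q, long long v, long long lo_v, long long hi_v) {
    if (hi_v - v < grow[q]) grow[q] = hi_v - v;
    if (v - lo_v < shrink[q]) shrink[q] = v - lo_v;
  }
};

inline bool is_enabled_t(const CompiledNet& net, const std::vector<long long>& m,
                         const std::vector<char>& dead, int t, Tracker* trk) {
  if (dead[t]) return false;
  if (trk && trk->active) {
    for (int k = net.prePtr[t]; k < net.prePtr[t + 1]; ++k) {
      int q = net.preP[k];
      long long need = net.preW[k];
      if (m[q] < need) { trk->cmp_false(q, need - 1 - m[q]); return false; }
      trk->cmp_true(q, m[q] - need);
    }
    return true;
  }
  for (int k = net.prePtr[t]; k < net.prePtr[t + 1]; ++k)
    if (m[net.preP[k]] < (long long)net.preW[k]) return false;
  return true;
}

// Largest number of consecutive firings of t that is equivalent to the
// step-by-step deterministic schedule: bounded by t's own token capacity and
// by the first firing count at which any earlier-priority transition in
// `earlier` becomes enabled (they are all disabled when t is chosen).
// Per-firing net change of place q is +post_w - pre_w over t's arcs.
long long batch_size(const CompiledNet& net, const std::vector<long long>& m,
                     const std::vector<long long>& delta,
                     const std::vector<char>& dead, int t,
                     const std::vector<int>& earlier, Tracker* trk) {
  bool tr = trk && trk->active;
  long long k = INF;
  for (int a = net.prePtr[t]; a < net.prePtr[t + 1]; ++a) {
    if (net.preRead[a]) continue;
    int q = net.preP[a];
    long long need = net.preW[a], d = delta[q];
    if (d >= 0) continue;  // never drops below its own requirement
    // max k with m[q] + (k-1)*d >= need  (t is enabled, so m[q] >= need)
    long long e = -d;
    long long cap = (m[q] - need) / e + 1;
    if (tr) trk->bucket(q, m[q], need + (cap - 1) * e, need + cap * e - 1);
    if (cap < k) k = cap;
  }
  for (size_t i = 0; i < earlier.size(); ++i) {
    int tp = earlier[i];
    if (dead[tp]) continue;
    // after j firings of t, place q holds m[q] + j*delta[q]; tp's enabling
    // window per pre-place is [lo, hi] in j; tp first enabled at max(lo)
    // provided that is <= min(hi)
    long long lo = 1, hi = INF;
    for (int a = net.prePtr[tp]; a < net.prePtr[tp + 1]; ++a) {
      int q = net.preP[a];
      long long need = net.preW[a], d = delta[q];
      if (m[q] >= need) {
        if (tr) trk->cmp_true(q, m[q] - need);
        if (d >= 0) continue;            // satisfied forever
        long long e = -d;
        long long jmax = (m[q] - need) / e;  // satisfied while j <= jmax
        if (tr) trk->bucket(q, m[q], need + jmax * e, need + (jmax + 1) * e - 1);
        if (jmax < hi) hi = jmax;
      } else {
        if (tr) trk->cmp_false(q, need - 1 - m[q]);
        if (d <= 0) { lo = INF; break; }  // never satisfied
        long long jq = (need - m[q] + d - 1) / d;
        if (tr) trk->bucket(q, m[q], need - jq * d, need - (jq - 1) * d - 1);
        if (jq > lo) lo = jq;
      }
    }
    if (lo <= hi && lo < k) k = lo;
  }
  return k < 1 ? 1 : k;
}

// returns termination reason: 0 target fired, 1 quiescent, 2 step budget
int run_core(const CompiledNet& net, std::vector<long long>& m, int target,
             int max_steps, bool deterministic, uint64_t seed, bool record,
             std::vector<int>* fired, int* steps_out, int* iters_out = 0,
             bool accel = true) {
  std::vector<char> dead(net.nT, 0);
  // enabled set as a bitmask; first enabled found via count-trailing-zeros
  int nWords = (net.nT + 63) / 64;
  std::vector<uint64_t> en(nWords, 0);
  int nEnabled = 0;
  for (int t = 0; t < net.nT; ++t)
    if (is_enabled_t(net, m, dead, t, 0)) {
      en[t >> 6] |= (uint64_t)1 << (t & 63);
      ++nEnabled;
    }
  Rng rng(seed);
  int steps = 0, reason = 1, iters = 0;
  std::vector<int> touched;
  std::vector<long long> dvec(net.nP, 0);
  // period fast-forward machinery (deterministic schedule only): when the
  // last P (transition, batch) pairs repeat the P before them, one further
  // period is verified under margin tracking, then whole periods are skipped
  const int MAXP = 32, RING = 1024, WINDOW = 896, MAXP_LONG = 400;
  std::vector<int> ringT(RING, -1);
  std::vector<long long> ringK(RING, -1);
  std::vector<long long> lastSeen(net.nT, -1);
  std::vector<int> pf(WINDOW);  // prefix-function scratch
  Tracker trk(net.nP);
  bool verifying = false;
  int P = 0, vpos = 0;
  std::vector<int> tmplT;
  std::vector<long long> tmplK;
  long long cooldownUntil = 0;
  while (nEnabled > 0) {
    if (steps >= max_steps) { reason = 2; break; }
    ++iters;
    int t = -1;
    long long k = 1;
    if (deterministic) {
      for (int w = 0; w < nWords; ++w)
        if (en[w]) { t = (w << 6) + __builtin_ctzll(en[w]); break; }
      if (t != target && !net.isSource[t]) {
        for (size_t i = 0; i < net.deltas[t].size(); ++i)
          dvec[net.deltas[t][i].first] = net.deltas[t][i].second;
        k = batch_size(net, m, dvec, dead, t, net.earlier[t], &trk);
        for (size_t i = 0; i < net.deltas[t].size(); ++i)
          dvec[net.deltas[t][i].first] = 0;
        long long left = max_steps - steps;
        if (k > left) k = left;
      }
    } else {
      size_t idx = rng.below((size_t)nEnabled);
      for (int w = 0; w < nWords && t < 0; ++w) {
        uint64_t bits = en[w];
        while (bits) {
          if (idx == 0) { t = (w << 6) + __builtin_ctzll(bits); break; }
          bits &= bits - 1;
          --idx;
        }
      }
    }
    touched.clear();
    for (int a = net.prePtr[t]; a < net.prePtr[t + 1]; ++a) {
      if (!net.preRead[a]) {
        m[net.preP[a]] -= k * net.preW[a];
        touched.push_back(net.preP[a]);
      }
    }
    for (int a = net.postPtr[t]; a < net.postPtr[t + 1]; ++a) {
      m[net.postP[a]] += k * net.postW[a];
      touched.push_back(net.postP[a]);
    }
    steps += (int)k;
    if (record)
      for (long long r = 0; r < k; ++r) fired->push_back(t);
    if (t == target) { reason = 0; break; }
    uint64_t bit = (uint64_t)1 << (t & 63);
    if (net.isSource[t]) {
      dead[t] = 1;
      if (en[t >> 6] & bit) { en[t >> 6] &= ~bit; --nEnabled; }
    }
    for (size_t i = 0; i < touched.size(); ++i) {
      int p = touched[i];
      for (int a = net.consPtr[p]; a < net.consPtr[p + 1]; ++a) {
        int c = net.consT[a];
        uint64_t cb = (uint64_t)1 << (c & 63);
        bool now = is_enabled_t(net, m, dead, c, &trk);
        bool was = (en[c >> 6] & cb) != 0;
        if (now != was) {
          en[c >> 6] ^= cb;
          nEnabled += now ? 1 : -1;
        }
      }
    }
    // a source transition has no ordinary pre-places: its own enabledness
    // only changes through `dead`, handled above; ordinary transitions are
    // consumers of their pre-places, so they were rechecked with `touched`
    if (net.prePtr[t] == net.prePtr[t + 1] && !net.isSource[t]) {
      // read-arc-only transition: still enabled unless its read places drained
      if (!is_enabled_t(net, m, dead, t, &trk) && (en[t >> 6] & bit)) {
        en[t >> 6] &= ~bit; --nEnabled;
      }
    }
    if (!accel || !deterministic) continue;
    // ---- period detection / verification ----
    long long it = iters - 1;  // 0-based index of the iteration just done
    if (verifying) {
      if (tmplT[vpos] != t || tmplK[vpos] != k) {
        verifying = false;
        trk.active = false;
        cooldownUntil = it + P;
      } else if (++vpos == P) {
        verifying = false;
        trk.active = false;
        // period delta is determined by the (t, k) template
        std::vector<std::pair<int, long long> > D;
        {
          std::map<int, long long> acc;
          for (int i2 = 0; i2 < P; ++i2)
            for (size_t a2 = 0; a2 < net.deltas[tmplT[i2]].size(); ++a2)
              acc[net.deltas[tmplT[i2]][a2].first] +=
                tmplK[i2] * net.deltas[tmplT[i2]][a2].second;
          for (std::map<int, long long>::iterator itr = acc.begin();
               itr != acc.end(); ++itr)
            if (itr->second != 0) D.push_back(*itr);
        }
        long long spp = 0;
        for (int i2 = 0; i2 < P; ++i2) spp += tmplK[i2];
        long long jmax = (max_steps - steps) / spp - 1;
        for (size_t i2 = 0; i2 < D.size() && jmax > 0; ++i2) {
          int q = D[i2].first;
          long long dq = D[i2].second;
          long long lim = dq > 0 ? trk.grow[q] / dq : trk.shrink[q] / (-dq);
          if (lim < jmax) jmax = lim;
        }
        if (jmax > 0) {
          for (size_t i2 = 0; i2 < D.size(); ++i2)
            m[D[i2].first] += jmax * D[i2].second;
          steps += (int)(jmax * spp);
          if (record)
            for (long long r = 0; r < jmax; ++r)
              for (int i2 = 0; i2 < P; ++i2)
                for (long long r2 = 0; r2 < tmplK[i2]; ++r2)
                  fired->push_back(tmplT[i2]);
          cooldownUntil = it + 1;
        } else {
          cooldownUntil = it + 4LL * P;
        }
      }
    } else {
      long long prev = lastSeen[t];
      int cand = -1;
      if (it >= cooldownUntil) {
        if (prev >= 0 && it - prev <= MAXP) {
          cand = (int)(it - prev);
        } else if (it >= WINDOW && (it & 255) == 0) {
          // longer periods (residue rotations): smallest period of the last
          // WINDOW (t, k) entries via the KMP prefix function
          int L = WINDOW;
          long long base = it - WINDOW;
          pf[0] = 0;
          for (int j = 1; j < L; ++j) {
            int kk = pf[j - 1];
            int ij = (int)((base + j) & (RING - 1));
            for (;;) {
              int ik = (int)((base + kk) & (RING - 1));
              if (ringT[ij] == ringT[ik] && ringK[ij] == ringK[ik]) {
                ++kk;
                break;
              }
              if (kk == 0) break;
              kk = pf[kk - 1];
            }
            pf[j] = kk;
          }
          int p = L - pf[L - 1];
          if (p >= 1 && p <= MAXP_LONG && 2 * p <= L) cand = p;
        }
      }
      if (cand >= 1) {
        // the ring holds iterations < it; compare iterations
        // (it-cand+1 .. it) against (it-2cand+1 .. it-cand), the current
        // iteration (t, k) standing in for index `it`
        if (it + 1 >= 2LL * cand) {
          bool match = (ringT[(int)((it - cand) & (RING - 1))] == t &&
                        ringK[(int)((it - cand) & (RING - 1))] == k);
          for (int off = 1; off < cand && match; ++off) {
            int i1 = (int)((it - off) & (RING - 1));
            int i0 = (int)((it - off - cand) & (RING - 1));
            if (ringT[i1] != ringT[i0] || ringK[i1] != ringK[i0])
              match = false;
          }
          if (match) {
            verifying = true;
            P = cand;
            vpos = 0;
            tmplT.resize(P);
            tmplK.resize(P);
            for (int off = 0; off < P - 1; ++off) {
              int src = (int)((it - P + 1 + off) & (RING - 1));
              tmplT[off] = ringT[src];
              tmplK[off] = ringK[src];
            }
            tmplT[P - 1] = t;
            tmplK[P - 1] = k;
            trk.reset();
            trk.active = true;
          }
        }
      }
    }
    lastSeen[t] = it;
    ringT[(int)(it & (RING - 1))] = t;
    ringK[(int)(it & (RING - 1))] = k;
  }
  *steps_out = steps;
  if (iters_out) *iters_out = iters;
  return reason;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(List compiled, IntegerVector m0, int target, int max_steps,
             bool deterministic, double seed, bool record,
             bool accel = false) {
  CompiledNet net = unpack(compiled);
  std::vector<long long> m(m0.begin(), m0.end());
  std::vector<int> fired;
  int steps = 0;
  int iters = 0;
  int reason = run_core(net, m, target, max_steps, deterministic,
                        (uint64_t)seed, record, &fired, &steps, &iters,
                        accel);
  IntegerVector mf(net.nP);
  for (int p = 0; p < net.nP; ++p) {
    if (m[p] > INT_MAX) stop("token count overflow in place index %d", p + 1);
    mf[p] = (int)m[p];
  }
  IntegerVector fv(fired.size());
  for (size_t i = 0; i < fired.size(); ++i) fv[i] = fired[i] + 1;  // 1-based
  return List::create(_["final"] = mf, _["fired"] = fv,
                      _["reason"] = reason, _["steps"] = steps,
                      _["iters"] = iters);
}

// Sweep a concentration grid: every (psi value, group level) cell gets a
// fresh copy of the base marking with psi places set to the psi value and
// each group's places set to that group's per-level value.
// [[Rcpp::export]]
List cpp_sweep(List compiled, IntegerVector base, IntegerVector psi_idx,
               IntegerVector psi_values, IntegerVector ga_idx,
               IntegerVector ga_values, IntegerVector gb_idx,
               IntegerVector gb_values, int target, int max_steps,
               bool accel = false) {
  CompiledNet net = unpack(compiled);
  int nPsi = psi_values.size(), nG = ga_values.size();
  if (gb_idx.size() > 0 && gb_values.size() != nG)
    stop("group value vectors must have equal length");
  LogicalMatrix hit(nPsi, nG);
  LogicalMatrix budget(nPsi, nG);
  std::vector<long long> m(net.nP);
  std::vector<int> fired;
  for (int j = 0; j < nG; ++j) {
    for (int i = 0; i < nPsi; ++i) {
      for (int p = 0; p < net.nP; ++p) m[p] = base[p];
      for (int k = 0; k < psi_idx.size(); ++k)
        m[psi_idx[k] - 1] = psi_values[i];
      for (int k = 0; k < ga_idx.size(); ++k)
        m[ga_idx[k] - 1] = ga_values[j];
      for (int k = 0; k < gb_idx.size(); ++k)
        m[gb_idx[k] - 1] = gb_values[j];
      int steps = 0;
      int iters = 0;
      int reason = run_core(net, m, target, max_steps, true, 0, false,
                            &fired, &steps, &iters, accel);
      hit(i, j) = (reason == 0);
      budget(i, j) = (reason == 2);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["fired"] = hit, _["budget"] = budget);
}
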