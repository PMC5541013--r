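// Monte Carlo engine for the two-layer voter model with ageing.
//
// One MCS: both layers are swept (random layer order); endogenous layers
// activate each node with probability b_l / tau_i, RAU layers perform N
// random node picks with forced adoption.  Persistence clocks are shared
// between the two copies of a common node and advance by one per MCS for
// every logical node that did not flip during that MCS.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding; one independent stream per
// realization so ensemble results do not depend on execution order.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed + stream * 0xd1b54a32d192ed03ULL;
    for (int k = 0; k < 4; ++k) s[k] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // unbiased bounded integer in [0, n)
  inline int below(int n) {
    unsigned __int128 m =
        (unsigned __int128)next() * (unsigned __int128)(uint64_t)n;
    return (int)(uint64_t)(m >> 64);
  }
};

struct Layer {
  bool complete;
  const int *off;   // CSR offsets, length n+1 (unused if complete)
  const int *adj;   // CSR neighbours (unused if complete)
  const int *partner;  // index in the other layer, -1 if not common
  int rule;         // 0 = endogenous, 1 = RAU
  double b;
  std::vector<int> spins;      // +1 / -1
  std::vector<double> tau;
  std::vector<unsigned char> flipped;  // flipped during current MCS
  int n_plus;
  double n_edges;
};

}  // namespace

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(int n,
                    bool complete1, IntegerVector off1, IntegerVector adj1,
                    bool complete2, IntegerVector off2, IntegerVector adj2,
                    IntegerVector partner1, IntegerVector partner2,
                    int rule1, int rule2, double b1, double b2,
                    IntegerVector spins1_in, IntegerVector spins2_in,
                    NumericVector tau1_in, NumericVector tau2_in,
                    int t0, int t_max, IntegerVector sample_times,
                    bool record_flips, double seed, double stream) {
  Layer lay[2];
  lay[0].complete = complete1;
  lay[0].off = complete1 ? nullptr : INTEGER(off1);
  lay[0].adj = complete1 ? nullptr : INTEGER(adj1);
  lay[0].partner = INTEGER(partner1);
  lay[0].rule = rule1;
  lay[0].b = b1;
  lay[1].complete = complete2;
  lay[1].off = complete2 ? nullptr : INTEGER(off2);
  lay[1].adj = complete2 ? nullptr : INTEGER(adj2);
  lay[1].partner = INTEGER(partner2);
  lay[1].rule = rule2;
  lay[1].b = b2;

  for (int L = 0; L < 2; ++L) {
    const IntegerVector &sp = (L == 0) ? spins1_in : spins2_in;
    const NumericVector &tv = (L == 0) ? tau1_in : tau2_in;
    lay[L].spins.assign(sp.begin(), sp.end());
    lay[L].tau.assign(tv.begin(), tv.end());
    lay[L].flipped.assign(n, 0);
    int np = 0;
    for (int i = 0; i < n; ++i)
      if (lay[L].spins[i] > 0) ++np;
    lay[L].n_plus = np;
    if (lay[L].complete) {
      lay[L].n_edges = (double)n * (n - 1) / 2.0;
    } else {
      const IntegerVector &a = (L == 0) ? adj1 : adj2;
      lay[L].n_edges = a.size() / 2.0;
    }
  }

  Xoshiro rng((uint64_t)seed, (uint64_t)stream);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  int n_common = 0;
  for (int i = 0; i < n; ++i)
    if (lay[0].partner[i] >= 0) ++n_common;

  const int n_samples = sample_times.size();
  NumericVector out_rho1(n_samples), out_rho2(n_samples);
  NumericVector out_m1(n_samples), out_m2(n_samples);
  NumericVector out_tb1(n_samples), out_tb2(n_samples);
  std::vector<int> flip_node, flip_time;
  std::vector<int> last_flip(2 * n, -1);
  long clamped = 0;

  auto rho_of = [&](int L) -> double {
    Layer &ly = lay[L];
    if (ly.complete) {
      double np = ly.n_plus, nm = n - ly.n_plus;
      return 2.0 * np * nm / ((double)n * (n - 1));
    }
    long active = 0;
    for (int i = 0; i < n; ++i)
      for (int k = ly.off[i]; k < ly.off[i + 1]; ++k) {
        int j = ly.adj[k];
        if (j > i && ly.spins[i] != ly.spins[j]) ++active;
      }
    return active / ly.n_edges;
  };
  auto taubar_of = [&](int L) -> double {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += lay[L].tau[i];
    return s / n;
  };
  auto record = [&](int idx) {
    out_rho1[idx] = rho_of(0);
    out_rho2[idx] = rho_of(1);
    out_m1[idx] = (2.0 * lay[0].n_plus - n) / n;
    out_m2[idx] = (2.0 * lay[1].n_plus - n) / n;
    out_tb1[idx] = taubar_of(0);
    out_tb2[idx] = taubar_of(1);
  };

  auto neighbour = [&](int L, int i) -> int {
    Layer &ly = lay[L];
    if (ly.complete) {
      int j = rng.below(n - 1);
      if (j >= i) ++j;
      return j;
    }
    int deg = ly.off[i + 1] - ly.off[i];
    if (deg == 0) return -1;
    return ly.adj[ly.off[i] + rng.below(deg)];
  };

  int t = t0;
  auto flip = [&](int L, int i, int new_spin, double reset) {
    Layer &ly = lay[L];
    ly.spins[i] = new_spin;
    ly.n_plus += (new_spin > 0) ? 1 : -1;
    ly.tau[i] = reset;
    ly.flipped[i] = 1;
    int pa = ly.partner[i];
    if (pa >= 0) {
      Layer &other = lay[1 - L];
      if (other.spins[pa] != new_spin) {
        other.spins[pa] = new_spin;
        other.n_plus += (new_spin > 0) ? 1 : -1;
      }
      other.tau[pa] = reset;
      other.flipped[pa] = 1;
    }
    if (record_flips) {
      // logical node id: layer-1 index for layer-1 and common nodes,
      // n + layer-2 index for nodes private to layer 2
      int id = (L == 0) ? i : (lay[1].partner[i] >= 0 ? lay[1].partner[i]
                                                      : n + i);
      int ft = t + 1;  // flips happen during the MCS ending at t+1
      if (last_flip[id] != ft) {
        flip_node.push_back(id);
        flip_time.push_back(ft);
        last_flip[id] = ft;
      }
    }
  };

  int sample_idx = 0;
  // record any sample times at or before the initial time
  while (sample_idx < n_samples && sample_times[sample_idx] <= t) {
    record(sample_idx);
    ++sample_idx;
  }

  int stop_reason = 0;  // 0 = t_max, 1 = consensus, 2 = frozen
  int t_stop = t_max;

  while (t < t_max) {
    int first = (rng.unif() < 0.5) ? 0 : 1;
    for (int k = 0; k < 2; ++k) {
      int L = (k == 0) ? first : 1 - first;
      Layer &ly = lay[L];
      if (ly.n_plus == 0 || ly.n_plus == n) continue;  // uniform: no-op
      if (ly.rule == 0) {
        // endogenous sweep in a fresh random permutation
        for (int i = n - 1; i > 0; --i) {
          int j = rng.below(i + 1);
          std::swap(perm[i], perm[j]);
        }
        for (int idx = 0; idx < n; ++idx) {
          int i = perm[idx];
          double p = ly.b / ly.tau[i];
          if (p > 1.0) {
            p = 1.0;
            ++clamped;
          }
          if (rng.unif() < p) {
            int j = neighbour(L, i);
            if (j >= 0 && ly.spins[j] != ly.spins[i])
              flip(L, i, ly.spins[j], 1.0 + ly.b);
          }
        }
      } else {
        // RAU: n basic steps, forced adoption
        for (int step = 0; step < n; ++step) {
          int i = rng.below(n);
          int j = neighbour(L, i);
          if (j >= 0 && ly.spins[j] != ly.spins[i])
            flip(L, i, ly.spins[j], 1.0 + ly.b);
        }
      }
    }
    // age every logical node that did not flip in this MCS
    for (int L = 0; L < 2; ++L) {
      Layer &ly = lay[L];
      for (int i = 0; i < n; ++i)
        if (!ly.flipped[i])
          ly.tau[i] += 1.0;
        else
          ly.flipped[i] = 0;
    }
    ++t;
    while (sample_idx < n_samples && sample_times[sample_idx] == t) {
      record(sample_idx);
      ++sample_idx;
    }
    bool u1 = (lay[0].n_plus == 0 || lay[0].n_plus == n);
    bool u2 = (lay[1].n_plus == 0 || lay[1].n_plus == n);
    if (u1 && u2) {
      bool same = (lay[0].n_plus == 0) == (lay[1].n_plus == 0);
      if (same) {
        stop_reason = 1;
        t_stop = t;
        break;
      }
      if (n_common == 0) {
        stop_reason = 2;
        t_stop = t;
        break;
      }
    }
  }
  if (stop_reason == 0) t_stop = t;

  // fill samples past an early stop: rho stays 0 (each layer uniform),
  // magnetization stays put, every node ages by one per MCS
  if (sample_idx < n_samples) {
    double m1 = (2.0 * lay[0].n_plus - n) / n;
    double m2 = (2.0 * lay[1].n_plus - n) / n;
    double tb1 = taubar_of(0), tb2 = taubar_of(1);
    for (; sample_idx < n_samples; ++sample_idx) {
      double dt = sample_times[sample_idx] - t_stop;
      out_rho1[sample_idx] = 0.0;
      out_rho2[sample_idx] = 0.0;
      out_m1[sample_idx] = m1;
      out_m2[sample_idx] = m2;
      out_tb1[sample_idx] = tb1 + dt;
      out_tb2[sample_idx] = tb2 + dt;
    }
  }

  return List::create(
      _["times"] = sample_times, _["rho1"] = out_rho1, _["rho2"] = out_rho2,
      _["m1"] = out_m1, _["m2"] = out_m2, _["taubar1"] = out_tb1,
      _["taubar2"] = out_tb2,
      _["spins1"] = IntegerVector(lay[0].spins.begin(), lay[0].spins.end()),
      _["spins2"] = IntegerVector(lay[1].spins.begin(), lay[1].spins.end()),
      _["tau1"] = NumericVector(lay[0].tau.begin(), lay[0].tau.end()),
      _["tau2"] = NumericVector(lay[1].tau.begin(), lay[1].tau.end()),
      _["t_final"] = t_stop, _["stop_reason"] = stop_reason,
      _["flip_node"] = IntegerVector(flip_node.begin(), flip_node.end()),
      _["flip_time"] = IntegerVector(flip_time.begin(), flip_time.end()),
      _["n_clamped"] = (double)clamped);
}
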