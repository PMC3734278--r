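// Exact event-driven (Gillespie) simulation of the SIS models with bulk
// treatment pulses.  Two schedules: "poisson" treats the pulse as an ordinary
// constant-propensity channel; "periodic" fires pulses deterministically at
// times k/nu, with the demographic clock capped at the next pulse (exact for
// exponential waiting times).
//
// RNG contract: xoshiro256++ streams, one per realization.  Stream i of a
// master seed m is seeded by running splitmix64 from state (m * GOLDEN + i).
// All uniform/exponential transforms are written out explicitly so that
// trajectories are bit-reproducible across platforms and compilers.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <deque>
#include <vector>

using namespace Rcpp;

namespace {

const uint64_t GOLDEN = 0x9E3779B97F4A7C15ULL;

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += GOLDEN);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
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
  // uniform on (0, 1]
  inline double runif_oc() {
    return (double)((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
  // uniform on [0, 1)
  inline double runif_co() {
    return (double)(next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double rexp(double rate) { return -std::log(runif_oc()) / rate; }
};

static inline uint64_t stream_seed(uint64_t master, uint64_t i) {
  return master * GOLDEN + i;
}

// number of infecteds removed by one pulse
static inline int pulse_removed(double kappa, int I, int rounding) {
  if (kappa <= 0.0 || I <= 0) return 0;
  double x = kappa * (double)I;
  int k = (rounding == 0) ? (int)std::floor(x + 1e-9) : (int)std::ceil(x - 1e-9);
  if (k < 0) k = 0;
  if (k > I) k = I;
  return k;
}

struct SimResult {
  double time;
  bool extinct;
  long long n_events;
};

// One realization.  model: 1 constrained, 2 full.  schedule: 0 poisson,
// 1 periodic.  rounding: 0 floor, 1 ceil.  If rec != nullptr, (t, S, I) after
// every event is appended (S = N - I for model 1 bookkeeping convenience).
static SimResult simulate_one(int model, double beta, double gamma, double mu,
                              int N, double kappa, double nu, int schedule,
                              int rounding, int S0, int I0, double t_max,
                              Xoshiro &rng,
                              std::vector<double> *rec_t,
                              std::vector<int> *rec_S,
                              std::vector<int> *rec_I,
                              std::vector<double> *rec_pulse,
                              long long max_events) {
  double t = 0.0;
  int S = S0, I = I0;
  long long ev = 0;
  const bool treat = (kappa > 0.0 && nu > 0.0);
  const bool periodic = (schedule == 1);
  double next_pulse = (treat && periodic) ? 1.0 / nu : R_PosInf;
  int k_pulse = 1;

  if (rec_t) { rec_t->push_back(0.0); rec_S->push_back(S); rec_I->push_back(I); }

  while (I > 0) {
    double a[6];
    int nch = 0;
    if (model == 1) {
      a[0] = beta * (double)I * (double)(N - I) / (double)N;  // infection +1
      a[1] = (gamma + mu) * (double)I;                        // recovery/death -1
      nch = 2;
    } else {
      a[0] = mu * (double)N;                                  // birth S+1
      a[1] = mu * (double)S;                                  // death S-1
      a[2] = mu * (double)I;                                  // death I-1
      a[3] = beta * (double)S * (double)I / (double)N;        // infection
      a[4] = gamma * (double)I;                               // recovery
      nch = 5;
    }
    if (treat && !periodic) { a[nch] = nu; nch += 1; }        // poisson pulses
    double total = 0.0;
    for (int c = 0; c < nch; ++c) total += a[c];

    double dt = (total > 0.0) ? rng.rexp(total) : R_PosInf;
    double t_next = t + dt;

    if (periodic && treat && next_pulse <= t_next && next_pulse <= t_max) {
      // pulse fires first (exponential clock is memoryless: discard the draw)
      t = next_pulse;
      int k = pulse_removed(kappa, I, rounding);
      I -= k;
      if (model == 2) S += k; else S = N - I;
      if (rec_pulse) rec_pulse->push_back(t);
      if (rec_t) { rec_t->push_back(t); rec_S->push_back(S); rec_I->push_back(I); }
      next_pulse = (double)(++k_pulse) / nu;
      if (++ev >= max_events) return {t, I == 0, ev};
      continue;
    }
    if (t_next > t_max)
      return {t_max, false, ev};  // censored
    t = t_next;

    double u = rng.runif_co() * total;
    int c = 0;
    double acc = a[0];
    while (u >= acc && c < nch - 1) { acc += a[++c]; }

    if (model == 1) {
      if (c == 0) I += 1;
      else if (c == 1) I -= 1;
      else {  // poisson pulse
        I -= pulse_removed(kappa, I, rounding);
        if (rec_pulse) rec_pulse->push_back(t);
      }
      S = N - I;
    } else {
      switch (c) {
        case 0: S += 1; break;
        case 1: S -= 1; break;
        case 2: I -= 1; break;
        case 3: S -= 1; I += 1; break;
        case 4: S += 1; I -= 1; break;
        default: {
          int k = pulse_removed(kappa, I, rounding);
          S += k; I -= k;
          if (rec_pulse) rec_pulse->push_back(t);
        }
      }
    }
    if (rec_t) { rec_t->push_back(t); rec_S->push_back(S); rec_I->push_back(I); }
    if (++ev >= max_events) return {t, I == 0, ev};
  }
  return {t, true, ev};
}

}  // namespace

// [[Rcpp::export]]
List ssa_run_cpp(int model, double beta, double gamma, double mu, int N,
                 double kappa, double nu, int schedule, int rounding,
                 int S0, int I0, double t_max, double seed, bool record,
                 double max_events) {
  Xoshiro rng(stream_seed((uint64_t)seed, 1));
  std::vector<double> rt, rp;
  std::vector<int> rS, rI;
  SimResult res = simulate_one(model, beta, gamma, mu, N, kappa, nu, schedule,
                               rounding, S0, I0, t_max, rng,
                               record ? &rt : nullptr, record ? &rS : nullptr,
                               record ? &rI : nullptr, &rp,
                               (long long)max_events);
  List out = List::create(_["time"] = res.time, _["extinct"] = res.extinct,
                          _["n_events"] = (double)res.n_events,
                          _["pulse_times"] = wrap(rp));
  if (record) {
    out["t"] = wrap(rt);
    out["S"] = wrap(rS);
    out["I"] = wrap(rI);
  }
  return out;
}

// [[Rcpp::export]]
List ssa_ensemble_cpp(int model, double beta, double gamma, double mu, int N,
                      double kappa, double nu, int schedule, int rounding,
                      int S0, int I0, double t_max, double master_seed, int n,
                      double max_events) {
  NumericVector times(n);
  LogicalVector extinct(n);
  for (int i = 0; i < n; ++i) {
    Xoshiro rng(stream_seed((uint64_t)master_seed, (uint64_t)(i + 1)));
    SimResult res = simulate_one(model, beta, gamma, mu, N, kappa, nu, schedule,
                                 rounding, S0, I0, t_max, rng, nullptr, nullptr,
                                 nullptr, nullptr, (long long)max_events);
    times[i] = res.time;
    extinct[i] = res.extinct;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = times, _["extinct"] = extinct);
}

// Time-weighted occupancy of the last `window` years before each extinction,
// pooled over realizations of the full model, binned over (S/N, I/N).
// [[Rcpp::export]]
List ssa_prehistory_cpp(double beta, double gamma, double mu, int N,
                        double kappa, double nu, int schedule, int rounding,
                        int S0, int I0, double t_max, double master_seed,
                        int n_extinct_target, int max_runs, double window,
                        double s_min, double s_max, int ns,
                        double x_min, double x_max, int nx,
                        double max_events) {
  NumericMatrix hist(ns, nx);  // rows: susceptible fraction, cols: infected fraction
  const double ds = (s_max - s_min) / ns, dx = (x_max - x_min) / nx;
  int n_ext = 0, runs = 0;
  struct Ev { double t; int S, I; };

  for (runs = 0; runs < max_runs && n_ext < n_extinct_target; ++runs) {
    Xoshiro rng(stream_seed((uint64_t)master_seed, (uint64_t)(runs + 1)));
    std::deque<Ev> buf;
    double t = 0.0;
    int S = S0, I = I0;
    long long ev = 0;
    const bool treat = (kappa > 0.0 && nu > 0.0);
    const bool periodic = (schedule == 1);
    double next_pulse = (treat && periodic) ? 1.0 / nu : R_PosInf;
    int k_pulse = 1;
    bool extinct = false;
    buf.push_back({0.0, S, I});

    while (I > 0) {
      double a[6];
      a[0] = mu * (double)N;
      a[1] = mu * (double)S;
      a[2] = mu * (double)I;
      a[3] = beta * (double)S * (double)I / (double)N;
      a[4] = gamma * (double)I;
      int nch = 5;
      if (treat && !periodic) { a[5] = nu; nch = 6; }
      double total = 0.0;
      for (int c = 0; c < nch; ++c) total += a[c];
      double dt = (total > 0.0) ? rng.rexp(total) : R_PosInf;
      double t_next = t + dt;
      bool was_pulse = false;
      if (periodic && treat && next_pulse <= t_next && next_pulse <= t_max) {
        t = next_pulse;
        int k = pulse_removed(kappa, I, rounding);
        S += k; I -= k;
        next_pulse = (double)(++k_pulse) / nu;
        was_pulse = true;
      } else if (t_next > t_max) {
        break;  // censored
      } else {
        t = t_next;
        double u = rng.runif_co() * total;
        int c = 0;
        double acc = a[0];
        while (u >= acc && c < nch - 1) acc += a[++c];
        switch (c) {
          case 0: S += 1; break;
          case 1: S -= 1; break;
          case 2: I -= 1; break;
          case 3: S -= 1; I += 1; break;
          case 4: S += 1; I -= 1; break;
          default: {
            int k = pulse_removed(kappa, I, rounding);
            S += k; I -= k;
          }
        }
      }
      (void)was_pulse;
      buf.push_back({t, S, I});
      // drop events that ended before the trailing window
      while (buf.size() > 1 && buf[1].t < t - window) buf.pop_front();
      if (I == 0) { extinct = true; break; }
      if (++ev >= (long long)max_events) break;
    }

    if (!extinct) continue;
    const double T0 = t - window;
    for (size_t j = 0; j + 1 < buf.size(); ++j) {
      double a0 = std::max(buf[j].t, T0);
      double a1 = std::min(buf[j + 1].t, t);
      if (a1 <= a0) continue;
      int is = (int)std::floor(((double)buf[j].S / N - s_min) / ds);
      int ix = (int)std::floor(((double)buf[j].I / N - x_min) / dx);
      if (is >= 0 && is < ns && ix >= 0 && ix < nx) hist(is, ix) += a1 - a0;
    }
    ++n_ext;
    if (runs % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["hist"] = hist, _["n_extinct"] = n_ext,
                      _["n_runs"] = runs);
}
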