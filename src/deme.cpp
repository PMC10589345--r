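#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include "rng.h"

using namespace Rcpp;

// Per-patch event channels of the stochastic deme model
// (logistic birth, density-independent death, mass-action infection,
// infected death, per-capita migration):
// 0 WT division, 1 MUT division, 2 WT death, 3 MUT death,
// 4 WT infection, 5 MUT infection, 6 infected death, 7 migration (any class)
static const int N_CH = 8;

struct DemeParams {
  double r, d, beta, a, K, mu, s;
  int n1, n2;
  bool spatial;
};

static const int NBR[8][2] = {
  {-1, -1}, {-1, 0}, {-1, 1},
  { 0, -1},          { 0, 1},
  { 1, -1},          { 1, 0}, { 1, 1}
};

struct DemeSys {
  int Np;
  std::vector<long> x, y, z;
  long xtot, ytot, ztot;
  std::vector<double> patot;   // per-patch total rate
  double total;                // global total rate
  long events_since_refresh;

  void init(const IntegerVector& xi, const IntegerVector& yi,
            const IntegerVector& zi, const DemeParams& p) {
    Np = xi.size();
    x.assign(xi.begin(), xi.end());
    y.assign(yi.begin(), yi.end());
    z.assign(zi.begin(), zi.end());
    xtot = ytot = ztot = 0;
    for (int i = 0; i < Np; ++i) { xtot += x[i]; ytot += y[i]; ztot += z[i]; }
    patot.assign(Np, 0.0);
    for (int i = 0; i < Np; ++i) patot[i] = patch_total(i, p);
    refresh_total();
  }

  inline void channel_rates(int i, const DemeParams& p, double* c) const {
    double n = (double)(x[i] + y[i] + z[i]);
    double room = 1.0 - n / p.K;
    if (room < 0.0) room = 0.0;              // crowding beyond K: clamp
    c[0] = p.r * (double)x[i] * room;
    c[1] = p.r * (1.0 + p.s) * (double)y[i] * room;
    c[2] = p.d * (double)x[i];
    c[3] = p.d * (double)y[i];
    c[4] = p.beta * (double)x[i] * (double)z[i];
    c[5] = p.beta * (double)y[i] * (double)z[i];
    c[6] = p.a * (double)z[i];
    c[7] = p.mu * n;
  }

  inline double patch_total(int i, const DemeParams& p) const {
    double c[N_CH];
    channel_rates(i, p, c);
    double s = 0.0;
    for (int k = 0; k < N_CH; ++k) s += c[k];
    return s;
  }

  void refresh_total() {
    total = 0.0;
    for (int i = 0; i < Np; ++i) total += patot[i];
    events_since_refresh = 0;
  }

  inline void touched(int i, const DemeParams& p) {
    double old = patot[i];
    patot[i] = patch_total(i, p);
    total += patot[i] - old;
  }

  inline int moore_neighbor(int i, int which, const DemeParams& p) const {
    int r0 = i / p.n2, c0 = i % p.n2;
    int rr = r0 + NBR[which][0];
    int cc = c0 + NBR[which][1];
    if (rr < 0) rr += p.n1; else if (rr >= p.n1) rr -= p.n1;
    if (cc < 0) cc += p.n2; else if (cc >= p.n2) cc -= p.n2;
    return rr * p.n2 + cc;
  }

  // execute one event; returns waiting time, or -1 if the system is frozen
  double step(const DemeParams& p, Pcg32& rng) {
    if (total <= 0.0) return -1.0;
    if (++events_since_refresh >= 8192) refresh_total();
    if (total <= 0.0) return -1.0;
    double dt = rng.rexp(total);

    // pick patch proportionally to its total rate
    double u = rng.unif() * total;
    int i = -1;
    double acc = 0.0;
    for (int k = 0; k < Np; ++k) {
      acc += patot[k];
      if (u < acc) { i = k; break; }
    }
    if (i < 0) {                      // numerical slack: last non-zero patch
      for (int k = Np - 1; k >= 0; --k) if (patot[k] > 0.0) { i = k; break; }
      if (i < 0) return -1.0;
    }

    double c[N_CH];
    channel_rates(i, p, c);
    double psum = 0.0;
    for (int k = 0; k < N_CH; ++k) psum += c[k];
    double v = rng.unif() * psum;
    int ch = N_CH - 1;
    acc = 0.0;
    for (int k = 0; k < N_CH; ++k) {
      acc += c[k];
      if (v < acc) { ch = k; break; }
    }

    switch (ch) {
      case 0: x[i]++; xtot++; break;
      case 1: y[i]++; ytot++; break;
      case 2: x[i]--; xtot--; break;
      case 3: y[i]--; ytot--; break;
      case 4: x[i]--; z[i]++; xtot--; ztot++; break;
      case 5: y[i]--; z[i]++; ytot--; ztot++; break;
      case 6: z[i]--; ztot--; break;
      case 7: {
        // migrant class uniform over the patch's individuals
        long n = x[i] + y[i] + z[i];
        double w = rng.unif() * (double)n;
        int cls = (w < (double)x[i]) ? 0 : (w < (double)(x[i] + y[i]) ? 1 : 2);
        int j = p.spatial ? moore_neighbor(i, (int)rng.below(8), p)
                          : (int)rng.below((uint32_t)Np);  // self allowed (no-op)
        if (cls == 0) { x[i]--; x[j]++; }
        else if (cls == 1) { y[i]--; y[j]++; }
        else { z[i]--; z[j]++; }
        if (j != i) touched(j, p);
        break;
      }
    }
    touched(i, p);
    return dt;
  }
};

static DemeParams make_params(double r, double d, double beta, double a,
                              double K, double mu, double s, int n1, int n2,
                              bool spatial) {
  DemeParams p;
  p.r = r; p.d = d; p.beta = beta; p.a = a; p.K = K; p.mu = mu; p.s = s;
  p.n1 = n1; p.n2 = n2; p.spatial = spatial;
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_deme_rates(IntegerVector x, IntegerVector y, IntegerVector z,
                             double r, double d, double beta, double a,
                             double K, double mu, double s) {
  DemeParams p = make_params(r, d, beta, a, K, mu, s, 1, x.size(), false);
  DemeSys sys;
  sys.init(x, y, z, p);
  NumericMatrix out(x.size(), N_CH);
  double c[N_CH];
  for (int i = 0; i < x.size(); ++i) {
    sys.channel_rates(i, p, c);
    for (int k = 0; k < N_CH; ++k) out(i, k) = c[k];
  }
  return out;
}

// Advance the system from time t0 for `duration` time units.  Optionally
// records totals every sample_dt and accumulates the time-weighted mean of
// the total uninfected population over [avg_from, avg_to] (absolute times).
// [[Rcpp::export]]
List cpp_deme_run(IntegerVector x, IntegerVector y, IntegerVector z,
                  int n1, int n2, double r, double d, double beta, double a,
                  double K, double mu, double s, bool spatial,
                  double t0, double duration, double sample_dt,
                  double avg_from, double avg_to,
                  double seed, double stream) {
  DemeParams p = make_params(r, d, beta, a, K, mu, s, n1, n2, spatial);
  DemeSys sys;
  sys.init(x, y, z, p);
  Pcg32 rng((uint64_t)seed, (uint64_t)stream);

  double t_end = t0 + duration;
  double t = t0;
  bool frozen = false;
  long n_events = 0;

  bool record = sample_dt > 0.0;
  std::vector<double> st, sx, sy, sz;
  double next_sample = t0 + sample_dt;

  double avg_acc = 0.0;
  bool do_avg = avg_to > avg_from;

  while (t < t_end) {
    long uin = sys.xtot + sys.ytot;
    double dt = sys.step(p, rng);
    double t_next = (dt < 0.0) ? t_end : std::min(t + dt, t_end);

    if (do_avg) {
      double lo = std::max(t, avg_from), hi = std::min(t_next, avg_to);
      if (hi > lo) avg_acc += (double)uin * (hi - lo);
    }
    if (record) {
      while (next_sample <= t_next && next_sample <= t_end + 1e-12) {
        st.push_back(next_sample);
        sx.push_back((double)sys.xtot);
        sy.push_back((double)sys.ytot);
        sz.push_back((double)sys.ztot);
        next_sample += sample_dt;
      }
    }
    if (dt < 0.0) { frozen = true; t = t_end; break; }
    t = t + dt;
    n_events++;
    if (t >= t_end) { t = t_end; break; }
  }

  double avg = do_avg ? avg_acc / (avg_to - avg_from) : NA_REAL;
  return List::create(
    _["x"] = IntegerVector(sys.x.begin(), sys.x.end()),
    _["y"] = IntegerVector(sys.y.begin(), sys.y.end()),
    _["z"] = IntegerVector(sys.z.begin(), sys.z.end()),
    _["t"] = t_end,
    _["n_events"] = (double)n_events,
    _["frozen"] = frozen,
    _["extinct"] = (sys.xtot + sys.ytot + sys.ztot) == 0,
    _["avg_uninf"] = avg,
    _["series"] = DataFrame::create(
      _["t"] = NumericVector(st.begin(), st.end()),
      _["total_x"] = NumericVector(sx.begin(), sx.end()),
      _["total_y"] = NumericVector(sy.begin(), sy.end()),
      _["total_z"] = NumericVector(sz.begin(), sz.end())));
}

// Replace k uninfected WT individuals by mutants, each repetition picking a
// patch with probability proportional to its current x_i.
// [[Rcpp::export]]
List cpp_deme_introduce(IntegerVector x, IntegerVector y, int k,
                        double seed, double stream) {
  std::vector<long> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  long xtot = 0;
  for (size_t i = 0; i < xv.size(); ++i) xtot += xv[i];
  if (xtot < (long)k) stop("fewer uninfected wild-type individuals than mutants to introduce");
  Pcg32 rng((uint64_t)seed, (uint64_t)stream);
  for (int m = 0; m < k; ++m) {
    double u = rng.unif() * (double)xtot;
    double acc = 0.0;
    int pick = (int)xv.size() - 1;
    for (size_t i = 0; i < xv.size(); ++i) {
      acc += (double)xv[i];
      if (u < acc) { pick = (int)i; break; }
    }
    while (xv[pick] == 0) pick--;   // numerical guard
    xv[pick]--; yv[pick]++; xtot--;
  }
  return List::create(
    _["x"] = IntegerVector(xv.begin(), xv.end()),
    _["y"] = IntegerVector(yv.begin(), yv.end()));
}

// Full deme fixation trial.  Outcome codes: 1 fixation, 2 extinction,
// 3 global extinction, 4 censored.
// [[Rcpp::export]]
List cpp_deme_trial(IntegerVector x, IntegerVector y, IntegerVector z,
                    int n1, int n2, double r, double d, double beta, double a,
                    double K, double mu, double s, bool spatial,
                    double Nu, int k, double burn_in, double max_wait,
                    double max_time, double seed, double stream) {
  DemeParams p0 = make_params(r, d, beta, a, K, mu, 0.0, n1, n2, spatial);
  DemeParams p  = make_params(r, d, beta, a, K, mu, s, n1, n2, spatial);
  DemeSys sys;
  sys.init(x, y, z, p0);
  Pcg32 rng((uint64_t)seed, (uint64_t)stream);

  long target = (long)std::floor(Nu + 0.5);
  double t = 0.0;

  // phase 1: burn-in (mutant-free dynamics)
  while (t < burn_in) {
    double dt = sys.step(p0, rng);
    if (dt < 0.0 || sys.xtot + sys.ytot == 0) {
      return List::create(_["kind"] = 3, _["t_conditional"] = NA_REAL,
                          _["introduction_time"] = NA_REAL, _["t"] = t);
    }
    t += dt;
  }

  // phase 2: trigger when total uninfected hits round(Nu)
  long dmin = -1;
  double wait_start = t;
  while (sys.xtot + sys.ytot != target) {
    double dt = sys.step(p0, rng);
    if (dt < 0.0 || sys.xtot + sys.ytot == 0) {
      return List::create(_["kind"] = 3, _["t_conditional"] = NA_REAL,
                          _["introduction_time"] = NA_REAL, _["t"] = t);
    }
    t += dt;
    long dd = sys.xtot + sys.ytot - target;
    if (dd < 0) dd = -dd;
    if (dd == 0) break;
    double waited = t - wait_start;
    if (waited <= max_wait) {
      if (dmin < 0 || dd < dmin) dmin = dd;
    } else if (dd <= dmin || waited >= 2.0 * max_wait) {
      break;                        // nearest-crossing fallback
    }
  }

  // introduce k mutants, patch chosen proportionally to x_i
  if (sys.xtot < (long)k)
    stop("fewer uninfected wild-type individuals than mutants to introduce");
  for (int m = 0; m < k; ++m) {
    double u = rng.unif() * (double)sys.xtot;
    double acc = 0.0;
    int pick = sys.Np - 1;
    for (int i = 0; i < sys.Np; ++i) {
      acc += (double)sys.x[i];
      if (u < acc) { pick = i; break; }
    }
    while (sys.x[pick] == 0) pick--;
    sys.x[pick]--; sys.y[pick]++;
    sys.xtot--; sys.ytot++;
    sys.touched(pick, p);
  }
  // rates now include selection on the mutant
  for (int i = 0; i < sys.Np; ++i) sys.patot[i] = sys.patch_total(i, p);
  sys.refresh_total();
  double t_intro = t;

  // phase 3: run to absorption on uninfected totals
  while (t - t_intro < max_time) {
    double dt = sys.step(p, rng);
    if (dt >= 0.0) t += dt;
    long cw = sys.xtot, cm = sys.ytot;
    if (cm == 0 && cw == 0) {
      return List::create(_["kind"] = 3, _["t_conditional"] = NA_REAL,
                          _["introduction_time"] = t_intro, _["t"] = t);
    } else if (cm == 0) {
      return List::create(_["kind"] = 2, _["t_conditional"] = NA_REAL,
                          _["introduction_time"] = t_intro, _["t"] = t);
    } else if (cw == 0) {
      return List::create(_["kind"] = 1, _["t_conditional"] = t - t_intro,
                          _["introduction_time"] = t_intro, _["t"] = t);
    }
    if (dt < 0.0) {
      // frozen with both classes alive (only possible when all rates vanish)
      return List::create(_["kind"] = 4, _["t_conditional"] = NA_REAL,
                          _["introduction_time"] = t_intro, _["t"] = t);
    }
  }
  return List::create(_["kind"] = 4, _["t_conditional"] = NA_REAL,
                      _["introduction_time"] = t_intro, _["t"] = t);
}
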