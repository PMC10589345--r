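#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include "rng.h"

using namespace Rcpp;

// Site codes (shared with the R side and snapshot files):
// 0 empty, 1 uninfected WT, 2 infected WT, 3 uninfected MUT, 4 infected MUT
enum SiteState { EMPTY = 0, U_WT = 1, I_WT = 2, U_MUT = 3, I_MUT = 4 };

// Moore neighborhood, row-major offsets (row, col); index 0..7.
// Order matters only for forced-draw tests, which use this table.
static const int NBR[8][2] = {
  {-1, -1}, {-1, 0}, {-1, 1},
  { 0, -1},          { 0, 1},
  { 1, -1},          { 1, 0}, { 1, 1}
};

struct AbmGrid {
  int n1, n2;                 // rows, cols
  std::vector<int> lat;       // n1*n2 site states, row-major
  std::vector<int> occ;       // positions of occupied sites
  std::vector<int> slot;      // slot[pos] = index in occ, or -1
  long counts[5];             // per-state tallies

  void init(const IntegerMatrix& m) {
    n1 = m.nrow();
    n2 = m.ncol();
    lat.assign(n1 * n2, 0);
    slot.assign(n1 * n2, -1);
    occ.clear();
    for (int k = 0; k < 5; ++k) counts[k] = 0;
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j) {
        int st = m(i, j);
        int pos = i * n2 + j;
        lat[pos] = st;
        counts[st]++;
        if (st != EMPTY) {
          slot[pos] = (int)occ.size();
          occ.push_back(pos);
        }
      }
    }
  }

  inline void set_state(int pos, int st) {
    int old = lat[pos];
    if (old == st) return;
    counts[old]--;
    counts[st]++;
    lat[pos] = st;
    if (old == EMPTY) {            // becomes occupied
      slot[pos] = (int)occ.size();
      occ.push_back(pos);
    } else if (st == EMPTY) {      // becomes empty: swap-remove
      int k = slot[pos];
      int last = occ.back();
      occ[k] = last;
      slot[last] = k;
      occ.pop_back();
      slot[pos] = -1;
    }
  }

  inline int neighbor(int pos, int which) const {
    int r = pos / n2, c = pos % n2;
    int rr = r + NBR[which][0];
    int cc = c + NBR[which][1];
    if (rr < 0) rr += n1; else if (rr >= n1) rr -= n1;
    if (cc < 0) cc += n2; else if (cc >= n2) cc -= n2;
    return rr * n2 + cc;
  }

  inline long n_uninf() const { return counts[U_WT] + counts[U_MUT]; }
  inline long n_occ()   const { return (long)occ.size(); }

  IntegerMatrix as_matrix() const {
    IntegerMatrix m(n1, n2);
    for (int i = 0; i < n1; ++i)
      for (int j = 0; j < n2; ++j)
        m(i, j) = lat[i * n2 + j];
    return m;
  }
};

// One elementary rule application at `pos`, given the event variate u and a
// lazily used neighbor index nbr (0..7).  Returns an event code:
// 0 nothing, 1 division, 2 death (uninfected), 3 infection, 4 death (infected),
// 5 blocked division (occupied target), 6 failed infection (target not uninfected).
static int apply_rule(AbmGrid& g, int pos, double u, int nbr,
                      double R, double D, double A, double B, double s) {
  int st = g.lat[pos];
  if (st == U_WT || st == U_MUT) {
    double pdiv = (st == U_MUT) ? R * (1.0 + s) : R;
    if (u < pdiv) {
      int tgt = g.neighbor(pos, nbr);
      if (g.lat[tgt] == EMPTY) {
        g.set_state(tgt, st);      // offspring inherits genotype, uninfected
        return 1;
      }
      return 5;                    // occupied target: division silently fails
    } else if (u < pdiv + D) {
      g.set_state(pos, EMPTY);
      return 2;
    }
    return 0;
  } else if (st == I_WT || st == I_MUT) {
    if (u < B) {
      int tgt = g.neighbor(pos, nbr);
      int tst = g.lat[tgt];
      if (tst == U_WT) { g.set_state(tgt, I_WT); return 3; }
      if (tst == U_MUT) { g.set_state(tgt, I_MUT); return 3; }
      return 6;                    // infection needs an uninfected target
    } else if (u < B + A) {
      g.set_state(pos, EMPTY);
      return 4;
    }
    return 0;
  }
  return 0; // empty site should never be picked
}

// One time-step: N1 elementary updates with N1 frozen at the step boundary;
// picks are uniform over currently occupied sites, with replacement.
// Returns false if the grid went (globally) extinct during the step.
static bool time_step(AbmGrid& g, Pcg32& rng,
                      double R, double D, double A, double B, double s) {
  long N1 = g.n_occ();
  for (long j = 0; j < N1; ++j) {
    long nocc = g.n_occ();
    if (nocc == 0) return false;
    int pos = g.occ[rng.below((uint32_t)nocc)];
    double u = rng.unif();
    int st = g.lat[pos];
    // draw the neighbor variate only when the event needs one
    bool needs_nbr = (st == U_WT || st == U_MUT)
                       ? (u < ((st == U_MUT) ? R * (1.0 + s) : R))
                       : (u < B);
    int nbr = needs_nbr ? (int)rng.below(8) : 0;
    apply_rule(g, pos, u, nbr, R, D, A, B, s);
  }
  return g.n_occ() > 0;
}

// [[Rcpp::export]]
List cpp_abm_run(IntegerMatrix lattice, double R, double D, double A, double B,
                 double s, int steps, double seed, double stream, bool record) {
  AbmGrid g;
  g.init(lattice);
  Pcg32 rng((uint64_t)seed, (uint64_t)stream);

  IntegerMatrix series(record ? steps : 0, 4);
  int done = 0;
  bool extinct = (g.n_occ() == 0);
  for (int t = 0; t < steps && !extinct; ++t) {
    extinct = !time_step(g, rng, R, D, A, B, s);
    done = t + 1;
    if (record) {
      series(t, 0) = (int)g.counts[U_WT];
      series(t, 1) = (int)g.counts[U_MUT];
      series(t, 2) = (int)g.counts[I_WT];
      series(t, 3) = (int)g.counts[I_MUT];
    }
  }
  if (!extinct) done = steps;
  return List::create(
    _["lattice"] = g.as_matrix(),
    _["series"] = series,
    _["steps_done"] = done,
    _["extinct"] = extinct,
    _["counts"] = IntegerVector::create(
      (int)g.counts[U_WT], (int)g.counts[U_MUT],
      (int)g.counts[I_WT], (int)g.counts[I_MUT]));
}

// Execute exactly one elementary rule with caller-supplied draws, on the real
// engine code path.  row/col are 0-based; nbr indexes the Moore table.
// [[Rcpp::export]]
List cpp_abm_forced_update(IntegerMatrix lattice, double R, double D, double A,
                           double B, double s, int row, int col, double u, int nbr) {
  AbmGrid g;
  g.init(lattice);
  int pos = row * g.n2 + col;
  if (g.lat[pos] == EMPTY) stop("picked site is empty");
  int ev = apply_rule(g, pos, u, nbr, R, D, A, B, s);
  return List::create(
    _["lattice"] = g.as_matrix(),
    _["event"] = ev,
    _["counts"] = IntegerVector::create(
      (int)g.counts[U_WT], (int)g.counts[U_MUT],
      (int)g.counts[I_WT], (int)g.counts[I_MUT]));
}

// Full fixation trial: burn-in, wait for the uninfected count to hit
// round(Nu), convert n_mutants uniformly chosen uninfected-WT sites, then run
// to absorption (or censor).  Outcome codes: 1 fixation, 2 extinction,
// 3 global extinction, 4 censored.
// [[Rcpp::export]]
List cpp_abm_trial(IntegerMatrix lattice, double R, double D, double A, double B,
                   double s, double Nu, int n_mutants, int burn_in, int max_wait,
                   double max_steps, double seed, double stream) {
  AbmGrid g;
  g.init(lattice);
  Pcg32 rng((uint64_t)seed, (uint64_t)stream);

  long target = (long)std::floor(Nu + 0.5);
  double intro_step = NA_REAL;
  long step = 0;

  // phase 1: burn-in (mutant-free)
  for (int t = 0; t < burn_in; ++t) {
    if (!time_step(g, rng, R, D, A, B, 0.0) || g.n_uninf() == 0) {
      return List::create(_["kind"] = 3, _["t_conditional"] = NA_REAL,
                          _["introduction_step"] = NA_REAL, _["step"] = step);
    }
    step++;
  }

  // phase 2: trigger on uninfected count == round(Nu); fallback to the
  // closest-approach count seen during the first waiting window
  long dmin = -1;
  bool triggered = (g.n_uninf() == target);
  long waited = 0;
  while (!triggered) {
    if (!time_step(g, rng, R, D, A, B, 0.0) || g.n_uninf() == 0) {
      return List::create(_["kind"] = 3, _["t_conditional"] = NA_REAL,
                          _["introduction_step"] = NA_REAL, _["step"] = step);
    }
    step++;
    waited++;
    long d = g.n_uninf() - target;
    if (d < 0) d = -d;
    if (d == 0) { triggered = true; break; }
    if (waited <= max_wait) {
      if (dmin < 0 || d < dmin) dmin = d;
    } else if (d <= dmin || waited >= 2L * max_wait) {
      triggered = true;            // nearest-crossing fallback
    }
  }

  // introduce mutants: uniform over uninfected-WT sites, without replacement,
  // simultaneous conversion
  {
    std::vector<int> wt;
    wt.reserve(g.counts[U_WT]);
    for (int p = 0; p < g.n1 * g.n2; ++p)
      if (g.lat[p] == U_WT) wt.push_back(p);
    if ((long)wt.size() < (long)n_mutants)
      stop("fewer uninfected wild-type cells than mutants to introduce");
    int nw = (int)wt.size();
    for (int k = 0; k < n_mutants; ++k) {   // partial Fisher-Yates
      int j = k + (int)rng.below((uint32_t)(nw - k));
      std::swap(wt[k], wt[j]);
      g.set_state(wt[k], U_MUT);
    }
  }
  intro_step = (double)step;

  // phase 3: run to absorption on uninfected-class counts
  double t_rel = 0.0;
  while (t_rel < max_steps) {
    long N1 = g.n_occ();
    if (N1 == 0) {
      return List::create(_["kind"] = 3, _["t_conditional"] = NA_REAL,
                          _["introduction_step"] = intro_step, _["step"] = step);
    }
    for (long j = 0; j < N1; ++j) {
      long nocc = g.n_occ();
      if (nocc == 0) break;
      int pos = g.occ[rng.below((uint32_t)nocc)];
      double u = rng.unif();
      int st = g.lat[pos];
      bool needs_nbr = (st == U_WT || st == U_MUT)
                         ? (u < ((st == U_MUT) ? R * (1.0 + s) : R))
                         : (u < B);
      int nbr = needs_nbr ? (int)rng.below(8) : 0;
      int ev = apply_rule(g, pos, u, nbr, R, D, A, B, s);
      if (ev == 1 || ev == 2 || ev == 3 || ev == 4) { // counts changed
        long cw = g.counts[U_WT], cm = g.counts[U_MUT];
        if (cm == 0 && cw == 0) {
          return List::create(_["kind"] = 3, _["t_conditional"] = NA_REAL,
                              _["introduction_step"] = intro_step,
                              _["step"] = step);
        } else if (cm == 0) {
          return List::create(_["kind"] = 2, _["t_conditional"] = NA_REAL,
                              _["introduction_step"] = intro_step,
                              _["step"] = step);
        } else if (cw == 0) {
          double t_fix = t_rel + (double)(j + 1) / (double)N1;
          return List::create(_["kind"] = 1, _["t_conditional"] = t_fix,
                              _["introduction_step"] = intro_step,
                              _["step"] = step);
        }
      }
    }
    step++;
    t_rel += 1.0;
  }
  return List::create(_["kind"] = 4, _["t_conditional"] = NA_REAL,
                      _["introduction_step"] = intro_step, _["step"] = step);
}
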