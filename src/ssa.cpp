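// Exact stochastic simulation (Gillespie direct method) of the
// miRNA-target titration network.
//
// Species order: s, r1, r2, p1, p2.
// Channel order matches R's cerna_stoichiometry():
//   0 birth_s   1 birth_r1  2 birth_r2
//   3 death_s   4 death_r1  5 death_r2
//   6 joint_1   7 recycle_1 8 joint_2  9 recycle_2
//  10 transl_1 11 death_p1 12 transl_2 13 death_p2
// The joint channel removes the target and the miRNA together
// (probability alpha of an interaction); the recycling channel removes
// only the target.  Uses R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

static const int N_SPECIES = 5;
static const int N_CHANNEL = 14;

// stoichiometry[channel][species]
static const int STO[N_CHANNEL][N_SPECIES] = {
  { 1, 0, 0, 0, 0},  // birth_s
  { 0, 1, 0, 0, 0},  // birth_r1
  { 0, 0, 1, 0, 0},  // birth_r2
  {-1, 0, 0, 0, 0},  // death_s
  { 0,-1, 0, 0, 0},  // death_r1
  { 0, 0,-1, 0, 0},  // death_r2
  {-1,-1, 0, 0, 0},  // joint_1
  { 0,-1, 0, 0, 0},  // recycle_1
  {-1, 0,-1, 0, 0},  // joint_2
  { 0, 0,-1, 0, 0},  // recycle_2
  { 0, 0, 0, 1, 0},  // transl_1
  { 0, 0, 0,-1, 0},  // death_p1
  { 0, 0, 0, 0, 1},  // transl_2
  { 0, 0, 0, 0,-1}   // death_p2
};

struct Rates {
  double k_s, k_r1, k_r2, g_s, g_r1, g_r2, g_1, g_2, alpha, k_p1, k_p2,
         g_p1, g_p2;
};

static Rates unpack(const NumericVector& par) {
  Rates r;
  r.k_s = par[0];  r.k_r1 = par[1]; r.k_r2 = par[2];
  r.g_s = par[3];  r.g_r1 = par[4]; r.g_r2 = par[5];
  r.g_1 = par[6];  r.g_2 = par[7];  r.alpha = par[8];
  r.k_p1 = par[9]; r.k_p2 = par[10]; r.g_p1 = par[11]; r.g_p2 = par[12];
  return r;
}

static inline void propensities(const Rates& p, const double* x, double* a) {
  a[0] = p.k_s;
  a[1] = p.k_r1;
  a[2] = p.k_r2;
  a[3] = p.g_s  * x[0];
  a[4] = p.g_r1 * x[1];
  a[5] = p.g_r2 * x[2];
  double i1 = p.g_1 * x[0] * x[1];
  double i2 = p.g_2 * x[0] * x[2];
  a[6] = p.alpha * i1;
  a[7] = (1.0 - p.alpha) * i1;
  a[8] = p.alpha * i2;
  a[9] = (1.0 - p.alpha) * i2;
  a[10] = p.k_p1 * x[1];
  a[11] = p.g_p1 * x[3];
  a[12] = p.k_p2 * x[2];
  a[13] = p.g_p2 * x[4];
}

// one jump; returns channel index or -1 if total propensity is zero
static inline int step(const Rates& p, double* x, double& t) {
  double a[N_CHANNEL];
  propensities(p, x, a);
  double a0 = 0.0;
  for (int j = 0; j < N_CHANNEL; ++j) a0 += a[j];
  if (a0 <= 0.0) return -1;
  t += R::exp_rand() / a0;
  double u = unif_rand() * a0;
  double c = 0.0;
  int j = 0;
  for (; j < N_CHANNEL - 1; ++j) {
    c += a[j];
    if (u <= c) break;
  }
  for (int i = 0; i < N_SPECIES; ++i) x[i] += STO[j][i];
  return j;
}

// [[Rcpp::export]]
List cpp_gillespie(NumericVector par, NumericVector init, double t_max,
                   int max_events, bool store) {
  Rates p = unpack(par);
  double x[N_SPECIES];
  for (int i = 0; i < N_SPECIES; ++i) x[i] = init[i];
  std::vector<double> times;
  std::vector<double> states;
  IntegerVector counts(N_CHANNEL);
  if (store) {
    times.push_back(0.0);
    for (int i = 0; i < N_SPECIES; ++i) states.push_back(x[i]);
  }
  double t = 0.0;
  int n_events = 0;
  bool stalled = false;
  while (t < t_max) {
    double x_prev[N_SPECIES];
    for (int i = 0; i < N_SPECIES; ++i) x_prev[i] = x[i];
    int j = step(p, x, t);
    if (j < 0) { stalled = true; break; }
    if (t > t_max) {  // jump past the horizon is not realised
      for (int i = 0; i < N_SPECIES; ++i) x[i] = x_prev[i];
      break;
    }
    counts[j]++;
    n_events++;
    if (store) {
      times.push_back(t);
      for (int i = 0; i < N_SPECIES; ++i) states.push_back(x[i]);
    }
    if (n_events >= max_events) {
      stop("event cap reached (%d events before t_max); raise max_events",
           max_events);
    }
  }
  NumericVector final_state(N_SPECIES);
  for (int i = 0; i < N_SPECIES; ++i) final_state[i] = x[i];
  List out = List::create(
    _["final_state"] = final_state,
    _["t_end"] = std::min(t, t_max),
    _["n_events"] = n_events,
    _["channel_counts"] = counts,
    _["stalled"] = stalled);
  if (store) {
    int n = times.size();
    NumericMatrix S(n, N_SPECIES);
    for (int k = 0; k < n; ++k)
      for (int i = 0; i < N_SPECIES; ++i)
        S(k, i) = states[(size_t)k * N_SPECIES + i];
    out["times"] = NumericVector(times.begin(), times.end());
    out["states"] = S;
  }
  return out;
}

// Independent-replica stationary sampling: each row of the result is the
// state of one virtual cell after a burn-in of t_burn (plus optional
// extra thinned draws spaced by `spacing`, appended as further rows).
// [[Rcpp::export]]
NumericMatrix cpp_sample_cells(NumericVector par, NumericMatrix init,
                               double t_burn, int n_cells,
                               int draws_per_cell, double spacing) {
  Rates p = unpack(par);
  NumericMatrix out(n_cells * draws_per_cell, N_SPECIES);
  for (int c = 0; c < n_cells; ++c) {
    double x[N_SPECIES];
    int ir = (init.nrow() == 1) ? 0 : c;
    for (int i = 0; i < N_SPECIES; ++i) x[i] = init(ir, i);
    double t = 0.0;
    double next_record = t_burn;
    int rec = 0;
    while (rec < draws_per_cell) {
      double t_prev = t;
      int j = step(p, x, t);
      if (j < 0) {
        // absorbing state: it persists forever, record it
        for (; rec < draws_per_cell; ++rec)
          for (int i = 0; i < N_SPECIES; ++i)
            out(c * draws_per_cell + rec, i) = x[i];
        break;
      }
      // record the pre-jump state at every passed recording time
      while (rec < draws_per_cell && t > next_record) {
        for (int i = 0; i < N_SPECIES; ++i) {
          double xi = x[i] - STO[j][i];  // state held on (t_prev, t)
          out(c * draws_per_cell + rec, i) = xi;
        }
        (void)t_prev;
        next_record += spacing;
        rec++;
      }
    }
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Time-averaged means and second moments over a long run (post burn-in),
// used for mean-field validation at scale without storing trajectories.
// [[Rcpp::export]]
List cpp_time_average(NumericVector par, NumericVector init, double t_burn,
                      double t_avg) {
  Rates p = unpack(par);
  double x[N_SPECIES];
  for (int i = 0; i < N_SPECIES; ++i) x[i] = init[i];
  double t = 0.0;
  // burn-in
  while (t < t_burn) {
    int j = step(p, x, t);
    if (j < 0) break;
  }
  double m1[N_SPECIES] = {0, 0, 0, 0, 0};
  double m2[N_SPECIES * N_SPECIES] = {0};
  double t0 = t, t_prev = t;
  double x_prev[N_SPECIES];
  for (int i = 0; i < N_SPECIES; ++i) x_prev[i] = x[i];
  long n_events = 0;
  while (t - t0 < t_avg) {
    int j = step(p, x, t);
    if (j < 0) {  // absorbing state holds for all remaining time
      double dt = t0 + t_avg - t_prev;
      for (int i = 0; i < N_SPECIES; ++i) {
        m1[i] += dt * x_prev[i];
        for (int k = 0; k < N_SPECIES; ++k)
          m2[i * N_SPECIES + k] += dt * x_prev[i] * x_prev[k];
      }
      t = t0 + t_avg;
      break;
    }
    double dt = std::min(t, t0 + t_avg) - t_prev;
    if (dt > 0) {
      for (int i = 0; i < N_SPECIES; ++i) {
        m1[i] += dt * x_prev[i];
        for (int k = 0; k < N_SPECIES; ++k)
          m2[i * N_SPECIES + k] += dt * x_prev[i] * x_prev[k];
      }
    }
    t_prev = std::min(t, t0 + t_avg);
    for (int i = 0; i < N_SPECIES; ++i) x_prev[i] = x[i];
    n_events++;
    if (n_events % 1000000 == 0) Rcpp::checkUserInterrupt();
  }
  double T = t_avg;
  NumericVector mean(N_SPECIES);
  NumericMatrix second(N_SPECIES, N_SPECIES);
  for (int i = 0; i < N_SPECIES; ++i) {
    mean[i] = m1[i] / T;
    for (int k = 0; k < N_SPECIES; ++k)
      second(i, k) = m2[i * N_SPECIES + k] / T;
  }
  return List::create(_["mean"] = mean, _["second_moment"] = second,
                      _["n_events"] = n_events);
}
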