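#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One continuous-time search trial (CTELM / CCTELM).
//
// Time advances in integer steps of dt (1 ms by default).  Evidence at every
// predefined location follows the exact leaky recursion
//   W <- dW + W * exp(-k dt),  dW ~ N(+-dt, 8 dt / a^2),
// with (a, k) evaluated once per fixation relative to the evidence-source
// position.  The posterior over locations is the normalized exponential of
// the summed per-fixation log-likelihood-ratio terms a^2 W / (2 + 2 e^{-Tk}),
// restricted to the current fixation plus the last M-1 finished ones.
//
// Event semantics: when a saccade decision triggers at time t, attention (and
// the probability fed to the stop/saccade rules) moves to the chosen location
// immediately; the eye follows at t + saccade_lag; evidence from the new
// location starts at t + saccade_lag + eye_brain_lag, until which the
// previous location's accumulation continues.  Saccades take zero time.
// A new saccade-decision process starts at the trigger; its collapsing-bound
// clock runs from the trigger, and the bound (and the stop rule) is evaluated
// only from eye_brain_lag onward.  Express saccades bypass the bound: their
// trigger time is a pre-drawn latency from the process start.

// Fast local generator (xoshiro256++ with Box-Muller normals), seeded from
// R's RNG stream so that set.seed() upstream fully determines a trial.
struct FastRng {
  uint64_t s[4];
  double cached;
  bool has_cached;
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    has_cached = false;
    for (int i = 0; i < 16; ++i) next();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double runif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rnorm() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = runif(), u2 = runif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 6.283185307179586 * u2;
    cached = r * std::sin(th);
    has_cached = true;
    return r * std::cos(th);
  }
};

struct TimedEvent {
  int step;
  double x, y;
  int node;      // grid node index (0-based) or -1 for off-grid landings
  int sacc_type; // 0 normal, 1 express
};

static inline double theta_s(double t, double q1, double q2, double q3) {
  if (t <= 0.0) return 1.0;
  return std::pow(10.0, q1 * std::exp(-std::pow(t / q2, q3)));
}

// [[Rcpp::export]]
List run_ct_trial_cpp(NumericMatrix grid_xy,
                      int target,            // 1-based node index
                      NumericVector field,   // p1..p5
                      double dprime_floor,
                      NumericVector qpar,    // q1, q2, q3
                      double eye_brain_lag, double saccade_lag,
                      double theta_T,
                      double sel_c, bool penalized, double expected_T,
                      int memory_M,          // <= 0 means unlimited
                      bool landing_enabled,
                      NumericVector landing_par, // sd_slope, sd_intercept, bias_slope, bias_onset
                      double field_radius,
                      bool disc_attention, double window_radius,
                      IntegerVector sacc_express,   // per saccade ordinal, 0/1
                      NumericVector express_latency, // seconds, per ordinal
                      int max_fixations,
                      double dt,
                      double max_time,
                      double fixed_duration) { // > 0: forced fixation duration,
                                               // per-fixation decisions, no lags
  const int n = grid_xy.nrow();
  const double p1 = field[0], p2 = field[1], p3 = field[2], p4 = field[3],
               p5 = field[4];
  const double q1 = qpar[0], q2 = qpar[1], q3 = qpar[2];
  const bool fixed_mode = fixed_duration > 0.0;
  const int lag_sac = fixed_mode ? 0 : (int)std::lround(saccade_lag / dt);
  const int lag_ebl = fixed_mode ? 0 : (int)std::lround(eye_brain_lag / dt);
  const int fixed_steps = fixed_mode ? (int)std::lround(fixed_duration / dt) : 0;
  const int max_steps = (int)std::lround(max_time / dt);
  const int tgt = target - 1;
  const double w2 = window_radius * window_radius;
  const int M_past = memory_M <= 0 ? -1 : memory_M - 1;

  FastRng rng;
  rng.seed_from_R();

  std::vector<double> gx(n), gy(n);
  for (int i = 0; i < n; ++i) { gx[i] = grid_xy(i, 0); gy[i] = grid_xy(i, 1); }

  // gain matrix: d'^2 of location i from candidate c at expected_T, n x n
  std::vector<double> d2mat((size_t)n * n);
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < n; ++i) {
      double dx = gx[i] - gx[c], dy = gy[i] - gy[c];
      double r = std::sqrt(dx * dx + p5 * dy * dy);
      double a = p1 * std::exp(-p2 * r);
      double k = p3 * std::exp(-p4 * r);
      double e = std::exp(-k * expected_T);
      double d = a * std::sqrt((1.0 - e) / (k * (1.0 + e)));
      if (d < dprime_floor) d = dprime_floor;
      d2mat[(size_t)c * n + i] = d * d;
    }
  }

  // per-epoch evidence fields
  std::vector<double> a2(n), kk(n), decay(n), sdv(n), drift(n), efac(n), W(n);
  std::vector<double> base(n, 0.0), tot(n), P(n);
  std::deque<std::vector<double> > past;

  auto set_epoch_fields = [&](double ex, double ey) {
    for (int i = 0; i < n; ++i) {
      double dx = gx[i] - ex, dy = gy[i] - ey;
      double r = std::sqrt(dx * dx + p5 * dy * dy);
      double a = p1 * std::exp(-p2 * r);
      double k = p3 * std::exp(-p4 * r);
      double afloor = dprime_floor * std::sqrt(k);
      if (a < afloor) a = afloor;
      a2[i] = a * a;
      kk[i] = k;
      decay[i] = std::exp(-k * dt);
      sdv[i] = std::sqrt(8.0 * dt) / a;
      drift[i] = (i == tgt) ? dt : -dt;
      W[i] = 0.0;
      efac[i] = 1.0;
    }
  };

  auto finalize_epoch = [&]() {
    std::vector<double> contrib(n);
    for (int i = 0; i < n; ++i) {
      contrib[i] = a2[i] * W[i] / (2.0 + 2.0 * efac[i]);
      base[i] += contrib[i];
    }
    past.push_back(std::move(contrib));
    if (M_past >= 0) {
      while ((int)past.size() > M_past) {
        const std::vector<double>& old = past.front();
        for (int i = 0; i < n; ++i) base[i] -= old[i];
        past.pop_front();
      }
    }
  };

  // attention state
  double att_x = 0.0, att_y = 0.0;
  int att_node = -1; // nearest node for the center start (grid searchers)
  std::vector<int> att_idx;
  auto set_attention = [&](double x, double y, int node) {
    att_x = x; att_y = y; att_node = node;
    if (disc_attention) {
      att_idx.clear();
      for (int i = 0; i < n; ++i) {
        double dx = gx[i] - x, dy = gy[i] - y;
        if (dx * dx + dy * dy <= w2) att_idx.push_back(i);
      }
    } else if (node < 0) {
      // center start: attend the nearest grid node
      double best = R_PosInf;
      for (int i = 0; i < n; ++i) {
        double dx = gx[i] - x, dy = gy[i] - y;
        double d2 = dx * dx + dy * dy;
        if (d2 < best) { best = d2; att_node = i; }
      }
    }
  };

  // fixation bookkeeping
  std::vector<double> fix_x, fix_y, fix_start, fix_dur;
  std::vector<int> fix_node, fix_type; // type of the saccade INTO the fixation
  fix_x.push_back(0.0); fix_y.push_back(0.0);
  fix_start.push_back(0.0); fix_node.push_back(-1); fix_type.push_back(-1);

  std::deque<TimedEvent> moveQ, switchQ;
  double eye_x = 0.0, eye_y = 0.0;

  set_epoch_fields(0.0, 0.0);
  set_attention(0.0, 0.0, -1);

  int t_dec = 0;           // steps since the decision process started
  int sacc_ordinal = 0;    // saccades triggered so far
  bool express_pending = sacc_express[0] == 1;
  int express_steps = (int)std::lround(express_latency[0] / dt);

  bool stopped = false, truncated = false;
  double stop_pa = NA_REAL; int stop_att_n = NA_INTEGER;
  int response_node = NA_INTEGER;
  double stop_time = NA_REAL;
  double T_e = 0.0;

  auto posterior_now = [&](double& maxv, double& Z) {
    maxv = R_NegInf;
    for (int i = 0; i < n; ++i) {
      tot[i] = base[i] + a2[i] * W[i] / (2.0 + 2.0 * efac[i]);
      if (tot[i] > maxv) maxv = tot[i];
    }
    Z = 0.0;
    for (int i = 0; i < n; ++i) { P[i] = std::exp(tot[i] - maxv); Z += P[i]; }
    for (int i = 0; i < n; ++i) P[i] /= Z;
  };

  auto p_attend = [&]() {
    if (disc_attention) {
      double s = 0.0;
      for (size_t j = 0; j < att_idx.size(); ++j) s += P[att_idx[j]];
      return s;
    }
    return P[att_node];
  };

  auto select_target = [&]() {
    int best = -1;
    double best_score = R_NegInf, best_dist = R_PosInf;
    for (int c = 0; c < n; ++c) {
      double g = 0.0;
      const double* col = &d2mat[(size_t)c * n];
      for (int i = 0; i < n; ++i) g += P[i] * col[i];
      g *= 0.5;
      double dx = gx[c] - att_x, dy = gy[c] - att_y;
      double D = std::sqrt(dx * dx + dy * dy);
      double score = g;
      if (penalized && R_finite(sel_c)) {
        double Dp = D < 1.0 ? 1.0 : D;
        score = g * std::exp(-Dp / sel_c);
      }
      double rel = std::fabs(score - best_score);
      double tol = 1e-12 * (std::fabs(best_score) + 1e-300);
      if (score > best_score + tol) {
        best = c; best_score = score; best_dist = D;
      } else if (rel <= tol && (D < best_dist - 1e-12)) {
        best = c; best_score = score; best_dist = D;
      }
    }
    return best;
  };

  auto do_saccade = [&](int step, int type) -> bool {
    if ((int)fix_x.size() + (int)moveQ.size() + 1 > max_fixations) {
      truncated = true;
      return false;
    }
    int c = select_target();
    double nx = gx[c], ny = gy[c];
    int node = c;
    if (landing_enabled) {
      double dx = nx - att_x, dy = ny - att_y;
      double amp = std::sqrt(dx * dx + dy * dy);
      double s = landing_par[0] * amp + landing_par[1];
      double over = amp - landing_par[3];
      double b = over > 0.0 ? -over * landing_par[2] : 0.0;
      double mx = nx, my = ny;
      if (amp > 0.0) { mx += b * dx / amp; my += b * dy / amp; }
      bool ok = false;
      double lx = mx, ly = my;
      for (int att = 0; att < 100; ++att) {
        lx = mx + s * rng.rnorm();
        ly = my + s * rng.rnorm();
        if (lx * lx + ly * ly <= field_radius * field_radius) { ok = true; break; }
      }
      if (!ok) {
        double rr = std::sqrt(lx * lx + ly * ly);
        lx *= field_radius / rr; ly *= field_radius / rr;
      }
      nx = lx; ny = ly; node = -1;
    }
    TimedEvent mv; mv.step = step + lag_sac; mv.x = nx; mv.y = ny;
    mv.node = node; mv.sacc_type = type;
    moveQ.push_back(mv);
    TimedEvent sw; sw.step = step + lag_sac + lag_ebl; sw.x = nx; sw.y = ny;
    sw.node = node; sw.sacc_type = type;
    switchQ.push_back(sw);
    set_attention(nx, ny, node);
    // next decision process
    t_dec = 0;
    ++sacc_ordinal;
    int idx = sacc_ordinal < sacc_express.size() ? sacc_ordinal
                                                 : sacc_express.size() - 1;
    express_pending = sacc_express[idx] == 1;
    express_steps = (int)std::lround(express_latency[idx] / dt);
    return true;
  };

  auto exec_move = [&](const TimedEvent& mv) {
    fix_dur.push_back(mv.step * dt - fix_start.back());
    // fix_dur entry belongs to the fixation being left
    eye_x = mv.x; eye_y = mv.y;
    fix_x.push_back(mv.x); fix_y.push_back(mv.y);
    fix_start.push_back(mv.step * dt);
    fix_node.push_back(mv.node);
    fix_type.push_back(mv.sacc_type);
  };

  int step = 0;
  while (true) {
    ++step;
    if (step > max_steps) { truncated = true; break; }
    while (!moveQ.empty() && moveQ.front().step <= step) {
      exec_move(moveQ.front());
      moveQ.pop_front();
    }
    while (!switchQ.empty() && switchQ.front().step <= step) {
      finalize_epoch();
      set_epoch_fields(switchQ.front().x, switchQ.front().y);
      T_e = 0.0;
      switchQ.pop_front();
    }
    // evidence step
    T_e += dt;
    for (int i = 0; i < n; ++i) {
      efac[i] *= decay[i];
      W[i] = W[i] * decay[i] + drift[i] + sdv[i] * rng.rnorm();
    }
    ++t_dec;
    bool need_post = fixed_mode
      ? (int)std::lround(T_e / dt) >= fixed_steps
      : (t_dec >= lag_ebl || (express_pending && t_dec >= express_steps));
    if (need_post) {
      double maxv, Z;
      posterior_now(maxv, Z);
    }

    if (fixed_mode) {
      if ((int)std::lround(T_e / dt) >= fixed_steps) {
        double pa = p_attend();
        if (fix_node.back() >= 0 && pa > theta_T) {
          stopped = true;
          response_node = att_node + 1;
          stop_time = step * dt;
          break;
        }
        if (!do_saccade(step, 0)) break;
        // immediate move + evidence switch (no lags in fixed mode)
        exec_move(moveQ.front()); moveQ.pop_front();
        finalize_epoch();
        set_epoch_fields(switchQ.front().x, switchQ.front().y);
        T_e = 0.0;
        switchQ.pop_front();
      }
      continue;
    }

    bool can_eval = t_dec >= lag_ebl;
    if (can_eval) {
      double pa = p_attend();
      if (pa > theta_T) {
        stopped = true;
        stop_pa = pa; stop_att_n = disc_attention ? (int)att_idx.size() : -1;
        if (disc_attention) {
          int bi = 0;
          for (int i = 1; i < n; ++i) if (P[i] > P[bi]) bi = i;
          response_node = bi + 1;
        } else {
          response_node = att_node + 1;
        }
        stop_time = step * dt;
        break;
      }
      if (!express_pending && pa < theta_s(t_dec * dt, q1, q2, q3)) {
        if (!do_saccade(step, 0)) break;
        continue;
      }
    }
    if (express_pending && t_dec >= express_steps) {
      if (!do_saccade(step, 1)) break;
      continue;
    }
  }

  // duration of the last (possibly terminal) fixation
  double t_end = stopped ? stop_time : step * dt;
  fix_dur.push_back(t_end - fix_start.back());

  int nf = (int)fix_x.size();
  NumericMatrix fx(nf, 4);
  IntegerMatrix fi(nf, 2);
  for (int i = 0; i < nf; ++i) {
    fx(i, 0) = fix_x[i]; fx(i, 1) = fix_y[i];
    fx(i, 2) = fix_start[i]; fx(i, 3) = fix_dur[i];
    fi(i, 0) = fix_node[i] >= 0 ? fix_node[i] + 1 : NA_INTEGER;
    fi(i, 1) = fix_type[i] >= 0 ? fix_type[i] : NA_INTEGER;
  }
  bool correct = stopped && response_node != NA_INTEGER &&
                 response_node == target;
  return List::create(_["fix"] = fx, _["fix_node_type"] = fi,
                      _["stop_p_att"] = stop_pa,
                      _["final_logpost"] = NumericVector(tot.begin(), tot.end()),
                      _["final_base"] = NumericVector(base.begin(), base.end()),
                      _["stop_att_nodes"] = stop_att_n,
                      _["response_node"] = response_node,
                      _["correct"] = correct,
                      _["truncated"] = truncated,
                      _["stop_time"] = t_end,
                      _["n_fix"] = nf);
}
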