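// Hybrid deterministic-stochastic engine: deterministic ODE advance over each
// reporting interval dt, Poisson mutant injection, extinction clamping, and
// verdict classification. State layout is fixed across variants (D-layout):
//   y[0] = species-1 ancestor (A1)   y[1] = species-1 mutant (M1)
//   y[2] = species-2 ancestor (A2)   y[3] = species-2 mutant (M2)
// Single-species variants use species 1 only; in the cheater variant species 1
// is the cooperator and species 2 the cheater.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum Variant { BASELINE = 0, COOPERATION = 1, MUTUALISM = 2,
               MUTUALISM_NC = 3, CHEATER = 4 };

struct Pars {
  int variant;
  double rA1, rA2, rM1, rM2;
  double K, Nc, rho, delta;
  double mu1, mu2;
  double a, b;
  int smooth;      // 0 = step Allee response, 1 = smooth (Hill)
  double h;        // Hill steepness for the smooth form
  double dt;       // reporting / mutation interval
  double thr;      // extinction threshold
};

static Pars unpack(const NumericVector& p) {
  Pars q;
  q.variant = (int) p[0];
  q.rA1 = p[1];  q.rA2 = p[2];  q.rM1 = p[3];  q.rM2 = p[4];
  q.K = p[5];    q.Nc = p[6];   q.rho = p[7];  q.delta = p[8];
  q.mu1 = p[9];  q.mu2 = p[10]; q.a = p[11];   q.b = p[12];
  q.smooth = (int) p[13]; q.h = p[14]; q.dt = p[15]; q.thr = p[16];
  return q;
}

// Interpolates between the above-threshold multiplier `hi` and the
// below-threshold multiplier `lo` as a function of the reference density.
// Step form: strict '>' keeps the high branch, equality gets the reduced rate.
static inline double allee_mult(double hi, double lo, double Nref,
                                const Pars& p) {
  if (!p.smooth) return (Nref > p.Nc) ? hi : lo;
  double s;  // Hill weight Nref^h / (Nc^h + Nref^h)
  if (p.Nc <= 0.0) s = 1.0;
  else if (Nref <= 0.0) s = 0.0;
  else {
    double lr = p.h * (std::log(Nref) - std::log(p.Nc));
    if (lr > 700.0) s = 1.0;
    else if (lr < -700.0) s = 0.0;
    else { double e = std::exp(lr); s = e / (1.0 + e); }
  }
  return hi * s + lo * (1.0 - s);
}

static void rhs(const double* y, double* dy, const Pars& p, double delta) {
  const double A1 = y[0], M1 = y[1], A2 = y[2], M2 = y[3];
  const double NT1 = A1 + M1, NT2 = A2 + M2, NT = NT1 + NT2;
  const double lo = 1.0 - p.rho;

  switch (p.variant) {
  case BASELINE: case COOPERATION: {
    // growth-rate reference is the species' own total; baseline has no Allee
    double f = (p.variant == BASELINE) ? 1.0 : allee_mult(1.0, lo, NT1, p);
    double logi = 1.0 - NT1 / p.K;
    dy[0] = p.rA1 * f * A1 * logi - delta * A1;
    dy[1] = p.rM1 * f * M1 * logi - delta * M1;
    dy[2] = 0.0; dy[3] = 0.0;
    break;
  }
  case MUTUALISM: case MUTUALISM_NC: {
    // each species' growth-rate reference is its partner's total
    double f1 = allee_mult(1.0, lo, NT2, p);
    double f2 = allee_mult(1.0, lo, NT1, p);
    double logi1, logi2;
    if (p.variant == MUTUALISM) {
      logi1 = 1.0 - NT / p.K; logi2 = logi1;       // shared resources
    } else {
      logi1 = 1.0 - NT1 / p.K; logi2 = 1.0 - NT2 / p.K;  // no competition
    }
    dy[0] = p.rA1 * f1 * A1 * logi1 - delta * A1;
    dy[1] = p.rM1 * f1 * M1 * logi1 - delta * M1;
    dy[2] = p.rA2 * f2 * A2 * logi2 - delta * A2;
    dy[3] = p.rM2 * f2 * M2 * logi2 - delta * M2;
    break;
  }
  case CHEATER: {
    // reference is the cooperator total; cheaters gain (1+b) above Nc and
    // suffer (1-rho)(1-a) below; logistic crowding from the grand total
    double Ncoop = NT1;
    double fc = allee_mult(1.0, lo, Ncoop, p);
    double fq = allee_mult(1.0 + p.b, lo * (1.0 - p.a), Ncoop, p);
    double logi = 1.0 - NT / p.K;
    dy[0] = p.rA1 * fc * A1 * logi - delta * A1;
    dy[1] = p.rM1 * fc * M1 * logi - delta * M1;
    dy[2] = p.rA2 * fq * A2 * logi - delta * A2;
    dy[3] = p.rM2 * fq * M2 * logi - delta * M2;
    break;
  }
  default:
    stop("unknown model variant code");
  }
}

// Cash-Karp embedded RK45 with adaptive step control over one interval.
static void integrate_interval(double* y, double len, const Pars& p,
                               double delta, double rtol, double atol) {
  static const double
    b21 = 1.0/5.0,
    b31 = 3.0/40.0,       b32 = 9.0/40.0,
    b41 = 3.0/10.0,       b42 = -9.0/10.0,  b43 = 6.0/5.0,
    b51 = -11.0/54.0,     b52 = 5.0/2.0,    b53 = -70.0/27.0, b54 = 35.0/27.0,
    b61 = 1631.0/55296.0, b62 = 175.0/512.0, b63 = 575.0/13824.0,
    b64 = 44275.0/110592.0, b65 = 253.0/4096.0,
    c1 = 37.0/378.0, c3 = 250.0/621.0, c4 = 125.0/594.0, c6 = 512.0/1771.0,
    d1 = 2825.0/27648.0, d3 = 18575.0/48384.0, d4 = 13525.0/55296.0,
    d5 = 277.0/14336.0, d6 = 1.0/4.0;

  double t = 0.0, hstep = len;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], yt[4], y5[4], y4[4];
  int iter = 0;
  while (t < len) {
    if (hstep > len - t) hstep = len - t;
    rhs(y, k1, p, delta);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + hstep * b21 * k1[i];
    rhs(yt, k2, p, delta);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + hstep * (b31 * k1[i] + b32 * k2[i]);
    rhs(yt, k3, p, delta);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + hstep * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    rhs(yt, k4, p, delta);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + hstep * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i]
                              + b54 * k4[i]);
    rhs(yt, k5, p, delta);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + hstep * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i]
                              + b64 * k4[i] + b65 * k5[i]);
    rhs(yt, k6, p, delta);
    double errmax = 0.0;
    for (int i = 0; i < 4; ++i) {
      y5[i] = y[i] + hstep * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i]
                              + c6 * k6[i]);
      y4[i] = y[i] + hstep * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i]
                              + d5 * k5[i] + d6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(y5[i] - y4[i]) / sc;
      if (e > errmax) errmax = e;
      if (!std::isfinite(y5[i]))
        stop("integrator failure: non-finite state at interval time %g", t);
    }
    if (errmax <= 1.0) {
      t += hstep;
      for (int i = 0; i < 4; ++i) y[i] = y5[i];
      double fac = (errmax > 0.0)
        ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      hstep *= std::min(5.0, fac);
    } else {
      hstep *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
    }
    if (++iter > 100000)
      stop("integrator failure: step count exceeded within one interval");
  }
  for (int i = 0; i < 4; ++i) if (y[i] < 0.0) y[i] = 0.0;
}

// [[Rcpp::export]]
NumericVector engine_rhs(NumericVector y, NumericVector pack, double delta) {
  Pars p = unpack(pack);
  double dy[4];
  rhs(REAL(y), dy, p, delta);
  return NumericVector::create(dy[0], dy[1], dy[2], dy[3]);
}

// [[Rcpp::export]]
NumericVector engine_advance(NumericVector y, NumericVector pack, double len,
                             double delta, double rtol = 1e-8,
                             double atol = 1e-10) {
  Pars p = unpack(pack);
  NumericVector out = clone(y);
  integrate_interval(REAL(out), len, p, delta, rtol, atol);
  return out;
}

// Runs the hybrid loop from t0 to t_end. `mutation` enables Poisson arrivals
// (drawn from R's RNG: reproducible under set.seed), `verdict_check` enables
// rescue/extinction classification. Returns verdict code 0 = none/undecided,
// 1 = rescued, 2 = extinct.
// [[Rcpp::export]]
List engine_run(NumericVector y0, NumericVector pack, double t0, double t_end,
                double delta, bool mutation, bool verdict_check,
                int record_stride, double rtol = 1e-8, double atol = 1e-10) {
  Pars p = unpack(pack);
  double y[4] = { y0[0], y0[1], y0[2], y0[3] };
  const bool two_species = (p.variant == MUTUALISM || p.variant == MUTUALISM_NC
                            || p.variant == CHEATER);
  const double rescue_thr = std::max(p.Nc, p.thr);

  long n_steps = (long) std::ceil((t_end - t0) / p.dt - 1e-9);
  if (n_steps < 0) n_steps = 0;

  std::vector<double> ev_t, ev_sp, ev_n;
  std::vector<double> tr;
  bool record = record_stride > 0;
  if (record) {
    tr.reserve(5 * (n_steps / record_stride + 2));
    tr.push_back(t0);
    for (int i = 0; i < 4; ++i) tr.push_back(y[i]);
  }

  int verdict = 0;
  double verdict_time = NA_REAL;
  double t = t0;

  for (long s = 1; s <= n_steps; ++s) {
    const double A1s = y[0], A2s = y[2];  // ancestor sizes at interval start
    integrate_interval(y, p.dt, p, delta, rtol, atol);
    t = t0 + s * p.dt;

    if (mutation) {
      if (p.mu1 > 0.0 && A1s > 0.0) {
        double m = R::rpois(p.mu1 * A1s * p.dt);
        if (m > 0) { y[1] += m; ev_t.push_back(t); ev_sp.push_back(1);
                     ev_n.push_back(m); }
      }
      if (two_species && p.mu2 > 0.0 && A2s > 0.0) {
        double m = R::rpois(p.mu2 * A2s * p.dt);
        if (m > 0) { y[3] += m; ev_t.push_back(t); ev_sp.push_back(2);
                     ev_n.push_back(m); }
      }
    }

    for (int i = 0; i < 4; ++i) if (y[i] < p.thr) y[i] = 0.0;

    if (record && (s % record_stride == 0 || s == n_steps)) {
      tr.push_back(t);
      for (int i = 0; i < 4; ++i) tr.push_back(y[i]);
    }

    if (verdict_check) {
      bool extinct = (y[0] == 0.0 && y[1] == 0.0 && y[2] == 0.0
                      && y[3] == 0.0);
      if (extinct) { verdict = 2; verdict_time = t; break; }
      switch (p.variant) {
      case BASELINE: case COOPERATION:
        if (y[1] >= rescue_thr) { verdict = 1; verdict_time = t; }
        break;
      case MUTUALISM: case MUTUALISM_NC:
        if (y[1] >= rescue_thr && y[3] >= rescue_thr) {
          verdict = 1; verdict_time = t;
        }
        break;
      case CHEATER:
        // adapted cheaters can still crash a risen cooperator mutant, so the
        // verdict is only final once the cheater compartments are gone
        if (y[1] >= rescue_thr && y[2] == 0.0 && y[3] == 0.0) {
          verdict = 1; verdict_time = t;
        }
        break;
      }
      if (verdict != 0) break;
    }
    if (s % 16384 == 0) Rcpp::checkUserInterrupt();
  }

  // cheater runs that persist to t_end: rescued iff the cooperator mutant
  // holds the critical size at the horizon
  if (verdict_check && verdict == 0 && p.variant == CHEATER
      && y[1] >= rescue_thr) {
    verdict = 1; verdict_time = t;
  }

  NumericMatrix events(ev_t.size(), 3);
  for (size_t i = 0; i < ev_t.size(); ++i) {
    events(i, 0) = ev_t[i]; events(i, 1) = ev_sp[i]; events(i, 2) = ev_n[i];
  }
  colnames(events) = CharacterVector::create("time", "species", "count");

  List out = List::create(
    _["verdict"] = verdict,
    _["verdict_time"] = verdict_time,
    _["t_final"] = t,
    _["y_final"] = NumericVector::create(y[0], y[1], y[2], y[3]),
    _["events"] = events);
  if (record) {
    size_t nrec = tr.size() / 5;
    NumericMatrix traj(nrec, 5);
    for (size_t i = 0; i < nrec; ++i)
      for (int j = 0; j < 5; ++j) traj(i, j) = tr[5 * i + j];
    colnames(traj) = CharacterVector::create("t", "A1", "M1", "A2", "M2");
    out["trajectory"] = traj;
  }
  return out;
}
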