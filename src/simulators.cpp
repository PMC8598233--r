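// Stochastic cores: overdamped Langevin integration for the droplet (LPM)
// model, event-resolved binding-site (PBM) dynamics, and first-passage loops.
// Units: lengths in um, times in s, diffusivities in um^2/s, kBT = 1.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  explicit Rng(uint64_t seed) : eng(seed), norm(0.0, 1.0), unif(0.0, 1.0) {}
  double gauss() { return norm(eng); }
  double runif() { return unif(eng); }
};

inline double norm3(const double* x) {
  return std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
}

// Radial mirror into the ball of radius R: |x'| = 2R - |x|, direction kept.
// Steps are always << R, so one pass almost always suffices; guard anyway.
inline void reflect_ball(double* x, double R) {
  double r = norm3(x);
  int guard = 0;
  while (r > R && guard++ < 64) {
    if (r > 3.0 * R) stop("reflection: step carried particle beyond 3R; decrease dt");
    double rnew = std::fabs(2.0 * R - r);
    double s = (r > 0.0) ? rnew / r : 0.0;
    x[0] *= s; x[1] *= s; x[2] *= s;
    r = rnew;
  }
}

inline void wrap_box(double* x, double L) {
  for (int k = 0; k < 3; ++k) x[k] -= L * std::round(x[k] / L);
}

// Sigmoidal droplet profiles D(r), U(r) and the radial derivatives needed by
// the integrator (evaluated analytically, never by finite differences).
struct LpmProfile {
  double D0, Dn, A, b, rf;
  inline void eval(double r, double& D, double& Dp, double& Up) const {
    double z = b * (r - rf), s;
    if (z > 0) { double e = std::exp(-z); s = 1.0 / (1.0 + e); }
    else       { double e = std::exp(z);  s = e / (1.0 + e); }
    double sp = b * s * (1.0 - s);
    D  = D0 + (Dn - D0) * s;
    Dp = (Dn - D0) * sp;
    Up = A * sp;
  }
};

// One Ito step with spurious drift grad(D), force -D*grad(U), and the Milstein
// multiplicative-noise correction applied along the radial direction.
inline void lpm_step(double* x, const LpmProfile& P, double dt, double sq_dt,
                     double rn, Rng& rng, bool milstein) {
  double r = norm3(x);
  double D, Dp, Up;
  P.eval(r, D, Dp, Up);
  double driftr = Dp - D * Up;  // kBT = 1
  double sq2D = std::sqrt(2.0 * D);
  double inv_r = (r > 1e-12) ? 1.0 / r : 0.0;
  double y[3];
  for (int k = 0; k < 3; ++k) {
    double g = rng.gauss();
    double u = x[k] * inv_r;
    double dx = driftr * u * dt + sq2D * g * sq_dt;
    if (milstein) dx += 0.5 * Dp * u * (g * g - 1.0) * dt;
    y[k] = x[k] + dx;
  }
  reflect_ball(y, rn);
  x[0] = y[0]; x[1] = y[1]; x[2] = y[2];
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_lpm(NumericVector start, double rf, double rn, double D0,
                      double Dn, double A, double b, double dt, double n_steps,
                      int record_every, double seed, bool milstein) {
  LpmProfile P{D0, Dn, A, b, rf};
  Rng rng(static_cast<uint64_t>(seed));
  double x[3] = {start[0], start[1], start[2]};
  long long ns = static_cast<long long>(n_steps);
  long long nrec = ns / record_every + 1;
  NumericMatrix pos(nrec, 3);
  NumericVector tt(nrec);
  double sq_dt = std::sqrt(dt);
  long long irec = 0;
  pos(0, 0) = x[0]; pos(0, 1) = x[1]; pos(0, 2) = x[2]; tt[0] = 0.0; irec = 1;
  for (long long s = 1; s <= ns; ++s) {
    lpm_step(x, P, dt, sq_dt, rn, rng, milstein);
    if (s % record_every == 0 && irec < nrec) {
      pos(irec, 0) = x[0]; pos(irec, 1) = x[1]; pos(irec, 2) = x[2];
      tt[irec] = s * dt;
      ++irec;
    }
  }
  return List::create(_["t"] = tt, _["pos"] = pos);
}

// [[Rcpp::export]]
NumericVector cpp_fpt_lpm(NumericMatrix starts, double r0, double rf, double rn,
                          double D0, double Dn, double A, double b, double dt,
                          double seed, double max_steps) {
  LpmProfile P{D0, Dn, A, b, rf};
  Rng rng(static_cast<uint64_t>(seed));
  int n = starts.nrow();
  NumericVector out(n);
  double sq_dt = std::sqrt(dt);
  long long cap = static_cast<long long>(max_steps);
  for (int i = 0; i < n; ++i) {
    double x[3] = {starts(i, 0), starts(i, 1), starts(i, 2)};
    long long s = 0;
    bool hit = false;
    while (s < cap) {
      ++s;
      lpm_step(x, P, dt, sq_dt, rn, rng, true);
      if (norm3(x) <= r0) { hit = true; break; }
    }
    out[i] = hit ? s * dt : NA_REAL;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

namespace {

// Event-resolved PBM core. Binding sites (and inert crowders) live in the
// focus ball (or a periodic box in bulk mode) and diffuse at Db. Far sites
// are advanced lazily: a site untouched for `lag` steps takes one Gaussian
// step of variance 2*Db*lag*dt (exact for unconfined stretches). A Verlet
// neighbour list with a conservative displacement budget guarantees no
// tracer-site contact is ever missed.
struct PbmCore {
  double rf, rn, Dn, Db, rb, pb, koff_dt, dt, sq_dt, sqDb_dt;
  bool bulk;
  double L;        // box side (bulk mode)
  int n_bind, n_tot;
  std::vector<double> cx, cy, cz;
  std::vector<long long> upd;   // last step at which site i was advanced
  std::vector<int> nbr;
  long long step_now;
  long long last_rebuild;
  double xr[3];                 // tracer position at last rebuild
  double x[3];
  int bound;                    // site index or -1
  double off[3];                // tracer offset from its site while bound
  Rng rng;

  PbmCore(uint64_t seed) : rng(seed) {}

  inline void delta(double ax, double ay, double az, double bx, double by,
                    double bz, double* d) const {
    d[0] = ax - bx; d[1] = ay - by; d[2] = az - bz;
    if (bulk) for (int k = 0; k < 3; ++k) d[k] -= L * std::round(d[k] / L);
  }

  inline void confine_site(int i) {
    double c[3] = {cx[i], cy[i], cz[i]};
    if (bulk) wrap_box(c, L); else reflect_ball(c, rf);
    cx[i] = c[0]; cy[i] = c[1]; cz[i] = c[2];
  }

  inline void advance_site(int i, long long to_step) {
    long long lag = to_step - upd[i];
    if (lag <= 0) { upd[i] = to_step; return; }
    upd[i] = to_step;
    if (Db <= 0.0) return;
    double sd = std::sqrt(2.0 * Db * dt * static_cast<double>(lag));
    cx[i] += sd * rng.gauss();
    cy[i] += sd * rng.gauss();
    cz[i] += sd * rng.gauss();
    confine_site(i);
  }

  double rcut() const { return rb + 0.015; }

  // Allowed tracer excursion from the rebuild point before any stale site
  // could possibly be touched (accounts for 5-sigma site drift, capped by
  // confinement).
  double budget() const {
    double base = rcut() - rb;
    if (!bulk) {
      double rr = norm3(xr);
      double dfocus = rr - rf - rb;
      if (dfocus > base) base = dfocus;
    }
    return base;
  }

  double site_drift(long long lag) const {
    if (Db <= 0.0) return 0.0;
    double d = 5.0 * std::sqrt(6.0 * Db * dt * static_cast<double>(lag));
    double cap = bulk ? 0.5 * L : 2.0 * rf;
    return d < cap ? d : cap;
  }

  void rebuild() {
    nbr.clear();
    double rc = rcut();
    double d[3];
    for (int i = 0; i < n_tot; ++i) {
      double reach = site_drift(step_now - upd[i]);
      delta(x[0], x[1], x[2], cx[i], cy[i], cz[i], d);
      double dist = norm3(d);
      if (dist < rc + reach) {
        advance_site(i, step_now);
        delta(x[0], x[1], x[2], cx[i], cy[i], cz[i], d);
        if (norm3(d) < rc) nbr.push_back(i);
      }
    }
    last_rebuild = step_now;
    xr[0] = x[0]; xr[1] = x[1]; xr[2] = x[2];
  }

  inline bool need_rebuild(const double* y) const {
    double d[3];
    delta(y[0], y[1], y[2], xr[0], xr[1], xr[2], d);
    return norm3(d) + site_drift(step_now - last_rebuild) >= budget();
  }

  // One time step; returns true if the tracer is bound after the step.
  inline void step() {
    ++step_now;
    if (bound >= 0) {
      // tracer rides its binding site
      advance_site(bound, step_now);
      double c[3] = {cx[bound], cy[bound], cz[bound]};
      for (int k = 0; k < 3; ++k) x[k] = c[k] + off[k];
      if (bulk) wrap_box(x, L);
      if (rng.runif() < koff_dt) {
        bound = -1;
        last_rebuild = -1;  // force rebuild on next unbound step
      }
      return;
    }
    double y[3];
    for (int k = 0; k < 3; ++k) y[k] = x[k] + sqDb_free() * rng.gauss();
    if (last_rebuild < 0 || need_rebuild(y)) rebuild();
    // advance current neighbours to now so collision geometry is current
    if (Db > 0.0) for (int i : nbr) advance_site(i, step_now);
    // collision resolution: nearest site first, reflect or absorb, re-test
    double d[3];
    for (int iter = 0; iter < 16; ++iter) {
      int imin = -1;
      double dmin = rb;
      for (int i : nbr) {
        delta(y[0], y[1], y[2], cx[i], cy[i], cz[i], d);
        double dist = norm3(d);
        if (dist < dmin) { dmin = dist; imin = i; }
      }
      if (imin < 0) break;
      delta(y[0], y[1], y[2], cx[imin], cy[imin], cz[imin], d);
      double dist = norm3(d);
      if (dist < 1e-12) { d[0] = rb; d[1] = 0; d[2] = 0; dist = rb; }
      if (imin < n_bind && rng.runif() < pb) {
        // absorb at the intersection with the site surface
        for (int k = 0; k < 3; ++k) off[k] = d[k] * (rb / dist);
        bound = imin;
        x[0] = cx[imin] + off[0]; x[1] = cy[imin] + off[1]; x[2] = cz[imin] + off[2];
        if (bulk) wrap_box(x, L);
        return;
      }
      // partial reflection: new distance to this site centre is 2 rb - dist
      double scale = (2.0 * rb - dist) / dist;
      y[0] = cx[imin] + d[0] * scale;
      y[1] = cy[imin] + d[1] * scale;
      y[2] = cz[imin] + d[2] * scale;
    }
    if (bulk) wrap_box(y, L); else reflect_ball(y, rn);
    x[0] = y[0]; x[1] = y[1]; x[2] = y[2];
  }

  inline double sqDb_free() const { return sq2Dn_dt; }
  double sq2Dn_dt;

  void init(NumericVector start, NumericMatrix sites, int n_bind_, double rf_,
            double rn_, double Dn_, double Db_, double rb_, double pb_,
            double koff, double dt_, bool bulk_, double L_) {
    rf = rf_; rn = rn_; Dn = Dn_; Db = Db_; rb = rb_; pb = pb_;
    dt = dt_; koff_dt = koff * dt_;
    sq_dt = std::sqrt(dt);
    sq2Dn_dt = std::sqrt(2.0 * Dn * dt);
    bulk = bulk_; L = L_;
    n_bind = n_bind_;
    n_tot = sites.nrow();
    cx.resize(n_tot); cy.resize(n_tot); cz.resize(n_tot);
    upd.assign(n_tot, 0);
    for (int i = 0; i < n_tot; ++i) {
      cx[i] = sites(i, 0); cy[i] = sites(i, 1); cz[i] = sites(i, 2);
    }
    x[0] = start[0]; x[1] = start[1]; x[2] = start[2];
    bound = -1;
    step_now = 0;
    last_rebuild = -1;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_pbm(NumericVector start, NumericMatrix sites, int n_bind,
                      double rf, double rn, double Dn, double Db, double rb,
                      double pb, double k_off, double dt, double n_steps,
                      int record_every, double seed, bool bulk, double box) {
  PbmCore core(static_cast<uint64_t>(seed));
  core.init(start, sites, n_bind, rf, rn, Dn, Db, rb, pb, k_off, dt, bulk, box);
  long long ns = static_cast<long long>(n_steps);
  long long nrec = ns / record_every + 1;
  NumericMatrix pos(nrec, 3);
  IntegerVector bnd(nrec);
  NumericVector tt(nrec);
  pos(0, 0) = core.x[0]; pos(0, 1) = core.x[1]; pos(0, 2) = core.x[2];
  bnd[0] = 0; tt[0] = 0.0;
  long long irec = 1;
  for (long long s = 1; s <= ns; ++s) {
    core.step();
    if (s % record_every == 0 && irec < nrec) {
      pos(irec, 0) = core.x[0]; pos(irec, 1) = core.x[1]; pos(irec, 2) = core.x[2];
      bnd[irec] = core.bound >= 0 ? 1 : 0;
      tt[irec] = s * dt;
      ++irec;
    }
    if (s % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  // final site positions (synced) for inspection / chained runs
  NumericMatrix sites_out(core.n_tot, 3);
  for (int i = 0; i < core.n_tot; ++i) {
    core.advance_site(i, core.step_now);
    sites_out(i, 0) = core.cx[i]; sites_out(i, 1) = core.cy[i];
    sites_out(i, 2) = core.cz[i];
  }
  return List::create(_["t"] = tt, _["pos"] = pos, _["bound"] = bnd,
                      _["sites"] = sites_out);
}

// [[Rcpp::export]]
NumericVector cpp_fpt_pbm(NumericMatrix starts, int n_sites, double r0,
                          double rf, double rn, double Dn, double Db, double rb,
                          double pb, double k_off, double dt, double seed,
                          double max_steps) {
  Rng site_rng(static_cast<uint64_t>(seed) ^ 0x9e3779b97f4a7c15ULL);
  int n = starts.nrow();
  NumericVector out(n);
  long long cap = static_cast<long long>(max_steps);
  for (int i = 0; i < n; ++i) {
    // fresh uniform-in-ball site configuration per trajectory
    NumericMatrix sites(n_sites, 3);
    for (int j = 0; j < n_sites; ++j) {
      double p[3];
      do {
        p[0] = (2.0 * site_rng.runif() - 1.0) * rf;
        p[1] = (2.0 * site_rng.runif() - 1.0) * rf;
        p[2] = (2.0 * site_rng.runif() - 1.0) * rf;
      } while (norm3(p) > rf);
      sites(j, 0) = p[0]; sites(j, 1) = p[1]; sites(j, 2) = p[2];
    }
    PbmCore core(static_cast<uint64_t>(seed) + 1315423911u * (i + 1));
    NumericVector st = NumericVector::create(starts(i, 0), starts(i, 1), starts(i, 2));
    core.init(st, sites, n_sites, rf, rn, Dn, Db, rb, pb, k_off, dt, false, 0.0);
    long long s = 0;
    bool hit = false;
    while (s < cap) {
      ++s;
      core.step();
      if (norm3(core.x) <= r0) { hit = true; break; }
    }
    out[i] = hit ? s * dt : NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
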