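// Event-driven (Gillespie) lattice-gas engine for PomZ dimers elastically
// tethering the PomXY cluster to a 1D nucleoid lattice.
//
// State: cluster position x_c (continuous, overdamped, no Langevin noise),
// dimers with a nucleoid lattice site and, when cluster-bound, a cluster
// lattice site that translates rigidly with the cluster. Between events all
// rates are frozen at their values at the event time; the cluster advances
// by the exact exponential relaxation of the total tether stretch.
//
// Rate bookkeeping exploits that for a bound dimer with stretch s all four
// hop rates are eps0 * kap * u^{+-1} with u = exp(-k a s / (2 kBT)) and
// kap = exp(-k a^2 / (4 kBT)); a cluster displacement dx multiplies every
// bound dimer's u by the same factor exp(-k a dx / (2 kBT)).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double LOG_PRUNE = 27.631021115928547; // -log(1e-12)

struct Pars {
  double L, Lc, a, k, kBT, kon, ka0, kh, koff, Dn, Dc, gam, Fext, lam;
  int Ntot;
  double tmin;
  bool infinite;
  // derived
  int64_t nL, nC;
  double epsn, epsc;  // bare hop rates D/a^2
  double c1;          // k a / (2 kBT): u = exp(-c1 * s)
  double kap;         // exp(-k a^2 / (4 kBT))
  double kap2;        // kap^2 = exp(-k a^2 / (2 kBT)) = u-shift per lattice hop
  double cut;         // binding reach: |offset| <= cut keeps Boltzmann >= 1e-12
};

static Pars read_pars(const List& pl) {
  Pars p;
  p.L = pl["L"]; p.Lc = pl["L_c"]; p.a = pl["a"];
  p.k = pl["k"]; p.kBT = pl["kBT"];
  p.kon = pl["k_on"]; p.ka0 = pl["ka0"]; p.kh = pl["k_h"]; p.koff = pl["k_off"];
  p.Dn = pl["D_nuc"]; p.Dc = pl["D_clu"]; p.gam = pl["gamma_c"];
  p.Fext = pl["F_ext"]; p.lam = pl["lambda_null"];
  p.Ntot = as<int>(pl["N_total"]);
  p.tmin = pl["t_min"];
  p.infinite = as<bool>(pl["infinite_lattice"]);
  p.nL = (int64_t) std::llround(p.L / p.a);
  p.nC = (int64_t) std::llround(p.Lc / p.a);
  p.epsn = p.Dn / (p.a * p.a);
  p.epsc = p.Dc / (p.a * p.a);
  p.c1 = p.k * p.a / (2.0 * p.kBT);
  p.kap = std::exp(-p.k * p.a * p.a / (4.0 * p.kBT));
  p.kap2 = p.kap * p.kap;
  p.cut = (p.k > 0) ? std::sqrt(2.0 * p.kBT * LOG_PRUNE / p.k) : p.L;
  return p;
}

// Total spring-weighted binding propensity (sum of Eq-1 rates over cluster
// sites) as a function of d = x_nuc - x_c, tabulated on a fine grid.
struct ZTable {
  double dmin, step, inv_step;
  std::vector<double> v;
  void build(const Pars& p) {
    double range = p.Lc / 2.0 + p.cut + 2.0 * p.a;
    step = p.a / 64.0;
    inv_step = 1.0 / step;
    dmin = -range;
    int64_t n = (int64_t)std::ceil(2.0 * range / step) + 2;
    v.assign((size_t)n, 0.0);
    double pref = p.k / (2.0 * p.kBT);
    for (int64_t i = 0; i < n; ++i) {
      double d = dmin + step * (double)i;
      double z = 0.0;
      for (int64_t j = 0; j < p.nC; ++j) {
        double o = -p.Lc / 2.0 + p.a * ((double)j + 0.5);
        double e = pref * (o - d) * (o - d);
        if (e < LOG_PRUNE) z += std::exp(-e);
      }
      v[(size_t)i] = z;
    }
  }
  inline double operator()(double d) const {
    double x = (d - dmin) * inv_step;
    if (x <= 0.0 || x >= (double)(v.size() - 1)) return 0.0;
    int64_t i = (int64_t)x;
    double f = x - (double)i;
    return v[(size_t)i] * (1.0 - f) + v[(size_t)i + 1] * f;
  }
};

enum EvType { EV_HOP_NL, EV_HOP_NR, EV_HOP_CL, EV_HOP_CR,
              EV_HYD, EV_KOFF, EV_BIND, EV_ATTACH, EV_NULL };

struct Dimer {
  int64_t inuc;   // nucleoid site index
  int64_t joff;   // cluster site index; -1 if not cluster-bound
  double u;       // exp(-c1 * stretch), valid while bound
  int side;       // nucleoid side (relative to x_c) where the dimer attached
};

struct Engine {
  Pars p;
  ZTable ztab;
  double t, x_c;
  int n_cyto;
  std::vector<Dimer> dim;     // dimers currently on the nucleoid
  int nB;                     // number of cluster-bound dimers
  double Sxn, Soff;           // sums over bound dimers of x_nuc and offset
  bool cluster_mobile;
  // flat propensity catalogue, rebuilt each step
  std::vector<double> props;
  std::vector<int> ptype;
  std::vector<int> pidx;
  // accumulators
  bool acc_on;
  std::vector<double> dens_free, dens_bound;  // time-integrated occupancy
  std::vector<double> flux_net;               // net crossings per interior edge
  double acc_T, acc_F, acc_nB, acc_nFree;
  // cluster-relative accumulation (windowed dynamic profiles)
  bool rel_on;
  std::vector<double> rel_free, rel_bound, rel_flux;
  // event log
  int log_left;
  std::vector<double> log_t, log_dt, log_alpha;
  // stretch sampling
  double samp_dt, samp_next;
  std::vector<double> samp_s;
  int64_t steps_since_refresh;
  // event counters
  int64_t n_attach_ev, n_bind_ev, n_hyd_ev, n_koff_ev;

  double xn_of(const Dimer& d) const { return p.a * ((double)d.inuc + 0.5); }
  double off_of(const Dimer& d) const {
    return -p.Lc / 2.0 + p.a * ((double)d.joff + 0.5);
  }
  double stretch_of(const Dimer& d) const {
    return x_c + off_of(d) - xn_of(d);
  }

  void init(const Pars& pars) {
    p = pars;
    if (!p.infinite && p.ka0 > 0) ztab.build(p);
    t = 0.0; nB = 0; Sxn = 0.0; Soff = 0.0;
    n_cyto = p.Ntot;
    dim.clear();
    acc_on = false; rel_on = false;
    acc_T = acc_F = acc_nB = acc_nFree = 0.0;
    log_left = 0;
    samp_dt = 0.0;
    steps_since_refresh = 0;
    n_attach_ev = n_bind_ev = n_hyd_ev = n_koff_ev = 0;
  }

  void start_accumulate() {
    acc_on = true;
    size_t n = (size_t)p.nL;
    if (dens_free.empty()) {
      dens_free.assign(n, 0.0);
      dens_bound.assign(n, 0.0);
      flux_net.assign(n + 1, 0.0);
    }
    if (rel_on && rel_free.empty()) {
      rel_free.assign(n, 0.0);
      rel_bound.assign(n, 0.0);
      rel_flux.assign(n + 1, 0.0);
    }
  }

  void refresh_cached() {
    // re-derive u and the stretch sums from scratch (kills FP drift)
    Sxn = 0.0; Soff = 0.0;
    for (auto& d : dim) {
      if (d.joff != INT64_MIN) {
        double s = stretch_of(d);
        d.u = std::exp(-p.c1 * s);
        Sxn += xn_of(d);
        Soff += off_of(d);
      }
    }
    steps_since_refresh = 0;
  }

  inline bool bound(const Dimer& d) const { return d.joff != INT64_MIN; }

  // closed-form cluster position after time tau with frozen assignments
  inline double x_at(double tau) const {
    if (!cluster_mobile) return x_c;
    if (nB == 0) return x_c + p.Fext * tau / p.gam;
    // total stretch S = nB * x_c + (Soff - Sxn); x_eq solves 0 = -k S + Fext
    double x_eq = (p.Fext / p.k - (Soff - Sxn)) / (double)nB;
    return x_eq + (x_c - x_eq) * std::exp(-(double)nB * p.k * tau / p.gam);
  }

  double build_props() {
    props.clear(); ptype.clear(); pidx.clear();
    double alpha = 0.0;
    const int n = (int)dim.size();
    for (int i = 0; i < n; ++i) {
      const Dimer& d = dim[i];
      if (bound(d)) {
        double rl = p.epsn * p.kap * d.u;        // nucleoid hop left: s -> s + a
        double rr = p.epsn * p.kap / d.u;        // nucleoid hop right: s -> s - a
        double cl = p.epsc * p.kap / d.u;        // cluster-site hop left: s -> s - a
        double cr = p.epsc * p.kap * d.u;        // cluster-site hop right: s -> s + a
        if (!p.infinite) {
          if (d.inuc <= 0) rl = 0.0;
          if (d.inuc >= p.nL - 1) rr = 0.0;
          if (d.joff <= 0) cl = 0.0;             // reflecting cluster edges
          if (d.joff >= p.nC - 1) cr = 0.0;
        }
        if (rl > 0) { props.push_back(rl); ptype.push_back(EV_HOP_NL); pidx.push_back(i); alpha += rl; }
        if (rr > 0) { props.push_back(rr); ptype.push_back(EV_HOP_NR); pidx.push_back(i); alpha += rr; }
        if (cl > 0) { props.push_back(cl); ptype.push_back(EV_HOP_CL); pidx.push_back(i); alpha += cl; }
        if (cr > 0) { props.push_back(cr); ptype.push_back(EV_HOP_CR); pidx.push_back(i); alpha += cr; }
        if (p.kh > 0) { props.push_back(p.kh); ptype.push_back(EV_HYD); pidx.push_back(i); alpha += p.kh; }
      } else {
        double rl = (p.infinite || d.inuc > 0) ? p.epsn : 0.0;
        double rr = (p.infinite || d.inuc < p.nL - 1) ? p.epsn : 0.0;
        if (rl > 0) { props.push_back(rl); ptype.push_back(EV_HOP_NL); pidx.push_back(i); alpha += rl; }
        if (rr > 0) { props.push_back(rr); ptype.push_back(EV_HOP_NR); pidx.push_back(i); alpha += rr; }
        if (p.koff > 0) { props.push_back(p.koff); ptype.push_back(EV_KOFF); pidx.push_back(i); alpha += p.koff; }
        if (p.ka0 > 0 && !p.infinite) {
          double z = ztab(xn_of(d) - x_c);
          if (z > 0) {
            double rb = p.ka0 * z;
            props.push_back(rb); ptype.push_back(EV_BIND); pidx.push_back(i); alpha += rb;
          }
        }
      }
    }
    if (p.kon > 0 && n_cyto > 0 && !p.infinite) {
      double ra = p.kon * (double)n_cyto * (p.L - p.Lc) / p.L;
      props.push_back(ra); ptype.push_back(EV_ATTACH); pidx.push_back(-1); alpha += ra;
    }
    if (p.lam > 0) {
      props.push_back(p.lam); ptype.push_back(EV_NULL); pidx.push_back(-1); alpha += p.lam;
    }
    return alpha;
  }

  void accumulate(double dt) {
    if (!acc_on || dt <= 0) return;
    acc_T += dt;
    acc_nB += (double)nB * dt;
    acc_nFree += (double)((int)dim.size() - nB) * dt;
    acc_F += -p.k * ((double)nB * x_c + Soff - Sxn) * dt;
    if (p.infinite) return;
    for (const auto& d : dim) {
      double x = bound(d) ? (x_c + off_of(d)) : xn_of(d);
      int64_t b = (int64_t)std::floor(x / p.a);
      if (b >= 0 && b < p.nL) {
        if (bound(d)) dens_bound[(size_t)b] += dt; else dens_free[(size_t)b] += dt;
      }
      if (rel_on) {
        int64_t rb = (int64_t)std::floor((x - x_c + p.L / 2.0) / p.a);
        if (rb >= 0 && rb < p.nL) {
          if (bound(d)) rel_bound[(size_t)rb] += dt; else rel_free[(size_t)rb] += dt;
        }
      }
    }
  }

  void count_flux(int64_t edge, int dir, double x_edge) {
    if (!acc_on) return;
    if (edge >= 1 && edge <= p.nL - 1) flux_net[(size_t)edge] += dir;
    if (rel_on) {
      int64_t re = (int64_t)std::llround((x_edge - x_c + p.L / 2.0) / p.a);
      if (re >= 1 && re <= p.nL - 1) rel_flux[(size_t)re] += dir;
    }
  }

  void bind_dimer(int i) {
    Dimer& d = dim[(size_t)i];
    double dx = xn_of(d) - x_c;
    // sample the cluster site with probability proportional to Eq-1 rates
    double pref = p.k / (2.0 * p.kBT);
    int64_t jlo = (int64_t)std::floor((dx - p.cut + p.Lc / 2.0) / p.a - 0.5);
    int64_t jhi = (int64_t)std::ceil((dx + p.cut + p.Lc / 2.0) / p.a + 0.5);
    if (jlo < 0) jlo = 0;
    if (jhi > p.nC - 1) jhi = p.nC - 1;
    double tot = 0.0;
    std::vector<double> w((size_t)(jhi - jlo + 1), 0.0);
    for (int64_t j = jlo; j <= jhi; ++j) {
      double o = -p.Lc / 2.0 + p.a * ((double)j + 0.5);
      double e = pref * (o - dx) * (o - dx);
      if (e < LOG_PRUNE) { w[(size_t)(j - jlo)] = std::exp(-e); tot += w[(size_t)(j - jlo)]; }
    }
    if (tot <= 0) return; // numerically out of reach; treat as null
    double r = unif_rand() * tot;
    int64_t jsel = jhi;
    for (int64_t j = jlo; j <= jhi; ++j) {
      r -= w[(size_t)(j - jlo)];
      if (r <= 0) { jsel = j; break; }
    }
    d.joff = jsel;
    double s = stretch_of(d);
    d.u = std::exp(-p.c1 * s);
    nB += 1; Sxn += xn_of(d); Soff += off_of(d);
  }

  void remove_dimer(int i) {
    dim[(size_t)i] = dim.back();
    dim.pop_back();
  }

  void attach_dimer() {
    // uniform over nucleoid sites whose centre lies outside the cluster
    double e1 = x_c - p.Lc / 2.0, e2 = x_c + p.Lc / 2.0;
    int64_t nLeft = (int64_t)std::ceil(e1 / p.a - 0.5 - 1e-12);
    if (nLeft < 0) nLeft = 0;
    if (nLeft > p.nL) nLeft = p.nL;
    int64_t i0 = (int64_t)std::floor(e2 / p.a - 0.5 + 1e-12) + 1;
    if (i0 < 0) i0 = 0;
    int64_t nRight = p.nL - i0;
    if (nRight < 0) nRight = 0;
    int64_t tot = nLeft + nRight;
    if (tot <= 0) stop("no eligible attachment site: cluster covers the nucleoid");
    int64_t u = (int64_t)(unif_rand() * (double)tot);
    if (u >= tot) u = tot - 1;
    int64_t site = (u < nLeft) ? u : i0 + (u - nLeft);
    Dimer d;
    d.inuc = site; d.joff = INT64_MIN; d.u = 1.0;
    d.side = (p.a * ((double)site + 0.5) < x_c) ? -1 : 1;
    dim.push_back(d);
    n_cyto -= 1;
  }

  // apply the selected event; returns index of dimer hydrolysed (for the
  // one-particle driver) or -1
  int apply_event(int type, int i) {
    switch (type) {
    case EV_HOP_NL: case EV_HOP_NR: {
      Dimer& d = dim[(size_t)i];
      int dir = (type == EV_HOP_NR) ? 1 : -1;
      if (!bound(d)) {
        int64_t edge = (dir > 0) ? d.inuc + 1 : d.inuc;
        count_flux(edge, dir, p.a * (double)edge);
      } else {
        Sxn += dir * p.a;
        // right hop: s -> s - a => u /= kap2; left: u *= kap2
        if (dir > 0) d.u /= p.kap2; else d.u *= p.kap2;
      }
      d.inuc += dir;
      break;
    }
    case EV_HOP_CL: case EV_HOP_CR: {
      Dimer& d = dim[(size_t)i];
      int dir = (type == EV_HOP_CR) ? 1 : -1;
      d.joff += dir;
      Soff += dir * p.a;
      if (dir > 0) d.u *= p.kap2; else d.u /= p.kap2;
      break;
    }
    case EV_HYD: {
      Dimer& d = dim[(size_t)i];
      nB -= 1; Sxn -= xn_of(d); Soff -= off_of(d);
      remove_dimer(i);
      n_cyto += 1;
      ++n_hyd_ev;
      return i;
    }
    case EV_KOFF: {
      remove_dimer(i);
      n_cyto += 1;
      ++n_koff_ev;
      break;
    }
    case EV_BIND: bind_dimer(i); ++n_bind_ev; break;
    case EV_ATTACH: attach_dimer(); ++n_attach_ev; break;
    case EV_NULL: break;
    }
    return -1;
  }
};

// ---------------------------------------------------------------------------
// run drivers

// [[Rcpp::export]]
List cpp_run_dynamic(List pars, double t_end, double record_dt,
                     double x_c0, Nullable<List> condition,
                     int n_log) {
  Engine E; E.init(read_pars(pars));
  E.x_c = x_c0;
  E.cluster_mobile = false;
  E.log_left = n_log;

  bool windowed = false;
  double w_target = 0, w_enter = 0, w_exit = 0;
  if (condition.isNotNull()) {
    List cnd(condition);
    w_target = cnd["target"]; w_enter = cnd["enter_tol"]; w_exit = cnd["exit_tol"];
    windowed = true;
    E.rel_on = true;
    E.start_accumulate();
    E.acc_on = false;
  }
  bool in_window = false;
  int episodes = 0;

  double t_total = E.p.tmin + t_end;
  std::vector<double> r_t, r_x;
  std::vector<int> r_nb, r_nn, r_nc;
  double next_rec = 0.0;
  double excursion_time = 0.0;
  int64_t max_steps = INT64_MAX;
  int64_t step = 0;

  while (E.t < t_total && step < max_steps) {
    ++step;
    if (E.t >= E.p.tmin) E.cluster_mobile = true;
    double alpha = E.build_props();
    double dt;
    bool coasting = false;
    if (alpha <= 0) {
      // absorbing (possible only without dimers): coast, but stop at the
      // un-freeze time so the mobility switch is honoured
      coasting = true;
      dt = (!E.cluster_mobile && E.p.tmin < t_total)
             ? E.p.tmin - E.t + 1e-9
             : t_total - E.t;
      if (dt <= 0) dt = t_total - E.t + 1e-9;
    } else {
      dt = exp_rand() / alpha;
    }
    if (E.log_left > 0 && alpha > 0) {
      E.log_t.push_back(E.t); E.log_dt.push_back(dt); E.log_alpha.push_back(alpha);
      E.log_left--;
    }
    // trajectory sampling within [t, t+dt)
    while (next_rec <= E.t + dt && next_rec <= t_total) {
      double xr = (next_rec >= E.t) ? E.x_at(next_rec - E.t) : E.x_c;
      r_t.push_back(next_rec);
      r_x.push_back(xr);
      r_nb.push_back(E.nB);
      r_nn.push_back((int)E.dim.size() - E.nB);
      r_nc.push_back(E.n_cyto);
      next_rec += record_dt;
    }
    // windowed profile accumulation (state frozen over the interval)
    if (windowed) {
      double dev = std::fabs(E.x_c - w_target);
      if (!in_window && dev <= w_enter) { in_window = true; ++episodes; }
      else if (in_window && dev > w_exit) in_window = false;
      E.acc_on = in_window && E.cluster_mobile;
    }
    E.accumulate(dt);
    // advance cluster, update cached u
    if (E.cluster_mobile) {
      double x_new = E.x_at(dt);
      double dx = x_new - E.x_c;
      if (dx != 0.0 && E.nB > 0) {
        double f = std::exp(-E.p.c1 * dx);
        for (auto& d : E.dim) if (E.bound(d)) d.u *= f;
      }
      E.x_c = x_new;
      if (!E.p.infinite &&
          (E.x_c < E.p.Lc / 2.0 || E.x_c > E.p.L - E.p.Lc / 2.0))
        excursion_time += dt;
    }
    E.t += dt;
    if (coasting) {
      if (E.t >= t_total) break;
      continue;
    }
    // select and apply event (rates frozen at interval start)
    double r = unif_rand() * alpha;
    size_t sel = 0;
    for (; sel + 1 < E.props.size(); ++sel) {
      r -= E.props[sel];
      if (r <= 0) break;
    }
    E.apply_event(E.ptype[sel], E.pidx[sel]);
    if (++E.steps_since_refresh >= 4000000) E.refresh_cached();
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["t"] = r_t, _["x_c"] = r_x, _["n_bound"] = r_nb,
    _["n_nucleoid"] = r_nn, _["n_cyto"] = r_nc,
    _["excursion_time"] = excursion_time);
  if (windowed) {
    out["profiles"] = List::create(
      _["dens_free"] = E.dens_free, _["dens_bound"] = E.dens_bound,
      _["flux_net"] = E.flux_net,
      _["rel_free"] = E.rel_free, _["rel_bound"] = E.rel_bound,
      _["rel_flux"] = E.rel_flux,
      _["dwell"] = E.acc_T, _["episodes"] = episodes,
      _["mean_bound"] = (E.acc_T > 0 ? E.acc_nB / E.acc_T : NA_REAL));
  }
  if (n_log > 0)
    out["event_log"] = List::create(_["t"] = E.log_t, _["dt"] = E.log_dt,
                                    _["alpha"] = E.log_alpha);
  return out;
}

// [[Rcpp::export]]
List cpp_run_stationary(List pars, double x_c, double t_end, double burn_in,
                        int n_log, double sample_dt, int init_bound) {
  Engine E; E.init(read_pars(pars));
  E.x_c = x_c;
  E.cluster_mobile = false;
  E.log_left = n_log;
  E.samp_dt = sample_dt;
  E.samp_next = burn_in;

  // optionally start with dimers already doubly bound at the cluster centre
  for (int i = 0; i < init_bound; ++i) {
    Dimer d;
    d.inuc = (int64_t)std::llround(x_c / E.p.a - 0.5);
    d.joff = E.p.nC / 2;
    d.side = 1;
    double s = E.x_c + E.off_of(d) - E.xn_of(d);
    d.u = std::exp(-E.p.c1 * s);
    E.dim.push_back(d);
    E.nB += 1; E.Sxn += E.xn_of(d); E.Soff += E.off_of(d);
    E.n_cyto -= 1;
  }

  double t_total = burn_in + t_end;
  int64_t step = 0;
  while (E.t < t_total) {
    ++step;
    if (!E.acc_on && E.t >= burn_in) E.start_accumulate();
    double alpha = E.build_props();
    if (alpha <= 0) stop("absorbing state reached (total propensity is zero)");
    double dt = exp_rand() / alpha;
    if (E.t + dt > t_total) dt = t_total - E.t + 1e-12;
    if (E.log_left > 0) {
      E.log_t.push_back(E.t); E.log_dt.push_back(dt); E.log_alpha.push_back(alpha);
      E.log_left--;
    }
    if (E.samp_dt > 0) {
      while (E.samp_next <= E.t + dt && E.samp_next <= t_total) {
        double s = NA_REAL;
        for (const auto& d : E.dim) if (E.bound(d)) { s = E.stretch_of(d); break; }
        E.samp_s.push_back(s);
        E.samp_next += E.samp_dt;
      }
    }
    double dt_acc = std::min(dt, t_total - E.t);
    E.accumulate(dt_acc);
    E.t += dt;
    if (E.t >= t_total) break;
    double r = unif_rand() * alpha;
    size_t sel = 0;
    for (; sel + 1 < E.props.size(); ++sel) {
      r -= E.props[sel];
      if (r <= 0) break;
    }
    E.apply_event(E.ptype[sel], E.pidx[sel]);
    if (++E.steps_since_refresh >= 4000000) E.refresh_cached();
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["dens_free"] = E.dens_free, _["dens_bound"] = E.dens_bound,
    _["flux_net"] = E.flux_net, _["T"] = E.acc_T,
    _["mean_force"] = (E.acc_T > 0 ? E.acc_F / E.acc_T : NA_REAL),
    _["mean_bound"] = (E.acc_T > 0 ? E.acc_nB / E.acc_T : NA_REAL),
    _["mean_free"] = (E.acc_T > 0 ? E.acc_nFree / E.acc_T : NA_REAL));
  {
    std::vector<double> xn_free;
    for (const auto& d : E.dim) if (!E.bound(d)) xn_free.push_back(E.xn_of(d));
    out["final_xn_free"] = xn_free;
    out["events"] = List::create(
      _["attach"] = (double)E.n_attach_ev, _["bind"] = (double)E.n_bind_ev,
      _["hydrolysis"] = (double)E.n_hyd_ev, _["k_off"] = (double)E.n_koff_ev);
  }
  if (n_log > 0)
    out["event_log"] = List::create(_["t"] = E.log_t, _["dt"] = E.log_dt,
                                    _["alpha"] = E.log_alpha);
  if (sample_dt > 0) out["stretch_samples"] = E.samp_s;
  return out;
}

// [[Rcpp::export]]
List cpp_run_one_particle(List pars, double x_c, int64_t inject_site,
                          int n_interactions, double t_cap) {
  Engine E; E.init(read_pars(pars));
  E.x_c = x_c;
  E.cluster_mobile = false;
  if (E.p.Ntot != 1) stop("one-particle protocol requires N_total = 1");

  // the dimer starts on the nucleoid at the injection site (far right of the
  // cluster, outside binding reach); after each hydrolysis it is re-injected
  Dimer d0; d0.inuc = inject_site; d0.joff = INT64_MIN; d0.u = 1.0; d0.side = 1;
  E.dim.push_back(d0);
  E.n_cyto = 0;

  std::vector<double> t_attach, t_detach, dx_attach, f_int;
  double cur_attach = NA_REAL, cur_dx = NA_REAL, cur_fint = 0.0;
  bool interacting = false;

  int64_t step = 0;
  while ((int)t_detach.size() < n_interactions && E.t < t_cap) {
    ++step;
    double alpha = E.build_props();
    if (alpha <= 0) stop("absorbing state in one-particle run");
    double dt = exp_rand() / alpha;
    if (interacting) {
      // cluster frozen: the tether force is constant over the interval
      const Dimer& d = E.dim[0];
      cur_fint += -E.p.k * E.stretch_of(d) * dt;
    }
    E.t += dt;
    double r = unif_rand() * alpha;
    size_t sel = 0;
    for (; sel + 1 < E.props.size(); ++sel) {
      r -= E.props[sel];
      if (r <= 0) break;
    }
    int type = E.ptype[sel];
    bool was_bound = E.bound(E.dim[0]);
    E.apply_event(type, E.pidx[sel]);
    if (!was_bound && type == EV_BIND && E.bound(E.dim[0])) {
      interacting = true;
      cur_attach = E.t;
      cur_dx = E.stretch_of(E.dim[0]);
      cur_fint = 0.0;
    } else if (type == EV_HYD) {
      // interaction complete; record and re-inject
      t_attach.push_back(cur_attach);
      t_detach.push_back(E.t);
      dx_attach.push_back(cur_dx);
      f_int.push_back(cur_fint);
      interacting = false;
      Dimer d; d.inuc = inject_site; d.joff = INT64_MIN; d.u = 1.0; d.side = 1;
      E.dim.push_back(d);
      E.n_cyto = 0;
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t_attach"] = t_attach, _["t_detach"] = t_detach,
                      _["dx_attach"] = dx_attach, _["f_int"] = f_int,
                      _["t_sim"] = E.t);
}

// [[Rcpp::export]]
List cpp_run_friction(List pars, int n_bound, double t_end, double burn_in,
                      double record_dt, bool freeze_cluster,
                      double sample_dt) {
  Engine E; E.init(read_pars(pars));
  if (!E.p.infinite) stop("friction assay requires infinite_lattice = TRUE");
  E.x_c = 0.0;
  E.cluster_mobile = !freeze_cluster;
  E.samp_dt = sample_dt;
  E.samp_next = burn_in;

  // all dimers doubly bound at zero stretch; on the unbounded lattices the
  // cluster-site index grid coincides with the nucleoid grid (offset a*(j+1/2))
  for (int i = 0; i < n_bound; ++i) {
    Dimer d; d.inuc = 0; d.joff = 0; d.side = 1;
    // offset definition off = -Lc/2 + a(j+1/2) is replaced on the infinite
    // cluster by off = a*(j+1/2) - handled by using Lc = 0 internally
    E.dim.push_back(d);
  }
  E.p.Lc = 0.0; // infinite-cluster offsets measured from the cluster centre
  E.nB = n_bound;
  E.Sxn = 0; E.Soff = 0;
  for (auto& d : E.dim) {
    double s = E.x_c + E.off_of(d) - E.xn_of(d); // = 0 by construction
    d.u = std::exp(-E.p.c1 * s);
    E.Sxn += E.xn_of(d); E.Soff += E.off_of(d);
  }
  E.n_cyto = 0;

  double t_total = burn_in + t_end;
  std::vector<double> r_t, r_x;
  double next_rec = burn_in;
  int64_t step = 0;
  while (E.t < t_total) {
    ++step;
    double alpha = E.build_props();
    double dt = (alpha > 0) ? exp_rand() / alpha : (t_total - E.t + 1e-12);
    while (next_rec <= E.t + dt && next_rec <= t_total) {
      r_t.push_back(next_rec);
      r_x.push_back(E.x_at(next_rec - E.t));
      next_rec += record_dt;
    }
    if (E.samp_dt > 0) {
      while (E.samp_next <= E.t + dt && E.samp_next <= t_total) {
        double s = E.dim.empty() ? NA_REAL : E.stretch_of(E.dim[0]);
        E.samp_s.push_back(s);
        E.samp_next += E.samp_dt;
      }
    }
    if (E.cluster_mobile) {
      double x_new = E.x_at(dt);
      double dx = x_new - E.x_c;
      if (dx != 0.0 && E.nB > 0) {
        double f = std::exp(-E.p.c1 * dx);
        for (auto& d : E.dim) d.u *= f;
      }
      E.x_c = x_new;
    }
    E.t += dt;
    if (E.t >= t_total || alpha <= 0) break;
    double r = unif_rand() * alpha;
    size_t sel = 0;
    for (; sel + 1 < E.props.size(); ++sel) {
      r -= E.props[sel];
      if (r <= 0) break;
    }
    E.apply_event(E.ptype[sel], E.pidx[sel]);
    if (++E.steps_since_refresh >= 4000000) E.refresh_cached();
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["t"] = r_t, _["x_c"] = r_x);
  if (sample_dt > 0) out["stretch_samples"] = E.samp_s;
  return out;
}
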