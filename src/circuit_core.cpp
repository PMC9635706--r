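// Fixed-step RK4 integrator for the closed-loop atrioventricular-aortic
// circuit: elastance LV -> aortic valve -> R-L-C aorta ladder (with branches
// and terminal outlet units) -> two-chamber Windkessel -> reservoir -> LA ->
// mitral valve -> LV.  All quantities SI (Pa, m^3, s); unit conversion is
// done on the R side.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One-way valve flow: logistic conductance 1/(R*(1+exp(-dp/w))) times the
// pressure drop, clamped at zero so the diode never carries backflow and a
// closed loop at rest carries no leak.
static inline double valve_flow_si(double dp, double R, double w) {
  if (dp <= 0.0) return 0.0;
  double x = dp / w;
  if (x > 40.0) return dp / R;
  return dp / (R * (1.0 + std::exp(-x)));
}

struct Elastance {
  double E_min, E_amp; // E_amp = scale * (E_max - E_min), SI
  double T, t_rise, t_sys;
  double at(double t) const {
    double tc = t - T * std::floor(t / T); // periodic wrap
    double e;
    if (tc < t_rise) {
      e = 0.5 * (1.0 - std::cos(M_PI * tc / t_rise));
    } else if (tc < t_sys) {
      e = 0.5 * (1.0 + std::cos(M_PI * (tc - t_rise) / (t_sys - t_rise)));
    } else {
      e = 0.0;
    }
    return E_min + E_amp * e;
  }
};

struct Circuit {
  int n;                      // ladder compartments
  std::vector<int> parent;    // parent[i] in [0,n), parent[0] = -1 (valve)
  std::vector<double> Cc, Rl, Ll; // fast (wave-speed-true) node compliance
  // viscoelastic wall: slow creep compliance behind a relaxation resistance
  std::vector<double> Cw, Rw;
  // terminal outlet units: syringe compliance behind a port resistance
  // (shunt at the outlet node) plus a clamp into chamber 1
  int K;
  std::vector<int> tcomp;
  std::vector<double> tRcl, tCsyr, tRs;
  // lumped elements
  double V0lv, Cla, Cres, Pven0, Cch1, Cch2, Ric, Rout, Rven;
  double Rav, Rmv, wv;
  Elastance el;

  int nstate() const { return 3 * n + K + 5; }

  void rhs(double t, const double* y, double* dy) const {
    const double* V = y;          // fast compartment volumes
    const double* Q = y + n;      // link flows
    const double* Vw = y + 2 * n; // wall creep volumes
    const double* Vs = y + 3 * n; // outlet syringe volumes
    const double Vch1 = y[3 * n + K + 0];
    const double Vch2 = y[3 * n + K + 1];
    const double Vres = y[3 * n + K + 2];
    const double Vla  = y[3 * n + K + 3];
    const double Vlv  = y[3 * n + K + 4];

    std::vector<double> P(n);
    for (int i = 0; i < n; ++i) P[i] = V[i] / Cc[i];

    const double E    = el.at(t);
    const double Plv  = E * (Vlv - V0lv);
    const double Pla  = Vla / Cla;
    const double Pres = Pven0 + Vres / Cres;
    const double Pch1 = Vch1 / Cch1;
    const double Pch2 = Vch2 / Cch2;

    for (int i = 0; i < n; ++i) dy[i] = 0.0;
    dy[n] = 0.0; // Q[0] unused

    const double Qav = valve_flow_si(Plv - P[0], Rav, wv);
    dy[0] += Qav;

    for (int i = 1; i < n; ++i) {
      const int p = parent[i];
      dy[n + i] = (P[p] - P[i] - Rl[i] * Q[i]) / Ll[i];
      dy[i] += Q[i];
      dy[p] -= Q[i];
    }

    // wall creep: volume seeps into the slow compliance through the
    // relaxation resistance
    for (int i = 0; i < n; ++i) {
      const double Qw = (P[i] - Vw[i] / Cw[i]) / Rw[i];
      dy[i] -= Qw;
      dy[2 * n + i] = Qw;
    }

    double dVch1 = 0.0;
    for (int k = 0; k < K; ++k) {
      const double Qcl = (P[tcomp[k]] - Pch1) / tRcl[k];
      const double Qs  = (P[tcomp[k]] - Vs[k] / tCsyr[k]) / tRs[k];
      dy[tcomp[k]] -= Qcl + Qs;
      dy[3 * n + k] = Qs;
      dVch1 += Qcl;
    }

    const double Qic  = (Pch1 - Pch2) / Ric;
    const double Qout = (Pch2 - Pres) / Rout;
    const double Qven = (Pres - Pla) / Rven;
    const double Qmv  = valve_flow_si(Pla - Plv, Rmv, wv);

    dy[3 * n + K + 0] = dVch1 - Qic;
    dy[3 * n + K + 1] = Qic - Qout;
    dy[3 * n + K + 2] = Qout - Qven;
    dy[3 * n + K + 3] = Qven - Qmv;
    dy[3 * n + K + 4] = Qmv - Qav;
  }
};

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(List pars, NumericVector y0) {
  Circuit ck;
  ck.n      = as<int>(pars["n"]);
  ck.parent = as<std::vector<int> >(pars["parent"]);
  ck.Cc     = as<std::vector<double> >(pars["C"]);
  ck.Rl     = as<std::vector<double> >(pars["R"]);
  ck.Ll     = as<std::vector<double> >(pars["L"]);
  ck.Cw     = as<std::vector<double> >(pars["Cw"]);
  ck.Rw     = as<std::vector<double> >(pars["Rw"]);
  ck.K      = as<int>(pars["K"]);
  ck.tcomp  = as<std::vector<int> >(pars["tcomp"]);
  ck.tRcl   = as<std::vector<double> >(pars["tRcl"]);
  ck.tCsyr  = as<std::vector<double> >(pars["tCsyr"]);
  ck.tRs    = as<std::vector<double> >(pars["tRs"]);
  ck.V0lv   = as<double>(pars["V0lv"]);
  ck.Cla    = as<double>(pars["Cla"]);
  ck.Cres   = as<double>(pars["Cres"]);
  ck.Pven0  = as<double>(pars["Pven0"]);
  ck.Cch1   = as<double>(pars["Cch1"]);
  ck.Cch2   = as<double>(pars["Cch2"]);
  ck.Ric    = as<double>(pars["Ric"]);
  ck.Rout   = as<double>(pars["Rout"]);
  ck.Rven   = as<double>(pars["Rven"]);
  ck.Rav    = as<double>(pars["Rav"]);
  ck.Rmv    = as<double>(pars["Rmv"]);
  ck.wv     = as<double>(pars["wv"]);
  ck.el.E_min  = as<double>(pars["E_min"]);
  ck.el.E_amp  = as<double>(pars["E_amp"]);
  ck.el.T      = as<double>(pars["T"]);
  ck.el.t_rise = as<double>(pars["t_rise"]);
  ck.el.t_sys  = as<double>(pars["t_sys"]);

  const double dt      = as<double>(pars["dt"]);
  const int max_cycles = as<int>(pars["max_cycles"]);
  const int out_cycles = as<int>(pars["out_cycles"]);
  const int out_every  = as<int>(pars["out_every"]);
  const double tol     = as<double>(pars["tol"]);   // Pa
  const double Vconst  = as<double>(pars["V_unstressed"]); // bookkeeping offset

  const int ns = ck.nstate();
  if ((int)y0.size() != ns) stop("initial state has wrong length");
  const int steps = (int)std::lround(ck.el.T / dt);
  const int m = steps / out_every + ((steps % out_every) ? 1 : 0); // samples per cycle

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), yt(ns);

  // monitor = all compartment pressures + LV, LA, chambers, reservoir
  const int nmon = ck.n + 5;
  std::vector<double> mon_prev(nmon * m, 0.0), mon_cur(nmon * m, 0.0);

  // output ring buffer: out_cycles cycles x m samples x 9 channels
  const int nch = 9; // Plv Pla Pasc Pabd Qav Qmv Qasc Qabd Vtot
  const int tap_asc = as<int>(pars["tap_asc"]);
  const int tap_abd = as<int>(pars["tap_abd"]);
  std::vector<double> ring(out_cycles * m * nch, 0.0);

  bool converged = false;
  int cycles_run = 0, conv_cycle = -1;
  int post_left = -1; // recording cycles left after convergence

  auto sample = [&](int cyc_slot, int s_idx, double t) {
    // recompute derived pressures/flows at the current state
    const double* V = y.data();
    const double* Q = y.data() + ck.n;
    const double E = ck.el.at(t);
    const double Plv = E * (y[3 * ck.n + ck.K + 4] - ck.V0lv);
    const double Pla = y[3 * ck.n + ck.K + 3] / ck.Cla;
    const double Qav = valve_flow_si(Plv - V[0] / ck.Cc[0], ck.Rav, ck.wv);
    const double Qmv = valve_flow_si(Pla - Plv, ck.Rmv, ck.wv);
    double vt = Vconst;
    for (int i = 0; i < ck.n; ++i) vt += V[i] + y[2 * ck.n + i];
    for (int k = 0; k < ck.K; ++k) vt += y[3 * ck.n + k];
    for (int j = 0; j < 5; ++j) vt += y[3 * ck.n + ck.K + j];
    double* row = &ring[(cyc_slot * m + s_idx) * nch];
    row[0] = Plv;
    row[1] = Pla;
    row[2] = V[tap_asc] / ck.Cc[tap_asc];
    row[3] = V[tap_abd] / ck.Cc[tap_abd];
    row[4] = Qav;
    row[5] = Qmv;
    row[6] = (tap_asc == 0) ? Qav : Q[tap_asc];
    row[7] = (tap_abd == 0) ? Qav : Q[tap_abd];
    row[8] = vt;
    // convergence monitor
    double* mrow = &mon_cur[s_idx * nmon];
    for (int i = 0; i < ck.n; ++i) mrow[i] = V[i] / ck.Cc[i];
    mrow[ck.n + 0] = Plv;
    mrow[ck.n + 1] = Pla;
    mrow[ck.n + 2] = y[3 * ck.n + ck.K + 0] / ck.Cch1;
    mrow[ck.n + 3] = y[3 * ck.n + ck.K + 1] / ck.Cch2;
    mrow[ck.n + 4] = ck.Pven0 + y[3 * ck.n + ck.K + 2] / ck.Cres;
  };

  const int hard_cap = max_cycles + out_cycles;
  int slot = 0;
  while (cycles_run < hard_cap) {
    const double t0 = cycles_run * ck.el.T;
    int s_idx = 0;
    for (int s = 0; s < steps; ++s) {
      const double t = t0 + s * dt;
      if (s % out_every == 0) { sample(slot, s_idx, t); ++s_idx; }
      ck.rhs(t, y.data(), k1.data());
      for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
      ck.rhs(t + 0.5 * dt, yt.data(), k2.data());
      for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
      ck.rhs(t + 0.5 * dt, yt.data(), k3.data());
      for (int i = 0; i < ns; ++i) yt[i] = y[i] + dt * k3[i];
      ck.rhs(t + dt, yt.data(), k4.data());
      for (int i = 0; i < ns; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
    ++cycles_run;

    for (int i = 0; i < ns; ++i) {
      if (!std::isfinite(y[i])) {
        stop("non-finite state in compartment/state index %d after cycle %d (t = %.4f s)",
             i + 1, cycles_run, cycles_run * ck.el.T);
      }
    }

    if (post_left < 0) { // still in the convergence phase
      if (cycles_run >= 2) {
        double d = 0.0;
        for (int j = 0; j < nmon * m; ++j) {
          const double e = std::fabs(mon_cur[j] - mon_prev[j]);
          if (e > d) d = e;
        }
        if (d <= tol) {
          converged = true;
          conv_cycle = cycles_run;
          post_left = out_cycles; // record a clean post-convergence window
        }
      }
      if (!converged && cycles_run >= max_cycles) {
        conv_cycle = cycles_run;
        post_left = out_cycles;
      }
    } else if (post_left > 0) {
      --post_left;
    }
    if (post_left == 0) break;
    std::swap(mon_prev, mon_cur);
    slot = (slot + 1) % out_cycles;
  }

  // unwrap the ring buffer: oldest recorded cycle first
  NumericMatrix out(out_cycles * m, nch);
  for (int c = 0; c < out_cycles; ++c) {
    const int src = (slot + 1 + c) % out_cycles;
    for (int s = 0; s < m; ++s)
      for (int j = 0; j < nch; ++j)
        out(c * m + s, j) = ring[(src * m + s) * nch + j];
  }

  // mean aortic valve flow over the final recorded cycle
  double co = 0.0;
  for (int s = 0; s < m; ++s) co += ring[(slot * m + s) * nch + 4];
  co /= m;

  return List::create(
    _["out"] = out, _["samples_per_cycle"] = m, _["dt_out"] = out_every * dt,
    _["converged"] = converged, _["cycles_run"] = cycles_run,
    _["conv_cycle"] = conv_cycle, _["co_si"] = co,
    _["final_state"] = NumericVector(y.begin(), y.end()));
}
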