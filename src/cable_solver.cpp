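// Branched compartmental cable integrator.
//
// Crank-Nicolson time stepping on the tree (Hines elimination: one sweep up,
// one sweep down per step), dual-exponential synaptic conductances kept as
// two exactly-decaying state variables per synapse channel, optional
// Hodgkin-Huxley Na/K currents with exponential-Euler gate updates, and
// optional current-clamp sources. Units: mV, ms, uS, nF, nA.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x/(exp(x/y)-1) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct HH {
  static double am(double v) { return 0.1 * vtrap(-(v + 40.0), 10.0); }
  static double bm(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
  static double ah(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
  static double bh(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
  static double an(double v) { return 0.01 * vtrap(-(v + 55.0), 10.0); }
  static double bn(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }
};

// [[Rcpp::export]]
List simulate_cable_cpp(IntegerVector parent,       // 0-based, -1 for root, topologically sorted
                        NumericVector cm_nF,
                        NumericVector g_leak_uS,
                        double e_leak,
                        NumericVector g_axial_uS,   // conductance to parent, 0 at root
                        NumericVector gna_uS,
                        NumericVector gk_uS,
                        double ena, double ek,
                        IntegerVector syn_comp,     // per synapse channel, 0-based
                        NumericVector syn_tau1,
                        NumericVector syn_tau2,
                        NumericVector syn_erev,
                        IntegerVector ev_syn,       // 0-based into synapse channels
                        NumericVector ev_time,      // ms relative to protocol start, sorted
                        NumericVector ev_w,         // uS increment (already peak-normalised)
                        IntegerVector ic_comp,      // current clamps, 0-based
                        NumericVector ic_amp_nA,
                        NumericVector ic_start,
                        NumericVector ic_dur,
                        double duration, double dt, double stabilise,
                        IntegerVector record_comp,  // 0-based
                        int record_every) {
  const int n = parent.size();
  const int nsyn = syn_comp.size();
  const int nev = ev_syn.size();
  const int nic = ic_comp.size();
  const int nrec = record_comp.size();
  const bool active = (Rcpp::sum(gna_uS) > 0.0) || (Rcpp::sum(gk_uS) > 0.0);

  std::vector<double> v(n, e_leak), m(n), h(n), ngate(n);
  if (active) {
    for (int i = 0; i < n; ++i) {
      double vv = v[i];
      m[i] = HH::am(vv) / (HH::am(vv) + HH::bm(vv));
      h[i] = HH::ah(vv) / (HH::ah(vv) + HH::bh(vv));
      ngate[i] = HH::an(vv) / (HH::an(vv) + HH::bn(vv));
    }
  }

  std::vector<double> synA(nsyn, 0.0), synB(nsyn, 0.0);
  std::vector<double> dec1(nsyn), dec2(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    dec1[s] = std::exp(-dt / syn_tau1[s]);
    dec2[s] = std::exp(-dt / syn_tau2[s]);
  }

  const int nstab = (int)std::llround(stabilise / dt);
  const int nstep = (int)std::llround(duration / dt);
  const int nout = nstep / record_every + 1;
  NumericMatrix vm(nout, nrec);
  NumericVector tout(nout);

  // per-compartment accumulators for the two time levels
  std::vector<double> gsyn_now(n, 0.0), esyn_now(n, 0.0);
  std::vector<double> gsyn_new(n, 0.0), esyn_new(n, 0.0);
  std::vector<double> gchan(n, 0.0), echan(n, 0.0);
  std::vector<double> diag(n), rhs(n);

  int evptr = 0, outrow = 0;
  double tprot = 0.0;  // time within the protocol (<0 during stabilisation)

  for (int step = -nstab; step < nstep; ++step) {
    tprot = step * dt;
    double tnext = tprot + dt;

    // synaptic conductance at t (current states)
    std::fill(gsyn_now.begin(), gsyn_now.end(), 0.0);
    std::fill(esyn_now.begin(), esyn_now.end(), 0.0);
    for (int s = 0; s < nsyn; ++s) {
      double g = synB[s] - synA[s];
      if (g != 0.0) {
        gsyn_now[syn_comp[s]] += g;
        esyn_now[syn_comp[s]] += g * syn_erev[s];
      }
    }
    // advance synapse states to t+dt, then deposit events due in (t, t+dt]
    for (int s = 0; s < nsyn; ++s) { synA[s] *= dec1[s]; synB[s] *= dec2[s]; }
    while (evptr < nev && ev_time[evptr] <= tnext + 1e-9) {
      int s = ev_syn[evptr];
      synA[s] += ev_w[evptr];
      synB[s] += ev_w[evptr];
      ++evptr;
    }
    std::fill(gsyn_new.begin(), gsyn_new.end(), 0.0);
    std::fill(esyn_new.begin(), esyn_new.end(), 0.0);
    for (int s = 0; s < nsyn; ++s) {
      double g = synB[s] - synA[s];
      if (g != 0.0) {
        gsyn_new[syn_comp[s]] += g;
        esyn_new[syn_comp[s]] += g * syn_erev[s];
      }
    }

    // HH gates advanced to t+dt with V(t); conductances used at both levels
    if (active) {
      for (int i = 0; i < n; ++i) {
        if (gna_uS[i] == 0.0 && gk_uS[i] == 0.0) { gchan[i] = 0.0; echan[i] = 0.0; continue; }
        double vv = v[i];
        double amv = HH::am(vv), bmv = HH::bm(vv);
        double ahv = HH::ah(vv), bhv = HH::bh(vv);
        double anv = HH::an(vv), bnv = HH::bn(vv);
        double taum = 1.0 / (amv + bmv), minf = amv * taum;
        double tauh = 1.0 / (ahv + bhv), hinf = ahv * tauh;
        double taun = 1.0 / (anv + bnv), ninf = anv * taun;
        m[i] += (minf - m[i]) * (1.0 - std::exp(-dt / taum));
        h[i] += (hinf - h[i]) * (1.0 - std::exp(-dt / tauh));
        ngate[i] += (ninf - ngate[i]) * (1.0 - std::exp(-dt / taun));
        double gna = gna_uS[i] * m[i] * m[i] * m[i] * h[i];
        double gk = gk_uS[i] * ngate[i] * ngate[i] * ngate[i] * ngate[i];
        gchan[i] = gna + gk;
        echan[i] = gna * ena + gk * ek;
      }
    }

    // current clamps (constant over the step when inside their window)
    // assemble theta = 1/2 Crank-Nicolson system
    for (int i = 0; i < n; ++i) {
      double gm_new = g_leak_uS[i] + gsyn_new[i] + gchan[i];
      double gm_now = g_leak_uS[i] + gsyn_now[i] + gchan[i];
      double e_new = g_leak_uS[i] * e_leak + esyn_new[i] + echan[i];
      double e_now = g_leak_uS[i] * e_leak + esyn_now[i] + echan[i];
      double k = cm_nF[i] / dt;
      diag[i] = k + 0.5 * gm_new;
      rhs[i] = k * v[i] + 0.5 * (e_new + e_now - gm_now * v[i]);
    }
    for (int c = 0; c < nic; ++c) {
      int i = ic_comp[c];
      double inow = (tprot >= ic_start[c] - 1e-9 && tprot < ic_start[c] + ic_dur[c]) ? ic_amp_nA[c] : 0.0;
      double inew = (tnext >= ic_start[c] - 1e-9 && tnext < ic_start[c] + ic_dur[c]) ? ic_amp_nA[c] : 0.0;
      rhs[i] += 0.5 * (inow + inew);
    }
    // axial terms: explicit half on rhs, implicit half in the matrix
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      double ga = g_axial_uS[i];
      diag[i] += 0.5 * ga;
      diag[p] += 0.5 * ga;
      rhs[i] += 0.5 * ga * (v[p] - v[i]);
      rhs[p] += 0.5 * ga * (v[i] - v[p]);
    }
    // Hines elimination: children indexed after parents
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = (-0.5 * g_axial_uS[i]) / diag[i];
      diag[p] -= f * (-0.5 * g_axial_uS[i]);
      rhs[p] -= f * rhs[i];
    }
    double v0 = rhs[0] / diag[0];
    v[0] = v0;
    for (int i = 1; i < n; ++i) {
      v[i] = (rhs[i] - (-0.5 * g_axial_uS[i]) * v[parent[i]]) / diag[i];
    }

    if (!std::isfinite(v[0]) || std::fabs(v[0]) > 1e4)
      stop("cable solver diverged (non-finite or huge voltage) at t = %f ms", tnext);

    if (step >= 0 && ((step + 1) % record_every == 0 || step == nstep - 1)) {
      if (outrow < nout) {
        tout[outrow] = tnext;
        for (int r = 0; r < nrec; ++r) vm(outrow, r) = v[record_comp[r]];
        ++outrow;
      }
    }
  }

  NumericVector finalv(n);
  for (int i = 0; i < n; ++i) finalv[i] = v[i];
  return List::create(_["time_ms"] = tout[Range(0, outrow - 1)],
                      _["vm"] = vm(Range(0, outrow - 1), _),
                      _["final_v"] = finalv);
}
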