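// Implicit compartmental Hodgkin-Huxley cable integrator.
//
// Topology is a tree given by a parent vector with parent[i] < i, so the
// linearised backward-Euler system is solved exactly by a Hines sweep
// (leaf-to-root elimination, root-to-leaf substitution) in O(n) per step.
// Gating variables advance by exponential (Rush-Larsen) integration; the
// voltage step is backward Euler with conductances frozen at the updated
// gates. Rate functions are tabulated on a 0.05 mV grid with linear
// interpolation, NEURON-style; tables embed exp(-dt/tau) so they are rebuilt
// whenever dt changes.
//
// Units: mV, ms, nA, uS, nF. Conductance densities arrive as uS per
// compartment (density * area already applied on the R side).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double V_MIN = -120.0, V_MAX = 80.0, V_STEP = 0.05;
const int N_TAB = static_cast<int>((V_MAX - V_MIN) / V_STEP) + 1;

inline double vtrap(double x, double y) {
  // x / (exp(x / y) - 1) with the removable singularity at x = 0 filled in
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct RateTables {
  std::vector<double> minf, mfac, hinf, hfac, ninf, nfac;
  RateTables(double dt)
      : minf(N_TAB), mfac(N_TAB), hinf(N_TAB), hfac(N_TAB), ninf(N_TAB),
        nfac(N_TAB) {
    for (int i = 0; i < N_TAB; ++i) {
      double v = V_MIN + i * V_STEP;
      double am = 0.1 * vtrap(-(v + 40.0), 10.0);
      double bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
      double ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
      double bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
      double an = 0.01 * vtrap(-(v + 55.0), 10.0);
      double bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
      minf[i] = am / (am + bm);
      mfac[i] = std::exp(-dt * (am + bm));
      hinf[i] = ah / (ah + bh);
      hfac[i] = std::exp(-dt * (ah + bh));
      ninf[i] = an / (an + bn);
      nfac[i] = std::exp(-dt * (an + bn));
    }
  }
  inline void lookup(double v, double &mi, double &mf, double &hi, double &hf,
                     double &ni, double &nf) const {
    double u = (v - V_MIN) / V_STEP;
    if (u < 0.0) u = 0.0;
    if (u > N_TAB - 1.001) u = N_TAB - 1.001;
    int i = static_cast<int>(u);
    double w = u - i;
    mi = minf[i] + w * (minf[i + 1] - minf[i]);
    mf = mfac[i] + w * (mfac[i + 1] - mfac[i]);
    hi = hinf[i] + w * (hinf[i + 1] - hinf[i]);
    hf = hfac[i] + w * (hfac[i + 1] - hfac[i]);
    ni = ninf[i] + w * (ninf[i + 1] - ninf[i]);
    nf = nfac[i] + w * (nfac[i + 1] - nfac[i]);
  }
};

} // namespace

// Steady-state gate values at a voltage (exported for initialisation).
// [[Rcpp::export(name = ".hh_gate_steady")]]
NumericVector hh_gate_steady(double v) {
  double am = 0.1 * vtrap(-(v + 40.0), 10.0);
  double bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
  double ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  double an = 0.01 * vtrap(-(v + 55.0), 10.0);
  double bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  return NumericVector::create(_["m"] = am / (am + bm), _["h"] = ah / (ah + bh),
                               _["n"] = an / (an + bn));
}

// [[Rcpp::export(name = ".cable_hh_run")]]
List cable_hh_run(IntegerVector parent,   // parent index (0-based), -1 at root
                  NumericVector g_axial,  // uS, coupling to parent (0 at root)
                  NumericVector gna,      // uS per compartment
                  NumericVector gk,       // uS
                  NumericVector gl,       // uS
                  double ena, double ek, double el,
                  NumericVector cap,      // nF per compartment
                  double v_init, double dt, int n_steps,
                  NumericVector pulse_onset, NumericVector pulse_dur,
                  NumericVector pulse_amp, int inj_index,
                  IntegerVector probe_idx, bool record_all, int record_stride) {
  const int n = parent.size();
  const int np = probe_idx.size();
  RateTables tab(dt);

  std::vector<double> v(n, v_init), m(n), h(n), gn(n);
  {
    NumericVector g0 = hh_gate_steady(v_init);
    for (int i = 0; i < n; ++i) {
      m[i] = g0[0];
      h[i] = g0[1];
      gn[i] = g0[2];
    }
  }

  std::vector<double> diag(n), rhs(n);
  NumericMatrix probes(n_steps + 1, np);
  int n_rec = record_all ? (n_steps / record_stride + 1) : 0;
  NumericMatrix vrec(record_all ? n : 0, n_rec);
  NumericVector trec(n_rec);
  for (int p = 0; p < np; ++p) probes(0, p) = v[probe_idx[p]];
  if (record_all) {
    for (int i = 0; i < n; ++i) vrec(i, 0) = v[i];
    trec[0] = 0.0;
  }
  int rec_col = 1;
  bool diverged = false;
  const int n_pulses = pulse_onset.size();

  for (int s = 1; s <= n_steps && !diverged; ++s) {
    double t_prev = (s - 1) * dt;
    // gates: Rush-Larsen at the pre-step voltage
    for (int i = 0; i < n; ++i) {
      double mi, mf, hi, hf, ni, nf;
      tab.lookup(v[i], mi, mf, hi, hf, ni, nf);
      m[i] = mi + (m[i] - mi) * mf;
      h[i] = hi + (h[i] - hi) * hf;
      gn[i] = ni + (gn[i] - ni) * nf;
    }
    // assemble the linearised backward-Euler system
    double inj = 0.0;
    for (int q = 0; q < n_pulses; ++q) {
      if (t_prev >= pulse_onset[q] && t_prev < pulse_onset[q] + pulse_dur[q])
        inj = pulse_amp[q];
    }
    for (int i = 0; i < n; ++i) {
      double gna_i = gna[i] * m[i] * m[i] * m[i] * h[i];
      double gk_i = gk[i] * gn[i] * gn[i] * gn[i] * gn[i];
      double cdt = cap[i] / dt;
      diag[i] = cdt + gna_i + gk_i + gl[i];
      rhs[i] = cdt * v[i] + gna_i * ena + gk_i * ek + gl[i] * el;
    }
    if (inj != 0.0) rhs[inj_index] += inj;
    for (int i = 1; i < n; ++i) {
      diag[i] += g_axial[i];
      diag[parent[i]] += g_axial[i];
    }
    // Hines solve: eliminate children into parents, then substitute
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = g_axial[i] / diag[i];
      diag[p] -= f * g_axial[i];
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_axial[i] * v[parent[i]]) / diag[i];

    if (!std::isfinite(v[0]) || !std::isfinite(v[n - 1])) diverged = true;
    for (int p = 0; p < np; ++p) probes(s, p) = v[probe_idx[p]];
    if (record_all && s % record_stride == 0 && rec_col < n_rec) {
      for (int i = 0; i < n; ++i) vrec(i, rec_col) = v[i];
      trec[rec_col] = s * dt;
      ++rec_col;
    }
  }

  NumericVector vfin(n);
  for (int i = 0; i < n; ++i) vfin[i] = v[i];
  return List::create(_["probes"] = probes, _["v_record"] = vrec,
                      _["t_record"] = trec, _["v_final"] = vfin,
                      _["diverged"] = diverged);
}
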