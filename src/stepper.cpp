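// Implicit (backward-Euler) integrator for the branched cable equation with
// Hodgkin-Huxley channels and a double-cable myelin layer.
//
// Layout contract (from discretize()): compartments are ordered so that every
// parent index is smaller than its child, soma is compartment 0, and the
// compartments of one internode section are consecutive. The voltage system
// is solved exactly per step by Hines elimination; for sheathed internode
// compartments the periaxonal potential W is eliminated locally (its
// coefficients are constant in time because sheathed axolemma carries only
// leak), except for the small periaxonal axial current which is advanced
// explicitly (its time constant, ~10^2 us at the default geometry, is far
// above the spike time step). Gating variables advance by exact exponential
// relaxation toward their steady state at the pre-step voltage.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double trap(double v, double th, double a, double q) {
  double x = v - th;
  if (std::fabs(x / q) < 1e-6) return a * q * (1.0 + x / (2.0 * q));
  return a * x / (1.0 - std::exp(-x / q));
}

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

struct NaPar { double tha, qa, Ra, Rb, thi1, thi2, qd, qg, Rd, Rg, thinf, qinf, scale; };

struct Kin {
  NaPar na12, na16;
  double kdr_tha, kdr_qa, kdr_Ra, kdr_Rb, kdr_scale;
  double k1_vmh, k1_vmk, k1_tmin, k1_tamp, k1_tvh, k1_tk, k1_vhh, k1_vhk, k1_tauh;
  double ca_vmh, ca_vmk, ca_tmin, ca_tamp, ca_tvh, ca_tk, ca_pow;
  double ena, ek, eca;
};

static Kin unpack(const NumericVector& p) {
  Kin k;
  int i = 0;
  NaPar* nas[2] = { &k.na12, &k.na16 };
  for (int c = 0; c < 2; ++c) {
    NaPar& n = *nas[c];
    n.tha = p[i++]; n.qa = p[i++]; n.Ra = p[i++]; n.Rb = p[i++];
    n.thi1 = p[i++]; n.thi2 = p[i++]; n.qd = p[i++]; n.qg = p[i++];
    n.Rd = p[i++]; n.Rg = p[i++]; n.thinf = p[i++]; n.qinf = p[i++];
    n.scale = p[i++];
  }
  k.kdr_tha = p[i++]; k.kdr_qa = p[i++]; k.kdr_Ra = p[i++]; k.kdr_Rb = p[i++];
  k.kdr_scale = p[i++];
  k.k1_vmh = p[i++]; k.k1_vmk = p[i++]; k.k1_tmin = p[i++]; k.k1_tamp = p[i++];
  k.k1_tvh = p[i++]; k.k1_tk = p[i++]; k.k1_vhh = p[i++]; k.k1_vhk = p[i++];
  k.k1_tauh = p[i++];
  k.ca_vmh = p[i++]; k.ca_vmk = p[i++]; k.ca_tmin = p[i++]; k.ca_tamp = p[i++];
  k.ca_tvh = p[i++]; k.ca_tk = p[i++]; k.ca_pow = p[i++];
  k.ena = p[i++]; k.ek = p[i++]; k.eca = p[i++];
  return k;
}

static inline void na_update(const NaPar& n, double v, double dt,
                             double& m, double& h) {
  double am = trap(v, n.tha, n.Ra, n.qa);
  double bm = trap(-v, -n.tha, n.Rb, n.qa);
  double minf = am / (am + bm);
  double taum = 1.0 / (n.scale * (am + bm));
  double ah = trap(v, n.thi1, n.Rd, n.qd);
  double bh = trap(-v, -n.thi2, n.Rg, n.qg);
  double hinf = 1.0 / (1.0 + std::exp((v - n.thinf) / n.qinf));
  double tauh = 1.0 / (n.scale * (ah + bh));
  m = minf + (m - minf) * std::exp(-dt / taum);
  h = hinf + (h - hinf) * std::exp(-dt / tauh);
}

// [[Rcpp::export(name = ".cable_step_run")]]
List cable_step_run(List model, List state, double dt, int nsteps,
                    IntegerVector inj_comp, NumericVector inj_amp,
                    IntegerVector rec_idx, int rec_stride,
                    IntegerVector rec_ca_idx) {
  const int n = as<int>(model["n"]);
  const IntegerVector parent = model["parent"];
  const NumericVector g_ax = model["g_ax"];
  const NumericVector cm = model["cm"];
  const NumericMatrix G = model["G"]; // cols: na12 na16 kdr kv1 ca leak
  const NumericVector eleak = model["eleak"];
  const IntegerVector is_sheath = model["is_sheath"];
  const NumericVector gm_sheath = model["gm_sheath"];
  const NumericVector cm_sheath = model["cm_sheath"];
  const NumericVector g_peri_prev = model["g_peri_prev"];
  const NumericVector g_peri_ground = model["g_peri_ground"];
  const Kin kin = unpack(as<NumericVector>(model["kin_packed"]));

  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector W = clone(as<NumericVector>(state["W"]));
  NumericVector m12 = clone(as<NumericVector>(state["m12"]));
  NumericVector h12 = clone(as<NumericVector>(state["h12"]));
  NumericVector m16 = clone(as<NumericVector>(state["m16"]));
  NumericVector h16 = clone(as<NumericVector>(state["h16"]));
  NumericVector nkdr = clone(as<NumericVector>(state["n_kdr"]));
  NumericVector mk1 = clone(as<NumericVector>(state["m_kv1"]));
  NumericVector hk1 = clone(as<NumericVector>(state["h_kv1"]));
  NumericVector mca = clone(as<NumericVector>(state["m_ca"]));

  std::vector<double> d(n), od(n), rhs(n), Wold(n), Vn(n);
  // constant pieces of the sheath elimination
  std::vector<double> sh_ag(n), sh_D(n), sh_diag(n), sh_ab(n);
  for (int i = 0; i < n; ++i) {
    if (is_sheath[i]) {
      double alpha = cm[i] / dt, beta = cm_sheath[i] / dt, g = G(i, 5);
      double ag = alpha + g;
      double D = alpha + beta + gm_sheath[i] + g;
      sh_ag[i] = ag;
      sh_D[i] = D;
      sh_diag[i] = ag - ag * ag / D;
      sh_ab[i] = alpha + beta;
    }
  }
  std::vector<double> inj(n, 0.0);
  for (int k = 0; k < inj_comp.size(); ++k) inj[inj_comp[k]] += inj_amp[k];

  const int nrec = nsteps / rec_stride;
  NumericMatrix recV(rec_idx.size(), nrec);
  NumericMatrix recCa(rec_ca_idx.size(), nrec);
  NumericVector rec_t(nrec);
  int rec_col = 0;

  for (int step = 1; step <= nsteps; ++step) {
    // 1. gates (exact exponential relaxation at V^n)
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      if (G(i, 0) > 0) na_update(kin.na12, v, dt, m12[i], h12[i]);
      if (G(i, 1) > 0) na_update(kin.na16, v, dt, m16[i], h16[i]);
      if (G(i, 2) > 0) {
        double an = trap(v, kin.kdr_tha, kin.kdr_Ra, kin.kdr_qa);
        double bn = trap(-v, -kin.kdr_tha, kin.kdr_Rb, kin.kdr_qa);
        double ninf = an / (an + bn);
        double tau = 1.0 / (kin.kdr_scale * (an + bn));
        nkdr[i] = ninf + (nkdr[i] - ninf) * std::exp(-dt / tau);
      }
      if (G(i, 3) > 0) {
        double minf = boltz(v, kin.k1_vmh, kin.k1_vmk);
        double taum = kin.k1_tmin + kin.k1_tamp * boltz(-v, -kin.k1_tvh, kin.k1_tk);
        mk1[i] = minf + (mk1[i] - minf) * std::exp(-dt / taum);
        double hinf = 1.0 / (1.0 + std::exp((v - kin.k1_vhh) / kin.k1_vhk));
        hk1[i] = hinf + (hk1[i] - hinf) * std::exp(-dt / kin.k1_tauh);
      }
      if (G(i, 4) > 0) {
        double minf = boltz(v, kin.ca_vmh, kin.ca_vmk);
        double taum = kin.ca_tmin + kin.ca_tamp * boltz(-v, -kin.ca_tvh, kin.ca_tk);
        mca[i] = minf + (mca[i] - minf) * std::exp(-dt / taum);
      }
    }
    // 2. assemble
    for (int i = 0; i < n; ++i) {
      if (is_sheath[i]) {
        double alpha = cm[i] / dt, g = G(i, 5);
        double J = g_peri_ground[i] * W[i];
        if (g_peri_prev[i] > 0) J += g_peri_prev[i] * (W[i] - W[i - 1]);
        if (i + 1 < n && g_peri_prev[i + 1] > 0)
          J += g_peri_prev[i + 1] * (W[i] - W[i + 1]);
        double Rw = sh_ab[i] * W[i] - alpha * V[i] - g * eleak[i] - J;
        d[i] = sh_diag[i];
        rhs[i] = alpha * V[i] - alpha * W[i] + g * eleak[i] + inj[i] +
                 sh_ag[i] / sh_D[i] * Rw;
        Wold[i] = W[i];
        Vn[i] = V[i];
      } else {
        double gtot = G(i, 5);
        double ge = G(i, 5) * eleak[i];
        if (G(i, 0) > 0) {
          double go = G(i, 0) * m12[i] * m12[i] * m12[i] * h12[i];
          gtot += go; ge += go * kin.ena;
        }
        if (G(i, 1) > 0) {
          double go = G(i, 1) * m16[i] * m16[i] * m16[i] * h16[i];
          gtot += go; ge += go * kin.ena;
        }
        if (G(i, 2) > 0) {
          double go = G(i, 2) * nkdr[i];
          gtot += go; ge += go * kin.ek;
        }
        if (G(i, 3) > 0) {
          double go = G(i, 3) * mk1[i] * hk1[i];
          gtot += go; ge += go * kin.ek;
        }
        if (G(i, 4) > 0) {
          double go = G(i, 4) * std::pow(mca[i], kin.ca_pow);
          gtot += go; ge += go * kin.eca;
        }
        d[i] = cm[i] / dt + gtot;
        rhs[i] = cm[i] / dt * V[i] + ge + inj[i];
      }
      od[i] = -g_ax[i];
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      d[i] += g_ax[i];
      d[p] += g_ax[i];
    }
    // 3. Hines elimination (children fold into parents), then back-substitute
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = od[i] / d[i];
      d[p] -= f * od[i];
      rhs[p] -= f * rhs[i];
    }
    V[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) {
      V[i] = (rhs[i] - od[i] * V[parent[i]]) / d[i];
    }
    // 4. periaxonal potentials: W' = (ag V' + (a+b)W^n - a V^n + g E - J)/D
    for (int i = 0; i < n; ++i) {
      if (is_sheath[i]) {
        double alpha = cm[i] / dt, g = G(i, 5);
        double J = g_peri_ground[i] * Wold[i];
        if (g_peri_prev[i] > 0) J += g_peri_prev[i] * (Wold[i] - Wold[i - 1]);
        if (i + 1 < n && g_peri_prev[i + 1] > 0)
          J += g_peri_prev[i + 1] * (Wold[i] - Wold[i + 1]);
        W[i] = (sh_ag[i] * V[i] + sh_ab[i] * Wold[i] - alpha * Vn[i] -
                g * eleak[i] - J) / sh_D[i];
      }
    }
    if (rec_stride > 0 && step % rec_stride == 0) {
      for (int k = 0; k < rec_idx.size(); ++k) recV(k, rec_col) = V[rec_idx[k]];
      for (int k = 0; k < rec_ca_idx.size(); ++k) {
        int i = rec_ca_idx[k];
        recCa(k, rec_col) = G(i, 4) * std::pow(mca[i], kin.ca_pow) * (V[i] - kin.eca);
      }
      rec_t[rec_col] = step * dt;
      ++rec_col;
    }
    if (!std::isfinite(V[0])) {
      stop("voltage diverged (NaN/Inf) at t = %f ms", step * dt);
    }
  }

  return List::create(
    _["V"] = V, _["W"] = W,
    _["m12"] = m12, _["h12"] = h12, _["m16"] = m16, _["h16"] = h16,
    _["n_kdr"] = nkdr, _["m_kv1"] = mk1, _["h_kv1"] = hk1, _["m_ca"] = mca,
    _["rec_V"] = recV, _["rec_ICa"] = recCa, _["rec_t"] = rec_t
  );
}
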