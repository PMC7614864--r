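// Compartmental conductance-based neuron simulation core.
//
// Numerics: backward-Euler solve of the branched cable equation by a
// tree-structured (Hines) direct elimination each step; Hodgkin-Huxley
// gates advanced by exponential Euler with pre-tabulated steady states and
// step factors; Goldman-Hodgkin-Katz (GHK) channel and synaptic currents
// treated explicitly (evaluated at the current voltage); calcium handled in
// four concentric annuli per compartment with mobile buffer, membrane pump
// and radial + longitudinal diffusion.
//
// Unit conventions (NEURON-like, internally consistent):
//   t ms, V mV, capacitance nF, absolute current nA, axial conductance uS,
//   membrane current densities uA/cm^2, channel densities mS/cm^2 (ohmic)
//   or cm/s (GHK permeability), concentrations mM, lengths um (calcium
//   geometry), areas cm^2 (membrane).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.33212;   // C/mol
static const double RGAS    = 8.31446;       // J/(mol K)

// GHK constant-field flux, returns current density in uA/cm^2 (outward +).
// P cm/s, v mV, concentrations mM (= 1e-6 mol/cm^3), z valence, T kelvin.
static inline double ghk_uA(double P, double v, double ci, double co,
                            double z, double T) {
  const double vv = v * 1e-3;
  const double xi = z * vv * FARADAY / (RGAS * T);
  double term; // frac * xi with the removable singularity handled
  if (std::fabs(xi) < 1e-6) {
    // (ci - co e^{-xi}) * xi/(1-e^{-xi}) = (ci-co) + xi*(ci+co)/2 + O(xi^2)
    term = (ci - co) + 0.5 * xi * (ci + co);
  } else {
    const double em = std::exp(-xi);
    term = xi * (ci - co * em) / (1.0 - em);
  }
  return P * z * FARADAY * term * 1e-6 * 1e6; // uA/cm^2
}

struct Gate {
  int channel;      // channel index
  int expo;         // exponent
  int kind;         // 0 voltage-tabulated, 1 calcium Hill, 2 voltage+calcium
  // kind 0: interleaved (inf, afac) pairs per voltage-grid point
  std::vector<double> tab;
  // kind 1: Hill
  double kd, nhill;
  int nh_int; bool hill_int;
  // kind 2:
  double vh0, sh, caref, slope;
  double afac_const; // 1 - exp(-dt/tau) for constant-tau kinds
};

struct Channel {
  int law;                 // 0 ohmic, 1 ghk-calcium
  double erev;
  std::vector<int> comps;        // active compartment indices
  std::vector<double> dens;      // density per active compartment
  std::vector<int> gates;        // gate indices
};

static inline double gate_pow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List net, double dt, int nsteps, double t0,
              List init_state, int record_every,
              IntegerVector v_sites, IntegerVector ca_sites) {
  // ---- geometry / passive ----
  const int n = as<int>(net["n_comp"]);
  IntegerVector parent = net["parent"];      // 0-based, -1 root
  NumericVector g_ax = net["g_ax"];          // uS to parent
  NumericVector cm_nf = net["cm_nf"];        // nF
  NumericVector area = net["area"];          // cm^2
  NumericVector g_pas = net["g_pas"];        // mS/cm^2
  const double e_pas = as<double>(net["e_pas"]);
  NumericVector radius = net["radius_um"];
  NumericVector length = net["length_um"];
  const double T = as<double>(net["temp_K"]);

  // voltage table grid
  const double vmin = as<double>(net["vmin"]);
  const double dv = as<double>(net["dv"]);
  const int nv = as<int>(net["nv"]);

  // ---- channels and gates ----
  List chs = net["channels"];
  List gts = net["gates"];
  const int nch = chs.size();
  const int ng = gts.size();
  std::vector<Channel> C(nch);
  std::vector<Gate> G(ng);
  for (int g = 0; g < ng; ++g) {
    List gl = gts[g];
    G[g].channel = as<int>(gl["channel"]);
    G[g].expo = as<int>(gl["exponent"]);
    G[g].kind = as<int>(gl["kind"]);
    if (G[g].kind == 0) {
      std::vector<double> inf_tab = as<std::vector<double> >(gl["inf"]);
      std::vector<double> afac_tab = as<std::vector<double> >(gl["afac"]);
      G[g].tab.resize(2 * inf_tab.size());
      for (size_t k = 0; k < inf_tab.size(); ++k) {
        G[g].tab[2 * k] = inf_tab[k];
        G[g].tab[2 * k + 1] = afac_tab[k];
      }
    } else if (G[g].kind == 1) {
      G[g].kd = as<double>(gl["kd"]);
      G[g].nhill = as<double>(gl["nhill"]);
      G[g].nh_int = (int)std::floor(G[g].nhill + 0.5);
      G[g].hill_int = std::fabs(G[g].nhill - G[g].nh_int) < 1e-9;
      G[g].afac_const = as<double>(gl["afac"]);
    } else {
      G[g].vh0 = as<double>(gl["vh0"]);
      G[g].sh = as<double>(gl["sh"]);
      G[g].caref = as<double>(gl["caref"]);
      G[g].slope = as<double>(gl["k"]);
      G[g].afac_const = as<double>(gl["afac"]);
    }
  }
  for (int c = 0; c < nch; ++c) {
    List cl = chs[c];
    C[c].law = as<int>(cl["law"]);
    C[c].erev = as<double>(cl["erev"]);
    C[c].comps = as<std::vector<int> >(cl["comps"]);
    C[c].dens = as<std::vector<double> >(cl["dens"]);
    C[c].gates = as<std::vector<int> >(cl["gates"]);
  }

  // ---- calcium config ----
  List cacfg = net["calcium"];
  const int nsh = 4;
  const double D_ca = as<double>(cacfg["D_ca"]);     // um^2/ms
  const double D_buf = as<double>(cacfg["D_buf"]);
  const double k_on = as<double>(cacfg["k_on"]);     // /mM/ms
  const double k_off = as<double>(cacfg["k_off"]);   // /ms
  const double pump_km = as<double>(cacfg["pump_km"]); // mM
  const double ca0 = as<double>(cacfg["ca0"]);       // mM
  const double cao = as<double>(cacfg["ca_out"]);    // mM
  NumericVector totbuf = cacfg["totbuf_comp"];       // mM per compartment
  NumericVector pump_v = cacfg["pump_vmax_comp"];    // mM um / ms (flux dens.)
  const bool long_diff = as<bool>(cacfg["longitudinal"]);

  // shell geometry per compartment, with all constant factors (interface
  // couplings x dt, inverse volumes, influx and pump scalings) precomputed
  std::vector<double> shvol(n * nsh);       // um^3
  std::vector<double> inv_shvol(n * nsh);
  std::vector<double> rad_ca(n * (nsh - 1)), rad_bf(n * (nsh - 1));
  std::vector<double> sa_um2(n);            // membrane area um^2
  std::vector<double> f_in(n);              // uA/cm^2 -> mM per step
  std::vector<double> pcoef(n);             // pump: mM per step per hill
  for (int i = 0; i < n; ++i) {
    double r = radius[i], L = length[i], dr = r / nsh;
    sa_um2[i] = 2.0 * M_PI * r * L;
    for (int s = 0; s < nsh; ++s) {
      double ro = r - s * dr, ri = r - (s + 1) * dr;
      shvol[i * nsh + s] = M_PI * (ro * ro - ri * ri) * L;
      inv_shvol[i * nsh + s] = 1.0 / shvol[i * nsh + s];
    }
    for (int s = 0; s < nsh - 1; ++s) {
      double rif = r - (s + 1) * dr;
      double aif = 2.0 * M_PI * rif * L / dr;     // um
      rad_ca[i * (nsh - 1) + s] = D_ca * aif * dt;
      rad_bf[i * (nsh - 1) + s] = D_buf * aif * dt;
    }
    f_in[i] = (area[i] * 1e8) * 10.0 * dt /
              (2.0 * FARADAY * shvol[i * nsh + 0]);
    pcoef[i] = pump_v[i] * sa_um2[i] * inv_shvol[i * nsh + 0] * dt;
  }
  std::vector<double> lon_ca(n * nsh, 0.0), lon_bf(n * nsh, 0.0);
  if (long_diff) {
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      double dist = 0.5 * (length[i] + length[p]);
      for (int s = 0; s < nsh; ++s) {
        double ai = shvol[i * nsh + s] / length[i];
        double ap = shvol[p * nsh + s] / length[p];
        double aif = (ai < ap ? ai : ap);
        lon_ca[i * nsh + s] = D_ca * aif / dist * dt;
        lon_bf[i * nsh + s] = D_buf * aif / dist * dt;
      }
    }
  }
  const double hill0 = ca0 / (ca0 + pump_km);

  // ---- synapses (aggregated per compartment in R) ----
  List syn = net["synapses"];
  const bool has_syn = as<bool>(syn["enabled"]);
  std::vector<int> syn_comp;
  std::vector<double> syn_pA, syn_pN; // summed permeabilities cm/s
  NumericVector ev_times;
  double a_tr = 2, a_td = 10, n_tr = 5, n_td = 50;
  double a_norm = 1, n_norm = 1, mg_o = 2;
  double nai = 18, nao = 140, ki = 140, ko = 5;
  double pna = 1, pk = 1, pca = 10.6;
  double aA = 0, aB = 0, nA = 0, nB = 0; // kernel states (shared, synchronous)
  double fa_r = 0, fa_d = 0, fn_r = 0, fn_d = 0;
  int next_ev = 0;
  if (has_syn) {
    syn_comp = as<std::vector<int> >(syn["comp"]);
    syn_pA = as<std::vector<double> >(syn["pbar_ampa"]);
    syn_pN = as<std::vector<double> >(syn["pbar_nmda"]);
    ev_times = syn["event_times"];
    a_tr = as<double>(syn["ampa_tau_r"]); a_td = as<double>(syn["ampa_tau_d"]);
    n_tr = as<double>(syn["nmda_tau_r"]); n_td = as<double>(syn["nmda_tau_d"]);
    a_norm = as<double>(syn["ampa_norm"]);
    n_norm = as<double>(syn["nmda_norm"]);
    mg_o = as<double>(syn["mg_out"]);
    nai = as<double>(syn["na_in"]); nao = as<double>(syn["na_out"]);
    ki = as<double>(syn["k_in"]); ko = as<double>(syn["k_out"]);
    pna = as<double>(syn["p_na"]); pk = as<double>(syn["p_k"]);
    pca = as<double>(syn["p_ca"]);
    fa_r = std::exp(-dt / a_tr); fa_d = std::exp(-dt / a_td);
    fn_r = std::exp(-dt / n_tr); fn_d = std::exp(-dt / n_td);
  }

  // ---- stimuli ----
  NumericMatrix steps = net["stim_steps"]; // cols: comp, t_on, t_off, amp_nA
  // direct calcium influx events (testing fixture): inward Ca current
  // density in uA/cm^2 applied to a compartment's membrane
  NumericMatrix ca_steps = net["ca_steps"]; // comp, t_on, t_off, amp_uA_cm2
  List wave = net["stim_wave"];
  const bool has_wave = as<bool>(wave["enabled"]);
  int wave_comp = 0; double wave_t0 = 0; NumericVector wave_i;
  if (has_wave) {
    wave_comp = as<int>(wave["comp"]);
    wave_t0 = as<double>(wave["t0"]);
    wave_i = wave["i_nA"];
  }

  // ---- state ----
  std::vector<double> v(n), ca(n * nsh), buf(n * nsh), cab(n * nsh);
  std::vector<double> gs(ng * n, 0.0); // gate states (gate-major)
  bool restore = init_state.size() > 0;
  if (restore) {
    NumericVector vs = init_state["v"];
    NumericVector cas = init_state["ca"], bufs = init_state["buf"],
      cabs = init_state["cab"], gss = init_state["gates"];
    for (int i = 0; i < n; ++i) v[i] = vs[i];
    for (int i = 0; i < n * nsh; ++i) {
      ca[i] = cas[i]; buf[i] = bufs[i]; cab[i] = cabs[i];
    }
    for (int i = 0; i < ng * n; ++i) gs[i] = gss[i];
    if (has_syn && init_state.containsElementNamed("syn")) {
      NumericVector ss = init_state["syn"];
      aA = ss[0]; aB = ss[1]; nA = ss[2]; nB = ss[3];
    }
  } else {
    const double v_init = as<double>(net["v_init"]);
    for (int i = 0; i < n; ++i) v[i] = v_init;
    for (int i = 0; i < n; ++i)
      for (int s = 0; s < nsh; ++s) {
        int idx = i * nsh + s;
        ca[idx] = ca0;
        double kd_b = k_off / k_on;
        cab[idx] = totbuf[i] * ca0 / (ca0 + kd_b);
        buf[idx] = totbuf[i] - cab[idx];
      }
    // gates at steady state for v_init / resting calcium
    for (int g = 0; g < ng; ++g) {
      for (int i = 0; i < n; ++i) {
        double x;
        if (G[g].kind == 0) {
          double p = (v[i] - vmin) / dv;
          int k = (int)p; if (k < 0) k = 0; if (k > nv - 2) k = nv - 2;
          double w = p - k;
          x = G[g].tab[2 * k] * (1 - w) + G[g].tab[2 * k + 2] * w;
        } else if (G[g].kind == 1) {
          double c = ca[i * nsh];
          double r = std::pow(G[g].kd / c, G[g].nhill);
          x = 1.0 / (1.0 + r);
        } else {
          double c = ca[i * nsh];
          double vh = G[g].vh0 - G[g].sh * std::log10(c / G[g].caref);
          x = 1.0 / (1.0 + std::exp(-(v[i] - vh) / G[g].slope));
        }
        gs[g * n + i] = x;
      }
    }
  }

  // recording buffers
  const int nrec = (nsteps + record_every - 1) / record_every;
  NumericMatrix rec_v(nrec, v_sites.size());
  NumericMatrix rec_ca(nrec, ca_sites.size());
  NumericVector rec_t(nrec);
  int rec_i = 0;

  // solver workspaces
  std::vector<double> d(n), rhs(n), ica_memb(n); // ica in uA/cm^2
  std::vector<double> gsum(n), gesum(n), iexp(n), i_ext(n), pca_eff(n);

  // skip past events earlier than t0 (restored runs)
  if (has_syn) while (next_ev < ev_times.size() && ev_times[next_ev] < t0)
    ++next_ev;

  bool diverged = false; double t_div = NA_REAL;
  double t = t0;

  for (int istep = 0; istep < nsteps; ++istep) {
    // ---- 0. record the state at the start of the step ----
    if (istep % record_every == 0) {
      for (int s = 0; s < v_sites.size(); ++s) rec_v(rec_i, s) = v[v_sites[s]];
      for (int s = 0; s < ca_sites.size(); ++s)
        rec_ca(rec_i, s) = ca[ca_sites[s] * nsh];
      rec_t[rec_i] = t;
      ++rec_i;
    }

    // ---- 1. gates: exponential Euler using V(t), submembrane Ca(t) ----
    for (int c = 0; c < nch; ++c) {
      for (size_t gg = 0; gg < C[c].gates.size(); ++gg) {
        Gate &g = G[C[c].gates[gg]];
        double *st = &gs[C[c].gates[gg] * n];
        const std::vector<int> &ix = C[c].comps;
        if (g.kind == 0) {
          const double *tb = g.tab.data();
          for (size_t j = 0; j < ix.size(); ++j) {
            int i = ix[j];
            double p = (v[i] - vmin) / dv;
            int k = (int)p; if (k < 0) k = 0; if (k > nv - 2) k = nv - 2;
            double w = p - k;
            const double *t0_ = tb + 2 * k;
            double xinf = t0_[0] * (1 - w) + t0_[2] * w;
            double af = t0_[1] * (1 - w) + t0_[3] * w;
            st[i] += (xinf - st[i]) * af;
          }
        } else if (g.kind == 1) {
          for (size_t j = 0; j < ix.size(); ++j) {
            int i = ix[j];
            double c_ = ca[i * nsh]; if (c_ < 1e-9) c_ = 1e-9;
            double r = g.kd / c_;
            double rn = g.hill_int ? gate_pow(r, g.nh_int)
                                   : std::pow(r, g.nhill);
            double xinf = 1.0 / (1.0 + rn);
            st[i] += (xinf - st[i]) * g.afac_const;
          }
        } else {
          for (size_t j = 0; j < ix.size(); ++j) {
            int i = ix[j];
            double c_ = ca[i * nsh]; if (c_ < 1e-9) c_ = 1e-9;
            double vh = g.vh0 - g.sh * std::log10(c_ / g.caref);
            double xinf = 1.0 / (1.0 + std::exp(-(v[i] - vh) / g.slope));
            st[i] += (xinf - st[i]) * g.afac_const;
          }
        }
      }
    }

    // ---- 2. synaptic kernel states ----
    double sA = 0, sN = 0;
    if (has_syn) {
      // insert events due at the interval start, then decay across the
      // step, so each event kernel decays for exactly (t_end - t_event)
      while (next_ev < ev_times.size() &&
             ev_times[next_ev] <= t + 1e-9) {
        aA += 1.0; aB += 1.0; nA += 1.0; nB += 1.0; ++next_ev;
      }
      aA *= fa_r; aB *= fa_d; nA *= fn_r; nB *= fn_d;
      sA = a_norm * (aB - aA);
      sN = n_norm * (nB - nA);
    }

    // ---- 3. assemble linear system ----
    // per compartment: implicit ohmic part (g, g*E), explicit GHK part
    // (current evaluated at V(t))
    for (int i = 0; i < n; ++i) {
      gsum[i] = g_pas[i]; gesum[i] = g_pas[i] * e_pas;
      iexp[i] = 0.0; ica_memb[i] = 0.0;
    }
    // accumulate ohmic conductances and, for GHK calcium channels, the
    // per-compartment summed open permeability (one GHK evaluation per
    // compartment, since all calcium channels see the same voltage and
    // concentrations)
    std::fill(pca_eff.begin(), pca_eff.end(), 0.0);
    for (int c = 0; c < nch; ++c) {
      const std::vector<int> &ix = C[c].comps;
      for (size_t j = 0; j < ix.size(); ++j) {
        int i = ix[j];
        double open = 1.0;
        for (size_t gg = 0; gg < C[c].gates.size(); ++gg) {
          Gate &g = G[C[c].gates[gg]];
          open *= gate_pow(gs[C[c].gates[gg] * n + i], g.expo);
        }
        if (C[c].law == 0) {
          double gch = C[c].dens[j] * open;      // mS/cm^2
          gsum[i] += gch; gesum[i] += gch * C[c].erev;
        } else {
          pca_eff[i] += C[c].dens[j] * open;     // cm/s
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      if (pca_eff[i] > 0) {
        double ii = ghk_uA(pca_eff[i], v[i], ca[i * nsh], cao, 2.0, T);
        iexp[i] += ii;                           // uA/cm^2, outward +
        ica_memb[i] += ii;
      }
    }
    // synapses: explicit GHK currents at V(t), scaled by gating.
    // Permeabilities arrive pre-multiplied by the synaptic contact area
    // (cm^3/s), so ghk_uA yields uA; divide by compartment area to fold
    // the point current into the membrane density bookkeeping.
    if (has_syn && (sA > 0 || sN > 0)) {
      for (size_t sj = 0; sj < syn_comp.size(); ++sj) {
        int i = syn_comp[sj];
        const double inv_a = 1.0 / area[i]; // uA -> uA/cm^2
        double mgb = 1.0 / (1.0 + mg_o * std::exp(-0.062 * v[i]) / 3.57);
        double ina = 0, ik = 0, ica_s = 0;
        if (sA > 0) {
          ina += ghk_uA(syn_pA[sj] * pna * sA, v[i], nai, nao, 1.0, T);
          ik  += ghk_uA(syn_pA[sj] * pk  * sA, v[i], ki,  ko,  1.0, T);
        }
        if (sN > 0) {
          double f = sN * mgb;
          ina += ghk_uA(syn_pN[sj] * pna * f, v[i], nai, nao, 1.0, T);
          ik  += ghk_uA(syn_pN[sj] * pk  * f, v[i], ki,  ko,  1.0, T);
          ica_s = ghk_uA(syn_pN[sj] * pca * f, v[i], ca[i * nsh], cao, 2.0, T);
        }
        iexp[i] += (ina + ik + ica_s) * inv_a;
        ica_memb[i] += ica_s * inv_a;
      }
    }

    // prescribed calcium influx (does not enter the voltage equation)
    for (int s = 0; s < ca_steps.nrow(); ++s) {
      if (t >= ca_steps(s, 1) - 1e-9 && t < ca_steps(s, 2) - 1e-9)
        ica_memb[(int)ca_steps(s, 0)] -= ca_steps(s, 3);
    }

    // external stimuli (nA), positive = depolarizing injection
    std::fill(i_ext.begin(), i_ext.end(), 0.0);
    for (int s = 0; s < steps.nrow(); ++s) {
      if (t >= steps(s, 1) - 1e-9 && t < steps(s, 2) - 1e-9)
        i_ext[(int)steps(s, 0)] += steps(s, 3);
    }
    if (has_wave) {
      int k = (int)std::floor((t - wave_t0) / dt + 0.5);
      if (k >= 0 && k < wave_i.size()) i_ext[wave_comp] += wave_i[k];
    }

    for (int i = 0; i < n; ++i) {
      // nF/ms = uS ; mS/cm^2 * cm^2 = mS = 1e3 uS
      double gm_us = gsum[i] * area[i] * 1e3;
      double cdt = cm_nf[i] / dt;
      d[i] = cdt + gm_us;
      rhs[i] = cdt * v[i] + gesum[i] * area[i] * 1e3
             - iexp[i] * area[i] * 1e3   // uA/cm^2*cm^2=uA -> nA is *1e3
             + i_ext[i];
    }
    // add axial terms
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      d[i] += g_ax[i];
      d[p] += g_ax[i];
    }
    // Hines elimination (children ordered after parents)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = g_ax[i] / d[i];
      d[p] -= f * g_ax[i];
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_ax[i] * v[parent[i]]) / d[i];

    if (!std::isfinite(v[0]) || std::fabs(v[0]) > 500.0) {
      bool bad = false;
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(v[i]) || std::fabs(v[i]) > 500.0) { bad = true; break; }
      if (bad) { diverged = true; t_div = t; break; }
    }

    // ---- 4. calcium update (explicit, dt stability by small dt) ----
    for (int i = 0; i < n; ++i) {
      double *c_ = &ca[i * nsh];
      double *b_ = &buf[i * nsh];
      double *cb = &cab[i * nsh];
      const double *ivol = &inv_shvol[i * nsh];
      // membrane influx into the submembrane shell (inward current raises
      // calcium) and pump extrusion (net-zero at rest)
      double hill = c_[0] / (c_[0] + pump_km) - hill0;
      double dmemb = -ica_memb[i] * f_in[i] - pcoef[i] * hill;
      // mass-action buffer reaction (all shells)
      double dfr[4];
      for (int s = 0; s < nsh; ++s)
        dfr[s] = (k_on * c_[s] * b_[s] - k_off * cb[s]) * dt;
      // radial diffusion (calcium + mobile buffer, free and bound)
      double dca[4] = {0, 0, 0, 0}, dbf[4] = {0, 0, 0, 0},
             dcb[4] = {0, 0, 0, 0};
      for (int s = 0; s < nsh - 1; ++s) {
        double jc = rad_ca[i * (nsh - 1) + s] * (c_[s + 1] - c_[s]);
        double jb = rad_bf[i * (nsh - 1) + s] * (b_[s + 1] - b_[s]);
        double jcb = rad_bf[i * (nsh - 1) + s] * (cb[s + 1] - cb[s]);
        dca[s] += jc; dca[s + 1] -= jc;
        dbf[s] += jb; dbf[s + 1] -= jb;
        dcb[s] += jcb; dcb[s + 1] -= jcb;
      }
      for (int s = 0; s < nsh; ++s) {
        c_[s] += dca[s] * ivol[s] - dfr[s];
        b_[s] += dbf[s] * ivol[s] - dfr[s];
        cb[s] += dcb[s] * ivol[s] + dfr[s];
      }
      c_[0] += dmemb;
    }
    // longitudinal diffusion between compartment and parent, per shell
    if (long_diff) {
      for (int i = 1; i < n; ++i) {
        int p = parent[i];
        for (int s = 0; s < nsh; ++s) {
          int ii = i * nsh + s, pp = p * nsh + s;
          double jc = lon_ca[ii] * (ca[pp] - ca[ii]);
          double jb = lon_bf[ii] * (buf[pp] - buf[ii]);
          double jcb = lon_bf[ii] * (cab[pp] - cab[ii]);
          ca[ii] += jc * inv_shvol[ii];  ca[pp] -= jc * inv_shvol[pp];
          buf[ii] += jb * inv_shvol[ii]; buf[pp] -= jb * inv_shvol[pp];
          cab[ii] += jcb * inv_shvol[ii]; cab[pp] -= jcb * inv_shvol[pp];
        }
      }
    }

    t = t0 + (istep + 1) * dt;
  }

  // negative-concentration audit (numerical stability contract)
  bool ca_neg = false;
  for (int i = 0; i < n * nsh && !ca_neg; ++i)
    if (ca[i] < 0 || buf[i] < 0 || cab[i] < 0) ca_neg = true;

  List fin = List::create(
    _["v"] = NumericVector(v.begin(), v.end()),
    _["ca"] = NumericVector(ca.begin(), ca.end()),
    _["buf"] = NumericVector(buf.begin(), buf.end()),
    _["cab"] = NumericVector(cab.begin(), cab.end()),
    _["gates"] = NumericVector(gs.begin(), gs.end()),
    _["syn"] = NumericVector::create(aA, aB, nA, nB),
    _["t"] = t);

  return List::create(
    _["t"] = rec_t, _["v"] = rec_v, _["ca"] = rec_ca,
    _["state"] = fin,
    _["diverged"] = diverged, _["t_diverged"] = t_div,
    _["ca_negative"] = ca_neg,
    _["n_recorded"] = rec_i);
}
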