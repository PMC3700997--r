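// Inner integration loop of the compartmental electrical model.
//
// Voltage: backward Euler on the compartment tree, solved exactly per step
// by Hines elimination (parents precede children in the compartment order).
// Gates: exponential relaxation toward their voltage- (or calcium-)
// dependent steady state, exact for frozen rate constants over one step.
// Calcium shells: forward update of the thin-shell balance (influx from
// calcium-carrying currents, Michaelis-Menten pump, diffusive relaxation).
// Synapses: double-exponential conductances via two decaying states, with
// event insertion at step boundaries.
//
// Units: mV, ms, uS, nA, nF, mM, um; current densities in mA/cm^2.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

static inline double tab_lookup(const NumericMatrix& tab, double v) {
  const int n = tab.nrow();
  if (v <= tab(0, 0)) return tab(0, 1);
  if (v >= tab(n - 1, 0)) return tab(n - 1, 1);
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (tab(mid, 0) <= v) lo = mid; else hi = mid;
  }
  const double f = (v - tab(lo, 0)) / (tab(hi, 0) - tab(lo, 0));
  return tab(lo, 1) + f * (tab(hi, 1) - tab(lo, 1));
}

// [[Rcpp::export(name = ".elec_advance")]]
List elec_advance(List pack, double t0, double t1, double dt,
                  NumericVector ev_time, IntegerVector ev_syn,
                  double record_dt, IntegerVector rec_comp,
                  IntegerVector rec_kind) {
  // compartments
  IntegerVector parent = pack["parent"];
  NumericVector gax = pack["gax_uS"];
  NumericVector cm = pack["cm_nF"];
  NumericVector gl = pack["gl_uS"];
  NumericVector el = pack["el_mV"];
  NumericVector v = clone(as<NumericVector>(pack["v_mV"]));
  NumericVector iinj = pack["iinj_nA"];
  NumericVector area = pack["area_cm2"];
  const int ncomp = v.size();

  // calcium shells (one per compartment; inert when depth == 0)
  NumericVector ca = clone(as<NumericVector>(pack["ca_mM"]));
  NumericVector ca_inf = pack["ca_inf_mM"];
  NumericVector ca_tau = pack["ca_tau_ms"];
  NumericVector ca_vmax = pack["ca_pump_vmax"];   // mM/ms
  NumericVector ca_km = pack["ca_pump_km"];       // mM
  NumericVector ca_depth = pack["ca_depth_um"];   // um; 0 = no shell
  IntegerVector ca_route = pack["ca_route"];      // shell receiving each
                                                  // compartment's Ca current
  const double faraday = as<double>(pack["faraday"]); // C/mmol

  // channels
  IntegerVector ch_comp = pack["ch_comp"];
  NumericVector ch_gbar = pack["ch_gbar_uS"];
  NumericVector ch_erev = pack["ch_erev"];
  IntegerVector ch_x = pack["ch_x"];
  IntegerVector ch_y = pack["ch_y"];
  NumericVector ch_a = pack["ch_a"];
  IntegerVector ch_is_ca = pack["ch_is_ca"];
  IntegerVector ch_kind = pack["ch_kind"];        // 0 voltage, 1 ca-gated
  NumericVector m_vh = pack["m_vh"];
  NumericVector m_k = pack["m_k"];
  NumericVector m_tau_fix = pack["m_tau_fix"];
  IntegerVector m_tab = pack["m_tab"];            // 0-based into tau_tables, -1 none
  NumericVector h_vh = pack["h_vh"];
  NumericVector h_k = pack["h_k"];
  NumericVector h_tau_fix = pack["h_tau_fix"];
  IntegerVector h_tab = pack["h_tab"];
  NumericVector ca_kd = pack["ca_kd_mM"];
  NumericVector ca_hill = pack["ca_hill"];
  NumericVector gm = clone(as<NumericVector>(pack["gate_m"]));
  NumericVector gh = clone(as<NumericVector>(pack["gate_h"]));
  List tau_tables = pack["tau_tables"];
  const int nch = ch_comp.size();

  // synapses
  IntegerVector syn_comp = pack["syn_comp"];
  NumericVector syn_e = pack["syn_e"];
  NumericVector syn_taur = pack["syn_taur"];
  NumericVector syn_taud = pack["syn_taud"];
  NumericVector syn_gpeak = pack["syn_gpeak_uS"];
  NumericVector syn_cafrac = pack["syn_ca_frac"];
  NumericVector syn_w = pack["syn_weight"];
  NumericVector sA = clone(as<NumericVector>(pack["syn_A"]));
  NumericVector sB = clone(as<NumericVector>(pack["syn_B"]));
  const int nsyn = syn_comp.size();

  // normalization so one event peaks at weight * gpeak
  std::vector<double> syn_norm(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    const double tr = syn_taur[s], td = syn_taud[s];
    const double tp = tr * td / (td - tr) * std::log(td / tr);
    syn_norm[s] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  }

  // recording
  const int nrec = rec_comp.size();
  std::vector<double> rec_times;
  std::vector<double> rec_vals;
  double next_rec = R_PosInf;
  if (record_dt > 0) {
    next_rec = std::ceil((t0 + 1e-9) / record_dt) * record_dt;
    if (next_rec <= t0 + 1e-9) next_rec += record_dt;
  }

  std::vector<double> d(ncomp), rhs(ncomp), gsum(ncomp), esum(ncomp), ica(ncomp);
  int iev = 0, n_ca_clamped = 0;
  const int nev = ev_time.size();
  double t = t0;

  while (t < t1 - 1e-9) {
    const double h = std::min(dt, t1 - t);

    // deliver pending events scheduled at (or before) the step start
    while (iev < nev && ev_time[iev] <= t + 1e-9) {
      const int s = ev_syn[iev];
      const double amp = syn_w[s] * syn_gpeak[s] * syn_norm[s];
      sA[s] += amp;  // fast (rise) state
      sB[s] += amp;  // slow (decay) state
      ++iev;
    }

    // gate update (exponential toward steady state at current V / Ca)
    for (int c = 0; c < nch; ++c) {
      const double vc = v[ch_comp[c]];
      double minf, mtau;
      if (ch_kind[c] == 1) {
        const double cac = ca[ch_comp[c]];
        const double cn = std::pow(std::max(cac, 0.0), ca_hill[c]);
        const double kn = std::pow(ca_kd[c], ca_hill[c]);
        minf = cn / (cn + kn);
        mtau = m_tau_fix[c];
      } else {
        minf = boltz(vc, m_vh[c], m_k[c]);
        mtau = (m_tab[c] >= 0)
          ? tab_lookup(as<NumericMatrix>(tau_tables[m_tab[c]]), vc)
          : m_tau_fix[c];
      }
      gm[c] = minf + (gm[c] - minf) * std::exp(-h / mtau);
      if (gm[c] < 0) gm[c] = 0; else if (gm[c] > 1) gm[c] = 1;
      if (ch_y[c] > 0) {
        const double hinf = boltz(vc, h_vh[c], h_k[c]);
        const double htau = (h_tab[c] >= 0)
          ? tab_lookup(as<NumericMatrix>(tau_tables[h_tab[c]]), vc)
          : h_tau_fix[c];
        gh[c] = hinf + (gh[c] - hinf) * std::exp(-h / htau);
        if (gh[c] < 0) gh[c] = 0; else if (gh[c] > 1) gh[c] = 1;
      }
    }

    // synapse state decay over the step (analytic)
    for (int s = 0; s < nsyn; ++s) {
      sA[s] *= std::exp(-h / syn_taur[s]);
      sB[s] *= std::exp(-h / syn_taud[s]);
    }

    // assemble conductance and reversal-weighted sums per compartment
    for (int i = 0; i < ncomp; ++i) {
      gsum[i] = gl[i];
      esum[i] = gl[i] * el[i] + iinj[i];
      ica[i] = 0.0;
    }
    for (int c = 0; c < nch; ++c) {
      double g = ch_gbar[c];
      for (int p = 0; p < ch_x[c]; ++p) g *= gm[c];
      if (ch_y[c] > 0) {
        const double heff = ch_a[c] * gh[c] + (1.0 - ch_a[c]);
        for (int p = 0; p < ch_y[c]; ++p) g *= heff;
      }
      const int i = ch_comp[c];
      gsum[i] += g;
      esum[i] += g * ch_erev[c];
      if (ch_is_ca[c]) {
        // calcium current (nA) evaluated at pre-step V (explicit in the
        // shell); deposited into the routed shell (PSD feeds its head)
        ica[ca_route[i]] += g * (v[i] - ch_erev[c]);
      }
    }
    for (int s = 0; s < nsyn; ++s) {
      const double g = sB[s] - sA[s];
      const int i = syn_comp[s];
      gsum[i] += g;
      esum[i] += g * syn_e[s];
      if (syn_cafrac[s] > 0) {
        ica[ca_route[i]] += syn_cafrac[s] * g * (v[i] - syn_e[s]);
      }
    }

    // backward-Euler tree solve (Hines): (cm/h + gsum + sum gax) v' - ...
    for (int i = 0; i < ncomp; ++i) {
      d[i] = cm[i] / h + gsum[i];
      rhs[i] = cm[i] / h * v[i] + esum[i];
    }
    for (int i = 0; i < ncomp; ++i) {
      if (parent[i] >= 0) { d[i] += gax[i]; d[parent[i]] += gax[i]; }
    }
    for (int i = ncomp - 1; i > 0; --i) {
      if (parent[i] < 0) continue;
      const double f = gax[i] / d[i];
      d[parent[i]] -= f * gax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < ncomp; ++i) {
      v[i] = (parent[i] >= 0) ? (rhs[i] + gax[i] * v[parent[i]]) / d[i]
                              : rhs[i] / d[i];
    }

    // calcium shells: d[Ca]/dt = -10 I_Ca / (2 F depth) - pump - decay
    for (int i = 0; i < ncomp; ++i) {
      if (ca_depth[i] <= 0) continue;
      const double dens = ica[i] * 1e-6 / area[i];   // nA -> mA/cm^2
      const double influx = -10.0 * dens / (2.0 * faraday * ca_depth[i]);
      const double pump = ca_vmax[i] * ca[i] / (ca[i] + ca_km[i]);
      const double relax = (ca[i] - ca_inf[i]) / ca_tau[i];
      ca[i] += h * (influx - pump - relax);
      if (ca[i] < 0) { ca[i] = 0; ++n_ca_clamped; }
    }

    t += h;

    for (int i = 0; i < ncomp; ++i) {
      if (std::fabs(v[i]) > 200.0) {
        stop("electrical model numerical blow-up: |V| = %g mV in compartment %d at t = %g ms",
             v[i], i + 1, t);
      }
    }

    if (record_dt > 0 && t >= next_rec - 1e-9) {
      rec_times.push_back(t);
      for (int r = 0; r < nrec; ++r) {
        rec_vals.push_back(rec_kind[r] == 0 ? v[rec_comp[r]] : ca[rec_comp[r]]);
      }
      next_rec += record_dt;
    }
  }

  NumericMatrix trace(rec_times.size(), nrec + 1);
  for (size_t r = 0; r < rec_times.size(); ++r) {
    trace(r, 0) = rec_times[r];
    for (int c = 0; c < nrec; ++c) trace(r, c + 1) = rec_vals[r * nrec + c];
  }

  return List::create(
    _["v_mV"] = v, _["ca_mM"] = ca,
    _["gate_m"] = gm, _["gate_h"] = gh,
    _["syn_A"] = sA, _["syn_B"] = sB,
    _["n_events_consumed"] = iev,
    _["n_ca_clamped"] = n_ca_clamped,
    _["trace"] = trace
  );
}
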