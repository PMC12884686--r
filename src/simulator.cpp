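// Fixed-step network integrator for the mEC E-I-I model.
//
// Scheme: exponential-Euler for the membrane equation (all terms are in
// conductance form, including gap junctions with the peer voltage frozen
// within the step) and for the gating variables (rates frozen within the
// step); synaptic conductances decay with exact per-step factors and spikes
// are delivered through per-class delay ring buffers bucketed to the
// integration grid. Units: mV, ms, nS, pF, pA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the removable singularity handled
  double u = x / y;
  if (std::fabs(u) < 1e-6) return y * (1.0 - u / 2.0 + u * u / 12.0);
  return x / std::expm1(u);
}

// alpha rate of the PV gating parameterization
static inline double pv_alpha(double k1, double th, double s1, double v) {
  return k1 * vtrap(th - v, s1);
}

// Wang-Buzsaki fast-spiking Na+ inactivation rates (phi = 5), used as a
// calibrated stand-in for the degenerate printed h row
static inline void wb_h_rates(double v, double& o, double& c) {
  o = 5.0 * 0.07 * std::exp(-(v + 58.0) / 20.0);        // recovery
  c = 5.0 * 1.0 / (1.0 + std::exp(-0.1 * (v + 28.0)));  // inactivation
}

struct GateUpd {
  // advance gate x with opening rate o and closing rate c over dt
  static inline double step(double x, double o, double c, double dt) {
    double r = o + c;
    if (r > 1e-12) {
      double xinf = o / r;
      x = xinf + (x - xinf) * std::exp(-r * dt);
    } else {
      x += dt * (o * (1.0 - x) - c * x);
    }
    if (x < 0.0) x = 0.0;
    if (x > 1.0) x = 1.0;
    return x;
  }
};

// [[Rcpp::export]]
List run_network_cpp(
    int n_i, int n_e,
    NumericVector pv_par,      // cm ena ek el
    NumericVector i_gna, NumericVector i_gkv1, NumericVector i_gkv3,
    NumericVector i_gl,        // per-interneuron maximal conductances
    NumericMatrix pv_kin,      // rows m,h,n,a: theta s1 s2 k1 k2 inact
    double e_cm, NumericVector e_gna, NumericVector e_gk, NumericVector e_gl,
    NumericVector e_rev,       // ena ek el for E cells
    NumericMatrix ou_par,      // rows e_noise,i_noise: mean sd tau erev
    bool ou_on,
    NumericVector peaks_i, NumericVector peaks_e, double drive_freq,
    IntegerVector ii_pre, IntegerVector ii_post, NumericVector ii_w,
    IntegerVector ii_d,
    IntegerVector ie_pre, IntegerVector ie_post, NumericVector ie_w,
    IntegerVector ie_d,
    IntegerVector ei_pre, IntegerVector ei_post, NumericVector ei_w,
    IntegerVector ei_d,
    IntegerVector gap_a, IntegerVector gap_b, NumericVector gap_g,
    NumericVector syn_par,     // II: taur taud erev; IE: taur taud erev; EI: taud erev
    LogicalVector clamp_i, LogicalVector clamp_e, double v_hold,
    double dt, int n_steps, int record_stride,
    NumericVector v0_i, NumericVector v0_e,
    bool include_drive_in_clamp, bool record_v = false) {

  const double cm_i = pv_par[0], ena_i = pv_par[1], ek_i = pv_par[2],
               el_i = pv_par[3];
  const double ena_e = e_rev[0], ek_e = e_rev[1], el_e = e_rev[2];

  const double ii_taur = syn_par[0], ii_taud = syn_par[1], ii_erev = syn_par[2];
  const double ie_taur = syn_par[3], ie_taud = syn_par[4], ie_erev = syn_par[5];
  const double ei_taud = syn_par[6], ei_erev = syn_par[7];

  // bi-exponential normalization so peak conductance = summed weight
  auto biexp_norm = [](double tr, double td) {
    double tp = tr * td / (td - tr) * std::log(td / tr);
    return 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  };
  const double ii_norm = biexp_norm(ii_taur, ii_taud);
  const double ie_norm = biexp_norm(ie_taur, ie_taud);

  const double dII_A = std::exp(-dt / ii_taud), dII_B = std::exp(-dt / ii_taur);
  const double dIE_A = std::exp(-dt / ie_taud), dIE_B = std::exp(-dt / ie_taur);
  const double dEI   = std::exp(-dt / ei_taud);

  // OU exact-update coefficients
  double ouE_mean = ou_par(0, 0), ouE_sd = ou_par(0, 1), ouE_erev = ou_par(0, 3);
  double ouI_mean = ou_par(1, 0), ouI_sd = ou_par(1, 1), ouI_erev = ou_par(1, 3);
  double ouE_rho = std::exp(-dt / ou_par(0, 2));
  double ouI_rho = std::exp(-dt / ou_par(1, 2));
  double ouE_s = ouE_sd * std::sqrt(1.0 - ouE_rho * ouE_rho);
  double ouI_s = ouI_sd * std::sqrt(1.0 - ouI_rho * ouI_rho);

  // adjacency grouped by presynaptic cell
  struct Edge { int post; double w; int d; };
  std::vector<std::vector<Edge> > out_i(n_i), out_e(n_e);
  for (int k = 0; k < ii_pre.size(); ++k)
    out_i[ii_pre[k] - 1].push_back(Edge{ii_post[k] - 1, ii_w[k], ii_d[k]});
  for (int k = 0; k < ie_pre.size(); ++k)
    out_i[ie_pre[k] - 1].push_back(Edge{n_i + ie_post[k] - 1, ie_w[k], ie_d[k]});
  for (int k = 0; k < ei_pre.size(); ++k)
    out_e[ei_pre[k] - 1].push_back(Edge{ei_post[k] - 1, ei_w[k], ei_d[k]});

  int max_d = 1;
  for (int k = 0; k < ii_d.size(); ++k) max_d = std::max(max_d, ii_d[k]);
  for (int k = 0; k < ie_d.size(); ++k) max_d = std::max(max_d, ie_d[k]);
  for (int k = 0; k < ei_d.size(); ++k) max_d = std::max(max_d, ei_d[k]);
  const int L = max_d + 2;  // ring length

  // delay ring buffers: II and EI target I cells, IE targets E cells
  std::vector<double> buf_ii((size_t)L * n_i, 0.0);
  std::vector<double> buf_ei((size_t)L * n_i, 0.0);
  std::vector<double> buf_ie((size_t)L * n_e, 0.0);

  // synaptic state
  std::vector<double> A_ii(n_i, 0.0), B_ii(n_i, 0.0), g_ei(n_i, 0.0);
  std::vector<double> A_ie(n_e, 0.0), B_ie(n_e, 0.0);

  // cell state
  std::vector<double> Vi(v0_i.begin(), v0_i.end());
  std::vector<double> Ve(v0_e.begin(), v0_e.end());
  std::vector<double> gm(n_i), gh(n_i), gn(n_i), ga(n_i);
  std::vector<double> em(n_e), eh(n_e), en(n_e);
  std::vector<double> ouE(n_e, ouE_mean), ouI(n_e, ouI_mean);

  // PV gate steady states at v0
  for (int i = 0; i < n_i; ++i) {
    double v = clamp_i[i] ? v_hold : Vi[i];
    if (clamp_i[i]) Vi[i] = v_hold;
    double* gs[4] = {&gm[i], &gh[i], &gn[i], &ga[i]};
    for (int gidx = 0; gidx < 4; ++gidx) {
      double o, c;
      int form = (int)pv_kin(gidx, 5);
      if (form == 2) {
        wb_h_rates(v, o, c);
      } else {
        double a = pv_alpha(pv_kin(gidx, 3), pv_kin(gidx, 0), pv_kin(gidx, 1), v);
        double b = pv_kin(gidx, 4) * std::exp(v / pv_kin(gidx, 2));
        o = form == 1 ? b : a;
        c = form == 1 ? a : b;
      }
      double r = o + c;
      // r <= 0 (possible for the literal h gate, whose alpha is negative):
      // dx/dt = o - r*x >= 0 on [0,1], so the state runs to the upper bound
      double x = (r > 1e-12) ? o / r : 1.0;
      if (x < 0.0) x = 0.0;
      if (x > 1.0) x = 1.0;
      *gs[gidx] = x;
    }
  }
  for (int j = 0; j < n_e; ++j) {
    double v = clamp_e[j] ? v_hold : Ve[j];
    if (clamp_e[j]) Ve[j] = v_hold;
    double am = 0.1 * vtrap(-(v + 40.0), 10.0), bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
    double ah = 0.07 * std::exp(-(v + 65.0) / 20.0), bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
    double an = 0.01 * vtrap(-(v + 55.0), 10.0), bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
    em[j] = am / (am + bm); eh[j] = ah / (ah + bh); en[j] = an / (an + bn);
  }

  std::vector<std::vector<double> > spikes_i(n_i), spikes_e(n_e);
  std::vector<double> last_spike_i(n_i, -1e9), last_spike_e(n_e, -1e9);

  std::vector<int> rec_i, rec_e;
  for (int i = 0; i < n_i; ++i) if (clamp_i[i]) rec_i.push_back(i);
  for (int j = 0; j < n_e; ++j) if (clamp_e[j]) rec_e.push_back(j);
  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix clampI(n_rec, (int)rec_i.size());
  NumericMatrix clampE(n_rec, (int)rec_e.size());
  NumericVector rec_time(n_rec), rec_drive(n_rec);
  NumericMatrix vI(record_v ? n_rec : 1, record_v ? n_i : 0);
  NumericMatrix vE(record_v ? n_rec : 1, record_v ? n_e : 0);

  const double w2pi = 2.0 * M_PI * drive_freq / 1000.0;  // rad per ms
  // drive_freq <= 0 degrades to a constant drive at the peak conductance
  auto envel_at = [&](double tt) {
    return drive_freq > 0.0 ? (1.0 - std::cos(w2pi * tt)) / 2.0 : 1.0;
  };
  std::vector<double> igap_i(n_i, 0.0);

  auto record = [&](int ridx, double t, double envel) {
    rec_time[ridx] = t;
    rec_drive[ridx] = envel;
    if (record_v) {
      for (int i = 0; i < n_i; ++i) vI(ridx, i) = Vi[i];
      for (int j = 0; j < n_e; ++j) vE(ridx, j) = Ve[j];
    }
    for (size_t k = 0; k < rec_i.size(); ++k) {
      int i = rec_i[k];
      double g_inh = ii_norm * (A_ii[i] - B_ii[i]);
      double ic = g_inh * (ii_erev - v_hold) + g_ei[i] * (ei_erev - v_hold);
      if (include_drive_in_clamp) ic += peaks_i[i] * envel * (0.0 - v_hold);
      clampI(ridx, k) = ic;
    }
    for (size_t k = 0; k < rec_e.size(); ++k) {
      int j = rec_e[k];
      double g_inh = ie_norm * (A_ie[j] - B_ie[j]);
      double ic = g_inh * (ie_erev - v_hold);
      if (include_drive_in_clamp) ic += peaks_e[j] * envel * (0.0 - v_hold);
      clampE(ridx, k) = ic;
    }
  };

  record(0, 0.0, envel_at(0.0));

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const double envel = envel_at(t);

    // deliver delayed spikes scheduled for this step
    const int slot = s % L;
    {
      double* bi = buf_ii.data() + (size_t)slot * n_i;
      double* be = buf_ei.data() + (size_t)slot * n_i;
      for (int i = 0; i < n_i; ++i) {
        if (bi[i] != 0.0) { A_ii[i] += bi[i]; B_ii[i] += bi[i]; bi[i] = 0.0; }
        if (be[i] != 0.0) { g_ei[i] += be[i]; be[i] = 0.0; }
      }
      double* bf = buf_ie.data() + (size_t)slot * n_e;
      for (int j = 0; j < n_e; ++j)
        if (bf[j] != 0.0) { A_ie[j] += bf[j]; B_ie[j] += bf[j]; bf[j] = 0.0; }
    }

    // gap-junction currents with peer voltages frozen at step start
    std::fill(igap_i.begin(), igap_i.end(), 0.0);
    for (int k = 0; k < gap_a.size(); ++k) {
      int a = gap_a[k] - 1, b = gap_b[k] - 1;
      double cur = gap_g[k] * (Vi[b] - Vi[a]);
      igap_i[a] += cur;
      igap_i[b] -= cur;
    }

    // interneurons
    for (int i = 0; i < n_i; ++i) {
      if (clamp_i[i]) continue;
      double v = Vi[i];
      // gates (rates at current v, frozen within the step)
      double gates[4] = {gm[i], gh[i], gn[i], ga[i]};
      for (int gidx = 0; gidx < 4; ++gidx) {
        double o, c;
        int form = (int)pv_kin(gidx, 5);
        if (form == 2) {
          wb_h_rates(v, o, c);
        } else {
          double a = pv_alpha(pv_kin(gidx, 3), pv_kin(gidx, 0), pv_kin(gidx, 1), v);
          double b = pv_kin(gidx, 4) * std::exp(v / pv_kin(gidx, 2));
          o = form == 1 ? b : a;
          c = form == 1 ? a : b;
        }
        gates[gidx] = GateUpd::step(gates[gidx], o, c, dt);
      }
      gm[i] = gates[0]; gh[i] = gates[1]; gn[i] = gates[2]; ga[i] = gates[3];

      double g_na = i_gna[i] * gm[i] * gm[i] * gm[i] * gh[i];
      double g_k1 = i_gkv1[i] * ga[i] * ga[i] * ga[i] * ga[i];
      double g_k3 = i_gkv3[i] * gn[i] * gn[i] * gn[i] * gn[i];
      double g_drv = peaks_i[i] * envel;
      double g_inh = ii_norm * (A_ii[i] - B_ii[i]);
      if (g_inh < 0.0) g_inh = 0.0;
      double g_exc = g_ei[i];
      double gtot = g_na + g_k1 + g_k3 + i_gl[i] + g_drv + g_inh + g_exc;
      double num = g_na * ena_i + (g_k1 + g_k3) * ek_i + i_gl[i] * el_i +
                   g_inh * ii_erev + g_exc * ei_erev + igap_i[i];
      // gap current enters as a fixed current over the step (peer frozen)
      double vinf = num / gtot;
      double vnew = vinf + (v - vinf) * std::exp(-dt * gtot / cm_i);
      if (vnew >= 0.0 && v < 0.0 && (t + dt - last_spike_i[i]) >= 1.0) {
        last_spike_i[i] = t + dt;
        spikes_i[i].push_back(t + dt);
        for (size_t k = 0; k < out_i[i].size(); ++k) {
          const Edge& e = out_i[i][k];
          int arr = (s + 1 + e.d) % L;
          if (e.post < n_i) buf_ii[(size_t)arr * n_i + e.post] += e.w;
          else buf_ie[(size_t)arr * n_e + (e.post - n_i)] += e.w;
        }
      }
      Vi[i] = vnew;
    }

    // stellate cells
    for (int j = 0; j < n_e; ++j) {
      if (clamp_e[j]) {
        if (ou_on) {  // keep the noise stream advancing identically
          ouE[j] = ouE_mean + (ouE[j] - ouE_mean) * ouE_rho + ouE_s * norm_rand();
          ouI[j] = ouI_mean + (ouI[j] - ouI_mean) * ouI_rho + ouI_s * norm_rand();
        }
        continue;
      }
      double v = Ve[j];
      double am = 0.1 * vtrap(-(v + 40.0), 10.0), bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
      double ah = 0.07 * std::exp(-(v + 65.0) / 20.0), bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
      double an = 0.01 * vtrap(-(v + 55.0), 10.0), bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
      em[j] = GateUpd::step(em[j], am, bm, dt);
      eh[j] = GateUpd::step(eh[j], ah, bh, dt);
      en[j] = GateUpd::step(en[j], an, bn, dt);

      double g_na = e_gna[j] * em[j] * em[j] * em[j] * eh[j];
      double g_k = e_gk[j] * en[j] * en[j] * en[j] * en[j];
      double g_drv = peaks_e[j] * envel;
      double g_inh = ie_norm * (A_ie[j] - B_ie[j]);
      if (g_inh < 0.0) g_inh = 0.0;
      double gE = 0.0, gI = 0.0;
      if (ou_on) {
        ouE[j] = ouE_mean + (ouE[j] - ouE_mean) * ouE_rho + ouE_s * norm_rand();
        ouI[j] = ouI_mean + (ouI[j] - ouI_mean) * ouI_rho + ouI_s * norm_rand();
        gE = ouE[j] > 0.0 ? ouE[j] : 0.0;
        gI = ouI[j] > 0.0 ? ouI[j] : 0.0;
      }
      double gtot = g_na + g_k + e_gl[j] + g_drv + g_inh + gE + gI;
      double num = g_na * ena_e + g_k * ek_e + e_gl[j] * el_e +
                   g_inh * ie_erev + gE * ouE_erev + gI * ouI_erev;
      double vinf = num / gtot;
      double vnew = vinf + (v - vinf) * std::exp(-dt * gtot / e_cm);
      if (vnew >= 0.0 && v < 0.0 && (t + dt - last_spike_e[j]) >= 1.0) {
        last_spike_e[j] = t + dt;
        spikes_e[j].push_back(t + dt);
        for (size_t k = 0; k < out_e[j].size(); ++k) {
          const Edge& e = out_e[j][k];
          int arr = (s + 1 + e.d) % L;
          buf_ei[(size_t)arr * n_i + e.post] += e.w;
        }
      }
      Ve[j] = vnew;
    }

    // synaptic decay to end of step
    for (int i = 0; i < n_i; ++i) {
      A_ii[i] *= dII_A; B_ii[i] *= dII_B; g_ei[i] *= dEI;
    }
    for (int j = 0; j < n_e; ++j) { A_ie[j] *= dIE_A; B_ie[j] *= dIE_B; }

    if ((s + 1) % record_stride == 0) {
      double t2 = (s + 1) * dt;
      record((s + 1) / record_stride, t2, envel_at(t2));
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n_i; ++i)
        if (!std::isfinite(Vi[i]))
          stop("non-finite state in I cell %d at t = %.3f ms", i + 1, t);
      for (int j = 0; j < n_e; ++j)
        if (!std::isfinite(Ve[j]))
          stop("non-finite state in E cell %d at t = %.3f ms", j + 1, t);
    }
  }

  List sp_i(n_i), sp_e(n_e);
  for (int i = 0; i < n_i; ++i) sp_i[i] = NumericVector(spikes_i[i].begin(), spikes_i[i].end());
  for (int j = 0; j < n_e; ++j) sp_e[j] = NumericVector(spikes_e[j].begin(), spikes_e[j].end());

  return List::create(
    _["spikes_i"] = sp_i, _["spikes_e"] = sp_e,
    _["clamp_i"] = clampI, _["clamp_e"] = clampE,
    _["time"] = rec_time, _["drive"] = rec_drive,
    _["v_final_i"] = NumericVector(Vi.begin(), Vi.end()),
    _["v_final_e"] = NumericVector(Ve.begin(), Ve.end()),
    _["v_i"] = vI, _["v_e"] = vE);
}
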