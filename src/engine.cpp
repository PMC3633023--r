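// Compiled core of the EAE regulatory-circuit simulator.
//
// The scheduler steps a discrete-time world (dt hours) in a fixed sub-step
// order: lifecycle -> movement/migration -> influx & CNS pathway ->
// DC processing/presentation -> licensing/binding/priming -> killing ->
// recording. Agent iteration order is reshuffled from the run's RNG every
// step so contention for grid spaces and DC binding sites carries no
// positional bias. All randomness is drawn from R's RNG: a run seeded with
// set.seed() in R is bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

enum Lin { L_UNPOL = 0, L_TH1, L_TH2, L_TREG4, L_TREG8, L_DC, L_MG, L_NEURON };
enum St  { S_NAIVE = 0, S_PARTIAL, S_EFF, S_APOP, S_REM };
enum Comp { C_CNS = 0, C_CLN, C_SPLEEN, C_CIRC };

static inline double ru() { return unif_rand(); }
static inline int rint_n(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct TCells {
  std::vector<int> lin, st, comp, space, bound, contacts;
  std::vector<double> age, eclock, contact_left, apop_t, t_eff;
  size_t size() const { return lin.size(); }
  int add(int l, int s, int c, int sp, double eck) {
    lin.push_back(l); st.push_back(s); comp.push_back(c); space.push_back(sp);
    bound.push_back(-1); contacts.push_back(0);
    age.push_back(0.0); eclock.push_back(eck);
    contact_left.push_back(0.0); apop_t.push_back(-1.0);
    t_eff.push_back(-1.0);
    return (int)lin.size() - 1;
  }
};

struct DCs {
  std::vector<int> comp, space, lock, bound_n;
  std::vector<double> age, lifespan, t_mbp, t_tcr, created_t, lic_t,
      t_pres_mbp, t_pres_tcr;  // display start times; -1 = never shown
  std::vector<char> mature, inv_mbp, inv_tcr, pres_mbp, pres_fr3,
      qa1, licensed, dead, polar1;
  size_t size() const { return comp.size(); }
  int add(int c, int sp, double life, double t) {
    comp.push_back(c); space.push_back(sp); lock.push_back(0);
    bound_n.push_back(0);
    age.push_back(0.0); lifespan.push_back(life);
    t_mbp.push_back(-1.0); t_tcr.push_back(-1.0);
    created_t.push_back(t); lic_t.push_back(-1.0);
    t_pres_mbp.push_back(-1.0); t_pres_tcr.push_back(-1.0);
    mature.push_back(0); inv_mbp.push_back(0); inv_tcr.push_back(0);
    pres_mbp.push_back(0); pres_fr3.push_back(0); qa1.push_back(0);
    licensed.push_back(0); dead.push_back(0); polar1.push_back(0);
    return (int)comp.size() - 1;
  }
};

// [[Rcpp::export]]
List sim_run_cpp(List cfg) {
  // ---- parameters ----------------------------------------------------
  const double duration_days = as<double>(cfg["duration_days"]);
  const double dt = as<double>(cfg["dt_hours"]);
  const double record_every = as<double>(cfg["record_every_hours"]);
  const int n_th = as<int>(cfg["n_cd4th_naive"]);
  const int n_t4 = as<int>(cfg["n_cd4treg_naive"]);
  const int n_t8 = as<int>(cfg["n_cd8treg_naive"]);
  const double inf_th = as<double>(cfg["naive_influx_cd4th"]);
  const double inf_t4 = as<double>(cfg["naive_influx_cd4treg"]);
  const double inf_t8 = as<double>(cfg["naive_influx_cd8treg"]);
  const int n_neurons0 = as<int>(cfg["n_neurons"]);
  const int n_mg = as<int>(cfg["n_microglia"]);
  const int dc0_spl = as<int>(cfg["n_dc_init_spleen"]);
  const int dc0_cln = as<int>(cfg["n_dc_init_cln"]);
  const int dc0_cns = as<int>(cfg["n_dc_init_cns"]);
  const double dcin_spl = as<double>(cfg["dc_influx_spleen"]);
  const double dcin_cln = as<double>(cfg["dc_influx_cln"]);
  const double dcin_cns = as<double>(cfg["dc_influx_cns"]);
  const double dc_life_mean = as<double>(cfg["dc_lifespan_mean"]);
  const double dc_life_jit = as<double>(cfg["dc_lifespan_jitter"]);
  const int dc_sites = as<int>(cfg["dc_binding_sites"]);
  const double proc_delay = as<double>(cfg["processing_delay_hours"]);
  const double proc_debris = as<double>(cfg["processing_delay_debris_hours"]);
  const double proc_bolus = as<double>(cfg["processing_delay_bolus_hours"]);
  const double p_pres_mbp = as<double>(cfg["p_present_mbp"]);
  const double p_pres_tcr = as<double>(cfg["p_present_tcr"]);
  const double p_eff = as<double>(cfg["p_efferocytose"]);
  const double p_proc_tcr = as<double>(cfg["p_process_tcr"]);
  const double p_eff_neuron = as<double>(cfg["p_eff_neuron"]);
  const double display_mbp = as<double>(cfg["display_mbp_hours"]);
  const double display_tcr = as<double>(cfg["display_tcr_hours"]);
  const double bolus_hours = as<double>(cfg["mbp_bolus_hours"]);
  const double p_mbp_uptake = as<double>(cfg["p_mbp_uptake"]);
  const double p_dc_mig = as<double>(cfg["p_dc_migrate_cns"]);
  const int nx[4] = {as<int>(cfg["grid_cns_nx"]), as<int>(cfg["grid_cln_nx"]),
                     as<int>(cfg["grid_spleen_nx"]), 1};
  const int ny[4] = {as<int>(cfg["grid_cns_ny"]), as<int>(cfg["grid_cln_ny"]),
                     as<int>(cfg["grid_spleen_ny"]), 1};
  const int cap_c[4] = {as<int>(cfg["capacity_cns"]),
                        as<int>(cfg["capacity_lymphoid"]),
                        as<int>(cfg["capacity_lymphoid"]), 1000000};
  const double contact_dur = as<double>(cfg["contact_duration_hours"]);
  const int n_contacts = as<int>(cfg["n_priming_contacts"]);
  const int n_contacts_t4 = as<int>(cfg["n_priming_contacts_cd4treg"]);
  const int n_contacts_t8 = as<int>(cfg["n_priming_contacts_cd8treg"]);
  const double p_bind = as<double>(cfg["p_bind"]);
  const double p_license = as<double>(cfg["p_license"]);
  const double cd40l_delay = as<double>(cfg["cd40l_delay_hours"]);
  const double p_th1 = as<double>(cfg["p_th1"]);
  const int burst[5] = {as<int>(cfg["burst_cd4th"]), as<int>(cfg["burst_cd4th"]),
                        as<int>(cfg["burst_cd4th"]), as<int>(cfg["burst_cd4treg"]),
                        as<int>(cfg["burst_cd8treg"])};
  const double elife[5] = {as<double>(cfg["eff_lifespan_th1"]),
                           as<double>(cfg["eff_lifespan_th1"]),
                           as<double>(cfg["eff_lifespan_th2"]),
                           as<double>(cfg["eff_lifespan_cd4treg"]),
                           as<double>(cfg["eff_lifespan_cd8treg"])};
  const double ejit = as<double>(cfg["eff_lifespan_jitter_frac"]);
  const double p_reloc = as<double>(cfg["p_relocate"]);
  const double p_exit_lym = as<double>(cfg["p_exit_lymphoid"]);
  const double p_circ_lym = as<double>(cfg["p_circ_to_lymphoid"]);
  const double frac_spleen = as<double>(cfg["frac_to_spleen"]);
  const double drain_frac = as<double>(cfg["drain_frac_spleen"]);
  const double p_th1_exit = as<double>(cfg["p_th1_exit_lymphoid"]);
  const double p_t4eff_exit = as<double>(cfg["p_treg4eff_exit_lymphoid"]);
  const double p_circ_cns = as<double>(cfg["p_circ_to_cns"]);
  const double p_drain = as<double>(cfg["p_apop_drain_cns"]);
  const double p_kill = as<double>(cfg["p_kill"]);
  const double p_mg_act = as<double>(cfg["p_mg_activate"]);
  const double p_nkill = as<double>(cfg["p_neuron_kill"]);
  const double apop_window = as<double>(cfg["apop_removal_window"]);
  const bool mutex_mode = as<bool>(cfg["mutex_mode"]);
  const std::string qa1_mode = as<std::string>(cfg["qa1_mode"]);
  const bool constitutive = (qa1_mode == "constitutive_after_delay");
  double qa1_delay = 0.0;
  if (constitutive) qa1_delay = as<double>(cfg["qa1_delay_hours"]);
  const bool abrogate_t4 = as<bool>(cfg["abrogate_cd4treg"]);
  const std::string occ_mode = as<std::string>(cfg["occupancy_mode"]);
  const bool relaxed = (occ_mode == "relaxed_cd8");
  int cd8_cap = 0;
  if (relaxed) cd8_cap = as<int>(cfg["cd8_cap"]);
  const bool debug_cons = as<bool>(cfg["debug_conservation"]);

  const int n_steps = (int)std::lround(duration_days * 24.0 / dt);
  const int steps_per_record = (int)std::lround(record_every / dt);

  // ---- grid ----------------------------------------------------------
  int comp_off[5];
  comp_off[0] = 0;
  for (int c = 0; c < 4; ++c) comp_off[c + 1] = comp_off[c] + nx[c] * ny[c];
  const int nspace = comp_off[4];
  std::vector<int> sp_comp(nspace), sp_cap(nspace);
  std::vector<std::vector<int> > nb(nspace);  // Moore neighbourhood + self
  for (int c = 0; c < 4; ++c) {
    for (int yy = 0; yy < ny[c]; ++yy) {
      for (int xx = 0; xx < nx[c]; ++xx) {
        int s = comp_off[c] + yy * nx[c] + xx;
        sp_comp[s] = c;
        sp_cap[s] = cap_c[c];
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x2 = xx + dx, y2 = yy + dy;
            if (x2 >= 0 && x2 < nx[c] && y2 >= 0 && y2 < ny[c])
              nb[s].push_back(comp_off[c] + y2 * nx[c] + x2);
          }
      }
    }
  }
  std::vector<int> occ(nspace, 0), occ8(nspace, 0);

  TCells T;
  DCs D;
  long created[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  long removedc[8] = {0, 0, 0, 0, 0, 0, 0, 0};

  // occupancy rule (standard / relaxed_cd8)
  auto allowed = [&](int s, int lin) -> bool {
    if (relaxed && lin == L_TREG8) return occ8[s] < cd8_cap;
    return occ[s] < sp_cap[s];
  };
  auto occ_add = [&](int s, int lin) {
    occ[s]++; if (lin == L_TREG8) occ8[s]++;
  };
  auto occ_del = [&](int s, int lin) {
    occ[s]--; if (lin == L_TREG8) occ8[s]--;
  };
  // peptide-MHC display is transient: a derived complex stays on the
  // surface for display_hours, then the sourced antigen is spent
  auto showing_mbp = [&](int d, double t) {
    return D.t_pres_mbp[d] >= 0 && t - D.t_pres_mbp[d] <= display_mbp;
  };
  auto showing_fr3 = [&](int d, double t) {
    return D.t_pres_tcr[d] >= 0 && t - D.t_pres_tcr[d] <= display_tcr;
  };
  // random allowed space in a compartment; -1 when everything tried is full
  auto place_random = [&](int c, int lin, int tries) -> int {
    int nsp = comp_off[c + 1] - comp_off[c];
    for (int k = 0; k < tries; ++k) {
      int s = comp_off[c] + rint_n(nsp);
      if (allowed(s, lin)) return s;
    }
    return -1;
  };
  auto add_tcell = [&](int lin, int st, int c, int sp, double eck) {
    T.add(lin, st, c, sp, eck);
    created[lin]++;
    if (st <= S_EFF) occ_add(sp, lin);
  };

  // ---- initial state -------------------------------------------------
  // naive pools: 45% Spleen, 30% CLN, 25% Circulation
  {
    const int pools[3] = {n_th, n_t4, n_t8};
    const int lins[3] = {L_UNPOL, L_TREG4, L_TREG8};
    for (int q = 0; q < 3; ++q) {
      if (lins[q] == L_TREG4 && abrogate_t4) continue;
      for (int i = 0; i < pools[q]; ++i) {
        double u = ru();
        int c = (u < 0.45) ? C_SPLEEN : (u < 0.75 ? C_CLN : C_CIRC);
        int s = place_random(c, lins[q], 30);
        if (s < 0) { c = C_CIRC; s = comp_off[C_CIRC]; }
        add_tcell(lins[q], S_NAIVE, c, s, -1.0);
      }
    }
  }
  {
    const int dc0[3] = {dc0_cns, dc0_cln, dc0_spl};
    const int cc[3] = {C_CNS, C_CLN, C_SPLEEN};
    for (int q = 0; q < 3; ++q)
      for (int i = 0; i < dc0[q]; ++i) {
        int nsp = comp_off[cc[q] + 1] - comp_off[cc[q]];
        double life = dc_life_mean + dc_life_jit * (2.0 * ru() - 1.0);
        D.add(cc[q], comp_off[cc[q]] + rint_n(nsp), life, 0.0);
        created[L_DC]++;
      }
  }
  int neurons_alive = n_neurons0;
  std::deque<double> neuron_corpses;  // corpse creation times
  int mg_active = 0;
  created[L_NEURON] = n_neurons0;
  created[L_MG] = n_mg;

  // ---- event logs ----------------------------------------------------
  std::vector<double> ev_prime_t, ev_lic_created, ev_lic_t, ev_kill_t,
      ev_cen_t;
  std::vector<int> ev_prime_lin, ev_prime_comp, ev_prime_dc, ev_lic_dc,
      ev_kill_comp, ev_cen_comp, ev_cen_mbp, ev_cen_tcr;
  std::vector<int> ev_cen_nb[5];
  long th1_apop_total = 0;
  bool conservation_ok = true;

  // ---- recording -----------------------------------------------------
  const int n_rec = (int)(n_steps * dt / record_every) + 1;
  IntegerVector counts(n_rec * 8 * 5 * 4);
  NumericVector record_times(n_rec);
  int rec_i = 0;
  auto cidx = [&](int ti, int lin, int st, int comp) {
    return ti + n_rec * (lin + 8 * (st + 5 * comp));
  };
  auto record = [&](double t) {
    if (rec_i >= n_rec) return;
    record_times[rec_i] = t;
    for (size_t i = 0; i < T.size(); ++i) {
      if (T.st[i] == S_REM) continue;
      counts[cidx(rec_i, T.lin[i], T.st[i], T.comp[i])]++;
    }
    for (size_t d = 0; d < D.size(); ++d) {
      if (D.dead[d]) continue;
      counts[cidx(rec_i, L_DC, D.mature[d] ? S_EFF : S_NAIVE, D.comp[d])]++;
    }
    counts[cidx(rec_i, L_MG, S_NAIVE, C_CNS)] += n_mg - mg_active;
    counts[cidx(rec_i, L_MG, S_EFF, C_CNS)] += mg_active;
    counts[cidx(rec_i, L_NEURON, S_NAIVE, C_CNS)] += neurons_alive;
    counts[cidx(rec_i, L_NEURON, S_APOP, C_CNS)] += (int)neuron_corpses.size();
    if (debug_cons) {
      long alive[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      for (size_t i = 0; i < T.size(); ++i)
        if (T.st[i] != S_REM) alive[T.lin[i]]++;
      for (size_t d = 0; d < D.size(); ++d)
        if (!D.dead[d]) alive[L_DC]++;
      alive[L_MG] = n_mg;
      alive[L_NEURON] = neurons_alive + (long)neuron_corpses.size();
      for (int l = 0; l < 8; ++l)
        if (created[l] != alive[l] + removedc[l]) conservation_ok = false;
    }
    rec_i++;
  };
  record(0.0);

  // scratch structures
  std::vector<std::vector<int> > t_by_space(nspace), dc_by_space(nspace);
  std::vector<int> order;

  auto rebuild_t = [&]() {
    for (int s = 0; s < nspace; ++s) t_by_space[s].clear();
    for (size_t i = 0; i < T.size(); ++i)
      if (T.st[i] <= S_EFF) t_by_space[T.space[i]].push_back((int)i);
  };
  auto rebuild_dc = [&]() {
    for (int s = 0; s < nspace; ++s) dc_by_space[s].clear();
    for (size_t d = 0; d < D.size(); ++d)
      if (!D.dead[d]) dc_by_space[D.space[d]].push_back((int)d);
  };
  auto shuffle = [&](std::vector<int> &v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = rint_n(i + 1);
      std::swap(v[i], v[j]);
    }
  };
  auto unbind = [&](int i) {
    int d = T.bound[i];
    if (d >= 0) {
      if (!D.dead[d]) D.bound_n[d]--;
      T.bound[i] = -1;
    }
  };
  // kind: 1 = MBP_source, 2 = TCR_source. `delay` is the antigen-processing
  // time; t_mbp / t_tcr record when the peptide becomes presentable.
  auto mutex_engulf = [&](int d, int kind, double t, double delay) {
    if (mutex_mode) {
      if (D.lock[d] == 0) D.lock[d] = kind;
      if (D.lock[d] != kind) { D.mature[d] = 1; return; }  // discarded
    }
    if (kind == 1) {
      D.inv_mbp[d] = 1;
      if (D.t_mbp[d] < 0) D.t_mbp[d] = t + delay;
    } else {
      D.inv_tcr[d] = 1;
      if (D.t_tcr[d] < 0) D.t_tcr[d] = t + delay;
    }
    D.mature[d] = 1;
  };

  // ---- main loop -----------------------------------------------------
  double t = 0.0;
  for (int step = 0; step < n_steps; ++step) {
    t = step * dt;
    const double t_next = t + dt;

    // (1) lifecycle --------------------------------------------------
    rebuild_t();
    for (size_t i = 0; i < T.size(); ++i) {
      if (T.st[i] == S_REM) continue;
      T.age[i] += dt;
      if (T.st[i] == S_EFF) {
        T.eclock[i] -= dt;
        if (T.eclock[i] <= 0.0) {  // activation-induced cell death
          unbind((int)i);
          T.st[i] = S_APOP;
          T.apop_t[i] = t_next;
          occ_del(T.space[i], T.lin[i]);
          if (T.lin[i] == L_TH1) th1_apop_total++;
        }
      } else if (T.st[i] == S_APOP) {
        if (t_next - T.apop_t[i] > apop_window) {
          T.st[i] = S_REM;
          removedc[T.lin[i]]++;
        }
      }
    }
    for (size_t d = 0; d < D.size(); ++d) {
      if (D.dead[d]) continue;
      D.age[d] += dt;
      if (D.age[d] >= D.lifespan[d]) {
        // DC apoptosis: census of presented kinds and T-cell neighbours
        D.dead[d] = 1;
        ev_cen_t.push_back(t_next);
        ev_cen_comp.push_back(D.comp[d]);
        ev_cen_mbp.push_back(D.pres_mbp[d] ? 1 : 0);
        ev_cen_tcr.push_back(D.pres_fr3[d] ? 1 : 0);
        int nbc[5] = {0, 0, 0, 0, 0};
        for (size_t k = 0; k < nb[D.space[d]].size(); ++k) {
          const std::vector<int> &lst = t_by_space[nb[D.space[d]][k]];
          for (size_t m = 0; m < lst.size(); ++m) {
            int lin = T.lin[lst[m]];
            if (lin <= L_TREG8) nbc[lin]++;
          }
        }
        for (int l = 0; l < 5; ++l) ev_cen_nb[l].push_back(nbc[l]);
        removedc[L_DC]++;
      }
    }
    // unbind T cells attached to dead DCs
    for (size_t i = 0; i < T.size(); ++i)
      if (T.bound[i] >= 0 && D.dead[T.bound[i]]) T.bound[i] = -1;
    // neuron corpses not efferocytosed in time are cleared
    while (!neuron_corpses.empty() &&
           t_next - neuron_corpses.front() > apop_window) {
      neuron_corpses.pop_front();
      removedc[L_NEURON]++;
    }

    // (2) movement / migration --------------------------------------
    order.resize(T.size());
    for (size_t i = 0; i < T.size(); ++i) order[i] = (int)i;
    shuffle(order);
    for (size_t k = 0; k < order.size(); ++k) {
      int i = order[k];
      if (T.st[i] == S_REM || T.bound[i] >= 0) continue;
      int c = T.comp[i];
      if (T.st[i] == S_APOP) {
        // apoptotic CD4Th1 drain from the CNS to CLN / Spleen
        if (T.lin[i] == L_TH1 && c == C_CNS && ru() < p_drain) {
          int c2 = (ru() < drain_frac) ? C_SPLEEN : C_CLN;
          int nsp = comp_off[c2 + 1] - comp_off[c2];
          T.comp[i] = c2;
          T.space[i] = comp_off[c2] + rint_n(nsp);
        }
        continue;
      }
      bool moved = false;
      if (T.lin[i] == L_TH1 && T.st[i] == S_EFF) {
        if ((c == C_CLN || c == C_SPLEEN) && ru() < p_th1_exit) {
          occ_del(T.space[i], T.lin[i]);
          T.comp[i] = C_CIRC; T.space[i] = comp_off[C_CIRC];
          occ_add(T.space[i], T.lin[i]);
          moved = true;
        } else if (c == C_CIRC && ru() < p_circ_cns) {
          int s2 = place_random(C_CNS, T.lin[i], 8);
          if (s2 >= 0) {
            occ_del(T.space[i], T.lin[i]);
            T.comp[i] = C_CNS; T.space[i] = s2;
            occ_add(s2, T.lin[i]);
          }
          moved = true;  // committed to CNS entry; waits if full
        }
      } else {
        // recirculation shared by all other live T cells; effector CD4Treg
        // emigrate faster once matured (patrolling after delivering help)
        double p_exit_here = (T.lin[i] == L_TREG4 && T.st[i] == S_EFF)
                                 ? p_t4eff_exit : p_exit_lym;
        if ((c == C_CLN || c == C_SPLEEN) && ru() < p_exit_here) {
          occ_del(T.space[i], T.lin[i]);
          T.comp[i] = C_CIRC; T.space[i] = comp_off[C_CIRC];
          occ_add(T.space[i], T.lin[i]);
          moved = true;
        } else if (c == C_CIRC && ru() < p_circ_lym) {
          int c2 = (ru() < frac_spleen) ? C_SPLEEN : C_CLN;
          int s2 = place_random(c2, T.lin[i], 8);
          if (s2 >= 0) {
            occ_del(T.space[i], T.lin[i]);
            T.comp[i] = c2; T.space[i] = s2;
            occ_add(s2, T.lin[i]);
          }
          moved = true;
        }
      }
      if (!moved && T.comp[i] != C_CIRC && ru() < p_reloc) {
        int s2 = place_random(T.comp[i], T.lin[i], 8);
        if (s2 >= 0 && s2 != T.space[i]) {
          occ_del(T.space[i], T.lin[i]);
          T.space[i] = s2;
          occ_add(s2, T.lin[i]);
        }
      }
    }

    // (3) influx and CNS pathway -------------------------------------
    {
      const double dcin[3] = {dcin_cns, dcin_cln, dcin_spl};
      const int cc[3] = {C_CNS, C_CLN, C_SPLEEN};
      for (int q = 0; q < 3; ++q) {
        int n_new = (int)R::rpois(dcin[q] * dt);
        for (int m = 0; m < n_new; ++m) {
          int nsp = comp_off[cc[q] + 1] - comp_off[cc[q]];
          double life = dc_life_mean + dc_life_jit * (2.0 * ru() - 1.0);
          D.add(cc[q], comp_off[cc[q]] + rint_n(nsp), life, t_next);
          created[L_DC]++;
        }
      }
      const double tin[3] = {inf_th, inf_t4, inf_t8};
      const int lins[3] = {L_UNPOL, L_TREG4, L_TREG8};
      for (int q = 0; q < 3; ++q) {
        if (lins[q] == L_TREG4 && abrogate_t4) continue;
        int n_new = (int)R::rpois(tin[q] * dt);
        for (int m = 0; m < n_new; ++m)
          add_tcell(lins[q], S_NAIVE, C_CIRC, comp_off[C_CIRC], -1.0);
      }
      // effector CD4Th1 in the CNS activate microglia; active microglia
      // kill neurons, producing MBP-bearing debris
      int th1_cns = 0;
      for (size_t i = 0; i < T.size(); ++i)
        if (T.lin[i] == L_TH1 && T.st[i] == S_EFF && T.comp[i] == C_CNS)
          th1_cns++;
      if (th1_cns > 0 && mg_active < n_mg) {
        double p_act = 1.0 - std::pow(1.0 - p_mg_act * dt, th1_cns);
        int n_inact = n_mg - mg_active;
        for (int m = 0; m < n_inact; ++m)
          if (ru() < p_act) mg_active++;
      }
      if (mg_active > 0 && neurons_alive > 0) {
        // per-neuron hazard, compounded over active microglia
        double hz = 1.0 - std::pow(1.0 - p_nkill * dt, mg_active);
        int nk = (int)R::rbinom((double)neurons_alive, hz);
        for (int m = 0; m < nk; ++m) {
          neurons_alive--;
          neuron_corpses.push_back(t_next);
        }
      }
    }

    // (4) DC processing: efferocytosis, migration, presentation ------
    rebuild_dc();
    // immunization bolus: MBP + adjuvant perceived by lymphoid DCs
    if (t < bolus_hours) {
      for (size_t d = 0; d < D.size(); ++d) {
        if (D.dead[d] || (D.comp[d] != C_CLN && D.comp[d] != C_SPLEEN))
          continue;
        if (ru() < p_mbp_uptake * dt) {
          mutex_engulf((int)d, 1, t_next, proc_bolus);
          D.polar1[d] = 1;  // adjuvant drives type1 polarization
        }
      }
    }
    // neuron debris engulfed by CNS DCs; hazard scales with debris load
    for (size_t d = 0; d < D.size() && !neuron_corpses.empty(); ++d) {
      if (D.dead[d] || D.comp[d] != C_CNS) continue;
      double hz_dc = 1.0 - std::pow(1.0 - p_eff_neuron * dt,
                                    (double)neuron_corpses.size());
      if (ru() < hz_dc) {
        neuron_corpses.pop_front();
        removedc[L_NEURON]++;
        mutex_engulf((int)d, 1, t_next, proc_debris);
        D.polar1[d] = 1;  // CNS inflammatory milieu is type1
      }
    }
    // apoptotic CD4Th1 efferocytosed by co-located DCs
    for (size_t i = 0; i < T.size(); ++i) {
      if (T.st[i] != S_APOP || T.lin[i] != L_TH1) continue;
      if (T.comp[i] == C_CIRC) continue;
      const std::vector<int> &dl = dc_by_space[T.space[i]];
      if (dl.empty()) continue;
      if (ru() < p_eff * dt) {
        int d = dl[rint_n((int)dl.size())];
        T.st[i] = S_REM;
        removedc[L_TH1]++;
        // cross-presentation bottleneck: engulfment only sometimes yields
        // presentable TCR-derived peptide
        if (ru() < p_proc_tcr) mutex_engulf(d, 2, t_next, proc_delay);
      }
    }
    // mature CNS DCs migrate to the CLN
    for (size_t d = 0; d < D.size(); ++d) {
      if (D.dead[d] || D.comp[d] != C_CNS || !D.mature[d]) continue;
      if (ru() < p_dc_mig * dt) {
        int nsp = comp_off[C_CLN + 1] - comp_off[C_CLN];
        D.comp[d] = C_CLN;
        D.space[d] = comp_off[C_CLN] + rint_n(nsp);
      }
    }
    rebuild_dc();
    // peptide presentation and Qa-1 expression
    for (size_t d = 0; d < D.size(); ++d) {
      if (D.dead[d] || !D.mature[d]) continue;
      if (D.inv_mbp[d] && !D.pres_mbp[d] && t_next >= D.t_mbp[d] &&
          ru() < p_pres_mbp * dt) {
        D.pres_mbp[d] = 1;  // ever-presented flag (apoptosis census)
        D.t_pres_mbp[d] = t_next;
      }
      if (D.inv_tcr[d] && !D.pres_fr3[d] && t_next >= D.t_tcr[d] &&
          ru() < p_pres_tcr * dt) {
        D.pres_fr3[d] = 1;
        D.t_pres_tcr[d] = t_next;
      }
      if (constitutive)
        D.qa1[d] = (D.age[d] >= qa1_delay) ? 1 : 0;
    }

    // (5) licensing, binding, priming --------------------------------
    rebuild_t();
    if (!constitutive) {
      for (size_t d = 0; d < D.size(); ++d) {
        if (D.dead[d] || !showing_fr3((int)d, t_next) || D.licensed[d])
          continue;
        int n_t4eff = 0;
        for (size_t k = 0; k < nb[D.space[d]].size(); ++k) {
          const std::vector<int> &lst = t_by_space[nb[D.space[d]][k]];
          for (size_t m = 0; m < lst.size(); ++m)
            if (T.lin[lst[m]] == L_TREG4 && T.st[lst[m]] == S_EFF &&
                t_next - T.t_eff[lst[m]] >= cd40l_delay) n_t4eff++;
        }
        if (n_t4eff > 0) {
          double p = 1.0 - std::pow(1.0 - p_license * dt, n_t4eff);
          if (ru() < p) {
            D.licensed[d] = 1;
            D.qa1[d] = 1;
            D.lic_t[d] = t_next;
            ev_lic_dc.push_back((int)d);
            ev_lic_created.push_back(D.created_t[d]);
            ev_lic_t.push_back(t_next);
          }
        }
      }
    }
    // binding of naive / partially activated T cells to presenting DCs
    order.clear();
    for (size_t i = 0; i < T.size(); ++i)
      if ((T.st[i] == S_NAIVE || T.st[i] == S_PARTIAL) && T.bound[i] < 0 &&
          T.comp[i] != C_CIRC)
        order.push_back((int)i);
    shuffle(order);
    std::vector<int> cand;
    for (size_t k = 0; k < order.size(); ++k) {
      int i = order[k];
      if (ru() >= p_bind) continue;
      cand.clear();
      for (size_t q = 0; q < nb[T.space[i]].size(); ++q) {
        const std::vector<int> &dl = dc_by_space[nb[T.space[i]][q]];
        for (size_t m = 0; m < dl.size(); ++m) {
          int d = dl[m];
          if (!D.mature[d] || D.bound_n[d] >= dc_sites) continue;
          bool ok = false;
          if (T.lin[i] == L_UNPOL) ok = showing_mbp(d, t_next);
          else if (T.lin[i] == L_TREG4) ok = showing_fr3(d, t_next);
          else if (T.lin[i] == L_TREG8)
            ok = showing_fr3(d, t_next) && D.qa1[d];
          if (ok) cand.push_back(d);
        }
      }
      if (!cand.empty()) {
        int d = cand[rint_n((int)cand.size())];
        T.bound[i] = d;
        D.bound_n[d]++;
        T.contact_left[i] = contact_dur;
      }
    }
    // progression of bound contacts
    for (size_t i = 0; i < T.size(); ++i) {
      int d = T.bound[i];
      if (d < 0 || T.st[i] > S_PARTIAL) continue;
      bool still = !D.dead[d];
      if (still) {
        if (T.lin[i] == L_UNPOL) still = showing_mbp(d, t_next);
        else if (T.lin[i] == L_TREG4) still = showing_fr3(d, t_next);
        else if (T.lin[i] == L_TREG8)
          still = showing_fr3(d, t_next) && D.qa1[d];
      }
      if (!still) {
        // interrupted contact: accumulated activation decays (the
        // partially_activated state itself is retained; maturity never
        // moves backwards)
        unbind((int)i);
        T.contacts[i] = 0;
        continue;
      }
      T.contact_left[i] -= dt;
      if (T.contact_left[i] > 0) continue;
      unbind((int)i);
      T.contacts[i]++;
      int need = (T.lin[i] == L_TREG4) ? n_contacts_t4
                 : (T.lin[i] == L_TREG8 ? n_contacts_t8 : n_contacts);
      if (T.contacts[i] < need) {
        T.st[i] = S_PARTIAL;
        continue;
      }
      // final contact: effector transition
      T.st[i] = S_EFF;
      T.t_eff[i] = t_next;
      if (T.lin[i] == L_UNPOL) {
        double p1 = D.polar1[d] ? p_th1 : 0.5;
        int newlin = (ru() < p1) ? L_TH1 : L_TH2;
        created[L_UNPOL]--;
        created[newlin]++;
        T.lin[i] = newlin;
      }
      T.eclock[i] = elife[T.lin[i]] * (1.0 + ejit * (2.0 * ru() - 1.0));
      ev_prime_t.push_back(t_next);
      ev_prime_lin.push_back(T.lin[i]);
      ev_prime_comp.push_back(T.comp[i]);
      ev_prime_dc.push_back(d);
      // clonal expansion burst; daughters arise in the parent cell's
      // neighbourhood around the priming DC and are lost if it is full
      int b = burst[T.lin[i]];
      int lin = T.lin[i], c = T.comp[i];
      double base = elife[lin];
      const std::vector<int> &nbs = nb[T.space[i]];
      for (int m = 0; m < b; ++m) {
        int s2 = -1;
        for (int k = 0; k < 6; ++k) {
          int cand2 = nbs[rint_n((int)nbs.size())];
          if (allowed(cand2, lin)) { s2 = cand2; break; }
        }
        if (s2 < 0) continue;  // crowded out
        add_tcell(lin, S_EFF, c, s2,
                  base * (1.0 + ejit * (2.0 * ru() - 1.0)));
        T.t_eff.back() = t_next;
      }
    }

    // (6) CD8Treg killing of effector CD4Th1 -------------------------
    rebuild_t();
    for (int s = 0; s < nspace; ++s) {
      if (sp_comp[s] == C_CIRC) continue;
      const std::vector<int> &lst = t_by_space[s];
      if (lst.empty()) continue;
      std::vector<int> killers, targets;
      for (size_t m = 0; m < lst.size(); ++m) {
        int i = lst[m];
        if (T.st[i] != S_EFF) continue;
        if (T.lin[i] == L_TREG8) killers.push_back(i);
        else if (T.lin[i] == L_TH1) targets.push_back(i);
      }
      if (killers.empty() || targets.empty()) continue;
      // cytotoxicity saturates locally: at most one target is eliminated
      // per grid space per step, however many CTLs are present
      for (size_t m = 0; m < killers.size() && !targets.empty(); ++m) {
        if (ru() < p_kill * dt) {
          int pick = rint_n((int)targets.size());
          int j = targets[pick];
          targets.erase(targets.begin() + pick);
          unbind(j);
          T.st[j] = S_APOP;
          T.apop_t[j] = t_next;
          occ_del(T.space[j], T.lin[j]);
          th1_apop_total++;
          ev_kill_t.push_back(t_next);
          ev_kill_comp.push_back(T.comp[j]);
          break;
        }
      }
    }

    // (7) recording ---------------------------------------------------
    if ((step + 1) % steps_per_record == 0) record(t_next);
  }

  // ---- assemble results ----------------------------------------------
  counts.attr("dim") = IntegerVector::create(n_rec, 8, 5, 4);
  CharacterVector lin_names = CharacterVector::create(
      "CD4Th_naive_unpolarized", "CD4Th1", "CD4Th2", "CD4Treg", "CD8Treg",
      "DendriticCell", "Microglia", "Neuron");
  CharacterVector comp_names =
      CharacterVector::create("CNS", "CLN", "Spleen", "Circulation");

  auto lin_factor = [&](std::vector<int> &v) {
    CharacterVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = lin_names[v[i]];
    return out;
  };
  auto comp_factor = [&](std::vector<int> &v) {
    CharacterVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = comp_names[v[i]];
    return out;
  };

  DataFrame priming = DataFrame::create(
      _["time"] = ev_prime_t, _["lineage"] = lin_factor(ev_prime_lin),
      _["compartment"] = comp_factor(ev_prime_comp),
      _["dc_id"] = ev_prime_dc, _["stringsAsFactors"] = false);
  DataFrame licensing = DataFrame::create(
      _["dc_id"] = ev_lic_dc, _["creation_time"] = ev_lic_created,
      _["licensing_time"] = ev_lic_t, _["stringsAsFactors"] = false);
  DataFrame kills = DataFrame::create(
      _["time"] = ev_kill_t, _["compartment"] = comp_factor(ev_kill_comp),
      _["stringsAsFactors"] = false);
  DataFrame census = DataFrame::create(
      _["time"] = ev_cen_t, _["compartment"] = comp_factor(ev_cen_comp),
      _["presented_mbp"] = ev_cen_mbp, _["presented_tcr"] = ev_cen_tcr,
      _["nb_cd4th_naive"] = ev_cen_nb[0], _["nb_cd4th1"] = ev_cen_nb[1],
      _["nb_cd4th2"] = ev_cen_nb[2], _["nb_cd4treg"] = ev_cen_nb[3],
      _["nb_cd8treg"] = ev_cen_nb[4], _["stringsAsFactors"] = false);

  NumericVector created_v(8), removed_v(8);
  for (int l = 0; l < 8; ++l) {
    created_v[l] = (double)created[l];
    removed_v[l] = (double)removedc[l];
  }
  created_v.attr("names") = lin_names;
  removed_v.attr("names") = lin_names;

  return List::create(
      _["counts"] = counts, _["record_times"] = record_times,
      _["priming"] = priming, _["licensing"] = licensing,
      _["kills"] = kills, _["dc_census"] = census,
      _["th1_apoptosis_total"] = (double)th1_apop_total,
      _["created"] = created_v, _["removed"] = removed_v,
      _["conservation_ok"] = conservation_ok);
}
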