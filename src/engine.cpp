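#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based substream RNG: every uniform is a pure hash of
// (master_seed, replicate, individual, arm, purpose, day, index), so any
// draw can be reproduced independently of execution order and arms can
// share uniforms (common random numbers).

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t stream_base(uint64_t seed, uint64_t rep, uint64_t id) {
  uint64_t h = sm64(seed ^ 0xA5A5A5A5DEADBEEFULL);
  h = sm64(h + rep);
  h = sm64(h + id);
  return h;
}

static inline double u01(uint64_t h) {
  // 53 random bits, open interval (0, 1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double stream_u(uint64_t base, int purpose, int arm,
                              uint64_t day, uint64_t idx) {
  uint64_t h = sm64(base + ((uint64_t)purpose << 1) + ((uint64_t)arm << 8));
  h = sm64(h + day);
  h = sm64(h + idx);
  return u01(h);
}

// [[Rcpp::export]]
NumericVector cpp_stream_uniform(double master_seed, double replicate_id,
                                 NumericVector individual_id, int arm_tag,
                                 int purpose, NumericVector day,
                                 NumericVector idx) {
  R_xlen_t n = std::max(individual_id.size(),
                        std::max(day.size(), idx.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t id = (uint64_t)individual_id[i % individual_id.size()];
    uint64_t base = stream_base((uint64_t)master_seed,
                                (uint64_t)replicate_id, id);
    out[i] = stream_u(base, purpose, arm_tag,
                      (uint64_t)day[i % day.size()],
                      (uint64_t)idx[i % idx.size()]);
  }
  return out;
}

// purposes (keep in sync with R/cohort.R)
enum Purpose {
  PUR_AGE = 0, PUR_INR = 1, PUR_BLEED_TEST = 2, PUR_TE_TEST = 3,
  PUR_BLEED_SUBTYPE = 4, PUR_BLEED_OUTCOME = 5, PUR_TE_SUBTYPE = 6,
  PUR_TE_OUTCOME = 7, PUR_DEATH_DAY = 8
};

struct EngineTables {
  int horizon;
  std::vector<double> disc;       // (1+r)^(-d/365)
  double inr_cut_y1[2], inr_cut_y2[2];
  double p_bleed_on[3];
  double p_te_total_on[3];
  double lam_te_on[12];           // state*4 + subtype (stroke, mi, pe, dvt)
  double p_te_total_off;
  double lam_te_off[4];
  double p_intracranial;
  double ich_cum[3];              // none, +mild, +severe (rest: death)
  double p_death_extracranial;
  double stroke_death[3];
  double stroke_seq_cum[2];       // survivors: severe, +mild (rest: none)
  double p_death_pe, p_death_dvt, p_death_mi;
  int gi_off_days;
  double drug_daily, monitor_y1, monitor_later, day0_cost;
  double cost_ich[4];             // none, mild, severe, death
  double cost_extracranial;
  double cost_stroke[4];
  double cost_mi, cost_pe, cost_dvt;
  double post_daily[3];           // by sequela level: 0, mild, severe
  double u_base;
  double u_ich[3], u_extracranial, u_stroke[3], u_mi, u_pe, u_dvt;
};

static void fill_tables(const List& tb, EngineTables& T) {
  T.horizon = as<int>(tb["horizon"]);
  double r = as<double>(tb["disc_annual"]);
  T.disc.resize(T.horizon);
  for (int d = 0; d < T.horizon; ++d)
    T.disc[d] = std::pow(1.0 + r, -(double)d / 365.0);
  NumericVector v;
  v = tb["inr_cut_y1"]; T.inr_cut_y1[0] = v[0]; T.inr_cut_y1[1] = v[1];
  v = tb["inr_cut_y2"]; T.inr_cut_y2[0] = v[0]; T.inr_cut_y2[1] = v[1];
  v = tb["p_bleed_on"]; for (int i = 0; i < 3; ++i) T.p_bleed_on[i] = v[i];
  v = tb["p_te_total_on"]; for (int i = 0; i < 3; ++i) T.p_te_total_on[i] = v[i];
  v = tb["lam_te_on"]; for (int i = 0; i < 12; ++i) T.lam_te_on[i] = v[i];
  T.p_te_total_off = as<double>(tb["p_te_total_off"]);
  v = tb["lam_te_off"]; for (int i = 0; i < 4; ++i) T.lam_te_off[i] = v[i];
  T.p_intracranial = as<double>(tb["p_intracranial"]);
  v = tb["ich_cum"]; for (int i = 0; i < 3; ++i) T.ich_cum[i] = v[i];
  T.p_death_extracranial = as<double>(tb["p_death_extracranial"]);
  v = tb["stroke_death"]; for (int i = 0; i < 3; ++i) T.stroke_death[i] = v[i];
  v = tb["stroke_seq_cum"]; T.stroke_seq_cum[0] = v[0]; T.stroke_seq_cum[1] = v[1];
  T.p_death_pe = as<double>(tb["p_death_pe"]);
  T.p_death_dvt = as<double>(tb["p_death_dvt"]);
  T.p_death_mi = as<double>(tb["p_death_mi"]);
  T.gi_off_days = as<int>(tb["gi_off_days"]);
  T.drug_daily = as<double>(tb["drug_daily"]);
  T.monitor_y1 = as<double>(tb["monitor_y1"]);
  T.monitor_later = as<double>(tb["monitor_later"]);
  T.day0_cost = as<double>(tb["day0_cost"]);
  v = tb["cost_ich"]; for (int i = 0; i < 4; ++i) T.cost_ich[i] = v[i];
  T.cost_extracranial = as<double>(tb["cost_extracranial"]);
  v = tb["cost_stroke"]; for (int i = 0; i < 4; ++i) T.cost_stroke[i] = v[i];
  T.cost_mi = as<double>(tb["cost_mi"]);
  T.cost_pe = as<double>(tb["cost_pe"]);
  T.cost_dvt = as<double>(tb["cost_dvt"]);
  v = tb["post_daily"]; for (int i = 0; i < 3; ++i) T.post_daily[i] = v[i];
  T.u_base = as<double>(tb["u_base"]);
  v = tb["u_ich"]; for (int i = 0; i < 3; ++i) T.u_ich[i] = v[i];
  T.u_extracranial = as<double>(tb["u_extracranial"]);
  v = tb["u_stroke"]; for (int i = 0; i < 3; ++i) T.u_stroke[i] = v[i];
  T.u_mi = as<double>(tb["u_mi"]);
  T.u_pe = as<double>(tb["u_pe"]);
  T.u_dvt = as<double>(tb["u_dvt"]);
}

struct EventLog {
  std::vector<int> id, day, category, subtype, fatal, death_day, sequela;
  void push(int i, int d, int cat, int sub, bool fat, int dd, int seq) {
    id.push_back(i); day.push_back(d); category.push_back(cat);
    subtype.push_back(sub); fatal.push_back(fat ? 1 : 0);
    death_day.push_back(dd); sequela.push_back(seq);
  }
};

// Simulate the full daily path of one individual under one arm.
// All event and resolution uniforms are keyed without the arm tag (common
// random numbers): arms facing identical hazards and splits reproduce
// identical trajectories, and between-arm deltas isolate the intervention.
static void simulate_one(uint64_t base, int arm_tag, const EngineTables& T,
                         int ind_id, bool collect, EventLog& log,
                         double& out_cost, double& out_qaly,
                         int& out_pdays, int& out_nbleed, int& out_nte,
                         bool& out_alive) {
  double cost = 0.0, qaly = 0.0;
  int off_until = -1;        // on treatment iff d > off_until (and not perm)
  bool off_perm = false;
  int seq_level = 0;         // 0 none, 1 mild, 2 severe
  double seq_util = 1.0;
  int seq_active_day = INT32_MAX;
  double win_util = 1.0;     // transient post-event utility window
  int win_end = -1;          // exclusive
  bool dying = false;
  int death_day = -1;
  int nbleed = 0, nte = 0;
  const int H = T.horizon;
  int d = 0;
  for (d = 0; d < H; ++d) {
    if (dying && d >= death_day) break;
    bool year1 = d < 365;
    bool on = !off_perm && d > off_until;
    double disc = T.disc[d];
    // --- daily costs ---
    double ctoday = 0.0;
    if (d == 0) ctoday += T.day0_cost;
    if (on) ctoday += T.drug_daily + (year1 ? T.monitor_y1 : T.monitor_later);
    if (seq_level > 0 && d >= seq_active_day) ctoday += T.post_daily[seq_level];
    // --- utility (before any event today) ---
    double u = T.u_base;
    if (d < win_end && win_util < u) u = win_util;
    if (seq_level > 0 && d >= seq_active_day && seq_util < u) u = seq_util;
    // --- events ---
    if (!dying) {
      double p_bleed, p_te_tot;
      const double* lam;
      if (on) {
        double ui = stream_u(base, PUR_INR, 0, d, 0);
        const double* cut = year1 ? T.inr_cut_y1 : T.inr_cut_y2;
        int st = (ui < cut[0]) ? 0 : (ui < cut[1] ? 1 : 2);
        p_bleed = T.p_bleed_on[st];
        p_te_tot = T.p_te_total_on[st];
        lam = &T.lam_te_on[st * 4];
      } else {
        p_bleed = 0.0;
        p_te_tot = T.p_te_total_off;
        lam = T.lam_te_off;
      }
      double u1 = stream_u(base, PUR_BLEED_TEST, 0, d, 0);
      bool bleed = u1 < p_bleed;
      bool te = false;
      if (!bleed) {
        double u2 = stream_u(base, PUR_TE_TEST, 0, d, 0);
        te = u2 < p_te_tot;
      }
      if (bleed) {
        ++nbleed;
        double us = stream_u(base, PUR_BLEED_SUBTYPE, 0, d, 0);
        if (us < T.p_intracranial) {
          // intracranial hemorrhage: outcome tree, permanent cessation
          double uo = stream_u(base, PUR_BLEED_OUTCOME, 0, d, 0);
          int oc = (uo < T.ich_cum[0]) ? 0 : (uo < T.ich_cum[1]) ? 1 :
                   (uo < T.ich_cum[2]) ? 2 : 3;
          off_perm = true;
          if (oc == 3) { // fatal within the first month
            double ud = stream_u(base, PUR_DEATH_DAY, 0, d, 0);
            death_day = d + 1 + (int)(ud * 30.0);
            dying = true;
            ctoday += T.cost_ich[3];
            win_util = (d < win_end) ? std::min(win_util, T.u_ich[2])
                                     : T.u_ich[2];
            win_end = death_day;
            if (collect) log.push(ind_id, d, 1, 1, true, death_day, 3);
          } else {
            ctoday += T.cost_ich[oc];
            double uw = T.u_ich[oc];
            win_util = (d < win_end) ? std::min(win_util, uw) : uw;
            win_end = std::max(win_end, d + 31);
            if (oc >= 1 && oc >= seq_level) { // carry the worse sequela
              seq_level = oc;
              seq_util = std::min(seq_util, uw);
              seq_active_day = std::min(seq_active_day, d + 31);
            }
            if (collect) log.push(ind_id, d, 1, 1, false, -1, oc >= 1 ? oc : 0);
          }
        } else {
          // extracranial (gastrointestinal) bleed: 30-day cessation
          double uo = stream_u(base, PUR_BLEED_OUTCOME, 0, d, 0);
          off_until = std::max(off_until, d + T.gi_off_days);
          ctoday += T.cost_extracranial;
          if (uo < T.p_death_extracranial) {
            double ud = stream_u(base, PUR_DEATH_DAY, 0, d, 0);
            death_day = d + 1 + (int)(ud * 30.0);
            dying = true;
            win_util = (d < win_end) ? std::min(win_util, T.u_extracranial)
                                     : T.u_extracranial;
            win_end = death_day;
            if (collect) log.push(ind_id, d, 1, 2, true, death_day, 3);
          } else {
            win_util = (d < win_end) ? std::min(win_util, T.u_extracranial)
                                     : T.u_extracranial;
            win_end = std::max(win_end, d + 31);
            if (collect) log.push(ind_id, d, 1, 2, false, -1, 0);
          }
        }
      } else if (te) {
        ++nte;
        double tot = lam[0] + lam[1] + lam[2] + lam[3];
        double us = stream_u(base, PUR_TE_SUBTYPE, 0, d, 0) * tot;
        int sub = (us < lam[0]) ? 0 : (us < lam[0] + lam[1]) ? 1 :
                  (us < lam[0] + lam[1] + lam[2]) ? 2 : 3;
        double uo = stream_u(base, PUR_TE_OUTCOME, 0, d, 0);
        if (sub == 0) {
          // stroke: death in months 1-3, survivors get sequelae
          double pd = T.stroke_death[0] + T.stroke_death[1] + T.stroke_death[2];
          if (uo < pd) {
            double ud = stream_u(base, PUR_DEATH_DAY, 0, d, 0);
            int month = (uo < T.stroke_death[0]) ? 0 :
                        (uo < T.stroke_death[0] + T.stroke_death[1]) ? 1 : 2;
            death_day = d + 1 + month * 30 + (int)(ud * 30.0);
            dying = true;
            ctoday += T.cost_stroke[3];
            win_util = (d < win_end) ? std::min(win_util, T.u_stroke[2])
                                     : T.u_stroke[2];
            win_end = death_day;
            if (collect) log.push(ind_id, d, 2, 3, true, death_day, 3);
          } else {
            double v = (uo - pd) / (1.0 - pd);
            int sq = (v < T.stroke_seq_cum[0]) ? 2 :
                     (v < T.stroke_seq_cum[1]) ? 1 : 0;
            ctoday += T.cost_stroke[sq];
            double uw = T.u_stroke[sq];
            win_util = (d < win_end) ? std::min(win_util, uw) : uw;
            win_end = std::max(win_end, d + 31);
            if (sq > 0 && sq >= seq_level) {
              seq_level = sq;
              seq_util = std::min(seq_util, uw);
              seq_active_day = std::min(seq_active_day, d + 31);
            }
            if (collect) log.push(ind_id, d, 2, 3, false, -1, sq);
          }
        } else {
          double pfat = (sub == 1) ? T.p_death_mi :
                        (sub == 2) ? T.p_death_pe : T.p_death_dvt;
          double cst = (sub == 1) ? T.cost_mi :
                       (sub == 2) ? T.cost_pe : T.cost_dvt;
          double uw = (sub == 1) ? T.u_mi : (sub == 2) ? T.u_pe : T.u_dvt;
          ctoday += cst;
          if (uo < pfat) {
            double ud = stream_u(base, PUR_DEATH_DAY, 0, d, 0);
            death_day = d + 1 + (int)(ud * 30.0);
            dying = true;
            win_util = (d < win_end) ? std::min(win_util, uw) : uw;
            win_end = death_day;
            if (collect) log.push(ind_id, d, 2, sub + 3, true, death_day, 3);
          } else {
            win_util = (d < win_end) ? std::min(win_util, uw) : uw;
            win_end = std::max(win_end, d + 31);
            if (collect) log.push(ind_id, d, 2, sub + 3, false, -1, 0);
          }
        }
      }
    }
    cost += ctoday * disc;
    qaly += u / 365.0 * disc;
  }
  out_cost = cost;
  out_qaly = qaly;
  out_pdays = d;
  out_nbleed = nbleed;
  out_nte = nte;
  out_alive = !(dying && death_day < H);
}

// [[Rcpp::export]]
List cpp_run_arm(int n, int arm_tag, double master_seed, double replicate_id,
                 List tb, bool collect_events) {
  EngineTables T;
  fill_tables(tb, T);
  NumericVector cost(n), qaly(n);
  IntegerVector pdays(n), nbleed(n), nte(n);
  LogicalVector alive(n);
  EventLog log;
  for (int i = 0; i < n; ++i) {
    uint64_t base = stream_base((uint64_t)master_seed,
                                (uint64_t)replicate_id, (uint64_t)i);
    double c, q; int pd, nb, nt; bool al;
    simulate_one(base, arm_tag, T, i, collect_events, log,
                 c, q, pd, nb, nt, al);
    cost[i] = c; qaly[i] = q; pdays[i] = pd;
    nbleed[i] = nb; nte[i] = nt; alive[i] = al;
  }
  List events = List::create(
    _["individual"] = wrap(log.id), _["day"] = wrap(log.day),
    _["category"] = wrap(log.category), _["subtype"] = wrap(log.subtype),
    _["fatal"] = wrap(log.fatal), _["death_day"] = wrap(log.death_day),
    _["sequela"] = wrap(log.sequela));
  return List::create(
    _["cost"] = cost, _["qaly"] = qaly, _["person_days"] = pdays,
    _["n_bleed"] = nbleed, _["n_te"] = nte, _["alive"] = alive,
    _["events"] = events);
}
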