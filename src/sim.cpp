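// Hourly individual-based engine for the mosquito lifecycle, genetics and
// release campaigns. All stochastic draws use R's RNG so that a single
// set.seed() on the R side fixes the whole trajectory.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// life states (DEAD only appears in the event log; dead agents are removed)
const int ST_EGG = 1, ST_LARVA = 2, ST_PUPA = 3, ST_IMM = 4, ST_MATE = 5,
          ST_BMSEEK = 6, ST_BMDIG = 7, ST_GRAVID = 8, ST_DEAD = 9;
const int FATE_OK = 0, FATE_EGG = 1, FATE_PUPA = 2;
const int IMPL_NONE = 0, IMPL_EBS = 1, IMPL_EFK = 2, IMPL_LBS = 3,
          IMPL_LFK = 4;
const int SEX_MALE = 0, SEX_FEMALE = 1;

const double HOURS_EGG_BASE = 24.0;   // 1 day + hatch time
const double HOURS_LARVA = 288.0;     // 12 days, exit at nighttime
const double HOURS_PUPA_BASE = 24.0;  // 1 day + hatch time, exit at nighttime
const double HOURS_IMM = 53.0;
const double HOURS_DIGEST = 36.0;
const double P_BLOODMEAL = 0.25;      // per nighttime hour

inline bool is_night_hod(int hod) { return hod >= 18 || hod < 6; }

// five-branch piecewise hatch-time curve over x in [0, 1], in hours
double hatch_time_pw(double x) {
  if (x <= 0.5)  return 40.0 * x;
  if (x <= 0.85) return 68.57 * x - 10.28;
  if (x <= 0.9)  return 480.0 * x - 360.0;
  if (x <= 0.94) return 600.0 * x - 468.0;
  return 2400.0 * x - 2160.0;
}

inline double draw_hatch() { return hatch_time_pw(unif_rand()); }

// age-dependent daily adult mortality, n in days (stable algebraic form)
inline double adult_rate(double n) {
  return 0.1 / (0.25 + 0.75 * std::exp(-n / 25.0));
}

// dominant single-locus lethality: where does a carrier stop developing?
inline int fate_of(int zyg, int sex, int impl) {
  if (impl == IMPL_NONE || zyg == 0) return FATE_OK;
  switch (impl) {
  case IMPL_EBS: return FATE_EGG;
  case IMPL_EFK: return sex == SEX_FEMALE ? FATE_EGG : FATE_OK;
  case IMPL_LBS: return FATE_PUPA;
  case IMPL_LFK: return sex == SEX_FEMALE ? FATE_PUPA : FATE_OK;
  }
  return FATE_OK;
}

struct Pop {
  std::vector<int> id, sex, zyg, state, birth, entry, clutch, sire_zyg, fate;
  std::vector<double> comp, hatch, sire_comp;
  std::vector<char> alive;
  int next_id;

  size_t size() const { return id.size(); }

  void push(int id_, int sex_, int zyg_, double comp_, int state_, int birth_,
            int entry_, double hatch_, int clutch_, int sire_zyg_,
            double sire_comp_, int fate_) {
    id.push_back(id_); sex.push_back(sex_); zyg.push_back(zyg_);
    comp.push_back(comp_); state.push_back(state_); birth.push_back(birth_);
    entry.push_back(entry_); hatch.push_back(hatch_);
    clutch.push_back(clutch_); sire_zyg.push_back(sire_zyg_);
    sire_comp.push_back(sire_comp_); fate.push_back(fate_);
    alive.push_back(1);
  }

  void compact() {
    size_t n = size(), k = 0;
    for (size_t i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      if (k != i) {
        id[k] = id[i]; sex[k] = sex[i]; zyg[k] = zyg[i]; comp[k] = comp[i];
        state[k] = state[i]; birth[k] = birth[i]; entry[k] = entry[i];
        hatch[k] = hatch[i]; clutch[k] = clutch[i];
        sire_zyg[k] = sire_zyg[i]; sire_comp[k] = sire_comp[i];
        fate[k] = fate[i]; alive[k] = 1;
      }
      ++k;
    }
    id.resize(k); sex.resize(k); zyg.resize(k); comp.resize(k);
    state.resize(k); birth.resize(k); entry.resize(k); hatch.resize(k);
    clutch.resize(k); sire_zyg.resize(k); sire_comp.resize(k);
    fate.resize(k); alive.resize(k);
  }
};

struct EventLog {
  bool on;
  std::vector<int> id, hour, from, to;
  void rec(int id_, int hour_, int from_, int to_) {
    if (!on) return;
    id.push_back(id_); hour.push_back(hour_);
    from.push_back(from_); to.push_back(to_);
  }
};

double l_mass_of(const Pop& p, int h) {
  double lm = 0.0;
  for (size_t i = 0; i < p.size(); ++i) {
    if (!p.alive[i] || p.state[i] != ST_LARVA) continue;
    int nd = (int)std::floor((h - p.birth[i]) / 24.0);
    if (nd < 1) continue;          // day-age 0 contributes nothing
    if (nd > 10) nd = 10;          // clamp: older larvae weigh as 10-day-olds
    lm += nd;
  }
  return lm;
}

Pop pop_from_df(DataFrame df, int next_id_hint) {
  Pop p;
  IntegerVector id = df["id"], sex = df["sex"], zyg = df["zygosity"],
                state = df["state"], birth = df["birth_hour"],
                entry = df["state_entry"], clutch = df["clutch"],
                sire_zyg = df["sire_zygosity"], fate = df["fate"];
  NumericVector comp = df["competitiveness"], hatch = df["hatch_hours"],
                sire_comp = df["sire_competitiveness"];
  int n = df.nrows();
  int mx = 0;
  for (int i = 0; i < n; ++i) {
    p.push(id[i], sex[i], zyg[i], comp[i], state[i], birth[i], entry[i],
           hatch[i], clutch[i], sire_zyg[i], sire_comp[i], fate[i]);
    if (id[i] > mx) mx = id[i];
  }
  p.next_id = std::max(mx + 1, next_id_hint);
  return p;
}

DataFrame pop_to_df(const Pop& p) {
  size_t n = p.size();
  IntegerVector id(n), sex(n), zyg(n), state(n), birth(n), entry(n),
                clutch(n), sire_zyg(n), fate(n);
  NumericVector comp(n), hatch(n), sire_comp(n);
  for (size_t i = 0; i < n; ++i) {
    id[i] = p.id[i]; sex[i] = p.sex[i]; zyg[i] = p.zyg[i];
    state[i] = p.state[i]; birth[i] = p.birth[i]; entry[i] = p.entry[i];
    clutch[i] = p.clutch[i]; sire_zyg[i] = p.sire_zyg[i];
    fate[i] = p.fate[i]; comp[i] = p.comp[i]; hatch[i] = p.hatch[i];
    sire_comp[i] = p.sire_comp[i];
  }
  return DataFrame::create(
      _["id"] = id, _["sex"] = sex, _["zygosity"] = zyg,
      _["competitiveness"] = comp, _["state"] = state,
      _["birth_hour"] = birth, _["state_entry"] = entry,
      _["hatch_hours"] = hatch, _["clutch"] = clutch,
      _["sire_zygosity"] = sire_zyg, _["sire_competitiveness"] = sire_comp,
      _["fate"] = fate);
}

}  // namespace

// Run the engine from start_hour (inclusive) to end_hour (exclusive).
// Daily cadence: mortality at 12:00; census at 15:00 (counts before the
// release, fecundity potential after); releases at 15:00 on campaign days;
// mating at 18:00; nighttime is [18:00, 06:00).
// campaign_start_day < 0 disables releases; baseline_start_day < 0 disables
// the baseline census; release_number_override >= 0 skips the baseline
// product and releases that fixed number.
// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(DataFrame init, int start_hour, int end_hour,
                double carrying_capacity, int clutch_size, int impl,
                int campaign_start_day, int campaign_days,
                double release_prop, double release_comp,
                int baseline_start_day, int baseline_days,
                int release_number_override, bool log_events) {
  if (carrying_capacity <= 0) stop("carrying capacity must be positive");
  if (release_prop < 0) stop("release proportion must be nonnegative");
  if (start_hour < 0 || end_hour < start_hour) stop("bad hour range");

  Pop p = pop_from_df(init, 1);
  EventLog ev; ev.on = log_events;

  double base_sum = 0.0; long base_n = 0;
  int release_number = release_number_override >= 0 ? release_number_override : -1;
  long released_total = 0;
  bool extinct_before_campaign = false;

  const int NCOL = 17;
  std::vector<double> rows;  // day + 16 measures per census day
  std::vector<double> cum(1, 0.0);  // cumulative male weights for mating

  for (int h = start_hour; h < end_hour; ++h) {
    int hod = h % 24;
    int day = h / 24;
    bool night = is_night_hod(hod);

    // ---- daily mortality pass at noon ----
    if (hod == 12) {
      double lm = l_mass_of(p, h);
      for (size_t i = 0; i < p.size(); ++i) {
        if (!p.alive[i]) continue;
        double pr;
        int st = p.state[i];
        if (st == ST_EGG || st == ST_PUPA) {
          pr = 0.1;
        } else if (st == ST_LARVA) {
          int nm = (int)std::floor((h - p.birth[i]) / 24.0);
          if (nm < 1) nm = 1;
          pr = 0.1 * std::exp(lm / (nm * carrying_capacity));
          if (pr > 1.0) pr = 1.0;
        } else {
          pr = adult_rate((h - p.birth[i]) / 24.0);
        }
        if (unif_rand() < pr) {
          p.alive[i] = 0;
          ev.rec(p.id[i], h, st, ST_DEAD);
        }
      }
      p.compact();
      if (p.size() == 0 && (campaign_start_day < 0 || day < campaign_start_day))
        extinct_before_campaign = true;
    }

    // ---- 15:00: census (before release), then release, then fecundity ----
    if (hod == 15) {
      double wt_af = 0, wt_am = 0, hom_am = 0, het_am = 0;
      double wt_lf = 0, wt_lm = 0, het_lf = 0, het_lm = 0;
      double hom_lf = 0, hom_lm = 0, n_eggs = 0, n_pupae = 0, n_imm = 0;
      for (size_t i = 0; i < p.size(); ++i) {
        if (!p.alive[i]) continue;
        int st = p.state[i];
        if (st == ST_EGG) { n_eggs += 1; continue; }
        if (st == ST_PUPA) { n_pupae += 1; continue; }
        if (st == ST_LARVA) {
          if (p.zyg[i] == 0) { if (p.sex[i] == SEX_FEMALE) wt_lf += 1; else wt_lm += 1; }
          else if (p.zyg[i] == 1) { if (p.sex[i] == SEX_FEMALE) het_lf += 1; else het_lm += 1; }
          else { if (p.sex[i] == SEX_FEMALE) hom_lf += 1; else hom_lm += 1; }
          continue;
        }
        // adult states (immature adult onward)
        if (st == ST_IMM) n_imm += 1;
        if (p.sex[i] == SEX_FEMALE) {
          if (p.zyg[i] == 0) wt_af += 1;
        } else {
          if (p.zyg[i] == 0) wt_am += 1;
          else if (p.zyg[i] == 1) het_am += 1;
          else hom_am += 1;
        }
      }
      double lm_now = l_mass_of(p, h);

      // 30-day baseline male census inside the burn-in
      if (baseline_start_day >= 0 && day >= baseline_start_day &&
          day < baseline_start_day + baseline_days) {
        base_sum += wt_am; base_n += 1;
      }

      bool campaign_on = campaign_start_day >= 0 && day >= campaign_start_day &&
                         day < campaign_start_day + campaign_days;
      if (campaign_start_day >= 0 && day == campaign_start_day &&
          release_number < 0) {
        release_number = 0;
        if (impl != IMPL_NONE && release_prop > 0 && base_n > 0) {
          double avg = base_sum / (double)base_n;
          release_number = (int)std::floor(avg * release_prop + 0.5);
        }
      }
      if (campaign_on && impl != IMPL_NONE && release_number > 0) {
        for (int r = 0; r < release_number; ++r) {
          p.push(p.next_id++, SEX_MALE, 2, release_comp, ST_MATE, h, h, 0.0,
                 0, -1, NA_REAL, fate_of(2, SEX_MALE, impl));
        }
        released_total += release_number;
      }

      // fecundity potential over the mate-seeking male pool, after release
      double s = 0, s_hom = 0, s_het = 0;
      for (size_t i = 0; i < p.size(); ++i) {
        if (!p.alive[i] || p.state[i] != ST_MATE || p.sex[i] != SEX_MALE)
          continue;
        s += p.comp[i];
        if (p.zyg[i] == 2) s_hom += p.comp[i];
        else if (p.zyg[i] == 1) s_het += p.comp[i];
      }
      double F = (s > 0) ? 1.0 - s_hom / s - s_het / (2.0 * s) : NA_REAL;

      rows.push_back((double)day);
      rows.push_back(wt_af); rows.push_back(wt_am);
      rows.push_back(hom_am); rows.push_back(het_am);
      rows.push_back(F);
      rows.push_back(wt_lf); rows.push_back(wt_lm);
      rows.push_back(het_lf); rows.push_back(het_lm);
      rows.push_back(lm_now / carrying_capacity);
      rows.push_back(hom_lf); rows.push_back(hom_lm);
      rows.push_back(n_eggs); rows.push_back(n_pupae); rows.push_back(n_imm);
      rows.push_back(lm_now);
    }

    // ---- hourly state transitions (agents present at the top of the hour) ----
    size_t n0 = p.size();
    for (size_t i = 0; i < n0; ++i) {
      if (!p.alive[i]) continue;
      int st = p.state[i];
      double in_state = (double)(h - p.entry[i]);
      switch (st) {
      case ST_EGG:
        if (in_state >= HOURS_EGG_BASE + p.hatch[i]) {
          if (p.fate[i] == FATE_EGG) {
            p.alive[i] = 0; ev.rec(p.id[i], h, ST_EGG, ST_DEAD);
          } else {
            p.state[i] = ST_LARVA; p.entry[i] = h;
            ev.rec(p.id[i], h, ST_EGG, ST_LARVA);
          }
        }
        break;
      case ST_LARVA:
        if (night && in_state >= HOURS_LARVA) {
          p.state[i] = ST_PUPA; p.entry[i] = h;
          p.hatch[i] = draw_hatch();  // fresh, independent pupal draw
          ev.rec(p.id[i], h, ST_LARVA, ST_PUPA);
        }
        break;
      case ST_PUPA:
        if (night && in_state >= HOURS_PUPA_BASE + p.hatch[i]) {
          if (p.fate[i] == FATE_PUPA) {
            p.alive[i] = 0; ev.rec(p.id[i], h, ST_PUPA, ST_DEAD);
          } else {
            p.state[i] = ST_IMM; p.entry[i] = h;
            ev.rec(p.id[i], h, ST_PUPA, ST_IMM);
          }
        }
        break;
      case ST_IMM:
        if (in_state >= HOURS_IMM) {
          p.state[i] = ST_MATE; p.entry[i] = h;
          ev.rec(p.id[i], h, ST_IMM, ST_MATE);
        }
        break;
      case ST_MATE:
        break;  // females pair at the 18:00 mating step; males wait
      case ST_BMSEEK:
        if (night && unif_rand() < P_BLOODMEAL) {
          p.state[i] = ST_BMDIG; p.entry[i] = h;  // meal completes in-hour
          ev.rec(p.id[i], h, ST_BMSEEK, ST_BMDIG);
        }
        break;
      case ST_BMDIG:
        if (night && in_state >= HOURS_DIGEST) {
          p.state[i] = ST_GRAVID; p.entry[i] = h;
          p.clutch[i] = clutch_size;
          ev.rec(p.id[i], h, ST_BMDIG, ST_GRAVID);
        }
        break;
      case ST_GRAVID:
        if (night && p.clutch[i] > 0) {
          int nc = p.clutch[i];
          for (int c = 0; c < nc; ++c) {
            int csex = unif_rand() < 0.5 ? SEX_MALE : SEX_FEMALE;
            int a = unif_rand() < p.zyg[i] / 2.0 ? 1 : 0;
            int b = unif_rand() < p.sire_zyg[i] / 2.0 ? 1 : 0;
            int cz = a + b;
            double cc = (p.comp[i] + p.sire_comp[i]) / 2.0;
            p.push(p.next_id++, csex, cz, cc, ST_EGG, h, h, draw_hatch(), 0,
                   -1, NA_REAL, fate_of(cz, csex, impl));
          }
          p.clutch[i] = 0;
          p.state[i] = ST_BMSEEK; p.entry[i] = h;
          ev.rec(p.id[i], h, ST_GRAVID, ST_BMSEEK);
        }
        break;
      default:
        stop("unknown life state");
      }
    }

    // ---- 18:00 mating: weighted mate choice, males stay in the pool ----
    if (hod == 18) {
      std::vector<size_t> males;
      for (size_t i = 0; i < p.size(); ++i)
        if (p.alive[i] && p.state[i] == ST_MATE && p.sex[i] == SEX_MALE)
          males.push_back(i);
      if (!males.empty()) {
        cum.assign(males.size(), 0.0);
        double tot = 0.0;
        for (size_t k = 0; k < males.size(); ++k) {
          tot += p.comp[males[k]];
          cum[k] = tot;
        }
        if (tot > 0) {
          for (size_t i = 0; i < p.size(); ++i) {
            if (!p.alive[i] || p.state[i] != ST_MATE || p.sex[i] != SEX_FEMALE)
              continue;
            double u = unif_rand() * tot;
            size_t k = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
            if (k >= males.size()) k = males.size() - 1;
            size_t m = males[k];
            p.sire_zyg[i] = p.zyg[m];
            p.sire_comp[i] = p.comp[m];
            p.state[i] = ST_BMSEEK; p.entry[i] = h;
            ev.rec(p.id[i], h, ST_MATE, ST_BMSEEK);
          }
        }
      }
    }
  }

  p.compact();

  int nrow = (int)(rows.size() / NCOL);
  NumericMatrix m(nrow, NCOL);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < NCOL; ++c) m(r, c) = rows[r * NCOL + c];
  colnames(m) = CharacterVector::create(
      "day", "wt_adult_females", "wt_adult_males", "hom_adult_males",
      "het_adult_males", "fecundity_potential", "wt_larval_females",
      "wt_larval_males", "het_larval_females", "het_larval_males",
      "larval_mortality_factor", "hom_larval_females", "hom_larval_males",
      "eggs", "pupae", "immature_adults", "larval_biomass");

  List out = List::create(
      _["measures"] = m,
      _["baseline_male_average"] =
          base_n > 0 ? base_sum / (double)base_n : NA_REAL,
      _["release_number"] = release_number < 0 ? 0 : release_number,
      _["released_total"] = (double)released_total,
      _["extinct_before_campaign"] = extinct_before_campaign,
      _["population"] = pop_to_df(p));
  if (log_events) {
    out["events"] = DataFrame::create(
        _["id"] = wrap(ev.id), _["hour"] = wrap(ev.hour),
        _["from"] = wrap(ev.from), _["to"] = wrap(ev.to));
  }
  return out;
}
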