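// Daily scheduler for the foraging-evolution simulator.
//
// The hot loop lives here because a default run is 279 x 365 days and the
// statistics layer wants many independent seeded runs. All randomness is
// drawn from R's RNG stream (unif_rand), so set.seed() on the R side makes
// trajectories bit-reproducible. The R package exposes the same primitive
// rules (inheritance kernel, FMR allometry, torus geometry, feeding order)
// as pure R functions; tests cross-check this engine against them.
//
// Phase order within a day:
//   1 carcass spawning (seasonal window, concurrency cap)
//   2 perception + movement (agents in daily-shuffled order; pursued prey
//     flee, the rest random-walk)
//   3 feeding contests at carcasses (descending dominance)
//   4 strike resolution for pursuits that closed below the capture radius
//   5 metabolic update + starvation deaths
//   6 births (per-agent Bernoulli, gated by the cap)
//   7 carcass decay / random removal / depletion
//   8 prey replenishment to the floor; calendar advance

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

inline double ru() { return unif_rand(); }

inline double mimg(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

inline double wrapc(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v -= L;      // guard against floating-point round-up
  return v;
}

inline double tdist(double x1, double y1, double x2, double y2, double L) {
  double dx = mimg(x2 - x1, L), dy = mimg(y2 - y1, L);
  return std::sqrt(dx * dx + dy * dy);
}

struct Prey {
  int id;
  double x, y;
  double heading;   // persistent heading for the correlated random walk
  int claimed_by;   // record index of pursuing agent, or -1
};

struct Carc {
  int id;
  double x, y;
  double init, cur;
  int origin;       // 0 sauropod, 1 killed prey
  int removal_day;  // scheduled early removal (-1: none); lifetime mode
  double consumed_today;
};

struct Pars {
  double L;
  int days, dpy;
  int n0, cap;
  double birth_p, birth_cost, birth_min;
  int min_prey;
  double speed, capture;
  int max_pursuit;
  double init_mass, floor_mass;
  double am, ar, ae;             // FMR anchor mass, anchor req, exponent
  int ccap;
  double p_spawn, clo, chi, prey_cmass;
  double resid, decay, removal;
  bool removal_daily;
  int init_carc;
  bool windows;
  bool refound;
  bool copy_same;
  bool log_ev;
  double wiggle;                 // max |heading change| per day, radians
  double scale[6], offset[6];
  double blo[5], bhi[5];
  double trans[25];              // row-major parent x offspring
};

struct Recs {
  std::vector<int> parent, born, died, cause, offspring;
  std::vector<double> final_mass, mass_sum, max_mass;
  std::vector<int> mass_n;
  std::vector<double> x, y, mass, intake, heading;
  std::vector<int> pursuit;        // prey id or -1
  std::vector<int> pursuit_days;
  std::vector<int> at_carc;        // per-day carcass index or -1
  std::vector<int> rank;           // n*6
  std::vector<double> fac, abil;   // n*6
  int n() const { return (int)parent.size(); }
};

struct Events {
  std::vector<int> day, type, agent, target;
  std::vector<double> value;
  bool on;
  void add(int d, int t, int a, int g, double v) {
    if (!on) return;
    day.push_back(d); type.push_back(t);
    agent.push_back(a); target.push_back(g); value.push_back(v);
  }
};

// seasonal mortality pulses: Q1, Q3, final 45 days (0-based day-of-year on
// a 365-day calendar; fractions scale for other calendar lengths)
inline bool in_window(int doy, int dpy) {
  double f = (double)doy / dpy * 365.0;
  return (f < 91.0) || (f >= 182.0 && f < 274.0) || (f >= 320.0);
}

inline int sample_class(const double *row) {
  double u = ru(), c = 0.0;
  for (int k = 0; k < 5; ++k) {
    c += row[k];
    if (u < c) return k;
  }
  return 4;
}

// In "lifetime" mode a fraction removal_prob of carcasses is fated to
// vanish early, at a uniform random day of the decay-limited life; the
// rest persist until rotted or eaten down to the residual. In "daily"
// mode every carcass faces an independent Bernoulli(removal_prob) each day.
Carc make_carcass(const Pars &P, int id, double x, double y, double mass,
                  int origin, int today) {
  int doom = -1;
  if (!P.removal_daily && ru() < P.removal) {
    double life = P.decay > 0 ? (1.0 - P.resid) / P.decay : 365.0;
    doom = today + 1 + (int)(ru() * life);
  }
  return Carc{id, x, y, mass, mass, origin, doom, 0.0};
}

int new_agent(Recs &R, const Pars &P, int parent, int day,
              double px, double py) {
  int i = R.n();
  R.parent.push_back(parent);
  R.born.push_back(day);
  R.died.push_back(-1);
  R.cause.push_back(-1);
  R.offspring.push_back(0);
  R.final_mass.push_back(P.init_mass);
  R.mass_sum.push_back(P.init_mass);
  R.mass_n.push_back(1);
  R.max_mass.push_back(P.init_mass);
  R.x.push_back(px);
  R.y.push_back(py);
  R.mass.push_back(P.init_mass);
  R.intake.push_back(0.0);
  R.heading.push_back(ru() * 2.0 * M_PI);
  R.pursuit.push_back(-1);
  R.pursuit_days.push_back(0);
  R.at_carc.push_back(-1);
  for (int g = 0; g < 6; ++g) {
    int cls;
    double f;
    if (parent < 0) {
      cls = (int)(ru() * 5.0);
      if (cls > 4) cls = 4;
      f = P.blo[cls] + ru() * (P.bhi[cls] - P.blo[cls]);
    } else {
      int pc = R.rank[(size_t)parent * 6 + g];
      cls = sample_class(P.trans + pc * 5);
      if (P.copy_same && cls == pc) {
        f = R.fac[(size_t)parent * 6 + g];
      } else {
        f = P.blo[cls] + ru() * (P.bhi[cls] - P.blo[cls]);
      }
    }
    R.rank.push_back(cls);
    R.fac.push_back(f);
    R.abil.push_back(P.scale[g] * f + P.offset[g]);
  }
  return i;
}

} // namespace

// [[Rcpp::export(name = ".run_engine")]]
List run_engine(List cfg) {
  Pars P;
  P.L = as<double>(cfg["grid_km"]);
  P.days = as<int>(cfg["days"]);
  P.dpy = as<int>(cfg["days_per_year"]);
  P.n0 = as<int>(cfg["init_allosaurs"]);
  P.cap = as<int>(cfg["max_allosaurs"]);
  P.birth_p = as<double>(cfg["birth_rate"]);
  P.birth_cost = as<double>(cfg["birth_cost_kg"]);
  P.birth_min = as<double>(cfg["birth_min_mass"]);
  P.min_prey = as<int>(cfg["min_prey"]);
  P.speed = as<double>(cfg["move_km"]);
  P.capture = as<double>(cfg["capture_km"]);
  P.max_pursuit = as<int>(cfg["max_pursuit_days"]);
  P.init_mass = as<double>(cfg["init_mass"]);
  P.floor_mass = as<double>(cfg["starvation_frac"]) * P.init_mass;
  P.am = as<double>(cfg["fmr_anchor_mass"]);
  P.ar = as<double>(cfg["fmr_anchor_req"]);
  P.ae = as<double>(cfg["fmr_exponent"]);
  P.ccap = as<int>(cfg["carcass_cap"]);
  P.p_spawn = as<double>(cfg["p_spawn"]);
  P.clo = as<double>(cfg["carcass_mass_min"]);
  P.chi = as<double>(cfg["carcass_mass_max"]);
  P.prey_cmass = as<double>(cfg["prey_carcass_mass"]);
  P.resid = as<double>(cfg["residual_frac"]);
  P.decay = as<double>(cfg["decay_frac"]);
  P.removal = as<double>(cfg["removal_prob"]);
  P.removal_daily = as<std::string>(cfg["removal_mode"]) == "daily";
  P.init_carc = as<int>(cfg["init_carcasses"]);
  P.wiggle = as<double>(cfg["wiggle_deg"]) * M_PI / 180.0;
  P.windows = as<bool>(cfg["spawn_windows"]);
  P.refound = as<bool>(cfg["refound_on_extinction"]);
  P.copy_same = as<bool>(cfg["copy_same"]);
  P.log_ev = as<bool>(cfg["log_events"]);
  {
    NumericVector sc = cfg["trait_scale"], of = cfg["trait_offset"];
    NumericVector lo = cfg["bound_lo"], hi = cfg["bound_hi"];
    NumericMatrix tr = cfg["transition"];
    for (int i = 0; i < 6; ++i) { P.scale[i] = sc[i]; P.offset[i] = of[i]; }
    for (int i = 0; i < 5; ++i) { P.blo[i] = lo[i]; P.bhi[i] = hi[i]; }
    for (int i = 0; i < 5; ++i)
      for (int j = 0; j < 5; ++j)
        P.trans[i * 5 + j] = tr(i, j);
  }

  RNGScope rng;

  Recs R;
  Events EV; EV.on = P.log_ev;
  std::vector<Prey> prey;
  std::vector<Carc> carc;
  std::vector<int> alive;
  int next_prey_id = 0, next_carc_id = 0;

  const int I_DET = 0, I_TF = 1, I_DOM = 2, I_BITE = 3, I_HEAR = 4,
            I_BIN = 5;

  double tot_intake = 0, tot_consumed = 0, tot_decayed = 0,
         tot_residual = 0, tot_spawn_mass = 0;
  long n_births = 0, n_starved = 0, n_kills = 0, n_strikes = 0,
       n_pursuits = 0, n_refound = 0, n_founders = 0;

  int years_total = (P.days + P.dpy - 1) / P.dpy;
  IntegerVector annual_spawns(years_total);
  IntegerMatrix snap_counts(years_total, 30);   // 6 traits x 5 classes
  NumericMatrix snap_abil(years_total, 6);      // ability sums
  NumericVector snap_mass(years_total);
  IntegerVector snap_alive(years_total);

  NumericMatrix daily(P.days, 8);
  // cols: alive, prey, sauropod carc, prey carc, intake, consumed, births,
  //       deaths

  // --- initialization -----------------------------------------------------
  for (int i = 0; i < P.min_prey; ++i) {
    prey.push_back(Prey{next_prey_id++, ru() * P.L, ru() * P.L,
                        ru() * 2.0 * M_PI, -1});
  }
  // the day-0 carrion field is a steady-state snapshot: carcass ages are
  // staggered uniformly over the decay-limited life, so the initial cohort
  // does not expire in unison
  for (int i = 0; i < P.init_carc; ++i) {
    double m = P.clo + ru() * (P.chi - P.clo);
    Carc c0 = make_carcass(P, next_carc_id++, ru() * P.L, ru() * P.L,
                           m, 0, 0);
    double age = ru() * 0.8 * (P.decay > 0 ? (1.0 - P.resid) / P.decay
                                           : 365.0);
    c0.cur = c0.init - P.decay * c0.init * age;
    tot_spawn_mass += c0.cur;       // only the standing mass enters the ledger
    carc.push_back(c0);
  }
  // founders join the standing carrion field (they are residents of the
  // carrion ecology, not randomly teleported starvelings); with no
  // standing carcasses they scatter uniformly
  for (int i = 0; i < P.n0; ++i) {
    double fx, fy;
    if (!carc.empty()) {
      int c = (int)(ru() * carc.size());
      if (c >= (int)carc.size()) c = (int)carc.size() - 1;
      fx = carc[c].x; fy = carc[c].y;
    } else {
      fx = ru() * P.L; fy = ru() * P.L;
    }
    alive.push_back(new_agent(R, P, -1, 0, fx, fy));
    ++n_founders;
  }

  std::vector<int> order;
  struct Strike { int agent; int prey_id; };
  std::vector<Strike> strikes;

  for (int t = 0; t < P.days; ++t) {
    int doy = t % P.dpy;
    int year = t / P.dpy;
    double day_intake = 0, day_consumed = 0;
    int day_births = 0, day_deaths = 0;

    // --- 1 spawn ----------------------------------------------------------
    int sauro_n = 0;
    for (size_t c = 0; c < carc.size(); ++c) {
      if (carc[c].origin == 0) ++sauro_n;
      carc[c].consumed_today = 0;
    }
    if ((!P.windows || in_window(doy, P.dpy)) && sauro_n < P.ccap &&
        ru() < P.p_spawn) {
      double m = P.clo + ru() * (P.chi - P.clo);
      carc.push_back(make_carcass(P, next_carc_id++, ru() * P.L, ru() * P.L,
                                  m, 0, t));
      tot_spawn_mass += m;
      annual_spawns[year] += 1;
      EV.add(t, 1, -1, carc.back().id, m);
    }

    // --- 2 perception + movement ------------------------------------------
    order = alive;
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = (int)(ru() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    strikes.clear();

    for (size_t oi = 0; oi < order.size(); ++oi) {
      int A = order[oi];
      R.at_carc[A] = -1;
      R.intake[A] = 0.0;

      // ongoing pursuit takes precedence (committed chase)
      int pslot = -1;
      if (R.pursuit[A] >= 0) {
        for (size_t p = 0; p < prey.size(); ++p) {
          if (prey[p].id == R.pursuit[A]) { pslot = (int)p; break; }
        }
        if (pslot < 0) { R.pursuit[A] = -1; R.pursuit_days[A] = 0; }
      }

      if (pslot < 0) {
        // perceive: nearest carcass first, else nearest unclaimed prey
        double det = R.abil[(size_t)A * 6 + I_DET];
        double bin = R.abil[(size_t)A * 6 + I_BIN];
        int best = -1;
        double bd = 1e30;
        for (size_t c = 0; c < carc.size(); ++c) {
          double d = tdist(R.x[A], R.y[A], carc[c].x, carc[c].y, P.L);
          if (d < bd) { bd = d; best = (int)c; }
        }
        if (best >= 0 && bd <= det) {
          if (bd <= P.speed) {        // land exactly on the carcass
            R.x[A] = carc[best].x; R.y[A] = carc[best].y;
            R.at_carc[A] = best;
          } else {
            double ux = mimg(carc[best].x - R.x[A], P.L) / bd;
            double uy = mimg(carc[best].y - R.y[A], P.L) / bd;
            R.x[A] = wrapc(R.x[A] + P.speed * ux, P.L);
            R.y[A] = wrapc(R.y[A] + P.speed * uy, P.L);
          }
          continue;
        }
        best = -1; bd = 1e30;
        for (size_t p = 0; p < prey.size(); ++p) {
          if (prey[p].claimed_by >= 0) continue;
          double d = tdist(R.x[A], R.y[A], prey[p].x, prey[p].y, P.L);
          if (d < bd) { bd = d; best = (int)p; }
        }
        if (best >= 0 && bd <= bin) {
          pslot = best;
          prey[pslot].claimed_by = A;
          R.pursuit[A] = prey[pslot].id;
          R.pursuit_days[A] = 0;
          ++n_pursuits;
        } else {
          // correlated random walk: keep the heading, wiggle it a little
          R.heading[A] += (ru() * 2.0 - 1.0) * P.wiggle;
          R.x[A] = wrapc(R.x[A] + P.speed * std::cos(R.heading[A]), P.L);
          R.y[A] = wrapc(R.y[A] + P.speed * std::sin(R.heading[A]), P.L);
          continue;
        }
      }

      // one day of the chase: simultaneous collinear motion, so the gap
      // changes at the relative speed; a strike fires the moment the gap
      // reaches the capture radius
      {
        Prey &pr = prey[pslot];
        R.pursuit_days[A] += 1;
        double gap = tdist(R.x[A], R.y[A], pr.x, pr.y, P.L);
        double ux, uy;
        if (gap > 1e-12) {
          ux = mimg(pr.x - R.x[A], P.L) / gap;
          uy = mimg(pr.y - R.y[A], P.L) / gap;
        } else {
          double th = ru() * 2.0 * M_PI;
          ux = std::cos(th); uy = std::sin(th);
        }
        double hear = R.abil[(size_t)A * 6 + I_HEAR];
        double vf = 1.0 - hear;
        if (vf < 0.3) vf = 0.3;
        if (vf > 1.7) vf = 1.7;
        double vp = P.speed * vf;
        double closing = P.speed - vp;
        if (closing > 0 && gap - closing <= P.capture) {
          double tau = (gap - P.capture) / closing;
          if (tau < 0) tau = 0;
          pr.x = wrapc(pr.x + vp * tau * ux, P.L);
          pr.y = wrapc(pr.y + vp * tau * uy, P.L);
          R.x[A] = wrapc(pr.x - P.capture * ux, P.L);
          R.y[A] = wrapc(pr.y - P.capture * uy, P.L);
          strikes.push_back(Strike{A, pr.id});
        } else {
          pr.x = wrapc(pr.x + vp * ux, P.L);
          pr.y = wrapc(pr.y + vp * uy, P.L);
          R.x[A] = wrapc(R.x[A] + P.speed * ux, P.L);
          R.y[A] = wrapc(R.y[A] + P.speed * uy, P.L);
          double ngap = tdist(R.x[A], R.y[A], pr.x, pr.y, P.L);
          double bin = R.abil[(size_t)A * 6 + I_BIN];
          if (ngap > bin) {                       // lost sight
            EV.add(t, 8, A, pr.id, ngap);
            pr.claimed_by = -1;
            R.pursuit[A] = -1; R.pursuit_days[A] = 0;
          } else if (R.pursuit_days[A] >= P.max_pursuit) {   // gave up
            EV.add(t, 9, A, pr.id, ngap);
            pr.claimed_by = -1;
            R.pursuit[A] = -1; R.pursuit_days[A] = 0;
          }
        }
      }
    }

    // unpursued prey random-walk (same correlated walk)
    for (size_t p = 0; p < prey.size(); ++p) {
      if (prey[p].claimed_by >= 0) continue;
      prey[p].heading += (ru() * 2.0 - 1.0) * P.wiggle;
      prey[p].x = wrapc(prey[p].x + P.speed * std::cos(prey[p].heading), P.L);
      prey[p].y = wrapc(prey[p].y + P.speed * std::sin(prey[p].heading), P.L);
    }

    // --- 3 feeding contests -------------------------------------------------
    {
      std::vector<int> att;
      for (size_t c = 0; c < carc.size(); ++c) {
        att.clear();
        for (size_t oi = 0; oi < order.size(); ++oi) {
          if (R.at_carc[order[oi]] == (int)c) att.push_back(order[oi]);
        }
        if (att.empty()) continue;
        // descending dominance; ties fall back on the daily shuffle order
        std::stable_sort(att.begin(), att.end(), [&](int u, int v) {
          return R.abil[(size_t)u * 6 + I_DOM] >
                 R.abil[(size_t)v * 6 + I_DOM];
        });
        double avail = carc[c].cur - P.resid * carc[c].init;
        for (size_t k = 0; k < att.size() && avail > 0; ++k) {
          int A = att[k];
          double take = R.abil[(size_t)A * 6 + I_TF];
          if (take > avail) take = avail;
          if (take <= 0) break;
          avail -= take;
          carc[c].cur -= take;
          carc[c].consumed_today += take;
          R.intake[A] += take;
          tot_intake += take;
          day_intake += take;
          EV.add(t, 2, A, carc[c].id, take);
        }
        tot_consumed += carc[c].consumed_today;
        day_consumed += carc[c].consumed_today;
      }
    }

    // --- 4 strike resolution ------------------------------------------------
    for (size_t s = 0; s < strikes.size(); ++s) {
      int A = strikes[s].agent;
      int pslot = -1;
      for (size_t p = 0; p < prey.size(); ++p) {
        if (prey[p].id == strikes[s].prey_id) { pslot = (int)p; break; }
      }
      if (pslot < 0) continue;      // defensive; claims are exclusive
      ++n_strikes;
      double bite = R.abil[(size_t)A * 6 + I_BITE];
      if (ru() < bite) {
        ++n_kills;
        Prey pr = prey[pslot];
        carc.push_back(make_carcass(P, next_carc_id++, pr.x, pr.y,
                                    P.prey_cmass, 1, t));
        tot_spawn_mass += P.prey_cmass;
        EV.add(t, 3, A, pr.id, P.prey_cmass);
        prey.erase(prey.begin() + pslot);
        R.pursuit[A] = -1;
        R.pursuit_days[A] = 0;
      } else {
        // the prey escapes only for the rest of the day: the claim holds
        // and the chase resumes tomorrow (strikes repeat until a kill,
        // lost sight, the give-up horizon, or the pursuer starves)
        EV.add(t, 4, A, prey[pslot].id, bite);
        if (R.pursuit_days[A] >= P.max_pursuit) {
          EV.add(t, 9, A, prey[pslot].id, P.capture);
          prey[pslot].claimed_by = -1;
          R.pursuit[A] = -1;
          R.pursuit_days[A] = 0;
        }
      }
    }

    // --- 5 metabolism + starvation ------------------------------------------
    {
      std::vector<int> still;
      still.reserve(alive.size());
      for (size_t k = 0; k < alive.size(); ++k) {
        int A = alive[k];
        double req = P.ar * std::pow(R.mass[A] / P.am, P.ae);
        R.mass[A] += R.intake[A] - req;
        R.mass_sum[A] += R.mass[A];
        R.mass_n[A] += 1;
        if (R.mass[A] > R.max_mass[A]) R.max_mass[A] = R.mass[A];
        if (R.mass[A] < P.floor_mass) {
          R.died[A] = t;
          R.cause[A] = 0;
          R.final_mass[A] = R.mass[A];
          ++n_starved;
          ++day_deaths;
          EV.add(t, 6, A, -1, R.mass[A]);
          if (R.pursuit[A] >= 0) {
            for (size_t p = 0; p < prey.size(); ++p) {
              if (prey[p].id == R.pursuit[A]) {
                prey[p].claimed_by = -1;
                break;
              }
            }
            R.pursuit[A] = -1;
            R.pursuit_days[A] = 0;
          }
        } else {
          still.push_back(A);
        }
      }
      alive.swap(still);
    }

    // --- 6 births -----------------------------------------------------------
    // breeding is condition-gated: only agents at or above the condition
    // floor attempt it, and a successful birth draws down maternal mass
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int A = order[oi];
      if (R.died[A] >= 0) continue;
      if ((int)alive.size() >= P.cap) break;
      if (R.mass[A] < P.birth_min) continue;
      if (ru() < P.birth_p) {
        int kid = new_agent(R, P, A, t, R.x[A], R.y[A]);
        alive.push_back(kid);
        R.offspring[A] += 1;
        R.mass[A] -= P.birth_cost;
        ++n_births;
        ++day_births;
        EV.add(t, 7, kid, A, 0);
      }
    }

    // --- 7 carcass decay / removal --------------------------------------------
    {
      std::vector<Carc> keep;
      keep.reserve(carc.size());
      for (size_t c = 0; c < carc.size(); ++c) {
        double dec = P.decay * carc[c].init;
        if (dec > carc[c].cur) dec = carc[c].cur;
        carc[c].cur -= dec;
        tot_decayed += dec;
        bool removed_random = P.removal_daily
          ? (ru() < P.removal)
          : (carc[c].removal_day >= 0 && t >= carc[c].removal_day);
        if (carc[c].cur < P.resid * carc[c].init) {
          tot_residual += carc[c].cur;
          EV.add(t, 5, 0, carc[c].id, carc[c].cur);
        } else if (removed_random) {
          tot_residual += carc[c].cur;
          EV.add(t, 5, 1, carc[c].id, carc[c].cur);
        } else {
          keep.push_back(carc[c]);
        }
      }
      carc.swap(keep);
    }

    // --- 8 prey replenishment + bookkeeping -----------------------------------
    while ((int)prey.size() < P.min_prey) {
      prey.push_back(Prey{next_prey_id++, ru() * P.L, ru() * P.L,
                          ru() * 2.0 * M_PI, -1});
    }

    // local extinction: a fresh founder cohort immigrates from the
    // regional metapopulation (the landscape is an open window, not a
    // closed universe), joining the standing carrion field
    if (P.refound && alive.empty() && t + 1 < P.days) {
      ++n_refound;
      for (int i = 0; i < P.n0; ++i) {
        double fx, fy;
        if (!carc.empty()) {
          int c = (int)(ru() * carc.size());
          if (c >= (int)carc.size()) c = (int)carc.size() - 1;
          fx = carc[c].x; fy = carc[c].y;
        } else {
          fx = ru() * P.L; fy = ru() * P.L;
        }
        int a = new_agent(R, P, -1, t + 1, fx, fy);
        alive.push_back(a);
        ++n_founders;
        EV.add(t, 10, a, -1, 0);
      }
    }

    int sn = 0, pn = 0;
    for (size_t c = 0; c < carc.size(); ++c) {
      if (carc[c].origin == 0) ++sn; else ++pn;
    }
    daily(t, 0) = (double)alive.size();
    daily(t, 1) = (double)prey.size();
    daily(t, 2) = (double)sn;
    daily(t, 3) = (double)pn;
    daily(t, 4) = day_intake;
    daily(t, 5) = day_consumed;
    daily(t, 6) = (double)day_births;
    daily(t, 7) = (double)day_deaths;

    if (doy == P.dpy - 1) {
      snap_alive[year] = (int)alive.size();
      for (size_t k = 0; k < alive.size(); ++k) {
        int A = alive[k];
        for (int g = 0; g < 6; ++g) {
          snap_counts(year, g * 5 + R.rank[(size_t)A * 6 + g]) += 1;
          snap_abil(year, g) += R.abil[(size_t)A * 6 + g];
        }
        snap_mass[year] += R.mass[A];
      }
    }
  }

  // survivors are censored, not dead
  for (size_t k = 0; k < alive.size(); ++k) {
    int A = alive[k];
    R.cause[A] = 1;
    R.final_mass[A] = R.mass[A];
  }

  double end_carc_mass = 0;
  for (size_t c = 0; c < carc.size(); ++c) end_carc_mass += carc[c].cur;

  int n = R.n();
  NumericMatrix rec(n, 27);
  for (int i = 0; i < n; ++i) {
    rec(i, 0) = i + 1;
    rec(i, 1) = R.parent[i] + 1;           // 0 => founder
    rec(i, 2) = R.born[i];
    rec(i, 3) = R.died[i];                 // -1 => censored
    rec(i, 4) = R.cause[i];                // 0 starved, 1 censored
    rec(i, 5) = R.offspring[i];
    rec(i, 6) = R.final_mass[i];
    rec(i, 7) = R.mass_sum[i] / R.mass_n[i];
    rec(i, 8) = R.max_mass[i];
    for (int g = 0; g < 6; ++g) {
      rec(i, 9 + g) = R.rank[(size_t)i * 6 + g];
      rec(i, 15 + g) = R.fac[(size_t)i * 6 + g];
      rec(i, 21 + g) = R.abil[(size_t)i * 6 + g];
    }
  }

  List counters = List::create(
    _["total_intake"] = tot_intake,
    _["total_consumed"] = tot_consumed,
    _["total_decayed"] = tot_decayed,
    _["total_removed_residual"] = tot_residual,
    _["total_spawned_mass"] = tot_spawn_mass,
    _["standing_carcass_mass"] = end_carc_mass,
    _["births"] = (double)n_births,
    _["starved"] = (double)n_starved,
    _["kills"] = (double)n_kills,
    _["strikes"] = (double)n_strikes,
    _["pursuits"] = (double)n_pursuits,
    _["founders"] = (double)n_founders,
    _["refoundings"] = (double)n_refound);

  List ev = List::create(
    _["day"] = wrap(EV.day), _["type"] = wrap(EV.type),
    _["agent"] = wrap(EV.agent), _["target"] = wrap(EV.target),
    _["value"] = wrap(EV.value));

  return List::create(
    _["records"] = rec,
    _["annual_spawns"] = annual_spawns,
    _["snap_counts"] = snap_counts,
    _["snap_abil"] = snap_abil,
    _["snap_mass"] = snap_mass,
    _["snap_alive"] = snap_alive,
    _["daily"] = daily,
    _["counters"] = counters,
    _["events"] = ev);
}
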