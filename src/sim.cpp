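// Event-driven individual-based foraging simulation core.
//
// The R layer owns configuration, genotype validation and analysis; this file
// owns the hot paths: lattice world construction, the local-neighborhood
// visibility query, and the event scheduler (actions, energetics, demography,
// mutation at birth, lineage and per-year bookkeeping).

#include <Rcpp.h>
#include <queue>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const int A_MOVE = 0, A_SCAN = 1, A_MTF = 2, A_EAT = 3, A_NONE = 4;

// genotype vector layout (shared with R/genotype.R):
// [0] kind (0 restricted, 1 extended)
// [1] t_m  [2] t_fs  [3] d_m  [4] d_fs  [5] a_t  [6] a_fs
// [7] p_mm [8] p_ss  [9] p_se [10] p_sn [11] p_mtf
static const int G_KIND = 0, G_TM = 1, G_TFS = 2, G_DM = 3, G_DFS = 4,
                 G_AT = 5, G_AFS = 6, G_PMM = 7, G_PSS = 8, G_PSE = 9,
                 G_PSN = 10, G_PMTF = 11, NGENE = 12;

struct Geno {
  int kind;
  double t_m, t_fs, d_m, d_fs, a_t, a_fs, p_mm, p_ss, p_se, p_sn, p_mtf;
};

static Geno geno_from_row(const NumericMatrix& m, int i) {
  Geno g;
  g.kind = (int)m(i, G_KIND);
  g.t_m = m(i, G_TM);  g.t_fs = m(i, G_TFS);
  g.d_m = m(i, G_DM);  g.d_fs = m(i, G_DFS);
  g.a_t = m(i, G_AT);  g.a_fs = m(i, G_AFS);
  g.p_mm = m(i, G_PMM); g.p_ss = m(i, G_PSS);
  g.p_se = m(i, G_PSE); g.p_sn = m(i, G_PSN); g.p_mtf = m(i, G_PMTF);
  return g;
}

static void geno_to_vec(const Geno& g, double* out) {
  out[G_KIND] = g.kind;
  out[G_TM] = g.t_m; out[G_TFS] = g.t_fs;
  out[G_DM] = g.d_m; out[G_DFS] = g.d_fs;
  out[G_AT] = g.a_t; out[G_AFS] = g.a_fs;
  out[G_PMM] = g.p_mm; out[G_PSS] = g.p_ss;
  out[G_PSE] = g.p_se; out[G_PSN] = g.p_sn; out[G_PMTF] = g.p_mtf;
}

struct Ind {
  int id, group;
  Geno g;
  double x, y, heading;           // heading in degrees, 0 = +x, CCW
  double E;
  double birth_time, last_update, action_end;
  int cur_action, last_action;
  bool found, in_reach;
  int target;                     // lattice cell index, -1 none
  int eats_year;
  bool alive;
  // patch-visit bookkeeping (reset each calendar year)
  int cur_patch;
  double visit_entry, visit_last_eat, visit_entry_avail;
  double acc_visit_time, acc_travel_time, acc_entry_avail;
  int n_visits, n_travels;
};

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  std::normal_distribution<double> norm{0.0, 1.0};
  explicit Rng(uint64_t seed) : eng(seed) {}
  double u() { return unif(eng); }
  double n() { return norm(eng); }
};

static inline double ang_norm(double a) {
  return a - std::floor(a / 360.0) * 360.0;
}
static inline double ang_diff(double a, double b) {
  // signed difference a-b mapped into [-180, 180)
  double d = a - b + 540.0;
  return d - std::floor(d / 360.0) * 360.0 - 180.0;
}
static const double DEG = M_PI / 180.0;

// detection probability of Eq.-1 form: saturating exponential in
// rate * scan_seconds / area; area == 0 is the co-located limit.
static inline double detect_prob(double scan_s, double area, double rate) {
  if (area <= 0.0) return scan_s > 0 ? 1.0 : 0.0;
  return -std::expm1(-rate * scan_s / area);
}

// ---------------------------------------------------------------------------
// World builders
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_uniform(int side, double density, double year_len, int seed) {
  Rng rng((uint64_t)seed * 2654435761u + 1013904223u);
  std::vector<int> idx;
  std::vector<double> app;
  R_xlen_t ncell = (R_xlen_t)side * side;
  idx.reserve((size_t)(ncell * density * 1.05) + 16);
  for (R_xlen_t c = 0; c < ncell; ++c) {
    if (rng.u() < density) {
      idx.push_back((int)c);
      app.push_back(rng.u() * year_len);
    }
  }
  return List::create(
    _["idx"] = IntegerVector(idx.begin(), idx.end()),
    _["count"] = IntegerVector(idx.size(), idx.empty() ? 0 : 1),
    _["app_time"] = NumericVector(app.begin(), app.end()),
    _["patch_id"] = IntegerVector(idx.size(), NA_INTEGER));
}

// [[Rcpp::export]]
List cpp_build_patchy(int side, int n_patches, double radius,
                      int items_per_cell, double year_len, int seed) {
  Rng rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  R_xlen_t ncell = (R_xlen_t)side * side;
  std::vector<int32_t> owner(ncell, -1);  // first-placed patch claims the cell
  NumericVector cx(n_patches), cy(n_patches), ptime(n_patches);
  IntegerVector pcells(n_patches);
  double hi = side - 1.0;
  int ir = (int)std::ceil(radius);
  for (int p = 0; p < n_patches; ++p) {
    double x0 = rng.u() * hi, y0 = rng.u() * hi;
    cx[p] = x0; cy[p] = y0;
    ptime[p] = rng.u() * year_len;
    int n_claimed = 0;
    int xlo = std::max(0, (int)std::ceil(x0 - radius));
    int xhi = std::min(side - 1, (int)std::floor(x0 + radius));
    (void)ir;
    for (int x = xlo; x <= xhi; ++x) {
      double dx = x - x0;
      double rem = radius * radius - dx * dx;
      if (rem < 0) continue;
      double dy = std::sqrt(rem);
      int ylo = std::max(0, (int)std::ceil(y0 - dy));
      int yhi2 = std::min(side - 1, (int)std::floor(y0 + dy));
      for (int y = ylo; y <= yhi2; ++y) {
        R_xlen_t c = (R_xlen_t)x + (R_xlen_t)side * y;
        if (owner[c] < 0) {
          owner[c] = p;
          ++n_claimed;
        }
      }
    }
    pcells[p] = n_claimed;
  }
  // collect occupied cells
  std::vector<int> idx;
  std::vector<int> pid;
  for (R_xlen_t c = 0; c < ncell; ++c) {
    if (owner[c] >= 0) {
      idx.push_back((int)c);
      pid.push_back(owner[c]);
    }
  }
  IntegerVector count(idx.size(), items_per_cell);
  NumericVector app(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) app[i] = ptime[pid[i]];
  return List::create(
    _["idx"] = IntegerVector(idx.begin(), idx.end()),
    _["count"] = count,
    _["app_time"] = app,
    _["patch_id"] = IntegerVector(pid.begin(), pid.end()),
    _["patch_x"] = cx, _["patch_y"] = cy,
    _["patch_time"] = ptime, _["patch_cells"] = pcells);
}

// ---------------------------------------------------------------------------
// Simulation engine
// ---------------------------------------------------------------------------

struct Engine {
  // world
  int side;
  double year_len;
  std::vector<uint8_t> cnt, init_cnt;
  std::vector<int32_t> patch_of;
  std::vector<int> occ_idx;                 // occupied cells, input order
  std::vector<int> ren_order;               // occupied cells sorted by app time
  std::vector<double> ren_time;
  size_t ren_ptr = 0;
  long long ren_year = 0;
  std::vector<double> patch_avail;
  double avail = 0, consumed = 0, renewed = 0, placed = 0;

  // config
  double reach, half_reach, detect_max, detect_rate;
  double eat_time, mtf_time, speed_cap;     // speed cap in m/min
  double e_item, e_max, e_birth, metab, death_rate, max_age_min;
  double mort_c = 0;                        // log(1 - death_rate) / year_len
  int rescue_floor;
  double mut_rate;
  std::vector<double> mut_sd, mut_lo, mut_hi;

  bool f_births, f_deaths, f_mutation, f_rescue, f_log, f_intake;
  R_xlen_t log_max;

  Rng rb, rd, rm;                           // behavior, demography, mutation

  std::vector<Ind> inds;
  int n_alive = 0;
  bool viable = false, extinct = false;
  int next_id = 1;
  double clock = 0;

  typedef std::pair<double, int> Ev;
  std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev> > q;

  // outputs
  std::vector<int> lin_child, lin_parent, lin_rescue;
  std::vector<double> lin_time;
  std::vector<double> lin_geno;             // NGENE per row
  std::vector<double> sn_year, sn_pop, sn_depl;
  std::vector<double> sn_geno;              // NGENE means per row
  std::vector<int> in_year, in_id, in_group, in_eats, in_nvis, in_ntrav;
  std::vector<double> in_vtime, in_ttime, in_entry;
  std::vector<double> lg_time, lg_x, lg_y, lg_energy, lg_pitems;
  std::vector<int> lg_id, lg_action, lg_ate, lg_cell;

  Engine(int seed_b, int seed_d, int seed_m)
    : rb((uint64_t)seed_b * 0x9E3779B97F4A7C15ULL + 1),
      rd((uint64_t)seed_d * 0x9E3779B97F4A7C15ULL + 2),
      rm((uint64_t)seed_m * 0x9E3779B97F4A7C15ULL + 3) {}

  void load_world(int side_, double year_len_, const IntegerVector& idx,
                  const IntegerVector& count, const NumericVector& app,
                  const IntegerVector& pid, int n_patch) {
    side = side_; year_len = year_len_;
    R_xlen_t ncell = (R_xlen_t)side * side;
    cnt.assign(ncell, 0);
    init_cnt.assign(ncell, 0);
    patch_of.assign(ncell, -1);
    patch_avail.assign(std::max(n_patch, 0), 0.0);
    R_xlen_t n = idx.size();
    occ_idx.assign(idx.begin(), idx.end());
    std::vector<std::pair<double, int> > ord(n);
    for (R_xlen_t i = 0; i < n; ++i) {
      int c = idx[i];
      cnt[c] = (uint8_t)count[i];
      init_cnt[c] = (uint8_t)count[i];
      avail += count[i];
      if (pid[i] != NA_INTEGER && pid[i] >= 0) {
        patch_of[c] = pid[i];
        patch_avail[pid[i]] += count[i];
      }
      ord[i] = std::make_pair(app[i], c);
    }
    placed = avail;
    std::sort(ord.begin(), ord.end());
    ren_order.resize(n);
    ren_time.resize(n);
    for (R_xlen_t i = 0; i < n; ++i) {
      ren_time[i] = ord[i].first;
      ren_order[i] = ord[i].second;
    }
    ren_ptr = 0; ren_year = 0;
  }

  void renew_to(double t_now) {
    if (ren_time.empty()) return;
    while (true) {
      double t_abs = ren_year * year_len + ren_time[ren_ptr];
      if (t_abs > t_now) break;
      int c = ren_order[ren_ptr];
      if (cnt[c] < init_cnt[c]) {
        double add = init_cnt[c] - cnt[c];
        renewed += add;
        avail += add;
        if (patch_of[c] >= 0) patch_avail[patch_of[c]] += add;
        cnt[c] = init_cnt[c];
      }
      if (++ren_ptr == ren_time.size()) { ren_ptr = 0; ++ren_year; }
    }
  }

  double action_duration(const Ind& a, int act) const {
    switch (act) {
      case A_MOVE: {
        double dur = a.g.t_m;
        if (a.g.d_m > speed_cap * dur) dur = a.g.d_m / speed_cap;
        return dur;
      }
      case A_SCAN: return a.g.t_fs;
      case A_MTF:  return mtf_time;
      case A_EAT:  return eat_time;
    }
    return a.g.t_fs;
  }

  void schedule(Ind& a, int act, double now) {
    a.cur_action = act;
    a.action_end = now + action_duration(a, act);
    q.push(std::make_pair(a.action_end, a.id));
  }

  int choose_next(Ind& a) {
    const Geno& g = a.g;
    switch (a.last_action) {
      case A_NONE:
        return A_SCAN;
      case A_MOVE:
        return (rb.u() < g.p_mm) ? A_MOVE : A_SCAN;
      case A_MTF:
        return A_EAT;
      case A_EAT: {
        double pr = g.kind == 0 ? g.p_ss : g.p_se;
        return (rb.u() < pr) ? A_SCAN : A_MOVE;
      }
      case A_SCAN: {
        if (a.found) {
          if (a.in_reach) return A_EAT;
          if (rb.u() < g.p_mtf) return A_MTF;
          // declined approach falls through to the no-food branch
        }
        double pr = g.kind == 0 ? g.p_ss : g.p_sn;
        return (rb.u() < pr) ? A_SCAN : A_MOVE;
      }
    }
    stop("unknown behavioral state");
    return A_SCAN;
  }

  void do_move(Ind& a) {
    double sgn = rb.u() < 0.5 ? -1.0 : 1.0;
    a.heading = ang_norm(a.heading + sgn * a.g.a_t);
    double h = a.heading * DEG;
    double nx = a.x + std::cos(h) * a.g.d_m;
    double ny = a.y + std::sin(h) * a.g.d_m;
    double hi = side - 1.0;
    if (nx < 0 || nx > hi || ny < 0 || ny > hi) {
      nx = std::min(std::max(nx, 0.0), hi);
      ny = std::min(std::max(ny, 0.0), hi);
      a.heading = rb.u() * 360.0;
    }
    a.x = nx; a.y = ny;
  }

  void do_scan(Ind& a) {
    const Geno& g = a.g;
    double R = std::min(g.d_fs, detect_max);
    double area = M_PI * g.d_fs * g.d_fs * g.a_fs / 360.0;
    double p = detect_prob(g.t_fs * 60.0, area, detect_rate);
    a.found = false; a.in_reach = false; a.target = -1;
    if (R < 0) return;
    int xlo = std::max(0, (int)std::ceil(a.x - R));
    int xhi = std::min(side - 1, (int)std::floor(a.x + R));
    double best = R * R + 1.0;
    int best_cell = -1, nties = 0;
    bool full = g.a_fs >= 360.0;
    for (int x = xlo; x <= xhi; ++x) {
      double dx = x - a.x;
      double rem = R * R - dx * dx;
      if (rem < 0) continue;
      double dy = std::sqrt(rem);
      int ylo = std::max(0, (int)std::ceil(a.y - dy));
      int yhi = std::min(side - 1, (int)std::floor(a.y + dy));
      for (int y = ylo; y <= yhi; ++y) {
        R_xlen_t c = (R_xlen_t)x + (R_xlen_t)side * y;
        if (!cnt[c]) continue;
        double ddy = y - a.y;
        double d2 = dx * dx + ddy * ddy;
        if (d2 > R * R + 1e-12) continue;
        if (!full && d2 > 1e-18) {
          double bearing = std::atan2(ddy, dx) / DEG;
          if (std::fabs(ang_diff(bearing, a.heading)) > g.a_fs / 2.0 + 1e-9)
            continue;
        }
        if (p < 1.0 && rb.u() >= p) continue;     // item not detected
        if (d2 < best - 1e-12) {
          best = d2; best_cell = (int)c; nties = 1;
        } else if (d2 <= best + 1e-12) {
          ++nties;
          if (rb.u() < 1.0 / nties) best_cell = (int)c;
        }
      }
    }
    if (best_cell >= 0) {
      a.found = true;
      a.target = best_cell;
      a.in_reach = std::sqrt(best) <= reach + 1e-12;
    }
  }

  void do_mtf(Ind& a) {
    int c = a.target;
    double tx = c % side, ty = c / side;
    double dx = tx - a.x, dy = ty - a.y;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d > half_reach) {
      double f = (d - half_reach) / d;
      a.x += dx * f;
      a.y += dy * f;
      a.heading = ang_norm(std::atan2(dy, dx) / DEG);
    }
    a.in_reach = true;
  }

  // returns 1 if an item was actually consumed
  int do_eat(Ind& a) {
    int c = a.target;
    if (c < 0 || !cnt[c]) {
      // item taken by a competitor during handling: no-food outcome
      a.found = false; a.in_reach = false; a.target = -1;
      return 0;
    }
    --cnt[c];
    --avail;
    ++consumed;
    if (patch_of[c] >= 0) patch_avail[patch_of[c]] -= 1;
    a.E = std::min(a.E + e_item, e_max);
    ++a.eats_year;
    // patch-visit bookkeeping
    int p = patch_of[c];
    if (p >= 0) {
      if (a.cur_patch >= 0 && p != a.cur_patch) {
        a.acc_visit_time += a.visit_last_eat - a.visit_entry;
        ++a.n_visits;
        a.acc_travel_time += clock - a.visit_last_eat;
        ++a.n_travels;
        a.cur_patch = -1;
      }
      if (a.cur_patch < 0) {
        a.cur_patch = p;
        a.visit_entry = clock;
        a.visit_entry_avail = patch_avail[p] + 1;  // including the eaten item
        a.acc_entry_avail += a.visit_entry_avail;
      }
      a.visit_last_eat = clock;
    }
    return 1;
  }

  Geno mutate(const Geno& mother) {
    Geno g = mother;
    double v[NGENE];
    geno_to_vec(g, v);
    for (int k = 1; k < NGENE; ++k) {
      bool evolvable;
      if (g.kind == 0)
        evolvable = (k != G_PSE && k != G_PSN && k != G_PMTF);
      else
        evolvable = (k != G_PSS);
      if (!evolvable) continue;
      if (rm.u() >= mut_rate) continue;
      double nv = v[k] + rm.n() * mut_sd[k];
      if (nv < mut_lo[k]) nv = mut_lo[k];
      if (nv > mut_hi[k]) nv = mut_hi[k];
      v[k] = nv;
    }
    Geno out;
    out.kind = g.kind;
    out.t_m = v[G_TM]; out.t_fs = v[G_TFS];
    out.d_m = v[G_DM]; out.d_fs = v[G_DFS];
    out.a_t = v[G_AT]; out.a_fs = v[G_AFS];
    out.p_mm = v[G_PMM]; out.p_ss = v[G_PSS];
    out.p_se = v[G_PSE]; out.p_sn = v[G_PSN]; out.p_mtf = v[G_PMTF];
    return out;
  }

  void log_lineage(const Ind& child, int parent, int rescue) {
    lin_child.push_back(child.id);
    lin_parent.push_back(parent);
    lin_time.push_back(child.birth_time);
    lin_rescue.push_back(rescue);
    double v[NGENE];
    geno_to_vec(child.g, v);
    for (int k = 0; k < NGENE; ++k) lin_geno.push_back(v[k]);
  }

  Ind& add_ind(const Geno& g, int group, double x, double y, double heading,
               double E, double now) {
    Ind a;
    a.id = next_id++;
    a.group = group;
    a.g = g;
    a.x = x; a.y = y; a.heading = heading;
    a.E = E;
    a.birth_time = now; a.last_update = now;
    a.cur_action = A_NONE; a.last_action = A_NONE;
    a.found = false; a.in_reach = false; a.target = -1;
    a.eats_year = 0; a.alive = true;
    a.cur_patch = -1;
    a.visit_entry = a.visit_last_eat = a.visit_entry_avail = 0;
    a.acc_visit_time = a.acc_travel_time = a.acc_entry_avail = 0;
    a.n_visits = a.n_travels = 0;
    inds.push_back(a);
    ++n_alive;
    if (f_rescue && n_alive >= 2 * rescue_floor) viable = true;
    return inds.back();
  }

  void birth(Ind& mother, double now, int rescue) {
    mother.E *= 0.5;
    Geno g = f_mutation ? mutate(mother.g) : mother.g;
    double mx = mother.x, my = mother.y, mE = mother.E;
    // rescue offspring get the standard endowment regardless of the mother's
    // (possibly empty) store: the rescue rule exists to keep a non-viable
    // founder population alive, which pure halving cannot do once stores run
    // dry. Ordinary births transfer the halved store as specified.
    double cE = rescue ? e_birth * 0.5 : mE;
    int mid = mother.id, mgrp = mother.group;
    Ind& child = add_ind(g, mgrp, mx, my, rd.u() * 360.0, cE, now);
    log_lineage(child, mid, rescue);
    schedule(child, A_SCAN, now);
  }

  void rescue_check(double now) {
    if (!f_rescue || viable) return;
    while (n_alive > 0 && n_alive < rescue_floor) {
      double tot = 0;
      for (size_t i = 0; i < inds.size(); ++i)
        if (inds[i].alive) tot += std::max(inds[i].E, 0.0);
      int pick = -1;
      if (tot > 0) {
        double r = rd.u() * tot, cum = 0;
        for (size_t i = 0; i < inds.size(); ++i) {
          if (!inds[i].alive) continue;
          cum += std::max(inds[i].E, 0.0);
          if (r <= cum) { pick = (int)i; break; }
        }
        if (pick < 0) {  // numeric edge
          for (size_t i = inds.size(); i-- > 0;)
            if (inds[i].alive) { pick = (int)i; break; }
        }
      } else {
        int nth = (int)(rd.u() * n_alive), seen = 0;
        for (size_t i = 0; i < inds.size(); ++i) {
          if (!inds[i].alive) continue;
          if (seen++ == nth) { pick = (int)i; break; }
        }
      }
      birth(inds[pick], now, 1);
    }
  }

  void year_end(int year) {
    double gm[NGENE];
    for (int k = 0; k < NGENE; ++k) gm[k] = 0;
    int np = 0;
    for (size_t i = 0; i < inds.size(); ++i) {
      Ind& a = inds[i];
      if (!a.alive) continue;
      ++np;
      double v[NGENE];
      geno_to_vec(a.g, v);
      for (int k = 0; k < NGENE; ++k) gm[k] += v[k];
      if (f_intake) {
        // close any open visit at the year boundary
        double vt = a.acc_visit_time, nv = a.n_visits;
        if (a.cur_patch >= 0) {
          vt += a.visit_last_eat - a.visit_entry;
          nv += 1;
        }
        in_year.push_back(year);
        in_id.push_back(a.id);
        in_group.push_back(a.group);
        in_eats.push_back(a.eats_year);
        in_nvis.push_back((int)nv);
        in_vtime.push_back(vt);
        in_ntrav.push_back(a.n_travels);
        in_ttime.push_back(a.acc_travel_time);
        in_entry.push_back(a.acc_entry_avail);
      }
      a.eats_year = 0;
      a.cur_patch = -1;
      a.acc_visit_time = a.acc_travel_time = a.acc_entry_avail = 0;
      a.n_visits = a.n_travels = 0;
    }
    sn_year.push_back(year);
    sn_pop.push_back(np);
    sn_depl.push_back(avail / ((double)side * side));
    for (int k = 0; k < NGENE; ++k)
      sn_geno.push_back(np > 0 ? gm[k] / np : NA_REAL);
  }

  void log_event(const Ind& a, int action, int ate, int cell) {
    if (!f_log || (R_xlen_t)lg_time.size() >= log_max) return;
    lg_time.push_back(clock);
    lg_id.push_back(a.id);
    lg_action.push_back(action);
    lg_x.push_back(a.x);
    lg_y.push_back(a.y);
    lg_ate.push_back(ate);
    lg_energy.push_back(a.E);
    lg_cell.push_back(cell);
    lg_pitems.push_back(cell >= 0 && patch_of[cell] >= 0
                          ? patch_avail[patch_of[cell]] + ate : NA_REAL);
  }

  void run(double t_stop) {
    long long year = (long long)std::floor(clock / year_len);
    double next_year = (year + 1) * year_len;
    rescue_check(clock);
    while (!q.empty()) {
      Ev ev = q.top();
      double t = ev.first;
      if (t > t_stop) { clock = t_stop; break; }
      q.pop();
      int ai = ev.second - 1;  // ids are contiguous, 1-based
      if (!inds[ai].alive || inds[ai].action_end != t) continue;  // stale
      Ind& a = inds[ai];
      while (t >= next_year) {
        year_end((int)(year + 1));
        ++year;
        next_year = (year + 1) * year_len;
      }
      clock = t;
      renew_to(t);
      // metabolism since the individual's last event (exact: constant rate)
      double dt = t - a.last_update;
      a.E -= metab * dt;
      a.last_update = t;
      if (f_deaths) {
        bool dead = false;
        if (a.E <= 0) dead = true;
        else if (t - a.birth_time >= max_age_min) dead = true;
        else if (death_rate > 0 && rd.u() < -std::expm1(mort_c * dt))
          dead = true;
        if (dead) {
          a.alive = false;
          --n_alive;
          rescue_check(t);
          if (n_alive == 0) { extinct = true; break; }
          continue;
        }
      } else if (a.E < 0) {
        a.E = 0;  // demography disabled: energy is bookkeeping only
      }
      // apply the completed action's effect
      int ate = 0, eat_cell = -1;
      switch (a.cur_action) {
        case A_MOVE: do_move(a); break;
        case A_SCAN: do_scan(a); break;
        case A_MTF:  do_mtf(a);  break;
        case A_EAT:
          eat_cell = a.target;
          ate = do_eat(a);
          break;
        case A_NONE: break;
      }
      int completed = a.cur_action;
      a.last_action = completed;
      if (completed == A_EAT) {
        if (!ate) a.last_action = A_SCAN;  // failed EAT == no-food outcome
        a.target = -1;
        if (ate) { a.found = false; a.in_reach = false; }
      }
      log_event(a, completed, ate, ate ? eat_cell : -1);
      if (f_births && a.E >= e_birth) birth(a, t, 0);
      // re-fetch: birth() may have reallocated the individual vector
      Ind& a2 = inds[ai];
      schedule(a2, choose_next(a2), t);
    }
    if (q.empty() && n_alive == 0) extinct = true;
    if (!extinct && clock < t_stop) clock = t_stop;
    // flush year boundaries reached by the stop time itself
    while (!extinct && (year + 1) * year_len <= t_stop * (1 + 1e-12)) {
      year_end((int)(year + 1));
      ++year;
    }
  }
};

// [[Rcpp::export]]
List cpp_run_sim(List world, List cfg, NumericMatrix genotypes,
                 IntegerVector groups, NumericVector energy0,
                 NumericVector x0, NumericVector y0, NumericVector h0,
                 double t_stop, List flags, IntegerVector seeds) {
  Engine eng(seeds[0], seeds[1], seeds[2]);

  int side = as<int>(world["side"]);
  double year_len = as<double>(cfg["year_len"]);
  IntegerVector widx = world["idx"], wcount = world["count"],
                wpid = world["patch_id"];
  NumericVector wapp = world["app_time"];
  int n_patch = as<int>(world["n_patches"]);
  eng.load_world(side, year_len, widx, wcount, wapp, wpid, n_patch);

  eng.reach = as<double>(cfg["reach"]);
  eng.half_reach = as<double>(cfg["approach_stop"]);
  eng.detect_max = as<double>(cfg["detect_max"]);
  eng.detect_rate = as<double>(cfg["detect_rate"]);
  eng.eat_time = as<double>(cfg["eat_time"]);
  eng.mtf_time = as<double>(cfg["mtf_time"]);
  eng.speed_cap = as<double>(cfg["speed_cap"]);
  eng.e_item = as<double>(cfg["energy_per_item"]);
  eng.e_max = as<double>(cfg["e_max"]);
  eng.e_birth = as<double>(cfg["e_birth"]);
  eng.metab = as<double>(cfg["metabolism"]);
  eng.death_rate = as<double>(cfg["death_rate"]);
  if (eng.death_rate > 0 && eng.death_rate < 1)
    eng.mort_c = std::log1p(-eng.death_rate) / year_len;
  eng.max_age_min = as<double>(cfg["max_age_years"]) * year_len;
  eng.rescue_floor = as<int>(cfg["rescue_floor"]);
  eng.mut_rate = as<double>(cfg["mut_rate"]);
  NumericVector msd = cfg["mut_sd"], mlo = cfg["mut_lo"], mhi = cfg["mut_hi"];
  eng.mut_sd.assign(msd.begin(), msd.end());
  eng.mut_lo.assign(mlo.begin(), mlo.end());
  eng.mut_hi.assign(mhi.begin(), mhi.end());

  eng.f_births = as<bool>(flags["births"]);
  eng.f_deaths = as<bool>(flags["deaths"]);
  eng.f_mutation = as<bool>(flags["mutation"]);
  eng.f_rescue = as<bool>(flags["rescue"]);
  eng.f_log = as<bool>(flags["log_trajectory"]);
  eng.f_intake = as<bool>(flags["record_intake"]);
  eng.log_max = as<double>(flags["log_max"]);

  int n0 = genotypes.nrow();
  double hi = side - 1.0;
  for (int i = 0; i < n0; ++i) {
    Geno g = geno_from_row(genotypes, i);
    double x = NumericVector::is_na(x0[i]) ? eng.rd.u() * hi : x0[i];
    double y = NumericVector::is_na(y0[i]) ? eng.rd.u() * hi : y0[i];
    double h = NumericVector::is_na(h0[i]) ? eng.rd.u() * 360.0 : h0[i];
    Ind& a = eng.add_ind(g, groups[i], x, y, h, energy0[i], 0.0);
    eng.log_lineage(a, NA_INTEGER, 0);
    eng.schedule(a, A_SCAN, 0.0);
  }

  eng.run(t_stop);

  // population table
  int n = (int)eng.inds.size();
  IntegerVector p_id(n), p_group(n), p_alive(n);
  NumericVector p_x(n), p_y(n), p_head(n), p_E(n), p_btime(n);
  NumericMatrix p_geno(n, NGENE);
  for (int i = 0; i < n; ++i) {
    const Ind& a = eng.inds[i];
    p_id[i] = a.id; p_group[i] = a.group; p_alive[i] = a.alive ? 1 : 0;
    p_x[i] = a.x; p_y[i] = a.y; p_head[i] = a.heading;
    p_E[i] = a.E; p_btime[i] = a.birth_time;
    double v[NGENE];
    geno_to_vec(a.g, v);
    for (int k = 0; k < NGENE; ++k) p_geno(i, k) = v[k];
  }

  int nl = (int)eng.lin_child.size();
  NumericMatrix l_geno(nl, NGENE);
  for (int i = 0; i < nl; ++i)
    for (int k = 0; k < NGENE; ++k) l_geno(i, k) = eng.lin_geno[(size_t)i * NGENE + k];

  int ns = (int)eng.sn_year.size();
  NumericMatrix s_geno(ns, NGENE);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < NGENE; ++k) s_geno(i, k) = eng.sn_geno[(size_t)i * NGENE + k];

  // final counts aligned with the input cell order
  IntegerVector fin(eng.occ_idx.size());
  for (size_t i = 0; i < eng.occ_idx.size(); ++i)
    fin[i] = eng.cnt[eng.occ_idx[i]];

  return List::create(
    _["population"] = List::create(
      _["id"] = p_id, _["group"] = p_group, _["alive"] = p_alive,
      _["x"] = p_x, _["y"] = p_y, _["heading"] = p_head,
      _["energy"] = p_E, _["birth_time"] = p_btime, _["genotype"] = p_geno),
    _["lineage"] = List::create(
      _["child_id"] = IntegerVector(eng.lin_child.begin(), eng.lin_child.end()),
      _["parent_id"] = IntegerVector(eng.lin_parent.begin(), eng.lin_parent.end()),
      _["birth_time"] = NumericVector(eng.lin_time.begin(), eng.lin_time.end()),
      _["rescue"] = IntegerVector(eng.lin_rescue.begin(), eng.lin_rescue.end()),
      _["genotype"] = l_geno),
    _["snapshots"] = List::create(
      _["year"] = NumericVector(eng.sn_year.begin(), eng.sn_year.end()),
      _["pop"] = NumericVector(eng.sn_pop.begin(), eng.sn_pop.end()),
      _["depletion"] = NumericVector(eng.sn_depl.begin(), eng.sn_depl.end()),
      _["genotype"] = s_geno),
    _["intake"] = List::create(
      _["year"] = IntegerVector(eng.in_year.begin(), eng.in_year.end()),
      _["id"] = IntegerVector(eng.in_id.begin(), eng.in_id.end()),
      _["group"] = IntegerVector(eng.in_group.begin(), eng.in_group.end()),
      _["eats"] = IntegerVector(eng.in_eats.begin(), eng.in_eats.end()),
      _["n_visits"] = IntegerVector(eng.in_nvis.begin(), eng.in_nvis.end()),
      _["visit_time"] = NumericVector(eng.in_vtime.begin(), eng.in_vtime.end()),
      _["n_travels"] = IntegerVector(eng.in_ntrav.begin(), eng.in_ntrav.end()),
      _["travel_time"] = NumericVector(eng.in_ttime.begin(), eng.in_ttime.end()),
      _["entry_items"] = NumericVector(eng.in_entry.begin(), eng.in_entry.end())),
    _["trajectory"] = List::create(
      _["time_min"] = NumericVector(eng.lg_time.begin(), eng.lg_time.end()),
      _["id"] = IntegerVector(eng.lg_id.begin(), eng.lg_id.end()),
      _["action"] = IntegerVector(eng.lg_action.begin(), eng.lg_action.end()),
      _["x"] = NumericVector(eng.lg_x.begin(), eng.lg_x.end()),
      _["y"] = NumericVector(eng.lg_y.begin(), eng.lg_y.end()),
      _["ate"] = IntegerVector(eng.lg_ate.begin(), eng.lg_ate.end()),
      _["energy"] = NumericVector(eng.lg_energy.begin(), eng.lg_energy.end()),
      _["cell"] = IntegerVector(eng.lg_cell.begin(), eng.lg_cell.end()),
      _["patch_items"] = NumericVector(eng.lg_pitems.begin(), eng.lg_pitems.end())),
    _["final_count"] = fin,
    _["counters"] = List::create(
      _["placed"] = eng.placed, _["consumed"] = eng.consumed,
      _["renewed"] = eng.renewed, _["available"] = eng.avail),
    _["clock"] = eng.clock,
    _["extinct"] = eng.extinct,
    _["viable"] = eng.viable,
    _["n_alive"] = eng.n_alive);
}
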