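// Lattice agent-based crypt simulator.
//
// Coordinates are 0-based: column x in [0, n_cols), row y in [0, n_rows),
// row 0 is the stem-cell niche, row n_rows-1 the luminal (top) row.
// Columns wrap (the crypt is a cylinder slit open and laid flat).
// All durations are held as integer multiples of the time step dt.
//
// Randomness comes exclusively from R's RNG stream (unif_rand), so a run is
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

enum CellState { ST_Q = 0, ST_G1 = 1, ST_SG2 = 2, ST_MIT = 3 };
enum DivType { DIV_ASYM = 0, DIV_SYM_DIFF = 1, DIV_SYM_SELF = 2 };

struct Cell {
  int x, y;
  int state;
  int t_state;   // steps spent in current state
  int age;       // steps since birth
  int ndiv;      // completed mitoses
  int k;         // stemness numerator; stemness = k / kmax, stem iff k == kmax
  int ancestor;  // founding stem lineage (0-based)
  int alleles;   // number of mutated APC alleles (0, 1 or 2)
  bool alive;
};

struct Timing {
  int tg1, tsg2;  // steps in G1 and in S+G2 before transition
};

struct Params {
  int n_cols, n_rows, n0, kmax;
  Timing stem, transit, het_stem, het_transit;
  double ps, bias;
  double het_ps, het_bias;       // NA -> inherit base value
  int mode;                      // 0 normal, 1 FAP, 2 sporadic
  double mu;                     // second-hit probability per daughter per division
  int hit_scope;                 // 0 stem-only, 1 any cell
  int max_iter, guard;
  bool stop_succession, stop_second_hit, record_trace;
  int ns_feedback;               // 0: stem-cell count, 1: niche-row occupancy
};

struct World {
  Params p;
  std::vector<Cell> cells;
  std::vector<int> free_slots;
  // occ[x * n_rows + y] -> indices of resident cells
  std::vector< std::vector<int> > occ;
  long long n_shed, n_born;

  int site(int x, int y) const { return x * p.n_rows + y; }

  void init_grid() {
    occ.assign((size_t)p.n_cols * p.n_rows, std::vector<int>());
    n_shed = n_born = 0;
  }

  int add_cell(const Cell& c) {
    int idx;
    if (!free_slots.empty()) {
      idx = free_slots.back();
      free_slots.pop_back();
      cells[idx] = c;
    } else {
      idx = (int)cells.size();
      cells.push_back(c);
    }
    occ[site(c.x, c.y)].push_back(idx);
    return idx;
  }

  void remove_from_site(int idx, int x, int y) {
    std::vector<int>& v = occ[site(x, y)];
    v.erase(std::remove(v.begin(), v.end(), idx), v.end());
  }

  void kill(int idx) {
    cells[idx].alive = false;
    free_slots.push_back(idx);
  }

  bool is_stem(const Cell& c) const { return c.k == p.kmax; }

  bool site_empty(int x, int y) const { return occ[site(x, y)].empty(); }
};

static inline double runif01() { return unif_rand(); }

// uniform integer in [0, n)
static inline int rint(int n) {
  int v = (int)(runif01() * n);
  return v >= n ? n - 1 : v;
}

static inline double clip01(double v) {
  if (v < 0) return 0;
  if (v > 1) return 1;
  return v;
}

// Insertion-site choice for a newly created daughter (§ rules: empty north,
// empty east/west, empty south, then occupied north/east/west).  Stem
// daughters go east or west only, so they never leave the niche row.
static void choose_site(const World& w, int mx, int my, bool stem_daughter,
                        int& ox, int& oy) {
  const int N = w.p.n_cols;
  int east = (mx + 1) % N;
  int west = (mx - 1 + N) % N;
  if (stem_daughter) {
    ox = (runif01() < 0.5) ? east : west;
    oy = my;  // my == 0 for a stem mother
    return;
  }
  bool has_north = my + 1 < w.p.n_rows;
  if (has_north && w.site_empty(mx, my + 1)) { ox = mx; oy = my + 1; return; }
  bool ee = w.site_empty(east, my), we = w.site_empty(west, my);
  if (ee && we) { ox = (runif01() < 0.5) ? east : west; oy = my; return; }
  if (ee) { ox = east; oy = my; return; }
  if (we) { ox = west; oy = my; return; }
  if (my > 0 && w.site_empty(mx, my - 1)) { ox = mx; oy = my - 1; return; }
  // all candidate neighbours occupied: uniform over {north, east, west}
  int cx[3], cy[3], n = 0;
  if (has_north) { cx[n] = mx; cy[n] = my + 1; n++; }
  cx[n] = east; cy[n] = my; n++;
  cx[n] = west; cy[n] = my; n++;
  int pick = rint(n);
  ox = cx[pick]; oy = cy[pick];
}

// Push the whole column of cells in column x strictly above row y up by one
// grid space; cells pushed beyond the top row are shed.
static void push_column_above(World& w, int x, int y) {
  for (int yy = w.p.n_rows - 1; yy > y; --yy) {
    std::vector<int> movers = w.occ[w.site(x, yy)];
    for (size_t i = 0; i < movers.size(); ++i) {
      int idx = movers[i];
      w.remove_from_site(idx, x, yy);
      if (yy + 1 >= w.p.n_rows) {
        w.kill(idx);
        w.n_shed++;
      } else {
        w.cells[idx].y = yy + 1;
        w.occ[w.site(x, yy + 1)].push_back(idx);
      }
    }
  }
}

// Mitotic-pressure migration: wherever a site holds more than one cell, the
// oldest (non-stem) resident moves up one row, pushing the column above it.
// Ties in age break uniformly at random.  Stem cells are never displaced, so
// a niche site may stay multi-occupied when all its residents are stem cells.
static void migrate(World& w) {
  for (int x = 0; x < w.p.n_cols; ++x) {
    int y = 0;
    while (y < w.p.n_rows) {
      std::vector<int>& res = w.occ[w.site(x, y)];
      if (res.size() <= 1) { y++; continue; }
      // candidate movers: non-stem residents only
      int best_age = -1;
      std::vector<int> tied;
      for (size_t i = 0; i < res.size(); ++i) {
        const Cell& c = w.cells[res[i]];
        if (w.is_stem(c)) continue;
        if (c.age > best_age) { best_age = c.age; tied.clear(); tied.push_back(res[i]); }
        else if (c.age == best_age) tied.push_back(res[i]);
      }
      if (tied.empty()) { y++; continue; }  // all residents are stem cells
      int mover = tied.size() == 1 ? tied[0] : tied[rint((int)tied.size())];
      push_column_above(w, x, y);
      w.remove_from_site(mover, x, y);
      if (y + 1 >= w.p.n_rows) {
        w.kill(mover);
        w.n_shed++;
      } else {
        w.cells[mover].y = y + 1;
        w.occ[w.site(x, y + 1)].push_back(mover);
      }
      // re-examine the same site: it may still be multi-occupied
    }
  }
}

static Timing timing_for(const World& w, const Cell& c) {
  bool het = (c.alleles == 1) && (w.p.mode != 0);
  if (w.is_stem(c)) return het ? w.p.het_stem : w.p.stem;
  return het ? w.p.het_transit : w.p.transit;
}

// One application of the cell-cycle state machine (a single rule per step).
// Returns true when the cell has just entered mitosis (divides this step).
static bool step_cycle(World& w, Cell& c) {
  c.age++;
  Timing tm = timing_for(w, c);
  switch (c.state) {
  case ST_Q:
    if (c.k > 0) { c.state = ST_G1; c.t_state = 0; }
    return false;
  case ST_G1:
    if (c.t_state >= tm.tg1) { c.state = ST_SG2; c.t_state = 0; }
    else c.t_state++;
    return false;
  case ST_SG2:
    if (c.t_state >= tm.tsg2) { c.state = ST_MIT; c.t_state = 0; return true; }
    c.t_state++;
    return false;
  case ST_MIT:
    // unreachable: mitosis resolves within the step it is entered
    return true;
  default:
    stop("invalid cell state");
  }
  return false;
}

struct HitRecord {
  int iter_any, iter_stem;  // first second-hit iteration, -1 if none yet
  HitRecord() : iter_any(-1), iter_stem(-1) {}
};

static void maybe_second_hit(World& w, Cell& c, int iter, HitRecord& hits) {
  if (w.p.mu <= 0 || c.alleles != 1) return;
  if (runif01() < w.p.mu) {
    c.alleles = 2;
    if (hits.iter_any < 0) hits.iter_any = iter;
    if (w.is_stem(c) && hits.iter_stem < 0) hits.iter_stem = iter;
  }
}

// Execute one division.  The mother agent persists as one of the two
// products; the other product is a freshly created agent.  Both products
// re-enter the cycle as quiescent cells and both receive an independent
// second-hit draw on an inherited heterozygous genotype.
static void divide(World& w, int midx, int ns_feedback_count, int iter,
                   HitRecord& hits) {
  Cell& m0 = w.cells[midx];
  int inherited = m0.alleles;
  int div_type;
  if (w.is_stem(m0)) {
    bool het = (m0.alleles == 1) && (w.p.mode != 0);
    double ps = (het && !ISNAN(w.p.het_ps)) ? w.p.het_ps : w.p.ps;
    double bias = (het && !ISNAN(w.p.het_bias)) ? w.p.het_bias : w.p.bias;
    double pd = clip01(bias * clip01((double)ns_feedback_count / w.p.n0 - 0.5));
    if (runif01() < ps) div_type = (runif01() < pd) ? DIV_SYM_DIFF : DIV_SYM_SELF;
    else div_type = DIV_ASYM;
  } else {
    if (m0.k <= 0) stop("terminally differentiated cell cannot divide");
    div_type = DIV_SYM_DIFF;  // transit divisions always differentiate
  }

  Cell d;
  d.state = ST_Q; d.t_state = 0; d.age = 0; d.ndiv = 0;
  d.ancestor = m0.ancestor; d.alleles = inherited; d.alive = true;

  bool stem_daughter;
  if (w.is_stem(m0)) {
    switch (div_type) {
    case DIV_ASYM:     d.k = w.p.kmax - 1; stem_daughter = false; break;
    case DIV_SYM_SELF: d.k = w.p.kmax;     stem_daughter = true;  break;
    default:           d.k = w.p.kmax - 1; stem_daughter = false;
                       m0.k = w.p.kmax - 1; break;  // SYM_DIFF
    }
  } else {
    m0.k -= 1;
    d.k = m0.k;
    stem_daughter = false;
  }
  m0.state = ST_Q; m0.t_state = 0; m0.ndiv++;

  int dx, dy;
  choose_site(w, m0.x, m0.y, stem_daughter, dx, dy);
  d.x = dx; d.y = dy;
  int didx = w.add_cell(d);
  w.n_born++;

  maybe_second_hit(w, w.cells[midx], iter, hits);
  maybe_second_hit(w, w.cells[didx], iter, hits);
}

static List cells_to_df(const World& w, double dt) {
  int n = 0;
  for (size_t i = 0; i < w.cells.size(); ++i) if (w.cells[i].alive) n++;
  IntegerVector x(n), y(n), state(n), ndiv(n), ancestor(n), alleles(n);
  NumericVector t_state(n), age(n), stemness(n);
  int j = 0;
  for (size_t i = 0; i < w.cells.size(); ++i) {
    const Cell& c = w.cells[i];
    if (!c.alive) continue;
    x[j] = c.x; y[j] = c.y; state[j] = c.state;
    t_state[j] = c.t_state * dt; age[j] = c.age * dt;
    ndiv[j] = c.ndiv; stemness[j] = (double)c.k / w.p.kmax;
    ancestor[j] = c.ancestor; alleles[j] = c.alleles;
    j++;
  }
  List df = List::create(
    _["x"] = x, _["y"] = y, _["state"] = state, _["time_in_state"] = t_state,
    _["age"] = age, _["num_divisions"] = ndiv, _["stemness"] = stemness,
    _["ancestor"] = ancestor, _["apc_alleles"] = alleles);
  df.attr("class") = "data.frame";
  df.attr("row.names") = IntegerVector::create(NA_INTEGER, -n);
  return df;
}

static Params unpack_params(List par) {
  Params p;
  p.n_cols = as<int>(par["n_cols"]);
  p.n_rows = as<int>(par["n_rows"]);
  p.n0 = as<int>(par["n0"]);
  p.kmax = as<int>(par["num_div_max"]);
  p.stem.tg1 = as<int>(par["tg1_stem_steps"]);
  p.stem.tsg2 = as<int>(par["tsg2_stem_steps"]);
  p.transit.tg1 = as<int>(par["tg1_transit_steps"]);
  p.transit.tsg2 = as<int>(par["tsg2_transit_steps"]);
  p.het_stem.tg1 = as<int>(par["het_tg1_stem_steps"]);
  p.het_stem.tsg2 = as<int>(par["het_tsg2_stem_steps"]);
  p.het_transit.tg1 = as<int>(par["het_tg1_transit_steps"]);
  p.het_transit.tsg2 = as<int>(par["het_tsg2_transit_steps"]);
  p.ps = as<double>(par["ps"]);
  p.bias = as<double>(par["bias"]);
  p.het_ps = as<double>(par["het_ps"]);
  p.het_bias = as<double>(par["het_bias"]);
  p.mode = as<int>(par["mode"]);
  p.mu = as<double>(par["mutation_prob"]);
  p.hit_scope = as<int>(par["hit_scope"]);
  p.max_iter = as<int>(par["max_iterations"]);
  p.guard = as<int>(par["max_stem_cells"]);
  p.stop_succession = as<bool>(par["stop_on_succession"]);
  p.stop_second_hit = as<bool>(par["stop_on_second_hit"]);
  p.record_trace = as<bool>(par["record_trace"]);
  p.ns_feedback = as<int>(par["ns_feedback"]);
  return p;
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List par, double dt) {
  World w;
  w.p = unpack_params(par);
  const Params& p = w.p;
  w.init_grid();

  // initial stem cells: one per niche column, all in G1 with a random
  // already-elapsed phase so divisions are asynchronous from the start
  for (int i = 0; i < p.n0; ++i) {
    Cell c;
    c.x = i; c.y = 0; c.state = ST_G1;
    c.t_state = rint(p.stem.tg1);
    c.age = 0; c.ndiv = 0; c.k = p.kmax; c.ancestor = i;
    c.alleles = (p.mode == 1) ? 1 : 0;
    c.alive = true;
    w.add_cell(c);
  }
  int marked = -1;
  if (p.mode == 2) {  // sporadic: one seed-chosen heterozygous stem cell
    marked = rint(p.n0);
    w.cells[marked].alleles = 1;
  }

  std::vector<int> live;
  for (size_t i = 0; i < w.cells.size(); ++i) live.push_back((int)i);

  std::vector<int> ns_series, occ_series, pop_series, born_series, shed_series;
  std::vector<int> anc_series;  // row-major per iteration if record_trace
  std::vector<int> anc_count(p.n0);

  HitRecord hits;
  int succession_iter = -1, winner = -1;
  int stop_reason = 0;  // 0 max_iter, 1 succession, 2 second hit, 3 overflow, 4 extinction
  int iter = 0;

  // a single founding lineage is already monoclonal at iteration 0
  {
    int alive0 = 0;
    std::fill(anc_count.begin(), anc_count.end(), 0);
    for (size_t i = 0; i < live.size(); ++i)
      if (w.cells[live[i]].k == p.kmax) anc_count[w.cells[live[i]].ancestor]++;
    for (int a = 0; a < p.n0; ++a)
      if (anc_count[a] > 0) { alive0++; winner = a; }
    if (alive0 == 1) {
      succession_iter = 0;
      if (p.stop_succession) stop_reason = 1;
    } else winner = -1;
  }

  std::vector<int> mothers;
  while (stop_reason != 1 && iter < p.max_iter) {
    iter++;
    // start-of-iteration census feeding the differentiation correction
    int ns = 0, nocc = 0;
    for (size_t i = 0; i < live.size(); ++i) {
      const Cell& c = w.cells[live[i]];
      if (c.k == p.kmax) ns++;
      if (c.y == 0) nocc++;
    }
    int ns_fb = (p.ns_feedback == 1) ? nocc : ns;

    long long born_before = w.n_born, shed_before = w.n_shed;

    // 1. synchronous cell-cycle pass on the start-of-step population
    mothers.clear();
    for (size_t i = 0; i < live.size(); ++i) {
      int idx = live[i];
      if (step_cycle(w, w.cells[idx])) mothers.push_back(idx);
    }
    // 2. commit divisions in a seeded random order
    for (int i = (int)mothers.size() - 1; i > 0; --i) {
      int j = rint(i + 1);
      std::swap(mothers[i], mothers[j]);
    }
    for (size_t i = 0; i < mothers.size(); ++i)
      divide(w, mothers[i], ns_fb, iter, hits);
    // 3. migration and shedding
    migrate(w);

    // refresh live list
    std::vector<int> live2;
    live2.reserve(live.size() + mothers.size());
    for (size_t i = 0; i < w.cells.size(); ++i)
      if (w.cells[i].alive) live2.push_back((int)i);
    live.swap(live2);

    // post-commit census
    std::fill(anc_count.begin(), anc_count.end(), 0);
    int ns_post = 0, nocc_post = 0;
    for (size_t i = 0; i < live.size(); ++i) {
      const Cell& c = w.cells[live[i]];
      if (c.k == p.kmax) { ns_post++; anc_count[c.ancestor]++; }
      if (c.y == 0) nocc_post++;
    }
    ns_series.push_back(ns_post);
    occ_series.push_back(nocc_post);
    pop_series.push_back((int)live.size());
    born_series.push_back((int)(w.n_born - born_before));
    shed_series.push_back((int)(w.n_shed - shed_before));
    if (p.record_trace)
      anc_series.insert(anc_series.end(), anc_count.begin(), anc_count.end());

    int alive_lineages = 0, last_anc = -1;
    for (int a = 0; a < p.n0; ++a)
      if (anc_count[a] > 0) { alive_lineages++; last_anc = a; }

    if (ns_post == 0) { stop_reason = 4; break; }
    if (ns_post > p.guard) { stop_reason = 3; break; }
    if (alive_lineages == 1 && succession_iter < 0) {
      succession_iter = iter;
      winner = last_anc;
      if (p.stop_succession) { stop_reason = 1; break; }
    }
    int hit_iter = (p.hit_scope == 0) ? hits.iter_stem : hits.iter_any;
    if (p.stop_second_hit && hit_iter >= 0) { stop_reason = 2; break; }
    if ((int)live.size() > 100 * p.guard)
      stop("population exploded beyond 100x the stem-cell guard");
  }

  List out = List::create(
    _["n_iter"] = iter,
    _["ns"] = wrap(ns_series),
    _["niche_occupancy"] = wrap(occ_series),
    _["population"] = wrap(pop_series),
    _["births"] = wrap(born_series),
    _["shed"] = wrap(shed_series),
    _["succession_iteration"] = succession_iter,
    _["winner"] = winner,
    _["marked"] = marked,
    _["second_hit_any"] = hits.iter_any,
    _["second_hit_stem"] = hits.iter_stem,
    _["stop_reason"] = stop_reason,
    _["cells"] = cells_to_df(w, dt));
  if (p.record_trace) {
    IntegerMatrix anc(p.n0, iter >= 1 ? (int)(anc_series.size() / p.n0) : 0);
    std::copy(anc_series.begin(), anc_series.end(), anc.begin());
    out["ancestor_counts"] = transpose(anc);
  } else {
    out["ancestor_counts"] = R_NilValue;
  }
  return out;
}

// --- probes used by unit tests ------------------------------------------

static World world_from_df(DataFrame cells, int n_cols, int n_rows, int kmax) {
  World w;
  w.p = Params();
  w.p.n_cols = n_cols; w.p.n_rows = n_rows; w.p.kmax = kmax; w.p.n0 = 1;
  w.init_grid();
  IntegerVector x = cells["x"], y = cells["y"];
  IntegerVector age = cells["age"];
  LogicalVector stem = cells["stem"];
  for (int i = 0; i < x.size(); ++i) {
    Cell c;
    c.x = x[i]; c.y = y[i]; c.age = age[i];
    c.k = stem[i] ? kmax : 0;
    c.state = ST_Q; c.t_state = 0; c.ndiv = 0; c.ancestor = 0; c.alleles = 0;
    c.alive = true;
    w.add_cell(c);
  }
  return w;
}

// [[Rcpp::export(name = ".cpp_choose_site")]]
IntegerVector cpp_choose_site(DataFrame cells, int n_cols, int n_rows,
                              int mx, int my, bool stem_daughter) {
  World w = world_from_df(cells, n_cols, n_rows, 1);
  int ox, oy;
  choose_site(w, mx, my, stem_daughter, ox, oy);
  return IntegerVector::create(_["x"] = ox, _["y"] = oy);
}

// [[Rcpp::export(name = ".cpp_migrate")]]
List cpp_migrate(DataFrame cells, int n_cols, int n_rows) {
  World w = world_from_df(cells, n_cols, n_rows, 1);
  migrate(w);
  int n = 0;
  for (size_t i = 0; i < w.cells.size(); ++i) if (w.cells[i].alive) n++;
  IntegerVector x(n), y(n), age(n), id(n);
  LogicalVector stem(n);
  int j = 0;
  for (size_t i = 0; i < w.cells.size(); ++i) {
    const Cell& c = w.cells[i];
    if (!c.alive) continue;
    id[j] = (int)i + 1; x[j] = c.x; y[j] = c.y; age[j] = c.age;
    stem[j] = (c.k == w.p.kmax);
    j++;
  }
  DataFrame df = DataFrame::create(_["id"] = id, _["x"] = x, _["y"] = y,
                                   _["age"] = age, _["stem"] = stem);
  return List::create(_["cells"] = df, _["n_shed"] = (int)w.n_shed);
}
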