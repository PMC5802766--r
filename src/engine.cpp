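#include <Rcpp.h>
#include <climits>
#include <cstdlib>
#include <vector>

using namespace Rcpp;

namespace {

// uniform integer in [0, n), consuming one draw from R's RNG stream
inline int unif_index(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Mutable snapshot of one simulation world plus the behavioural parameters.
// Positions are integer patch coordinates on a bounded (optionally toroidal)
// width x height grid with origin (0, 0).  Distances are Chebyshev
// (8-neighbour) patch counts; a male moves exactly one patch per tick.
struct Engine {
  int W, H;
  bool wrap;
  bool guarding, neutral, proximity_blocking;
  double preg_chance;
  int refr_dur, season_len;
  int nf, nm;
  std::vector<int> fx, fy, frefr, ffather, fpreg;
  std::vector<int> mx, my, geno, partner;
  std::vector<int> ord;    // scratch buffer for per-tick shuffles
  std::vector<int> flock;  // males pair-bonded to each female
  std::vector<int> focc;   // males standing on each female's patch
  long cops;

  Engine()
      : W(1), H(1), wrap(false), guarding(true), neutral(false),
        proximity_blocking(false), preg_chance(0.0), refr_dur(0),
        season_len(0), nf(0), nm(0), cops(0) {}

  int dist(int x1, int y1, int x2, int y2) const {
    int dx = std::abs(x1 - x2), dy = std::abs(y1 - y2);
    if (wrap) {
      if (W - dx < dx) dx = W - dx;
      if (H - dy < dy) dy = H - dy;
    }
    return dx > dy ? dx : dy;
  }

  int mfdist(int m, int f) const { return dist(mx[m], my[m], fx[f], fy[f]); }

  // A female is available to a candidate male iff she is neither pregnant
  // nor refractory and no other male has her locked up.  With mate guarding
  // on, a pair-bonded female is unavailable to everyone but her partner
  // (guarding is fully efficient).  Beyond that, the default rule blocks a
  // female only while another male occupies her patch; the optional
  // proximity rule blocks whenever any other male is strictly closer than
  // the candidate (distance ties never block).
  bool available(int f, int m) const {
    if (fpreg[f] || frefr[f] > 0) return false;
    if (guarding && !neutral &&
        flock[f] - (partner[m] == f ? 1 : 0) > 0) return false;
    int d = mfdist(m, f);
    if (proximity_blocking) {
      for (int j = 0; j < nm; ++j)
        if (j != m && mfdist(j, f) < d) return false;
    } else if (d > 0 && focc[f] > 0) {
      return false;  // d > 0 means the occupant is somebody else
    }
    return true;
  }

  // Nearest available female; exact distance ties broken by lowest female id.
  // Candidates are scanned in (distance, id) order so the first available
  // one wins and the scan stops.
  int select_target(int m) const {
    std::vector<int> cf(nf), cd(nf);
    int c = 0;
    for (int f = 0; f < nf; ++f) {
      if (fpreg[f] || frefr[f] > 0) continue;
      int d = mfdist(m, f);
      int k = c;  // insertion sort keeps (d, id) ascending; ids arrive ascending
      while (k > 0 && cd[k - 1] > d) {
        cd[k] = cd[k - 1];
        cf[k] = cf[k - 1];
        --k;
      }
      cd[k] = d;
      cf[k] = f;
      ++c;
    }
    for (int k = 0; k < c; ++k)
      if (available(cf[k], m)) return cf[k];
    return -1;
  }

  // One copulation: pregnancy with probability preg_chance (recording the
  // father's genotype), otherwise the female turns refractory.  An unpaired
  // monogamous male pair-bonds with her whichever way it goes.
  bool copulate(int m, int f) {
    ++cops;
    bool preg = unif_rand() < preg_chance;
    if (preg) {
      fpreg[f] = 1;
      ffather[f] = geno[m];
      frefr[f] = 0;
    } else {
      frefr[f] = refr_dur;
    }
    if (!neutral && geno[m] == 1 && partner[m] < 0) {
      partner[m] = f;
      ++flock[f];
    }
    return preg;
  }

  // Move a male, keeping the per-female patch-occupancy counts in step.
  void set_pos(int m, int nx, int ny) {
    if (nx == mx[m] && ny == my[m]) return;
    for (int f = 0; f < nf; ++f) {
      if (fx[f] == mx[m] && fy[f] == my[m]) --focc[f];
      if (fx[f] == nx && fy[f] == ny) ++focc[f];
    }
    mx[m] = nx;
    my[m] = ny;
  }

  int nneigh(int m, int outx[8], int outy[8]) const {
    static const int OX[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int OY[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    int n = 0;
    for (int k = 0; k < 8; ++k) {
      int nx = mx[m] + OX[k], ny = my[m] + OY[k];
      if (wrap) {
        nx = (nx + W) % W;
        ny = (ny + H) % H;
      } else if (nx < 0 || nx >= W || ny < 0 || ny >= H) {
        continue;
      }
      outx[n] = nx;
      outy[n] = ny;
      ++n;
    }
    return n;
  }

  void random_move(int m) {
    int nx[8], ny[8];
    int n = nneigh(m, nx, ny);
    if (n == 0) return;
    int k = unif_index(n);
    set_pos(m, nx[k], ny[k]);
  }

  // One 8-neighbour step minimising Chebyshev distance to (tx, ty); equally
  // good steps are chosen uniformly at random.
  void move_toward(int m, int tx, int ty) {
    int nx[8], ny[8];
    int n = nneigh(m, nx, ny);
    if (n == 0) return;
    int cx[8], cy[8], c = 0, bestd = INT_MAX;
    for (int k = 0; k < n; ++k) {
      int d = dist(nx[k], ny[k], tx, ty);
      if (d < bestd) { bestd = d; c = 0; }
      if (d == bestd) { cx[c] = nx[k]; cy[c] = ny[k]; ++c; }
    }
    int k = (c > 1) ? unif_index(c) : 0;
    set_pos(m, cx[k], cy[k]);
  }

  void step_male(int m) {
    int p = partner[m];
    if (!neutral && geno[m] == 1 && p >= 0) {
      if (guarding) {
        // Guarding male: never moves; his partner is always available to him.
        if (!fpreg[p] && frefr[p] == 0) copulate(m, p);
      } else {
        // Non-guarding monogamous male: wanders while his partner is
        // refractory (or pregnant), otherwise heads back to her; he never
        // courts other females.
        if (frefr[p] > 0 || fpreg[p]) {
          random_move(m);
        } else {
          if (mfdist(m, p) > 0) move_toward(m, fx[p], fy[p]);
          if (mfdist(m, p) == 0) copulate(m, p);
        }
      }
      return;
    }
    // Polygamous or still-unpaired male: chase the nearest available female,
    // or drift to a random neighbour patch when none qualifies.
    int t = select_target(m);
    if (t < 0) {
      random_move(m);
      return;
    }
    if (mfdist(m, t) > 0) move_toward(m, fx[t], fy[t]);
    if (mfdist(m, t) == 0) copulate(m, t);
  }

  // One tick: decrement refractory counters first, then step every male in a
  // freshly shuffled order.
  void tick() {
    for (int f = 0; f < nf; ++f)
      if (frefr[f] > 0) --frefr[f];
    for (int i = 0; i < nm; ++i) ord[i] = i;
    for (int i = nm - 1; i > 0; --i) {
      int j = unif_index(i + 1);
      int tmp = ord[i];
      ord[i] = ord[j];
      ord[j] = tmp;
    }
    for (int i = 0; i < nm; ++i) step_male(ord[i]);
  }
};

std::vector<int> as_std(SEXP x, int na_code) {
  IntegerVector v(x);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i)
    out[i] = (v[i] == NA_INTEGER) ? na_code : v[i];
  return out;
}

IntegerVector as_rint(const std::vector<int>& v, bool na_below_zero = false) {
  IntegerVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    out[i] = (na_below_zero && v[i] < 0) ? NA_INTEGER : v[i];
  return out;
}

void load_world(Engine& e, List world) {
  e.W = as<int>(world["width"]);
  e.H = as<int>(world["height"]);
  e.wrap = as<bool>(world["wrap"]);
  e.fx = as_std(world["fx"], 0);
  e.fy = as_std(world["fy"], 0);
  e.fpreg = as_std(world["f_pregnant"], 0);
  e.frefr = as_std(world["f_refractory"], 0);
  e.ffather = as_std(world["f_father"], -1);
  e.mx = as_std(world["mx"], 0);
  e.my = as_std(world["my"], 0);
  e.geno = as_std(world["genotype"], 0);
  IntegerVector pv(world["partner"]);
  e.partner.resize(pv.size());
  for (int i = 0; i < pv.size(); ++i)
    e.partner[i] = (pv[i] == NA_INTEGER) ? -1 : pv[i] - 1;
  e.nf = static_cast<int>(e.fx.size());
  e.nm = static_cast<int>(e.mx.size());
  e.ord.resize(e.nm);
  e.flock.assign(e.nf, 0);
  e.focc.assign(e.nf, 0);
  for (int j = 0; j < e.nm; ++j) {
    if (e.partner[j] >= 0 && e.partner[j] < e.nf) ++e.flock[e.partner[j]];
    for (int f = 0; f < e.nf; ++f)
      if (e.fx[f] == e.mx[j] && e.fy[f] == e.my[j]) ++e.focc[f];
  }
  if (e.W < 1 || e.H < 1) stop("world dimensions must be positive");
}

void load_params(Engine& e, List params) {
  e.guarding = as<bool>(params["mate_guarding"]);
  e.preg_chance = as<double>(params["pregnancy_chance"]);
  e.refr_dur = as<int>(params["refractory_period_duration"]);
  e.season_len = as<int>(params["season_duration"]);
  e.neutral = params.containsElementNamed("neutral")
                  ? as<bool>(params["neutral"])
                  : false;
  e.proximity_blocking = params.containsElementNamed("proximity_blocking")
                  ? as<bool>(params["proximity_blocking"])
                  : false;
}

List store_world(const Engine& e, List world) {
  List w = clone(world);
  w["f_pregnant"] = as_rint(e.fpreg);
  w["f_refractory"] = as_rint(e.frefr);
  w["f_father"] = as_rint(e.ffather, true);
  w["mx"] = as_rint(e.mx);
  w["my"] = as_rint(e.my);
  IntegerVector pv(e.nm);
  for (int i = 0; i < e.nm; ++i)
    pv[i] = e.partner[i] < 0 ? NA_INTEGER : e.partner[i] + 1;
  w["partner"] = pv;
  return w;
}

}  // namespace

// [[Rcpp::export]]
bool cpp_is_available(List world, List params, int female, int male) {
  Engine e;
  load_world(e, world);
  load_params(e, params);
  if (female < 1 || female > e.nf || male < 1 || male > e.nm)
    stop("female/male index out of range");
  return e.available(female - 1, male - 1);
}

// [[Rcpp::export]]
int cpp_select_target(List world, List params, int male) {
  Engine e;
  load_world(e, world);
  load_params(e, params);
  if (male < 1 || male > e.nm) stop("male index out of range");
  int t = e.select_target(male - 1);
  return t < 0 ? 0 : t + 1;
}

// [[Rcpp::export]]
List cpp_attempt_copulation(List world, List params, int male, int female) {
  Engine e;
  load_world(e, world);
  load_params(e, params);
  if (female < 1 || female > e.nf || male < 1 || male > e.nm)
    stop("female/male index out of range");
  int f = female - 1, m = male - 1;
  if (e.fpreg[f] || e.frefr[f] > 0)
    stop("attempt_copulation: female is pregnant or refractory");
  bool preg = e.copulate(m, f);
  return List::create(_["world"] = store_world(e, world),
                      _["outcome"] = std::string(preg ? "pregnant" : "refractory"));
}

// [[Rcpp::export]]
List cpp_step_male(List world, List params, int male) {
  Engine e;
  load_world(e, world);
  load_params(e, params);
  if (male < 1 || male > e.nm) stop("male index out of range");
  e.step_male(male - 1);
  return store_world(e, world);
}

// [[Rcpp::export]]
List cpp_tick(List world, List params) {
  Engine e;
  load_world(e, world);
  load_params(e, params);
  e.tick();
  List w = store_world(e, world);
  w["tick"] = as<int>(world["tick"]) + 1;
  return w;
}

// [[Rcpp::export]]
List cpp_run_season(List world, List params) {
  Engine e;
  load_world(e, world);
  load_params(e, params);
  for (int t = 0; t < e.season_len; ++t) e.tick();
  List w = store_world(e, world);
  w["tick"] = as<int>(world["tick"]) + e.season_len;
  return List::create(_["world"] = w,
                      _["copulations"] = static_cast<double>(e.cops));
}
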