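#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

// State codes shared with the R side: -1 destroyed, 0 vacant, 1 NC, 2 exploiter.
static const int S_DES = -1, S_VAC = 0, S_NC = 1, S_EX = 2;

// Offsets of the Hamming (L1) ball of radius r, focal site excluded.
static std::vector<std::pair<int, int> > hamming_offsets(int r) {
  std::vector<std::pair<int, int> > off;
  for (int dr = -r; dr <= r; ++dr) {
    int rem = r - std::abs(dr);
    for (int dc = -rem; dc <= rem; ++dc) {
      if (dr == 0 && dc == 0) continue;
      off.push_back(std::make_pair(dr, dc));
    }
  }
  return off;
}

static inline int wrap(int x, int L) {
  x %= L;
  return x < 0 ? x + L : x;
}

static inline int rand_int(int n) {
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Swap-remove bookkeeping for the per-state site lists.
struct SiteList {
  std::vector<int> items;
  std::vector<int> pos; // pos[site] = index in items, or -1
  SiteList(int N) : pos(N, -1) {}
  void add(int s) { pos[s] = (int)items.size(); items.push_back(s); }
  void remove(int s) {
    int p = pos[s], last = items.back();
    items[p] = last;
    pos[last] = p;
    items.pop_back();
    pos[s] = -1;
  }
  int size() const { return (int)items.size(); }
  int pick() const { return items[rand_int((int)items.size())]; }
};

// Continuous-time Gillespie run of the niche-construction particle system.
// Source-driven formulation: occupied sites fire death, colonization-attempt and
// construction-attempt clocks; attempts landing on an ineligible target are
// no-ops (exact thinning of the per-site rates). Destruction is one global
// channel at rate e * (#non-destroyed sites).
// [[Rcpp::export]]
List run_ips_cpp(IntegerVector grid0, int L, double delta, double e,
                 double cons, double alpha, int r_col, int r_con,
                 bool global_con, double t_max, double sample_dt,
                 int record_row, int seed_row, int seed_col,
                 bool track_extent) {
  const int N = L * L;
  std::vector<int> g(grid0.begin(), grid0.end());

  SiteList nc(N), ex(N), alive(N); // alive = any non-destroyed site
  for (int s = 0; s < N; ++s) {
    if (g[s] != S_DES) alive.add(s);
    if (g[s] == S_NC) nc.add(s);
    else if (g[s] == S_EX) ex.add(s);
  }

  std::vector<std::pair<int, int> > zcol = hamming_offsets(r_col);
  std::vector<std::pair<int, int> > zcon;
  if (!global_con && r_con >= 1) zcon = hamming_offsets(r_con);
  const int nzcol = (int)zcol.size();
  const int nzcon = (int)zcon.size();

  const double beta = std::pow(1.0 - cons, alpha); // colonization discount

  const int nsamp = (int)std::floor(t_max / sample_dt + 1e-9) + 1;
  NumericVector times(nsamp), p_minus(nsamp), p_vac(nsamp), p_nc(nsamp), p_ex(nsamp);
  IntegerVector occ_count(nsamp);
  IntegerVector extent(track_extent ? nsamp : 0);
  IntegerMatrix row_snap(record_row >= 0 ? nsamp : 0, record_row >= 0 ? L : 0);
  for (int k = 0; k < nsamp; ++k) times[k] = k * sample_dt;

  // Realized-event tallies.
  long long n_ext_nc = 0, n_ext_ex = 0, n_destr = 0, n_col_nc = 0, n_col_ex = 0,
            n_con = 0, n_attempts = 0;

  bool absorbed = (nc.size() + ex.size()) == 0;
  double t_absorbed = absorbed ? 0.0 : NA_REAL;

  int si = 0;
  double t = 0.0;

  // Record the current configuration at sample index k.
  #define RECORD(k) do {                                                  \
    int nn = nc.size(), ne = ex.size(), na = alive.size();                \
    p_nc[k] = (double)nn / N;                                             \
    p_ex[k] = (double)ne / N;                                             \
    p_minus[k] = (double)(N - na) / N;                                    \
    p_vac[k] = (double)(na - nn - ne) / N;                                \
    occ_count[k] = nn + ne;                                               \
    if (track_extent) {                                                   \
      int ext = 0;                                                        \
      for (int ii = 0; ii < nn + ne; ++ii) {                              \
        int s2 = ii < nn ? nc.items[ii] : ex.items[ii - nn];              \
        int dr = std::abs(s2 % L - seed_row); if (L - dr < dr) dr = L - dr; \
        int dc = std::abs(s2 / L - seed_col); if (L - dc < dc) dc = L - dc; \
        int ch = dr > dc ? dr : dc;                                       \
        if (ch > ext) ext = ch;                                           \
      }                                                                   \
      extent[k] = ext;                                                    \
    }                                                                     \
    if (record_row >= 0)                                                  \
      for (int jj = 0; jj < L; ++jj) row_snap(k, jj) = g[jj * L + record_row]; \
  } while (0)

  while (true) {
    int nn = nc.size(), ne = ex.size(), na = alive.size();
    double r_death_nc = nn * delta;
    double r_death_ex = ne * delta;
    double r_col_nc = nn * beta;
    double r_col_ex = (double)ne;
    double r_con_nc = cons > 0 ? nn * cons : 0.0;
    double r_destr = e * na;
    double rtot = r_death_nc + r_death_ex + r_col_nc + r_col_ex + r_con_nc + r_destr;

    if (rtot <= 0.0) { // frozen configuration: nothing can ever fire again
      while (si < nsamp) { RECORD(si); ++si; }
      t = t_max;
      break;
    }

    double tn = t + R::exp_rand() / rtot;
    while (si < nsamp && times[si] < tn) { RECORD(si); ++si; }
    if (tn >= t_max) {
      while (si < nsamp) { RECORD(si); ++si; }
      t = t_max;
      break;
    }
    t = tn;
    ++n_attempts;

    double u = R::unif_rand() * rtot;
    if (u < r_death_nc) {
      int s = nc.pick();
      nc.remove(s); g[s] = S_VAC; ++n_ext_nc;
    } else if ((u -= r_death_nc) < r_death_ex) {
      int s = ex.pick();
      ex.remove(s); g[s] = S_VAC; ++n_ext_ex;
    } else if ((u -= r_death_ex) < r_col_nc) {
      int s = nc.pick();
      std::pair<int, int> d = zcol[rand_int(nzcol)];
      int tgt = wrap(s / L + d.second, L) * L + wrap(s % L + d.first, L);
      if (g[tgt] == S_VAC) { g[tgt] = S_NC; nc.add(tgt); ++n_col_nc; }
    } else if ((u -= r_col_nc) < r_col_ex) {
      int s = ex.pick();
      std::pair<int, int> d = zcol[rand_int(nzcol)];
      int tgt = wrap(s / L + d.second, L) * L + wrap(s % L + d.first, L);
      if (g[tgt] == S_VAC) { g[tgt] = S_EX; ex.add(tgt); ++n_col_ex; }
    } else if ((u -= r_col_ex) < r_con_nc) {
      int s = nc.pick();
      int tgt;
      if (global_con) {
        tgt = rand_int(N - 1);
        if (tgt >= s) ++tgt; // uniform over the lattice minus the focal site
      } else {
        std::pair<int, int> d = zcon[rand_int(nzcon)];
        tgt = wrap(s / L + d.second, L) * L + wrap(s % L + d.first, L);
      }
      if (g[tgt] == S_DES) { g[tgt] = S_VAC; alive.add(tgt); ++n_con; }
    } else {
      int s = alive.pick();
      if (g[s] == S_NC) nc.remove(s);
      else if (g[s] == S_EX) ex.remove(s);
      alive.remove(s); g[s] = S_DES; ++n_destr;
    }

    if (!absorbed && nc.size() + ex.size() == 0) {
      absorbed = true;
      t_absorbed = t;
    }
  }
  #undef RECORD

  IntegerVector gout(g.begin(), g.end());
  List out = List::create(
      _["times"] = times, _["p_minus"] = p_minus, _["p_vacant"] = p_vac,
      _["p_nc"] = p_nc, _["p_ex"] = p_ex, _["occupied"] = occ_count,
      _["final_grid"] = gout, _["t_final"] = t, _["absorbed"] = absorbed,
      _["t_absorbed"] = t_absorbed,
      _["event_counts"] = NumericVector::create(
          _["extinction_nc"] = (double)n_ext_nc,
          _["extinction_ex"] = (double)n_ext_ex,
          _["destruction"] = (double)n_destr,
          _["colonization_nc"] = (double)n_col_nc,
          _["colonization_ex"] = (double)n_col_ex,
          _["construction"] = (double)n_con,
          _["attempts"] = (double)n_attempts));
  if (track_extent) out["extent"] = extent;
  if (record_row >= 0) out["row_snapshots"] = row_snap;
  return out;
}

// Connected components of target-state sites under 4-connectivity.
// wrap = FALSE is used for non-spatial masks (e.g. phase-diagram persistence
// regions); the lattice itself is always toroidal.
// [[Rcpp::export]]
List clusters_cpp(IntegerVector grid, int nrow, int ncol, IntegerVector targets,
                  bool wrap_edges) {
  const int N = nrow * ncol;
  std::vector<bool> is_target(N, false);
  for (int s = 0; s < N; ++s)
    for (int k = 0; k < targets.size(); ++k)
      if (grid[s] == targets[k]) { is_target[s] = true; break; }

  IntegerVector labels(N, 0);
  std::vector<int> sizes;
  std::vector<int> stack;
  int lab = 0;
  for (int s0 = 0; s0 < N; ++s0) {
    if (!is_target[s0] || labels[s0] != 0) continue;
    ++lab;
    int size = 0;
    stack.push_back(s0);
    labels[s0] = lab;
    while (!stack.empty()) {
      int s = stack.back();
      stack.pop_back();
      ++size;
      int r = s % nrow, c = s / nrow;
      const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (wrap_edges) {
          rr = wrap(rr, nrow);
          cc = wrap(cc, ncol);
        } else if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) {
          continue;
        }
        int t = cc * nrow + rr;
        if (is_target[t] && labels[t] == 0) {
          labels[t] = lab;
          stack.push_back(t);
        }
      }
    }
    sizes.push_back(size);
  }
  return List::create(_["labels"] = labels, _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}
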