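#include <Rcpp.h>
#include <queue>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Grid convention shared with the R side: cells are indexed 1..nrow*ncol in
// row-major order, i.e. cell k sits at row r = (k-1) / ncol, col c = (k-1) % ncol
// (0-based internally). All 8-neighbourhoods are "queen" neighbourhoods.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline int cell_of(int r, int c, int ncol) { return r * ncol + c; }

// Euclidean distance (in cells) from every inside cell to the nearest outside
// cell centre. Outside candidates are outside cells with at least one inside
// 8-neighbour, plus a virtual one-cell ring beyond the grid edge so that masks
// touching the edge still have a border. Exact: the nearest outside cell to an
// inside cell is always adjacent to some inside cell along the joining segment.
// [[Rcpp::export]]
NumericVector cpp_dist_border(LogicalVector mask, int nrow, int ncol,
                              double cell_side) {
  int n = nrow * ncol;
  std::vector<std::pair<int, int> > cand;
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      if (mask[cell_of(r, c, ncol)]) continue;
      bool near_inside = false;
      for (int j = 0; j < 8 && !near_inside; ++j) {
        int rr = r + DR[j], cc = c + DC[j];
        if (rr >= 0 && rr < nrow && cc >= 0 && cc < ncol &&
            mask[cell_of(rr, cc, ncol)])
          near_inside = true;
      }
      if (near_inside) cand.push_back(std::make_pair(r, c));
    }
  }
  // virtual ring just beyond the grid edge
  for (int c = -1; c <= ncol; ++c) {
    cand.push_back(std::make_pair(-1, c));
    cand.push_back(std::make_pair(nrow, c));
  }
  for (int r = 0; r < nrow; ++r) {
    cand.push_back(std::make_pair(r, -1));
    cand.push_back(std::make_pair(r, ncol));
  }
  NumericVector out(n, 0.0);
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      int k = cell_of(r, c, ncol);
      if (!mask[k]) continue;
      double best = R_PosInf;
      for (size_t i = 0; i < cand.size(); ++i) {
        double dr = r - cand[i].first, dc = c - cand[i].second;
        double d2 = dr * dr + dc * dc;
        if (d2 < best) best = d2;
      }
      out[k] = std::sqrt(best) * cell_side;
    }
  }
  return out;
}

// Global Moran's I over inside cells, queen contiguity, row-standardised
// weights. Cells without inside neighbours contribute no weight row.
// [[Rcpp::export]]
double cpp_morans_i(NumericVector x, LogicalVector mask, int nrow, int ncol) {
  double mu = 0.0;
  int n = 0;
  int ncell = nrow * ncol;
  for (int k = 0; k < ncell; ++k)
    if (mask[k]) { mu += x[k]; ++n; }
  mu /= n;
  double num = 0.0, den = 0.0, s0 = 0.0;
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      int k = cell_of(r, c, ncol);
      if (!mask[k]) continue;
      double zi = x[k] - mu;
      den += zi * zi;
      int nb = 0;
      double acc = 0.0;
      for (int j = 0; j < 8; ++j) {
        int rr = r + DR[j], cc = c + DC[j];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
        int kk = cell_of(rr, cc, ncol);
        if (!mask[kk]) continue;
        ++nb;
        acc += x[kk] - mu;
      }
      if (nb > 0) {
        num += zi * acc / nb;
        s0 += 1.0;  // row-standardised: each row of weights sums to 1
      }
    }
  }
  return (n / s0) * (num / den);
}

// Mean of value over the cell's 8-neighbourhood plus itself, restricted to
// inside cells; 0 outside the mask.
// [[Rcpp::export]]
NumericVector cpp_neigh_mean(NumericVector x, LogicalVector mask, int nrow,
                             int ncol) {
  NumericVector out(nrow * ncol, 0.0);
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      int k = cell_of(r, c, ncol);
      if (!mask[k]) continue;
      double acc = x[k];
      int m = 1;
      for (int j = 0; j < 8; ++j) {
        int rr = r + DR[j], cc = c + DC[j];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
        int kk = cell_of(rr, cc, ncol);
        if (mask[kk]) { acc += x[kk]; ++m; }
      }
      out[k] = acc / m;
    }
  }
  return out;
}

// Territory-origin search: free inside cells within max_r (cells) of the
// natal cell having no cell of another female's territory within excl_r
// (cells) — enough open space to establish a territory without immediate
// competition. Returns all 1-based cells tied for the highest score (the
// caller breaks ties at random).
// [[Rcpp::export]]
IntegerVector cpp_origin_candidates(IntegerVector occ, NumericVector score,
                                    LogicalVector mask, int nrow, int ncol,
                                    int natal, double max_r, double excl_r) {
  int r0 = (natal - 1) / ncol, c0 = (natal - 1) % ncol;
  double max_r2 = max_r * max_r, excl2 = excl_r * excl_r;
  int er = (int)std::floor(excl_r);
  double best = R_NegInf;
  std::vector<int> ties;
  int rlo = std::max(0, r0 - (int)std::ceil(max_r));
  int rhi = std::min(nrow - 1, r0 + (int)std::ceil(max_r));
  for (int r = rlo; r <= rhi; ++r) {
    for (int c = 0; c < ncol; ++c) {
      int k = cell_of(r, c, ncol);
      if (!mask[k] || occ[k] != 0) continue;
      double dr = r - r0, dc = c - c0;
      if (dr * dr + dc * dc > max_r2) continue;
      if (score[k] < best) continue;
      bool blocked = false;
      for (int ir = -er; ir <= er && !blocked; ++ir) {
        int rr = r + ir;
        if (rr < 0 || rr >= nrow) continue;
        for (int ic = -er; ic <= er; ++ic) {
          int cc = c + ic;
          if (cc < 0 || cc >= ncol) continue;
          if ((double)(ir * ir + ic * ic) > excl2) continue;
          if (occ[cell_of(rr, cc, ncol)] != 0) { blocked = true; break; }
        }
      }
      if (blocked) continue;
      if (score[k] > best) {
        best = score[k];
        ties.clear();
      }
      ties.push_back(k + 1);
    }
  }
  return wrap(ties);
}

// generation-stamped scratch buffer for frontier dedup scans
static std::vector<long long> g_stamp;
static long long g_stamp_gen = 0;

static void ensure_stamp(size_t n) {
  if (g_stamp.size() < n) g_stamp.assign(n, -1);
}

// Greedy territory growth: repeatedly add the free adjoining inside cell with
// the highest prey (uniform tie-break via R's RNG) until the prey sum reaches
// stop_sum, max_add cells have been added, the cell cap is hit, or no free
// adjoining cell remains ("blocked"). Modifies occ in place.
// [[Rcpp::export]]
List cpp_grow(IntegerVector occ, NumericVector prey, LogicalVector mask,
              int nrow, int ncol, IntegerVector cells, int owner, int max_add,
              double stop_sum, double cur_sum, int max_cells) {
  std::vector<int> terr(cells.begin(), cells.end());
  std::vector<int> added;
  ensure_stamp((size_t)nrow * ncol);
  bool blocked = false;
  while (cur_sum < stop_sum && (int)added.size() < max_add &&
         (int)terr.size() < max_cells) {
    double best = R_NegInf;
    int pick = -1, nties = 0;
    ++g_stamp_gen;
    for (size_t i = 0; i < terr.size(); ++i) {
      int k = terr[i] - 1;
      int r = k / ncol, c = k % ncol;
      for (int j = 0; j < 8; ++j) {
        int rr = r + DR[j], cc = c + DC[j];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
        int kk = cell_of(rr, cc, ncol);
        if (!mask[kk] || occ[kk] != 0 || g_stamp[kk] == g_stamp_gen) continue;
        g_stamp[kk] = g_stamp_gen;
        if (prey[kk] > best) {
          best = prey[kk];
          pick = kk;
          nties = 1;
        } else if (prey[kk] == best) {
          ++nties;
          if (R::unif_rand() < 1.0 / nties) pick = kk;
        }
      }
    }
    if (pick < 0) { blocked = true; break; }
    occ[pick] = owner;
    terr.push_back(pick + 1);
    added.push_back(pick + 1);
    cur_sum += prey[pick];
  }
  return List::create(_["cells"] = wrap(terr), _["added"] = wrap(added),
                      _["sum"] = cur_sum, _["blocked"] = blocked);
}

// Is the cell set (1-based) of owner, excluding `skip` (0 = none), 8-connected
// when traversal starts from `start`?  Membership is read from occ. Uses a
// generation-stamped workspace so repeated calls avoid re-zeroing buffers
// (R is single-threaded).
static std::vector<int> g_seen;
static std::vector<int> g_queue;
static int g_gen = 0;

static bool connected_without(const IntegerVector &occ, int nrow, int ncol,
                              int owner, int start, int skip, int count) {
  if (count <= 0) return true;
  size_t n = (size_t)nrow * ncol;
  if (g_seen.size() < n) g_seen.assign(n, 0);
  ++g_gen;
  g_queue.clear();
  g_queue.push_back(start - 1);
  g_seen[start - 1] = g_gen;
  int found = 1;
  for (size_t qi = 0; qi < g_queue.size(); ++qi) {
    int k = g_queue[qi];
    int r = k / ncol, c = k % ncol;
    for (int j = 0; j < 8; ++j) {
      int rr = r + DR[j], cc = c + DC[j];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      int kk = cell_of(rr, cc, ncol);
      if (g_seen[kk] == g_gen || occ[kk] != owner || kk == skip - 1) continue;
      g_seen[kk] = g_gen;
      ++found;
      g_queue.push_back(kk);
    }
  }
  return found == count;
}

// [[Rcpp::export]]
bool cpp_connected(IntegerVector occ, int nrow, int ncol, int owner, int start,
                   int count) {
  return connected_without(occ, nrow, ncol, owner, start, 0, count);
}

// ---- articulation points on a territory subgraph ---------------------------
// Local scratch for mapping grid cells to territory-local indices.
static std::vector<long long> g_loc_stamp;
static std::vector<int> g_loc_idx;

// Computes, for the 8-connected subgraph induced by `terr` (1-based cells,
// membership checked against occ == owner), which cells are articulation
// (cut) vertices: exactly the cells whose removal disconnects the territory.
static std::vector<int> g_ap_adj, g_ap_deg, g_ap_disc, g_ap_low, g_ap_parent,
    g_ap_eidx, g_ap_stack;

static void find_cut_vertices(const std::vector<int> &terr,
                              const IntegerVector &occ, int owner, int nrow,
                              int ncol, std::vector<char> &is_cut) {
  int n = (int)terr.size();
  is_cut.assign(n, 0);
  if (n <= 2) return;
  size_t ncell = (size_t)nrow * ncol;
  if (g_loc_stamp.size() < ncell) {
    g_loc_stamp.assign(ncell, -1);
    g_loc_idx.assign(ncell, 0);
  }
  ++g_stamp_gen;
  for (int i = 0; i < n; ++i) {
    g_loc_stamp[terr[i] - 1] = g_stamp_gen;
    g_loc_idx[terr[i] - 1] = i;
  }
  if ((int)g_ap_deg.size() < n) {
    g_ap_adj.resize((size_t)n * 8);
    g_ap_deg.resize(n);
    g_ap_disc.resize(n);
    g_ap_low.resize(n);
    g_ap_parent.resize(n);
    g_ap_eidx.resize(n);
    g_ap_stack.resize(n);
  }
  for (int i = 0; i < n; ++i) {
    int k = terr[i] - 1;
    int r = k / ncol, c = k % ncol;
    int d = 0;
    for (int j = 0; j < 8; ++j) {
      int rr = r + DR[j], cc = c + DC[j];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      int kk = cell_of(rr, cc, ncol);
      if (occ[kk] == owner && g_loc_stamp[kk] == g_stamp_gen)
        g_ap_adj[(size_t)i * 8 + d++] = g_loc_idx[kk];
    }
    g_ap_deg[i] = d;
    g_ap_disc[i] = 0;
    g_ap_eidx[i] = 0;
    g_ap_parent[i] = -1;
  }
  // iterative Tarjan DFS from node 0
  int timer = 0, root_children = 0, top = 0;
  g_ap_stack[0] = 0;
  g_ap_disc[0] = g_ap_low[0] = ++timer;
  while (top >= 0) {
    int u = g_ap_stack[top];
    if (g_ap_eidx[u] < g_ap_deg[u]) {
      int v = g_ap_adj[(size_t)u * 8 + g_ap_eidx[u]++];
      if (v == g_ap_parent[u]) continue;
      if (g_ap_disc[v]) {
        if (g_ap_disc[v] < g_ap_low[u]) g_ap_low[u] = g_ap_disc[v];
      } else {
        g_ap_parent[v] = u;
        g_ap_disc[v] = g_ap_low[v] = ++timer;
        if (u == 0) ++root_children;
        g_ap_stack[++top] = v;
      }
    } else {
      --top;
      int pnode = g_ap_parent[u];
      if (pnode >= 0) {
        if (g_ap_low[u] < g_ap_low[pnode]) g_ap_low[pnode] = g_ap_low[u];
        if (pnode != 0 && g_ap_low[u] >= g_ap_disc[pnode]) is_cut[pnode] = 1;
      }
    }
  }
  if (root_children > 1) is_cut[0] = 1;
}

// Territory adjustment: while under the swap budget, drop the lowest-prey
// removable cell (not the origin, removal keeps the territory connected) in
// favour of the best free adjoining cell, if that strictly increases prey.
// Modifies occ in place.
// [[Rcpp::export]]
List cpp_adjust(IntegerVector occ, NumericVector prey, LogicalVector mask,
                int nrow, int ncol, IntegerVector cells, int owner, int origin,
                int max_swaps, double cur_sum) {
  std::vector<int> terr(cells.begin(), cells.end());
  int swaps = 0;
  ensure_stamp((size_t)nrow * ncol);
  std::vector<char> is_cut;
  while (swaps < max_swaps) {
    // best free adjoining cell (uniform tie-break)
    double best = R_NegInf;
    int pick = -1, nties = 0;
    ++g_stamp_gen;
    for (size_t i = 0; i < terr.size(); ++i) {
      int k = terr[i] - 1;
      int r = k / ncol, c = k % ncol;
      for (int j = 0; j < 8; ++j) {
        int rr = r + DR[j], cc = c + DC[j];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
        int kk = cell_of(rr, cc, ncol);
        if (!mask[kk] || occ[kk] != 0 || g_stamp[kk] == g_stamp_gen) continue;
        g_stamp[kk] = g_stamp_gen;
        if (prey[kk] > best) {
          best = prey[kk];
          pick = kk;
          nties = 1;
        } else if (prey[kk] == best) {
          ++nties;
          if (R::unif_rand() < 1.0 / nties) pick = kk;
        }
      }
    }
    if (pick < 0) break;
    // cheapest removable (non-cut, non-origin) cell strictly below the pick
    find_cut_vertices(terr, occ, owner, nrow, ncol, is_cut);
    int pr = pick / ncol, pc = pick % ncol;
    int drop_idx = -1;
    double drop_prey = best;
    for (size_t i = 0; i < terr.size(); ++i) {
      int cell = terr[i];
      if (cell == origin || is_cut[i]) continue;
      if (prey[cell - 1] >= drop_prey) continue;
      // candidate must still adjoin the territory without `cell`
      bool adjok = false;
      for (int j = 0; j < 8 && !adjok; ++j) {
        int rr = pr + DR[j], cc = pc + DC[j];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
        int kk = cell_of(rr, cc, ncol);
        if (occ[kk] == owner && kk != cell - 1) adjok = true;
      }
      if (!adjok) continue;
      drop_idx = (int)i;
      drop_prey = prey[cell - 1];
    }
    if (drop_idx < 0) break;
    int dropped = terr[drop_idx];
    occ[dropped - 1] = 0;
    occ[pick] = owner;
    terr[drop_idx] = pick + 1;
    cur_sum += prey[pick] - prey[dropped - 1];
    ++swaps;
  }
  return List::create(_["cells"] = wrap(terr), _["sum"] = cur_sum,
                      _["swaps"] = swaps);
}

// Shed surplus: drop the lowest-prey removable cells (never the origin,
// removal keeps the territory connected) while the remaining prey sum stays
// at or above keep_sum, up to max_drop cells. Modifies occ in place.
// [[Rcpp::export]]
List cpp_trim(IntegerVector occ, NumericVector prey, int nrow, int ncol,
              IntegerVector cells, int owner, int origin, double keep_sum,
              double cur_sum, int max_drop) {
  std::vector<int> terr(cells.begin(), cells.end());
  int dropped = 0;
  std::vector<char> is_cut;
  while (dropped < max_drop) {
    find_cut_vertices(terr, occ, owner, nrow, ncol, is_cut);
    int drop_idx = -1;
    double drop_prey = R_PosInf;
    for (size_t i = 0; i < terr.size(); ++i) {
      int cell = terr[i];
      if (cell == origin || is_cut[i]) continue;
      if (prey[cell - 1] < drop_prey) {
        drop_prey = prey[cell - 1];
        drop_idx = (int)i;
      }
    }
    if (drop_idx < 0) break;
    if (cur_sum - drop_prey < keep_sum) break;
    int cell = terr[drop_idx];
    occ[cell - 1] = 0;
    cur_sum -= drop_prey;
    terr.erase(terr.begin() + drop_idx);
    ++dropped;
  }
  return List::create(_["cells"] = wrap(terr), _["sum"] = cur_sum,
                      _["dropped"] = dropped);
}

// Unique pairs of distinct owners whose territories share an 8-adjacency
// border. Returns a 2-column matrix (a < b).
// [[Rcpp::export]]
IntegerMatrix cpp_contacts(IntegerVector occ, int nrow, int ncol) {
  // scan a half neighbourhood so each adjacency is seen once
  static const int HR[4] = {0, 1, 1, 1};
  static const int HC[4] = {1, -1, 0, 1};
  std::set<std::pair<int, int> > pairs;
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      int a = occ[cell_of(r, c, ncol)];
      if (a == 0) continue;
      for (int j = 0; j < 4; ++j) {
        int rr = r + HR[j], cc = c + HC[j];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
        int b = occ[cell_of(rr, cc, ncol)];
        if (b == 0 || b == a) continue;
        pairs.insert(std::make_pair(std::min(a, b), std::max(a, b)));
      }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  int i = 0;
  for (std::set<std::pair<int, int> >::iterator it = pairs.begin();
       it != pairs.end(); ++it, ++i) {
    out(i, 0) = it->first;
    out(i, 1) = it->second;
  }
  return out;
}

// Unique territory owner ids having at least one cell within `radius` cells
// of the centre cell (1-based).
// [[Rcpp::export]]
IntegerVector cpp_owners_within(IntegerVector occ, int nrow, int ncol,
                                int center, double radius) {
  int r0 = (center - 1) / ncol, c0 = (center - 1) % ncol;
  int rad = (int)std::floor(radius);
  double r2 = radius * radius;
  std::set<int> owners;
  for (int dr = -rad; dr <= rad; ++dr) {
    int r = r0 + dr;
    if (r < 0 || r >= nrow) continue;
    for (int dc = -rad; dc <= rad; ++dc) {
      int c = c0 + dc;
      if (c < 0 || c >= ncol) continue;
      if ((double)(dr * dr + dc * dc) > r2) continue;
      int o = occ[cell_of(r, c, ncol)];
      if (o != 0) owners.insert(o);
    }
  }
  return wrap(std::vector<int>(owners.begin(), owners.end()));
}

// Take from the loser the highest-prey cell that borders the winner's
// territory, is not the loser's origin, and whose removal keeps the loser's
// territory connected. Ties broken at random. Returns the 1-based cell taken
// (occ updated in place) or 0 if no cell qualifies.
// [[Rcpp::export]]
int cpp_take_border_cell(IntegerVector occ, NumericVector prey, int nrow,
                         int ncol, IntegerVector loser_cells, int loser_origin,
                         int winner, int loser) {
  std::vector<int> terr(loser_cells.begin(), loser_cells.end());
  if (terr.size() <= 1) return 0;
  std::vector<char> is_cut;
  find_cut_vertices(terr, occ, loser, nrow, ncol, is_cut);
  double best = R_NegInf;
  int pick = -1, nties = 0;
  for (size_t i = 0; i < terr.size(); ++i) {
    int cell = terr[i];
    if (cell == loser_origin || is_cut[i]) continue;
    int k = cell - 1;
    int r = k / ncol, c = k % ncol;
    bool border = false;
    for (int j = 0; j < 8 && !border; ++j) {
      int rr = r + DR[j], cc = c + DC[j];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      if (occ[cell_of(rr, cc, ncol)] == winner) border = true;
    }
    if (!border) continue;
    if (prey[k] > best) {
      best = prey[k];
      pick = cell;
      nties = 1;
    } else if (prey[k] == best) {
      ++nties;
      if (R::unif_rand() < 1.0 / nties) pick = cell;
    }
  }
  if (pick < 0) return 0;
  occ[pick - 1] = winner;
  return pick;
}
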