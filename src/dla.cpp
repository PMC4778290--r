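#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline bool in_grid(int r, int c, int nr, int nc) {
  return r >= 0 && c >= 0 && r < nr && c < nc;
}

// any cell of the dp x dp footprint anchored at (r, c) 8-adjacent to (or on)
// an occupied cell?
static bool touches_cluster(const IntegerMatrix &occ, int r, int c, int dp) {
  int nr = occ.nrow(), nc = occ.ncol();
  for (int i = r - 1; i <= r + dp; ++i)
    for (int j = c - 1; j <= c + dp; ++j)
      if (in_grid(i, j, nr, nc) && occ(i, j)) return true;
  return false;
}

static int stamp(IntegerMatrix &occ, const LogicalMatrix &domain, int r,
                 int c, int dp) {
  int nr = occ.nrow(), nc = occ.ncol(), added = 0;
  for (int i = r; i < r + dp; ++i)
    for (int j = c; j < c + dp; ++j)
      if (in_grid(i, j, nr, nc) && domain(i, j) && !occ(i, j)) {
        occ(i, j) = 1;
        ++added;
      }
  return added;
}

// Sequential on-lattice DLA aggregation. Walkers launch at uniformly random
// free in-domain cells; each step is an 8-neighbour move of length dp, taken
// toward the nucleus with probability `bias` and uniformly at random
// otherwise. A walker leaving the domain, or exceeding max_steps, is
// relaunched. It sticks (stamps its dp x dp footprint) as soon as any
// footprint cell is 8-adjacent to the cluster. Uses the R RNG stream.
// [[Rcpp::export]]
IntegerMatrix dla_aggregate_cpp(LogicalMatrix domain, int n_particles, int dp,
                                int nuc_r, int nuc_c, double bias,
                                int max_steps) {
  int nr = domain.nrow(), nc = domain.ncol();
  if (!in_grid(nuc_r, nuc_c, nr, nc) || !domain(nuc_r, nuc_c))
    stop("nucleus lies outside the walk domain");
  IntegerMatrix occ(nr, nc);
  int n_domain = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (domain(i, j)) ++n_domain;
  int occupied = stamp(occ, domain, nuc_r, nuc_c, dp);

  for (int p = 0; p < n_particles; ++p) {
    if (occupied >= n_domain) {  // domain full: stop attaching
      warning("walk domain saturated after %d of %d particles", p,
              n_particles);
      break;
    }
    bool placed = false;
    int relaunches = 0;
    while (!placed) {
      if (++relaunches > 200000) stop("DLA walker failed to attach");
      int r, c, tries = 0;
      for (;;) {  // launch at a free in-domain cell
        r = (int)(unif_rand() * nr);
        if (r >= nr) r = nr - 1;
        c = (int)(unif_rand() * nc);
        if (c >= nc) c = nc - 1;
        if (domain(r, c) && !occ(r, c)) break;
        if (++tries > 200000) stop("walk domain is saturated");
      }
      for (int steps = 0; steps <= max_steps; ++steps) {
        if (touches_cluster(occ, r, c, dp)) {
          occupied += stamp(occ, domain, r, c, dp);
          placed = true;
          break;
        }
        int k;
        if (unif_rand() < bias) {  // centre-seeking move
          double best = R_PosInf;
          k = 0;
          for (int m = 0; m < 8; ++m) {
            double rr = r + dp * DR8[m] - nuc_r;
            double cc = c + dp * DC8[m] - nuc_c;
            double d2 = rr * rr + cc * cc;
            if (d2 < best) {
              best = d2;
              k = m;
            }
          }
        } else {
          k = (int)(unif_rand() * 8);
          if (k > 7) k = 7;
        }
        int r2 = r + dp * DR8[k], c2 = c + dp * DC8[k];
        if (!in_grid(r2, c2, nr, nc) || !domain(r2, c2)) break;  // relaunch
        r = r2;
        c = c2;
      }
    }
  }
  return occ;
}

// Sinusoid cells (label 2) 8-connected to any seed cell. labels: 0 outside,
// 1 tissue, 2 sinusoid; seeds are 0-based (row, col) pairs.
// [[Rcpp::export]]
LogicalMatrix reachable_sinusoid_cpp(IntegerMatrix labels,
                                     IntegerMatrix seeds) {
  int nr = labels.nrow(), nc = labels.ncol();
  LogicalMatrix vis(nr, nc);
  std::deque<int> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int r = seeds(s, 0), c = seeds(s, 1);
    if (in_grid(r, c, nr, nc) && labels(r, c) == 2 && !vis(r, c)) {
      vis(r, c) = true;
      q.push_back(r + c * nr);
    }
  }
  while (!q.empty()) {
    int u = q.front();
    q.pop_front();
    int r = u % nr, c = u / nr;
    for (int m = 0; m < 8; ++m) {
      int r2 = r + DR8[m], c2 = c + DC8[m];
      if (in_grid(r2, c2, nr, nc) && labels(r2, c2) == 2 && !vis(r2, c2)) {
        vis(r2, c2) = true;
        q.push_back(r2 + c2 * nr);
      }
    }
  }
  return vis;
}

// Bridge every sinusoid cell not 8-connected to the seed component onto it by
// a thin path of newly labeled sinusoid cells. A 0-1 BFS over active cells
// (cost 0 through sinusoid, 1 through tissue) from the seed component makes
// bridges follow the existing network and add as few new cells as possible.
// Returns the repaired label matrix and the number of converted cells.
// [[Rcpp::export]]
List repair_connectivity_cpp(IntegerMatrix labels, IntegerMatrix seeds) {
  int nr = labels.nrow(), nc = labels.ncol();
  LogicalMatrix main_set = reachable_sinusoid_cpp(labels, seeds);

  std::vector<int> dist(nr * nc, -1), parent(nr * nc, -1);
  std::deque<int> q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (main_set(r, c)) {
        dist[r + c * nr] = 0;
        q.push_back(r + c * nr);
      }
  while (!q.empty()) {
    int u = q.front();
    q.pop_front();
    int r = u % nr, c = u / nr;
    for (int m = 0; m < 8; ++m) {
      int r2 = r + DR8[m], c2 = c + DC8[m];
      if (!in_grid(r2, c2, nr, nc) || labels(r2, c2) == 0) continue;
      int v = r2 + c2 * nr;
      int w = (labels(r2, c2) == 2) ? 0 : 1;
      if (dist[v] < 0 || dist[u] + w < dist[v]) {
        dist[v] = dist[u] + w;
        parent[v] = u;
        if (w == 0)
          q.push_front(v);
        else
          q.push_back(v);
      }
    }
  }

  int bridged = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (labels(r, c) != 2 || main_set(r, c)) continue;
      int v = r + c * nr;
      if (dist[v] < 0)
        stop("sinusoid cell unreachable through the active lattice");
      while (v >= 0 && !main_set(v % nr, v / nr)) {
        int rr = v % nr, cc = v / nr;
        if (labels(rr, cc) == 1) {
          labels(rr, cc) = 2;
          ++bridged;
        }
        main_set(rr, cc) = true;
        v = parent[v];
      }
    }
  return List::create(_["labels"] = labels, _["n_bridged"] = bridged);
}
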