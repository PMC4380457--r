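// Kinetic Monte Carlo simulation of birth-death (Yule) trees with Bernoulli
// leaf sampling, plus genealogy-based extraction of pair-distance statistics.
//
// All randomness goes through R's RNG (unif_rand / exp_rand), so results are
// fully determined by set.seed() on the R side.
//
// Node bookkeeping: nodes are created in birth order, so a child's index is
// always larger than its parent's; post-order accumulations can therefore
// run as a single reverse sweep over the node arrays.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

enum NodeKind { SPLIT = 0, DEATH = 1, EXTANT = 2 };

struct Tree {
  std::vector<int> parent;    // -1 for root
  std::vector<double> t_birth;
  std::vector<double> t_end;  // split/death time, or height for extant
  std::vector<int> kind;
  std::vector<int> child1, child2;  // -1 unless split
  std::vector<int> observed;        // 0/1, extant leaves only
};

static void add_node(Tree& tr, int parent, double t_birth, double height) {
  tr.parent.push_back(parent);
  tr.t_birth.push_back(t_birth);
  tr.t_end.push_back(height);
  tr.kind.push_back(EXTANT);
  tr.child1.push_back(-1);
  tr.child2.push_back(-1);
  tr.observed.push_back(0);
}

static Tree simulate_one(double lambda, double mu, double sigma,
                         double height, int cap) {
  Tree tr;
  add_node(tr, -1, 0.0, height);
  std::vector<int> alive;
  alive.push_back(0);
  double rate = lambda + mu;
  double t = 0.0;
  while (rate > 0.0 && !alive.empty()) {
    double m = static_cast<double>(alive.size());
    double dt = exp_rand() / (m * rate);
    if (t + dt > height) break;  // freeze state at height
    t += dt;
    int i = static_cast<int>(unif_rand() * m);
    if (i >= static_cast<int>(alive.size())) i = alive.size() - 1;
    int node = alive[i];
    tr.t_end[node] = t;
    if (unif_rand() * rate < lambda) {
      tr.kind[node] = SPLIT;
      add_node(tr, node, t, height);
      add_node(tr, node, t, height);
      int n = tr.parent.size();
      tr.child1[node] = n - 2;
      tr.child2[node] = n - 1;
      alive[i] = n - 2;
      alive.push_back(n - 1);
      if (static_cast<int>(alive.size()) > cap)
        stop("lineage cap exceeded (cap = %d): explosive growth, "
             "reduce lambda*height or raise the cap", cap);
    } else {
      tr.kind[node] = DEATH;
      alive[i] = alive.back();
      alive.pop_back();
    }
  }
  for (size_t j = 0; j < alive.size(); ++j)
    tr.observed[alive[j]] = (unif_rand() < sigma) ? 1 : 0;
  return tr;
}

// counts of observed descendants per node (reverse sweep)
static void obs_counts(const Tree& tr, std::vector<int>& cnt) {
  int n = tr.parent.size();
  cnt.assign(n, 0);
  for (int i = n - 1; i >= 0; --i) {
    if (tr.kind[i] == EXTANT) cnt[i] = tr.observed[i];
    else if (tr.kind[i] == SPLIT) cnt[i] = cnt[tr.child1[i]] + cnt[tr.child2[i]];
  }
}

// [[Rcpp::export]]
List sim_tree_cpp(double lambda, double mu, double sigma, double height,
                  int cap) {
  Tree tr = simulate_one(lambda, mu, sigma, height, cap);
  int n = tr.parent.size();
  IntegerVector parent(n), kind(n), observed(n);
  NumericVector tb(n), te(n);
  for (int i = 0; i < n; ++i) {
    parent[i] = tr.parent[i] < 0 ? NA_INTEGER : tr.parent[i] + 1;
    tb[i] = tr.t_birth[i];
    te[i] = tr.t_end[i];
    kind[i] = tr.kind[i];
    observed[i] = tr.observed[i];
  }
  return List::create(_["parent"] = parent, _["t_birth"] = tb,
                      _["t_end"] = te, _["kind"] = kind,
                      _["observed"] = observed);
}

struct BinGrid {
  double lo, w;
  int nb;
  BinGrid(const NumericVector& edges) {
    lo = edges[0];
    nb = edges.size() - 1;
    w = (edges[nb] - lo) / nb;
  }
  // half-open bins [l, r), last bin closed
  int index(double x) const {
    if (x < lo) return -1;
    int b = static_cast<int>((x - lo) / w);
    if (b == nb && x <= lo + nb * w + 1e-12 * w) b = nb - 1;
    return (b >= 0 && b < nb) ? b : -1;
  }
};

// nearest-neighbour distance of each observed leaf (2*(height - split time)
// of the first ancestor with an observed leaf on the other side); leaves
// alone on the tree get no value (handled by caller)
static void nn_distances(const Tree& tr, const std::vector<int>& cnt,
                         double height, std::vector<double>& nn) {
  nn.clear();
  int n = tr.parent.size();
  for (int L = 0; L < n; ++L) {
    if (tr.kind[L] != EXTANT || !tr.observed[L]) continue;
    int v = L;
    while (tr.parent[v] >= 0) {
      int p = tr.parent[v];
      if (cnt[p] - cnt[v] > 0) {
        nn.push_back(2.0 * (height - tr.t_end[p]));
        break;
      }
      v = p;
    }
  }
}

// per-tree statistic values accumulated into per-tree bin counts
static void tree_bin_counts(const Tree& tr, double height, const BinGrid& grid,
                            const std::vector<int>& nmin_orders,
                            bool do_pairwise, bool do_cherry, bool do_min2,
                            std::vector< std::vector<double> >& tree_counts) {
  std::vector<int> cnt;
  obs_counts(tr, cnt);
  int n = tr.parent.size();
  int stat = 0;
  if (do_pairwise) {
    std::vector<double>& tc = tree_counts[stat++];
    for (int i = 0; i < n; ++i) {
      if (tr.kind[i] != SPLIT) continue;
      double np = static_cast<double>(cnt[tr.child1[i]]) * cnt[tr.child2[i]];
      if (np <= 0) continue;
      int b = grid.index(2.0 * (height - tr.t_end[i]));
      if (b >= 0) tc[b] += np;
    }
  }
  for (size_t k = 0; k < nmin_orders.size(); ++k) {
    std::vector<double>& tc = tree_counts[stat++];
    int ord = nmin_orders[k];
    for (int L = 0; L < n; ++L) {
      if (tr.kind[L] != EXTANT || !tr.observed[L]) continue;
      int v = L, cum = 0;
      while (tr.parent[v] >= 0) {
        int p = tr.parent[v];
        int sib = cnt[p] - cnt[v];
        if (cum + sib >= ord) {  // ord-th neighbour sits at this depth
          int b = grid.index(2.0 * (height - tr.t_end[p]));
          if (b >= 0) tc[b] += 1.0;
          break;
        }
        cum += sib;
        v = p;
      }
    }
  }
  if (do_cherry) {
    std::vector<double>& tc = tree_counts[stat++];
    for (int i = 0; i < n; ++i) {
      if (tr.kind[i] != SPLIT) continue;
      if (cnt[tr.child1[i]] == 1 && cnt[tr.child2[i]] == 1) {
        int b = grid.index(2.0 * (height - tr.t_end[i]));
        if (b >= 0) tc[b] += 1.0;
      }
    }
  }
  if (do_min2) {
    std::vector<double>& tc = tree_counts[stat++];
    std::vector<double> nn;
    nn_distances(tr, cnt, height, nn);
    int M = nn.size();
    if (M >= 2) {
      std::sort(nn.begin(), nn.end());
      // the k-th smallest NN distance is the pair minimum for all pairs
      // formed with the M-k leaves that have larger NN distances
      for (int k = 0; k < M - 1; ++k) {
        int b = grid.index(nn[k]);
        if (b >= 0) tc[b] += static_cast<double>(M - 1 - k);
      }
    }
  }
}

// [[Rcpp::export]]
List ensemble_hist_cpp(double lambda, double mu, double sigma, double height,
                       int S, NumericVector edges, IntegerVector nmin_orders,
                       bool do_pairwise, bool do_cherry, bool do_min2,
                       int cap, bool do_cov) {
  BinGrid grid(edges);
  std::vector<int> orders(nmin_orders.begin(), nmin_orders.end());
  int nstat = (do_pairwise ? 1 : 0) + orders.size() +
              (do_cherry ? 1 : 0) + (do_min2 ? 1 : 0);
  NumericMatrix counts(grid.nb, nstat), sumsq(grid.nb, nstat);
  IntegerMatrix nonzero(grid.nb, nstat);
  NumericVector total(nstat), totalsq(nstat);  // per-tree totals and squares
  // raw second-moment matrices of the per-tree bin-count vectors, one
  // nb x nb block per statistic (for covariance-aware ensemble tests)
  NumericVector covacc(do_cov ? nstat * grid.nb * grid.nb : 0);
  std::vector<int> m_tally(1, 0);  // observed leaf-count frequencies
  std::vector< std::vector<double> > tree_counts(nstat);
  std::vector<int> nz_bins;

  for (int s = 0; s < S; ++s) {
    if (s % 256 == 0) checkUserInterrupt();
    Tree tr = simulate_one(lambda, mu, sigma, height, cap);
    std::vector<int> cnt;
    obs_counts(tr, cnt);
    int M = cnt.empty() ? 0 : cnt[0];
    if (M >= static_cast<int>(m_tally.size())) m_tally.resize(M + 1, 0);
    m_tally[M] += 1;
    for (int k = 0; k < nstat; ++k) tree_counts[k].assign(grid.nb, 0.0);
    tree_bin_counts(tr, height, grid, orders, do_pairwise, do_cherry,
                    do_min2, tree_counts);
    for (int k = 0; k < nstat; ++k) {
      double tot = 0.0;
      nz_bins.clear();
      for (int b = 0; b < grid.nb; ++b) {
        double c = tree_counts[k][b];
        if (c > 0) {
          counts(b, k) += c;
          sumsq(b, k) += c * c;
          nonzero(b, k) += 1;
          tot += c;
          nz_bins.push_back(b);
        }
      }
      total[k] += tot;
      totalsq[k] += tot * tot;
      if (do_cov) {
        double* blk = covacc.begin() +
          static_cast<size_t>(k) * grid.nb * grid.nb;
        for (size_t i = 0; i < nz_bins.size(); ++i)
          for (size_t j = 0; j < nz_bins.size(); ++j)
            blk[nz_bins[i] * grid.nb + nz_bins[j]] +=
              tree_counts[k][nz_bins[i]] * tree_counts[k][nz_bins[j]];
      }
    }
  }
  return List::create(_["counts"] = counts, _["sumsq"] = sumsq,
                      _["nonzero"] = nonzero,
                      _["total"] = total, _["totalsq"] = totalsq,
                      _["covacc"] = covacc,
                      _["m_tally"] = IntegerVector(m_tally.begin(),
                                                   m_tally.end()));
}

// [[Rcpp::export]]
IntegerVector occupancy_cpp(double lambda, double mu, double sigma,
                            double height, int S, double t, double dt,
                            int nmax, int cap) {
  // tally of the number of observed pairs with distance in [t, t+dt)
  // per tree; index nmax+1 collects overflow
  IntegerVector tally(nmax + 2);
  for (int s = 0; s < S; ++s) {
    if (s % 256 == 0) checkUserInterrupt();
    Tree tr = simulate_one(lambda, mu, sigma, height, cap);
    std::vector<int> cnt;
    obs_counts(tr, cnt);
    long npairs = 0;
    int n = tr.parent.size();
    for (int i = 0; i < n; ++i) {
      if (tr.kind[i] != SPLIT) continue;
      double d = 2.0 * (height - tr.t_end[i]);
      if (d >= t && d < t + dt)
        npairs += static_cast<long>(cnt[tr.child1[i]]) * cnt[tr.child2[i]];
    }
    if (npairs > nmax) tally[nmax + 1] += 1;
    else tally[npairs] += 1;
  }
  return tally;
}
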