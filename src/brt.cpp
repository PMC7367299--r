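#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Regression-tree nodes are stored row-wise in a numeric matrix:
//   col 0: split column (1-based; 0 for a leaf)
//   col 1: threshold (continuous/ordered splits; NA for nominal)
//   col 2: level bitmask for nominal splits (bit l-1 set => level l goes left)
//   col 3: 1 if missing values are routed left, 0 if right
//   col 4: left child row (1-based; 0 for a leaf)
//   col 5: right child row
//   col 6: node mean (the prediction at a leaf)
//   col 7: squared-error improvement of the split (0 at a leaf)
//   col 8: number of training rows reaching the node
// This flat layout serialises to JSON/CSV without further translation.

static const int T_COL = 0, T_THR = 1, T_MASK = 2, T_NAL = 3, T_LEFT = 4,
                 T_RIGHT = 5, T_VAL = 6, T_IMP = 7, T_N = 8, T_NCOL = 9;

struct SplitChoice {
  bool found = false;
  int col = -1;                 // 0-based
  double thr = NA_REAL;
  double mask = 0.0;            // nominal level bitmask
  bool is_nominal = false;
  bool na_left = false;
  double gain = 0.0;            // SSE reduction over all node rows
  std::vector<int> left_rows, right_rows;
};

static inline double node_sse(double sum, double sumsq, double n) {
  return n > 0 ? sumsq - sum * sum / n : 0.0;
}

// Evaluate the best split of `rows` (indices into X/y) over all columns.
// Missing values in the split column are routed to the child holding more
// non-missing rows (ties go left); the recorded gain is the SSE reduction
// over *all* node rows under that routing. Ties across candidates keep the
// first maximum, so the lowest column index and lowest threshold win.
static SplitChoice best_split(const NumericMatrix& X, const IntegerVector& kind,
                              const NumericVector& y,
                              const std::vector<int>& rows, int min_obs) {
  SplitChoice best;
  const int p = X.ncol();
  const double EPS = 1e-12;

  double sumA = 0.0, sqA = 0.0;
  for (int r : rows) { sumA += y[r]; sqA += y[r] * y[r]; }
  const double nA = (double)rows.size();
  const double sseA = node_sse(sumA, sqA, nA);

  for (int j = 0; j < p; ++j) {
    std::vector<int> pres, miss;
    pres.reserve(rows.size());
    for (int r : rows) {
      if (ISNAN(X(r, j))) miss.push_back(r); else pres.push_back(r);
    }
    if (pres.size() < 2) continue;
    double sumM = 0.0, sqM = 0.0;
    for (int r : miss) { sumM += y[r]; sqM += y[r] * y[r]; }
    const double nM = (double)miss.size();

    // candidate evaluation shared by every split family
    auto consider = [&](double nL, double sumL, double sqL, double thr,
                       double mask, bool is_nominal) {
      const double nR = (double)pres.size() - nL;
      const double sumR = (sumA - sumM) - sumL, sqR = (sqA - sqM) - sqL;
      if (nL < 1 || nR < 1) return;
      const bool na_left = nL >= nR;
      double nLa = nL, sumLa = sumL, sqLa = sqL;
      double nRa = nR, sumRa = sumR, sqRa = sqR;
      if (na_left) { nLa += nM; sumLa += sumM; sqLa += sqM; }
      else { nRa += nM; sumRa += sumM; sqRa += sqM; }
      if (nLa < min_obs || nRa < min_obs) return;
      const double gain = sseA - node_sse(sumLa, sqLa, nLa)
                               - node_sse(sumRa, sqRa, nRa);
      if (gain > EPS && gain > best.gain + EPS) {
        best.found = true; best.col = j; best.thr = thr; best.mask = mask;
        best.is_nominal = is_nominal; best.na_left = na_left;
        best.gain = gain;
      }
    };

    if (kind[j] == 0) {  // continuous or ordered-categorical (integer codes)
      std::vector<int> ord(pres);
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, j) < X(b, j);
      });
      double sumL = 0.0, sqL = 0.0;
      for (size_t i = 0; i + 1 < ord.size(); ++i) {
        const double yv = y[ord[i]];
        sumL += yv; sqL += yv * yv;
        const double xl = X(ord[i], j), xr = X(ord[i + 1], j);
        if (xl == xr) continue;  // no boundary between equal values
        consider((double)(i + 1), sumL, sqL, 0.5 * (xl + xr), 0.0, false);
      }
    } else {             // nominal: subset search over present levels
      // per-level sufficient statistics
      std::vector<int> levels;
      std::vector<double> lev_n, lev_sum, lev_sq;
      for (int r : pres) {
        const int lv = (int)X(r, j);
        size_t k = 0;
        for (; k < levels.size(); ++k) if (levels[k] == lv) break;
        if (k == levels.size()) {
          levels.push_back(lv);
          lev_n.push_back(0); lev_sum.push_back(0); lev_sq.push_back(0);
        }
        lev_n[k] += 1; lev_sum[k] += y[r]; lev_sq[k] += y[r] * y[r];
      }
      const int m = (int)levels.size();
      if (m < 2) continue;
      if (m <= 10) {
        // exhaustive: local level 0 pinned to the right avoids complements;
        // ascending masks give the lowest-mask tie-break
        // order local levels by code so masks are canonical
        std::vector<int> ordlev(m);
        for (int k = 0; k < m; ++k) ordlev[k] = k;
        std::sort(ordlev.begin(), ordlev.end(), [&](int a, int b) {
          return levels[a] < levels[b];
        });
        const long top = 1L << (m - 1);
        for (long s = 1; s < top; ++s) {
          double nL = 0, sumL = 0, sqL = 0, mask = 0;
          for (int b = 0; b < m - 1; ++b) {
            if (s & (1L << b)) {
              const int k = ordlev[b + 1];  // ordlev[0] stays right
              nL += lev_n[k]; sumL += lev_sum[k]; sqL += lev_sq[k];
              mask += std::ldexp(1.0, levels[k] - 1);
            }
          }
          consider(nL, sumL, sqL, NA_REAL, mask, true);
        }
      } else {
        // mean-ordered scan (CART shortcut for many levels)
        std::vector<int> ordlev(m);
        for (int k = 0; k < m; ++k) ordlev[k] = k;
        std::sort(ordlev.begin(), ordlev.end(), [&](int a, int b) {
          const double ma = lev_sum[a] / lev_n[a], mb = lev_sum[b] / lev_n[b];
          if (ma != mb) return ma < mb;
          return levels[a] < levels[b];
        });
        double nL = 0, sumL = 0, sqL = 0, mask = 0;
        for (int i = 0; i + 1 < m; ++i) {
          const int k = ordlev[i];
          nL += lev_n[k]; sumL += lev_sum[k]; sqL += lev_sq[k];
          mask += std::ldexp(1.0, levels[k] - 1);
          consider(nL, sumL, sqL, NA_REAL, mask, true);
        }
      }
    }
  }

  if (best.found) {  // materialise the row partition for the chosen split
    std::vector<int> pres_left, pres_right, miss;
    for (int r : rows) {
      const double v = X(r, best.col);
      if (ISNAN(v)) { miss.push_back(r); continue; }
      bool left;
      if (best.is_nominal) {
        const long long bit = 1LL << ((int)v - 1);
        left = ((long long)best.mask & bit) != 0;
      } else left = v < best.thr;
      (left ? pres_left : pres_right).push_back(r);
    }
    best.left_rows = pres_left; best.right_rows = pres_right;
    auto& side = best.na_left ? best.left_rows : best.right_rows;
    side.insert(side.end(), miss.begin(), miss.end());
  }
  return best;
}

struct BuildNode {
  std::vector<int> rows;
  double mean = 0.0;
  SplitChoice split;
  bool open = true;   // still a leaf eligible for splitting
  int mat_row = -1;
};

// Grow one least-squares regression tree by best-first splitting: at each of
// at most `max_splits` steps the leaf offering the largest SSE reduction is
// split (earliest-created leaf wins ties).
static NumericMatrix grow_tree(const NumericMatrix& X, const IntegerVector& kind,
                               const NumericVector& y,
                               const std::vector<int>& rows,
                               int max_splits, int min_obs) {
  std::vector<BuildNode> nodes;
  {
    BuildNode root; root.rows = rows;
    double s = 0; for (int r : rows) s += y[r];
    root.mean = rows.empty() ? 0.0 : s / rows.size();
    root.split = best_split(X, kind, y, rows, min_obs);
    nodes.push_back(std::move(root));
  }
  std::vector<std::array<int, 2>> children(1, {-1, -1});

  for (int step = 0; step < max_splits; ++step) {
    int pick = -1; double gbest = 0.0;
    for (size_t i = 0; i < nodes.size(); ++i)
      if (nodes[i].open && nodes[i].split.found &&
          nodes[i].split.gain > gbest + 1e-12) {
        gbest = nodes[i].split.gain; pick = (int)i;
      }
    if (pick < 0) break;
    BuildNode& nd = nodes[pick];
    nd.open = false;
    for (int side = 0; side < 2; ++side) {
      BuildNode ch;
      ch.rows = side == 0 ? nd.split.left_rows : nd.split.right_rows;
      double s = 0; for (int r : ch.rows) s += y[r];
      ch.mean = ch.rows.empty() ? nd.mean : s / ch.rows.size();
      ch.split = best_split(X, kind, y, ch.rows, min_obs);
      children.push_back({-1, -1});
      children[pick][side] = (int)nodes.size();
      nodes.push_back(std::move(ch));
    }
  }

  NumericMatrix M((int)nodes.size(), T_NCOL);
  for (size_t i = 0; i < nodes.size(); ++i) {
    const BuildNode& nd = nodes[i];
    const bool leaf = children[i][0] < 0;
    M(i, T_COL) = leaf ? 0 : nd.split.col + 1;
    M(i, T_THR) = leaf ? NA_REAL : nd.split.thr;
    M(i, T_MASK) = leaf ? 0 : nd.split.mask;
    M(i, T_NAL) = leaf ? 0 : (nd.split.na_left ? 1 : 0);
    M(i, T_LEFT) = leaf ? 0 : children[i][0] + 1;
    M(i, T_RIGHT) = leaf ? 0 : children[i][1] + 1;
    M(i, T_VAL) = nd.mean;
    M(i, T_IMP) = leaf ? 0 : nd.split.gain;
    M(i, T_N) = (double)nd.rows.size();
  }
  return M;
}

// Predict one row, optionally clamping columns in `clamp_cols` (0-based) to
// `clamp_vals` — used for partial dependence.
static double predict_row(const NumericMatrix& tree, const NumericMatrix& X,
                          int row, const std::vector<int>& clamp_cols,
                          const std::vector<double>& clamp_vals) {
  int node = 0;
  while ((int)tree(node, T_COL) != 0) {
    const int j = (int)tree(node, T_COL) - 1;
    double v = X(row, j);
    for (size_t k = 0; k < clamp_cols.size(); ++k)
      if (clamp_cols[k] == j) v = clamp_vals[k];
    bool left;
    if (ISNAN(v)) {
      left = tree(node, T_NAL) != 0;
    } else if (!ISNAN(tree(node, T_THR))) {
      left = v < tree(node, T_THR);
    } else {
      const long long bit = 1LL << ((int)v - 1);
      left = ((long long)tree(node, T_MASK) & bit) != 0;
    }
    node = (int)tree(node, left ? T_LEFT : T_RIGHT) - 1;
  }
  return tree(node, T_VAL);
}

// [[Rcpp::export(name = ".fit_tree_cpp")]]
NumericMatrix fit_tree_cpp(NumericMatrix X, IntegerVector kind, NumericVector y,
                           IntegerVector rows, int max_splits, int min_obs) {
  std::vector<int> rr(rows.begin(), rows.end());  // 0-based from R wrapper
  return grow_tree(X, kind, y, rr, max_splits, min_obs);
}

// Stagewise least-squares boosting. `pred`/`pred_test` carry the running
// ensemble predictions in and out so cross-validation folds can grow in
// chunks; bagging consumes R's RNG stream (set.seed reproducible).
// [[Rcpp::export(name = ".boost_cpp")]]
List boost_cpp(NumericMatrix X, IntegerVector kind, NumericVector y,
               NumericVector pred, Nullable<NumericMatrix> X_test,
               Nullable<NumericVector> pred_test, int n_trees,
               double learning_rate, double bag_fraction, int max_splits,
               int min_obs) {
  const int n = X.nrow();
  NumericVector pr = clone(pred);
  NumericMatrix Xt;
  NumericVector prt;
  const bool has_test = X_test.isNotNull();
  if (has_test) { Xt = NumericMatrix(X_test); prt = clone(NumericVector(pred_test)); }

  List trees(n_trees);
  NumericVector train_dev(n_trees);
  NumericVector resid(n);
  std::vector<int> perm(n);
  const int bag_n = bag_fraction >= 1.0 ? n
                    : std::max(2, (int)std::floor(bag_fraction * n));
  const std::vector<int> no_clamp_c; const std::vector<double> no_clamp_v;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pr[i];
    std::vector<int> bag;
    if (bag_n >= n) {
      bag.resize(n);
      for (int i = 0; i < n; ++i) bag[i] = i;
    } else {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = 0; i < bag_n; ++i) {  // partial Fisher-Yates via R's RNG
        const int j = i + (int)std::floor(unif_rand() * (n - i));
        std::swap(perm[i], perm[std::min(j, n - 1)]);
      }
      bag.assign(perm.begin(), perm.begin() + bag_n);
      std::sort(bag.begin(), bag.end());
    }
    NumericMatrix tr = grow_tree(X, kind, resid, bag, max_splits, min_obs);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      pr[i] += learning_rate * predict_row(tr, X, i, no_clamp_c, no_clamp_v);
      const double e = y[i] - pr[i];
      sse += e * e;
    }
    if (has_test)
      for (int i = 0; i < Xt.nrow(); ++i)
        prt[i] += learning_rate * predict_row(tr, Xt, i, no_clamp_c, no_clamp_v);
    trees[t] = tr;
    train_dev[t] = sse / n;
  }

  List out = List::create(_["trees"] = trees, _["pred"] = pr,
                          _["train_deviance"] = train_dev);
  if (has_test) out["pred_test"] = prt;
  return out;
}

// [[Rcpp::export(name = ".predict_trees_cpp")]]
NumericVector predict_trees_cpp(List trees, NumericMatrix X,
                                double learning_rate, double init,
                                int n_trees) {
  const int n = X.nrow();
  NumericVector out(n, init);
  const std::vector<int> cc; const std::vector<double> cv;
  const int nt = std::min(n_trees, (int)trees.size());
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i)
      out[i] += learning_rate * predict_row(tr, X, i, cc, cv);
  }
  return out;
}

// Partial dependence: average prediction over the observed rows with the
// given columns clamped to each grid point (grid is g x length(cols)).
// [[Rcpp::export(name = ".partial_dependence_cpp")]]
NumericVector partial_dependence_cpp(List trees, NumericMatrix X,
                                     double learning_rate, double init,
                                     int n_trees, IntegerVector cols,
                                     NumericMatrix grid) {
  const int n = X.nrow(), g = grid.nrow(), q = cols.size();
  const int nt = std::min(n_trees, (int)trees.size());
  NumericVector out(g);
  std::vector<int> cc(q);
  for (int k = 0; k < q; ++k) cc[k] = cols[k] - 1;
  std::vector<NumericMatrix> tr;
  tr.reserve(nt);
  for (int t = 0; t < nt; ++t) tr.push_back(as<NumericMatrix>(trees[t]));
  for (int gi = 0; gi < g; ++gi) {
    std::vector<double> cv(q);
    for (int k = 0; k < q; ++k) cv[k] = grid(gi, k);
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double p = init;
      for (int t = 0; t < nt; ++t)
        p += learning_rate * predict_row(tr[t], X, i, cc, cv);
      acc += p;
    }
    out[gi] = acc / n;
  }
  return out;
}
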