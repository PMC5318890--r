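#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Best-first regression-tree growth for gradient boosting.
//
// Split search: candidates are midpoints between consecutive distinct sorted
// values of each predictor; the split maximising the between-group sum of
// squares (equivalently minimising total within-node SSE) wins. Ties in
// improvement break toward the lowest variable index, then the lowest
// threshold, by scanning variables and thresholds in ascending order and
// replacing only on strict improvement.

struct NodeRows {
  std::vector<int> rows;  // 0-based row indices into X
  int node_id;
  int best_var;           // -1 when no admissible split
  double best_thr;
  double best_imp;
  int order;              // creation order, tie-break for frontier choice
};

static void find_best_split(const NumericMatrix& X, const NumericVector& r,
                            const std::vector<int>& rows, int min_node,
                            int& bvar, double& bthr, double& bimp) {
  bvar = -1; bthr = 0.0; bimp = 0.0;
  const int m = rows.size();
  if (m < 2 * min_node) return;
  double S = 0.0;
  for (int i = 0; i < m; ++i) S += r[rows[i]];
  const double base = S * S / m;
  const int p = X.ncol();
  std::vector<std::pair<double, double> > xv(m);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < m; ++i)
      xv[i] = std::make_pair(X(rows[i], j), r[rows[i]]);
    std::sort(xv.begin(), xv.end());
    double SL = 0.0;
    for (int k = 0; k < m - 1; ++k) {
      SL += xv[k].second;
      if (xv[k].first == xv[k + 1].first) continue;
      const int nL = k + 1, nR = m - nL;
      if (nL < min_node || nR < min_node) continue;
      const double SR = S - SL;
      const double imp = SL * SL / nL + SR * SR / nR - base;
      if (imp > bimp) {
        bimp = imp;
        bvar = j;
        bthr = 0.5 * (xv[k].first + xv[k + 1].first);
      }
    }
  }
  if (bimp <= 0.0) bvar = -1;
}

// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, NumericVector r, IntegerVector rows0,
                  int max_splits, int min_node) {
  std::vector<int> root_rows(rows0.begin(), rows0.end());
  const int m = root_rows.size();
  double mean0 = 0.0;
  for (int i = 0; i < m; ++i) mean0 += r[root_rows[i]];
  mean0 = (m > 0) ? mean0 / m : 0.0;

  // node arrays (grown as splits happen)
  std::vector<int> var(1, -1), left(1, -1), right(1, -1);
  std::vector<double> thr(1, 0.0), pred(1, mean0), imp(1, 0.0);

  std::vector<NodeRows> frontier;
  NodeRows root;
  root.rows = root_rows; root.node_id = 0; root.order = 0;
  find_best_split(X, r, root.rows, min_node, root.best_var, root.best_thr,
                  root.best_imp);
  frontier.push_back(root);
  int order_counter = 1;

  for (int s = 0; s < max_splits; ++s) {
    // pick frontier leaf with largest improvement; tie -> earliest created
    int pick = -1;
    for (size_t i = 0; i < frontier.size(); ++i) {
      if (frontier[i].best_var < 0) continue;
      if (pick < 0 || frontier[i].best_imp > frontier[pick].best_imp ||
          (frontier[i].best_imp == frontier[pick].best_imp &&
           frontier[i].order < frontier[pick].order))
        pick = (int)i;
    }
    if (pick < 0) break;
    NodeRows nd = frontier[pick];
    frontier.erase(frontier.begin() + pick);

    const int id = nd.node_id;
    var[id] = nd.best_var;
    thr[id] = nd.best_thr;
    imp[id] = nd.best_imp;

    NodeRows lo, hi;
    for (size_t i = 0; i < nd.rows.size(); ++i) {
      if (X(nd.rows[i], nd.best_var) < nd.best_thr)
        lo.rows.push_back(nd.rows[i]);
      else
        hi.rows.push_back(nd.rows[i]);
    }
    double ml = 0.0, mh = 0.0;
    for (size_t i = 0; i < lo.rows.size(); ++i) ml += r[lo.rows[i]];
    for (size_t i = 0; i < hi.rows.size(); ++i) mh += r[hi.rows[i]];
    ml /= lo.rows.size();
    mh /= hi.rows.size();

    lo.node_id = (int)var.size();
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    thr.push_back(0.0); pred.push_back(ml); imp.push_back(0.0);
    hi.node_id = (int)var.size();
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    thr.push_back(0.0); pred.push_back(mh); imp.push_back(0.0);
    left[id] = lo.node_id;
    right[id] = hi.node_id;

    lo.order = order_counter++;
    hi.order = order_counter++;
    find_best_split(X, r, lo.rows, min_node, lo.best_var, lo.best_thr,
                    lo.best_imp);
    find_best_split(X, r, hi.rows, min_node, hi.best_var, hi.best_thr,
                    hi.best_imp);
    frontier.push_back(lo);
    frontier.push_back(hi);
  }

  const int nn = (int)var.size();
  IntegerVector v(nn), l(nn), rg(nn);
  NumericVector t(nn), pr(nn), im(nn);
  for (int i = 0; i < nn; ++i) {
    v[i] = (var[i] < 0) ? NA_INTEGER : var[i] + 1;  // 1-based for R
    l[i] = (left[i] < 0) ? NA_INTEGER : left[i] + 1;
    rg[i] = (right[i] < 0) ? NA_INTEGER : right[i] + 1;
    t[i] = thr[i]; pr[i] = pred[i]; im[i] = imp[i];
  }
  return List::create(_["var"] = v, _["threshold"] = t, _["left"] = l,
                      _["right"] = rg, _["pred"] = pr,
                      _["improvement"] = im);
}

static double predict_one(const IntegerVector& var, const NumericVector& thr,
                          const IntegerVector& left, const IntegerVector& right,
                          const NumericVector& pred, const NumericMatrix& X,
                          int i) {
  int node = 0;
  while (var[node] != NA_INTEGER) {
    if (X(i, var[node] - 1) < thr[node])
      node = left[node] - 1;
    else
      node = right[node] - 1;
  }
  return pred[node];
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["threshold"], pred = tree["pred"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = predict_one(var, thr, left, right, pred, X, i);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_ensemble(List trees, NumericMatrix X, double init,
                                   double shrinkage, int n_trees) {
  const int n = X.nrow();
  NumericVector out(n, init);
  for (int t = 0; t < n_trees; ++t) {
    List tree = trees[t];
    IntegerVector var = tree["var"], left = tree["left"],
                  right = tree["right"];
    NumericVector thr = tree["threshold"], pred = tree["pred"];
    for (int i = 0; i < n; ++i)
      out[i] += shrinkage * predict_one(var, thr, left, right, pred, X, i);
  }
  return out;
}
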