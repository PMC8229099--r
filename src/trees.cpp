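// CART-style trees grown on a variance-reduction criterion. For 0/1
// responses this is equivalent to Gini impurity (gini = 2 p (1-p)), so a
// single split rule serves classification, bagged forests, and the
// regression trees used inside gradient boosting.
//
// Two split-search strategies: a sort-per-node scan for random-feature
// forests (mtry << p), and a presorted full-feature scan whose column
// order is computed once per matrix and shared across nodes and boosting
// rounds.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf prediction
};

// column-sorted sample indices, computed once per matrix
struct Presort {
  std::vector<std::vector<int> > order;
  explicit Presort(const NumericMatrix& X) {
    int n = X.nrow(), p = X.ncol();
    order.resize(p);
    for (int j = 0; j < p; ++j) {
      order[j].resize(n);
      for (int i = 0; i < n; ++i) order[j][i] = i;
      const double* col = &X(0, j);
      std::sort(order[j].begin(), order[j].end(),
                [col](int a, int b) { return col[a] < col[b]; });
    }
  }
};

struct Grower {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& denom;    // optional Newton denominators (len 0 = off)
  int max_depth, min_split, mtry;
  std::mt19937 rng;
  const Presort* presort;        // non-null enables full-feature scan
  std::vector<uint8_t> in_node;
  TreeBuf tree;

  Grower(const NumericMatrix& X_, const NumericVector& y_,
         const NumericVector& denom_, int max_depth_, int min_split_,
         int mtry_, unsigned seed, const Presort* presort_ = nullptr)
    : X(X_), y(y_), denom(denom_), max_depth(max_depth_),
      min_split(min_split_), mtry(mtry_), rng(seed), presort(presort_) {
    if (presort) in_node.assign(X.nrow(), 0);
  }

  double leaf_value(const std::vector<int>& idx) {
    double num = 0.0, den = 0.0;
    for (int i : idx) {
      num += y[i];
      den += denom.size() ? denom[i] : 1.0;
    }
    if (den < 1e-10) den = 1e-10;
    return num / den;
  }

  int make_leaf(const std::vector<int>& idx) {
    int id = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(leaf_value(idx));
    return id;
  }

  // best split over a random subset, sorting node members per feature
  void search_sampled(const std::vector<int>& idx, double sum,
                      double& best_gain, int& best_feat, double& best_thr) {
    int n = (int)idx.size(), p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feats[j], feats[pick(rng)]);
    }
    std::vector<std::pair<double,double> > xy(n);
    for (int jj = 0; jj < m; ++jj) {
      int j = feats[jj];
      for (int i = 0; i < n; ++i) {
        xy[i].first = X(idx[i], j);
        xy[i].second = y[idx[i]];
      }
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue;
      double ls = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        ls += xy[i].second;
        if (xy[i].first == xy[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double rs = sum - ls;
        double gain = ls * ls / nl + rs * rs / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = j;
          best_thr = (xy[i].first + xy[i + 1].first) / 2.0;
        }
      }
    }
  }

  // best split over all features using the shared presorted column order
  void search_presorted(const std::vector<int>& idx, double sum,
                        double& best_gain, int& best_feat,
                        double& best_thr) {
    int n = (int)idx.size(), p = X.ncol(), ntot = X.nrow();
    for (int i : idx) in_node[i] = 1;
    for (int j = 0; j < p; ++j) {
      const std::vector<int>& ord = presort->order[j];
      const double* col = &X(0, j);
      double ls = 0.0;
      int nl = 0;
      double prev = 0.0;
      bool have_prev = false;
      for (int s = 0; s < ntot; ++s) {
        int i = ord[s];
        if (!in_node[i]) continue;
        double xv = col[i];
        if (have_prev && xv > prev && nl < n) {
          double rs = sum - ls;
          int nr = n - nl;
          double gain = ls * ls / nl + rs * rs / nr - sum * sum / n;
          if (gain > best_gain) {
            best_gain = gain;
            best_feat = j;
            best_thr = (prev + xv) / 2.0;
          }
        }
        ls += y[i];
        ++nl;
        prev = xv;
        have_prev = true;
      }
    }
    for (int i : idx) in_node[i] = 0;
  }

  int grow(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    double sum = 0.0, sumsq = 0.0;
    for (int i : idx) { sum += y[i]; sumsq += y[i] * y[i]; }
    double sse = sumsq - sum * sum / n;
    if (depth >= max_depth || n < min_split || sse < 1e-12)
      return make_leaf(idx);

    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    if (presort && mtry >= X.ncol()) {
      search_presorted(idx, sum, best_gain, best_feat, best_thr);
    } else {
      search_sampled(idx, sum, best_gain, best_feat, best_thr);
    }
    if (best_feat < 0) return make_leaf(idx);

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return make_leaf(idx);

    int id = (int)tree.feature.size();
    tree.feature.push_back(best_feat);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-2);
    tree.right.push_back(-2);
    tree.value.push_back(sum / n);
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    tree.left[id] = l;
    tree.right[id] = r;
    return id;
  }
};

List tree_to_list(const TreeBuf& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

void predict_one_tree(const List& tree, const NumericMatrix& X,
                      std::vector<double>& out) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_tree_fit(NumericMatrix X, NumericVector y, int max_depth,
                  int min_split, int mtry, int seed,
                  Nullable<IntegerVector> rows = R_NilValue,
                  Nullable<NumericVector> denom = R_NilValue) {
  NumericVector d = denom.isNull() ? NumericVector(0)
                                   : NumericVector(denom.get());
  Presort ps(X);
  Grower g(X, y, d, max_depth, min_split, mtry, (unsigned)seed, &ps);
  std::vector<int> idx;
  if (rows.isNull()) {
    idx.resize(X.nrow());
    for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  } else {
    IntegerVector r(rows.get());
    idx.assign(r.begin(), r.end());   // 0-based
  }
  g.grow(idx, 0);
  return tree_to_list(g.tree);
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  std::vector<double> out(X.nrow());
  predict_one_tree(tree, X, out);
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, int n_trees,
                int max_depth, int min_split, int mtry, int seed) {
  std::mt19937 rng((unsigned)seed);
  int n = X.nrow();
  List trees(n_trees);
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int t = 0; t < n_trees; ++t) {
    NumericVector d(0);
    Grower g(X, y, d, max_depth, min_split, mtry, rng());
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);   // bootstrap
    g.grow(idx, 0);
    trees[t] = tree_to_list(g.tree);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List forest, NumericMatrix X) {
  int n = X.nrow(), B = forest.size();
  NumericVector acc(n);
  std::vector<double> out(n);
  for (int t = 0; t < B; ++t) {
    predict_one_tree(forest[t], X, out);
    for (int i = 0; i < n; ++i) acc[i] += out[i];
  }
  for (int i = 0; i < n; ++i) acc[i] /= B;
  return acc;
}

// Gradient boosting for binary log-loss: regression trees fit to the
// residual y - p with Newton leaf values sum(r)/sum(p(1-p)). The column
// presort is computed once and reused by every round.
// [[Rcpp::export]]
List cpp_gbm_fit(NumericMatrix X, NumericVector y, int n_rounds,
                 int max_depth, double shrinkage, int seed) {
  int n = X.nrow();
  double ybar = std::min(std::max((double)mean(y), 1e-6), 1.0 - 1e-6);
  double f0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, f0);
  List trees(n_rounds);
  std::mt19937 rng((unsigned)seed);
  Presort ps(X);
  std::vector<double> out(n);
  for (int t = 0; t < n_rounds; ++t) {
    NumericVector r(n), w(n);
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - p;
      w[i] = std::max(p * (1.0 - p), 1e-6);
    }
    Grower g(X, r, w, max_depth, 2, X.ncol(), rng(), &ps);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    g.grow(idx, 0);
    List tr = tree_to_list(g.tree);
    predict_one_tree(tr, X, out);
    for (int i = 0; i < n; ++i) F[i] += shrinkage * out[i];
    trees[t] = tr;
  }
  return List::create(_["trees"] = trees, _["init"] = f0,
                      _["shrinkage"] = shrinkage);
}

// [[Rcpp::export]]
NumericVector cpp_gbm_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  double f0 = as<double>(model["init"]);
  double shrink = as<double>(model["shrinkage"]);
  int n = X.nrow();
  NumericVector F(n, f0);
  std::vector<double> out(n);
  for (int t = 0; t < trees.size(); ++t) {
    predict_one_tree(trees[t], X, out);
    for (int i = 0; i < n; ++i) F[i] += shrink * out[i];
  }
  for (int i = 0; i < n; ++i) F[i] = 1.0 / (1.0 + std::exp(-F[i]));
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_row_medians(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(p);
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int j = 0; j < p; ++j) {
      double v = X(i, j);
      if (!ISNAN(v)) buf.push_back(v);
    }
    if (buf.empty()) { out[i] = NA_REAL; continue; }
    size_t m = buf.size() / 2;
    std::nth_element(buf.begin(), buf.begin() + m, buf.end());
    double hi = buf[m];
    if (buf.size() % 2 == 1) out[i] = hi;
    else {
      double lo = *std::max_element(buf.begin(), buf.begin() + m);
      out[i] = (lo + hi) / 2.0;
    }
  }
  return out;
}
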