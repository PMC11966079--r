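// Exact Shapley attributions for tree ensembles (the polynomial-time
// tree-path algorithm), in double precision, plus double-precision margin
// traversal. Node covers (training hessian sums) supply the background
// weighting, matching the ensemble's own training distribution.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature, yes, no;
  std::vector<double> threshold, value, cover;
};

static std::vector<Tree> parse_trees(const List &trees) {
  std::vector<Tree> out;
  out.reserve(trees.size());
  for (R_xlen_t t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    Tree tt;
    tt.feature = as<std::vector<int>>(tr["feature"]);
    tt.threshold = as<std::vector<double>>(tr["threshold"]);
    tt.yes = as<std::vector<int>>(tr["yes"]);
    tt.no = as<std::vector<int>>(tr["no"]);
    tt.value = as<std::vector<double>>(tr["value"]);
    tt.cover = as<std::vector<double>>(tr["cover"]);
    out.push_back(std::move(tt));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector ensemble_margin(List trees, NumericMatrix X) {
  std::vector<Tree> ts = parse_trees(trees);
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (const Tree &tt : ts) {
      int node = 0;
      while (tt.feature[node] >= 0) {
        double v = X(i, tt.feature[node]);
        node = ((float)v < (float)tt.threshold[node]) ? tt.yes[node] : tt.no[node];
      }
      tot += tt.value[node];
    }
    out[i] = tot;
  }
  return out;
}

// cover-weighted expectation of each tree's output
// [[Rcpp::export]]
NumericVector ensemble_expected_value(List trees) {
  std::vector<Tree> ts = parse_trees(trees);
  NumericVector out(ts.size());
  for (size_t t = 0; t < ts.size(); ++t) {
    const Tree &tt = ts[t];
    double e = 0.0, root = tt.cover[0];
    for (size_t j = 0; j < tt.feature.size(); ++j)
      if (tt.feature[j] < 0) e += tt.value[j] * (tt.cover[j] / root);
    out[t] = e;
  }
  return out;
}

struct PathElement {
  int feature_index;
  double zero_fraction, one_fraction, pweight;
};

static void extend_path(PathElement *path, unsigned depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[depth].feature_index = feature_index;
  path[depth].zero_fraction = zero_fraction;
  path[depth].one_fraction = one_fraction;
  path[depth].pweight = (depth == 0 ? 1.0 : 0.0);
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1.0) / (depth + 1.0);
    path[i].pweight = zero_fraction * path[i].pweight * (depth - i) / (depth + 1.0);
  }
}

static void unwind_path(PathElement *path, unsigned depth, unsigned index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (depth + 1.0) / ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction * (depth - i) / (depth + 1.0);
    } else {
      path[i].pweight = (path[i].pweight * (depth + 1.0)) / (zero_fraction * (depth - i));
    }
  }
  for (unsigned i = index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *path, unsigned depth,
                               unsigned index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  double total = 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (depth + 1.0) / ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight -
        tmp * zero_fraction * ((depth - i) / (depth + 1.0));
    } else {
      total += (path[i].pweight / zero_fraction) / ((depth - i) / (depth + 1.0));
    }
  }
  return total;
}

static void tree_shap_recursive(const Tree &tt, const double *x, double *phi,
                                unsigned node, unsigned depth,
                                PathElement *parent_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *path = parent_path + depth + 1;
  for (unsigned i = 0; i <= depth; ++i) path[i] = parent_path[i];
  extend_path(path, depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (tt.feature[node] < 0) {  // leaf
    for (unsigned i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      const PathElement &el = path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) * tt.value[node];
    }
    return;
  }

  const int split_feature = tt.feature[node];
  const unsigned hot = ((float)x[split_feature] < (float)tt.threshold[node]) ? tt.yes[node] : tt.no[node];
  const unsigned cold = (hot == (unsigned)tt.yes[node]) ? tt.no[node] : tt.yes[node];
  const double w = tt.cover[node];
  const double hot_zero_fraction = tt.cover[hot] / w;
  const double cold_zero_fraction = tt.cover[cold] / w;
  double incoming_zero_fraction = 1.0, incoming_one_fraction = 1.0;

  unsigned path_index = 0;
  for (; path_index <= depth; ++path_index)
    if (path[path_index].feature_index == split_feature) break;
  if (path_index != depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, depth, path_index);
    depth -= 1;
  }

  tree_shap_recursive(tt, x, phi, hot, depth + 1, path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tt, x, phi, cold, depth + 1, path,
                      cold_zero_fraction * incoming_zero_fraction,
                      0.0, split_feature);
}

static unsigned tree_max_depth(const Tree &tt, unsigned node, unsigned d) {
  if (tt.feature[node] < 0) return d;
  unsigned a = tree_max_depth(tt, tt.yes[node], d + 1);
  unsigned b = tree_max_depth(tt, tt.no[node], d + 1);
  return a > b ? a : b;
}

// [[Rcpp::export]]
NumericMatrix ensemble_shap(List trees, NumericMatrix X) {
  std::vector<Tree> ts = parse_trees(trees);
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  unsigned maxd = 0;
  for (const Tree &tt : ts) {
    unsigned d = tree_max_depth(tt, 0, 0);
    if (d > maxd) maxd = d;
  }
  // each recursion level copies the path into fresh buffer space
  std::vector<PathElement> buffer((maxd + 2) * (maxd + 3));
  std::vector<double> xi(p), ph(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) { xi[j] = X(i, j); ph[j] = 0.0; }
    for (const Tree &tt : ts)
      tree_shap_recursive(tt, xi.data(), ph.data(), 0, 0, buffer.data(),
                          1.0, 1.0, -1);
    for (int j = 0; j < p; ++j) phi(i, j) = ph[j];
  }
  return phi;
}
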