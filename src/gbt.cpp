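// Gradient-boosted regression trees with Newton leaf weights and a softmax
// multiclass objective (binary is the K = 2 case). Features are pre-binned
// into at most 64 quantile bins and splits are found by histogram scan
// (the LightGBM/xgboost-hist strategy), with second-order gain
//   0.5 * [GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda)]
// and leaf weight -G/(H+lambda). Deterministic: ties in gain keep the
// first (lowest feature index, lowest threshold) candidate.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

const int MAX_BINS = 64;
const int MIN_LEAF = 5;
const double MIN_CHILD_WEIGHT = 1.0;

struct BinnedData {
  int n, p;
  std::vector<unsigned char> bins;          // n x p, column-major
  std::vector<std::vector<double>> cuts;    // per feature: upper edge of bin b
  int n_bins(int f) const { return (int)cuts[f].size() + 1; }
  unsigned char at(int i, int f) const { return bins[(size_t)f * n + i]; }
};

// quantile-style cuts; a value x falls in bin b iff
// cuts[b-1] < x <= cuts[b] (bin 0: x <= cuts[0]; last bin: x > cuts.back())
void bin_features(const NumericMatrix& X, BinnedData& bd) {
  bd.n = X.nrow(); bd.p = X.ncol();
  bd.bins.resize((size_t)bd.n * bd.p);
  bd.cuts.resize(bd.p);
  std::vector<double> col(bd.n);
  for (int f = 0; f < bd.p; ++f) {
    for (int i = 0; i < bd.n; ++i) col[i] = X(i, f);
    std::vector<double> sorted(col);
    std::sort(sorted.begin(), sorted.end());
    sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());

    std::vector<double>& cuts = bd.cuts[f];
    const int m = (int)sorted.size();
    if (m <= MAX_BINS) {
      for (int k = 0; k + 1 < m; ++k)
        cuts.push_back(0.5 * (sorted[k] + sorted[k + 1]));
    } else {
      for (int b = 1; b < MAX_BINS; ++b) {
        int k = (int)((double)b * m / MAX_BINS);
        k = std::min(k, m - 2);
        double c = 0.5 * (sorted[k] + sorted[k + 1]);
        if (cuts.empty() || c > cuts.back()) cuts.push_back(c);
      }
    }
    for (int i = 0; i < bd.n; ++i) {
      int b = (int)(std::upper_bound(cuts.begin(), cuts.end(), col[i]) -
                    cuts.begin());
      bd.bins[(size_t)f * bd.n + i] = (unsigned char)b;
    }
  }
}

struct TreeNodes {
  std::vector<double> feature, threshold, left, right, value;
  int add_leaf(double w) {
    feature.push_back(-1); threshold.push_back(0);
    left.push_back(-1); right.push_back(-1); value.push_back(w);
    return (int)feature.size() - 1;
  }
  int add_split(int f, double thr) {
    feature.push_back(f); threshold.push_back(thr);
    left.push_back(-1); right.push_back(-1); value.push_back(0);
    return (int)feature.size() - 1;
  }
};

struct SplitInfo {
  bool found = false;
  int feature = -1, bin = -1;
  double threshold = 0, gain = 0;
};

SplitInfo best_split(const BinnedData& bd, const std::vector<int>& rows,
                     const std::vector<double>& g,
                     const std::vector<double>& h, double lambda) {
  double G = 0, H = 0;
  for (int i : rows) { G += g[i]; H += h[i]; }
  const double parent = G * G / (H + lambda);
  const int n = (int)rows.size();

  SplitInfo best;
  double Gb[MAX_BINS], Hb[MAX_BINS];
  int Cb[MAX_BINS];
  for (int f = 0; f < bd.p; ++f) {
    const int nb = bd.n_bins(f);
    if (nb < 2) continue;
    std::fill(Gb, Gb + nb, 0.0);
    std::fill(Hb, Hb + nb, 0.0);
    std::fill(Cb, Cb + nb, 0);
    for (int i : rows) {
      const int b = bd.at(i, f);
      Gb[b] += g[i]; Hb[b] += h[i]; ++Cb[b];
    }
    double GL = 0, HL = 0;
    int CL = 0;
    for (int b = 0; b + 1 < nb; ++b) {
      GL += Gb[b]; HL += Hb[b]; CL += Cb[b];
      if (CL < MIN_LEAF || n - CL < MIN_LEAF) continue;
      const double HR = H - HL;
      if (HL < MIN_CHILD_WEIGHT || HR < MIN_CHILD_WEIGHT) continue;
      const double GR = G - GL;
      const double gain =
        0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent);
      if (gain > best.gain + 1e-12) {
        best.found = true;
        best.feature = f;
        best.bin = b;
        best.threshold = bd.cuts[f][b];
        best.gain = gain;
      }
    }
  }
  return best;
}

void build_node(const BinnedData& bd, std::vector<int>& rows,
                const std::vector<double>& g, const std::vector<double>& h,
                int depth, int max_depth, double lambda, TreeNodes& tree,
                std::vector<int>& leaf_of, int node_slot) {
  double G = 0, H = 0;
  for (int i : rows) { G += g[i]; H += h[i]; }

  SplitInfo sp;
  if (depth < max_depth && (int)rows.size() >= 2 * MIN_LEAF)
    sp = best_split(bd, rows, g, h, lambda);

  if (!sp.found) {
    int id = tree.add_leaf(-G / (H + lambda));
    if (node_slot >= 0) {
      if (tree.left[node_slot] < 0) tree.left[node_slot] = id;
      else tree.right[node_slot] = id;
    }
    for (int i : rows) leaf_of[i] = id;
    return;
  }

  std::vector<int> li, ri;
  li.reserve(rows.size());
  for (int i : rows)
    (bd.at(i, sp.feature) <= sp.bin ? li : ri).push_back(i);

  int id = tree.add_split(sp.feature, sp.threshold);
  if (node_slot >= 0) {
    if (tree.left[node_slot] < 0) tree.left[node_slot] = id;
    else tree.right[node_slot] = id;
  }
  rows.clear(); rows.shrink_to_fit();
  build_node(bd, li, g, h, depth + 1, max_depth, lambda, tree, leaf_of, id);
  build_node(bd, ri, g, h, depth + 1, max_depth, lambda, tree, leaf_of, id);
}

NumericMatrix tree_to_matrix(const TreeNodes& t) {
  int n = (int)t.feature.size();
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = t.feature[i];
    m(i, 1) = t.threshold[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "value");
  return m;
}

double predict_tree(const NumericMatrix& tree, const NumericMatrix& X,
                    int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    node = (X(row, (int)tree(node, 0)) <= tree(node, 1))
      ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

void softmax_rows(std::vector<double>& F, int n, int K,
                  std::vector<double>& P) {
  for (int i = 0; i < n; ++i) {
    double mx = F[i];
    for (int k = 1; k < K; ++k) mx = std::max(mx, F[i + (size_t)k * n]);
    double s = 0;
    for (int k = 0; k < K; ++k) {
      double e = std::exp(F[i + (size_t)k * n] - mx);
      P[i + (size_t)k * n] = e;
      s += e;
    }
    for (int k = 0; k < K; ++k) P[i + (size_t)k * n] /= s;
  }
}

}  // namespace

// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                 int n_rounds, int max_depth, double learning_rate,
                 double lambda) {
  const int n = X.nrow(), K = n_classes;
  if (n_rounds < 1 || max_depth < 1 || K < 2)
    stop("invalid boosting parameters");
  for (int i = 0; i < n; ++i)
    if (y[i] < 0 || y[i] >= K) stop("label out of range at row %d", i + 1);

  BinnedData bd;
  bin_features(X, bd);

  std::vector<double> F((size_t)n * K, 0.0), P((size_t)n * K, 0.0);
  std::vector<double> g(n), h(n);
  std::vector<int> leaf_of(n);
  List trees(n_rounds * K);

  for (int r = 0; r < n_rounds; ++r) {
    softmax_rows(F, n, K, P);
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) {
        double p = P[i + (size_t)k * n];
        g[i] = p - (y[i] == k ? 1.0 : 0.0);
        h[i] = std::max(p * (1.0 - p), 1e-10);
      }
      TreeNodes tree;
      std::vector<int> all(n);
      for (int i = 0; i < n; ++i) all[i] = i;
      build_node(bd, all, g, h, 0, max_depth, lambda, tree, leaf_of, -1);
      trees[(size_t)r * K + k] = tree_to_matrix(tree);
      for (int i = 0; i < n; ++i)
        F[i + (size_t)k * n] += learning_rate * tree.value[leaf_of[i]];
    }
  }
  return List::create(_["trees"] = trees, _["n_classes"] = K,
                      _["n_rounds"] = n_rounds,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export]]
NumericMatrix gbt_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  const int K = as<int>(model["n_classes"]);
  const int R = as<int>(model["n_rounds"]);
  const double lr = as<double>(model["learning_rate"]);
  const int n = X.nrow();

  std::vector<double> F((size_t)n * K, 0.0), P((size_t)n * K, 0.0);
  for (int r = 0; r < R; ++r) {
    for (int k = 0; k < K; ++k) {
      NumericMatrix tm = trees[(size_t)r * K + k];
      for (int i = 0; i < n; ++i)
        F[i + (size_t)k * n] += lr * predict_tree(tm, X, i);
    }
  }
  softmax_rows(F, n, K, P);
  NumericMatrix out(n, K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) out(i, k) = P[i + (size_t)k * n];
  return out;
}
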