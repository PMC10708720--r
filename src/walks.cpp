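// Anonymous-walk distribution kernels.
//
// The exact kernel traverses every walk of l steps (start uniform over
// non-isolated nodes, steps uniform over neighbors), accumulating walk
// probabilities per anonymous pattern. At n = 16, l = 5 the walk space is
// at most 16 * 15^5 ~ 1.2e7 paths; recursion with an incrementally encoded
// pattern key keeps this well under a second. The sampled kernel simulates
// walks with R's RNG so set.seed() governs it.

#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

typedef std::unordered_map<long long, int> PatternIndex;

static PatternIndex index_patterns(const List& patterns, long long base) {
  PatternIndex idx;
  for (int k = 0; k < patterns.size(); ++k) {
    IntegerVector p = patterns[k];
    long long key = 0;
    for (int t = 0; t < p.size(); ++t) key = key * base + p[t];
    idx[key] = k;
  }
  return idx;
}

static std::vector<std::vector<int>> neighbor_lists(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nbrs(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && i != j) nbrs[i].push_back(j);
  return nbrs;
}

static void walk_recurse(int node, int depth, int l,
                         std::vector<int>& label_of, int max_label,
                         long long key, long long base, double prob,
                         const std::vector<std::vector<int>>& nbrs,
                         const PatternIndex& pat_index,
                         std::vector<double>& out) {
  if (depth == l) {
    PatternIndex::const_iterator it = pat_index.find(key);
    if (it != pat_index.end()) out[it->second] += prob;
    return;
  }
  const std::vector<int>& nb = nbrs[node];
  double step = prob / nb.size();
  for (size_t k = 0; k < nb.size(); ++k) {
    int nxt = nb[k];
    bool fresh = (label_of[nxt] == 0);
    int lab = fresh ? max_label + 1 : label_of[nxt];
    if (fresh) label_of[nxt] = lab;
    walk_recurse(nxt, depth + 1, l, label_of, fresh ? lab : max_label,
                 key * base + lab, base, step, nbrs, pat_index, out);
    if (fresh) label_of[nxt] = 0;  // labels retire in LIFO order
  }
}

// [[Rcpp::export]]
NumericVector exact_walk_probs_cpp(IntegerMatrix adj, int l, List patterns) {
  int n = adj.nrow();
  long long base = l + 2;
  PatternIndex idx = index_patterns(patterns, base);
  std::vector<std::vector<int>> nbrs = neighbor_lists(adj);
  std::vector<int> starts;
  for (int i = 0; i < n; ++i) if (!nbrs[i].empty()) starts.push_back(i);
  std::vector<double> out(patterns.size(), 0.0);
  if (!starts.empty()) {
    double p0 = 1.0 / starts.size();
    std::vector<int> label_of(n, 0);
    for (size_t s = 0; s < starts.size(); ++s) {
      label_of[starts[s]] = 1;
      walk_recurse(starts[s], 0, l, label_of, 1, 1, base, p0,
                   nbrs, idx, out);
      label_of[starts[s]] = 0;
    }
  }
  return wrap(out);
}

// [[Rcpp::export]]
NumericVector sampled_walk_probs_cpp(IntegerMatrix adj, int l, int n_samples,
                                     List patterns) {
  int n = adj.nrow();
  long long base = l + 2;
  PatternIndex idx = index_patterns(patterns, base);
  std::vector<std::vector<int>> nbrs = neighbor_lists(adj);
  std::vector<int> starts;
  for (int i = 0; i < n; ++i) if (!nbrs[i].empty()) starts.push_back(i);
  NumericVector out(patterns.size());
  if (starts.empty() || n_samples < 1) return out;
  RNGScope scope;
  std::vector<int> label_of(n);
  for (int s = 0; s < n_samples; ++s) {
    std::fill(label_of.begin(), label_of.end(), 0);
    int node = starts[(int)(unif_rand() * starts.size())];
    label_of[node] = 1;
    int max_label = 1;
    long long key = 1;
    for (int t = 0; t < l; ++t) {
      const std::vector<int>& nb = nbrs[node];
      node = nb[(int)(unif_rand() * nb.size())];
      if (label_of[node] == 0) label_of[node] = ++max_label;
      key = key * base + label_of[node];
    }
    PatternIndex::iterator it = idx.find(key);
    if (it != idx.end()) out[it->second] += 1.0;
  }
  return out / (double)n_samples;
}
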