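#include <Rcpp.h>
#include <map>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving; components of the suprathreshold set of a
// channels x time statistic map, connected through temporal contiguity
// (adjacent samples, same channel) and spatial adjacency (neighbouring
// channels, same sample).  Positive and negative suprathreshold points are
// never merged: clusters are signed.

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// [[Rcpp::export]]
List cluster_components_cpp(NumericMatrix tmap, double threshold, List adj) {
  int nch = tmap.nrow(), nt = tmap.ncol(), n = nch * nt;
  std::vector<signed char> mask(n, 0);
  for (int j = 0; j < nt; ++j)
    for (int i = 0; i < nch; ++i) {
      double v = tmap(i, j);
      if (R_finite(v)) {
        if (v > threshold) mask[i + j * nch] = 1;
        else if (v < -threshold) mask[i + j * nch] = -1;
      }
    }
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int j = 1; j < nt; ++j)
    for (int i = 0; i < nch; ++i) {
      int a = i + (j - 1) * nch, b = i + j * nch;
      if (mask[a] != 0 && mask[a] == mask[b]) uf_union(parent, a, b);
    }
  for (int i = 0; i < nch; ++i) {
    IntegerVector nb = adj[i];
    for (int k = 0; k < nb.size(); ++k) {
      int i2 = nb[k];
      if (i2 <= i) continue;  // each pair once
      for (int j = 0; j < nt; ++j) {
        int a = i + j * nch, b = i2 + j * nch;
        if (mask[a] != 0 && mask[a] == mask[b]) uf_union(parent, a, b);
      }
    }
  }
  std::map<int, int> root2id;
  std::vector<double> sums;
  std::vector<int> signs;
  std::vector<std::set<int> > chsets;
  IntegerMatrix labels(nch, nt);
  for (int j = 0; j < nt; ++j)
    for (int i = 0; i < nch; ++i) {
      int idx = i + j * nch;
      if (!mask[idx]) continue;
      int r = uf_find(parent, idx);
      std::map<int, int>::iterator it = root2id.find(r);
      int id;
      if (it == root2id.end()) {
        id = (int) sums.size();
        root2id[r] = id;
        sums.push_back(0.0);
        signs.push_back(mask[idx]);
        chsets.push_back(std::set<int>());
      } else {
        id = it->second;
      }
      sums[id] += tmap(i, j);
      chsets[id].insert(i);
      labels(i, j) = id + 1;
    }
  int m = (int) sums.size();
  NumericVector s(m);
  IntegerVector nc(m), sg(m);
  for (int k = 0; k < m; ++k) {
    s[k] = sums[k];
    nc[k] = (int) chsets[k].size();
    sg[k] = signs[k];
  }
  return List::create(_["labels"] = labels, _["sum"] = s,
                      _["n_channels"] = nc, _["sign"] = sg);
}

// Permutation-null cluster statistics.  Each row of `tmats` is one
// permutation's t map, flattened channel-major (as.vector of the
// channels x time matrix).  Returns, per permutation, the max (or mean)
// |cluster sum| over clusters spanning at least `min_channels` distinct
// channels; 0 when no such cluster exists.

// [[Rcpp::export]]
NumericVector cluster_null_stats_cpp(NumericMatrix tmats, int n_channels,
                                     int n_time, double threshold, List adj,
                                     int min_channels, bool mean_stat) {
  int nperm = tmats.nrow();
  int n = n_channels * n_time;
  NumericVector out(nperm);
  std::vector<signed char> mask(n);
  std::vector<int> parent(n);
  std::vector<std::vector<int> > nbr(n_channels);
  for (int i = 0; i < n_channels; ++i) {
    IntegerVector v = adj[i];
    for (int k = 0; k < v.size(); ++k)
      if (v[k] > i) nbr[i].push_back(v[k]);
  }
  for (int p = 0; p < nperm; ++p) {
    bool any = false;
    for (int idx = 0; idx < n; ++idx) {
      double v = tmats(p, idx);
      signed char m = 0;
      if (R_finite(v)) {
        if (v > threshold) m = 1;
        else if (v < -threshold) m = -1;
      }
      mask[idx] = m;
      if (m) any = true;
    }
    if (!any) { out[p] = 0.0; continue; }
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int j = 1; j < n_time; ++j)
      for (int i = 0; i < n_channels; ++i) {
        int a = i + (j - 1) * n_channels, b = i + j * n_channels;
        if (mask[a] && mask[a] == mask[b]) uf_union(parent, a, b);
      }
    for (int i = 0; i < n_channels; ++i)
      for (size_t k = 0; k < nbr[i].size(); ++k) {
        int i2 = nbr[i][k];
        for (int j = 0; j < n_time; ++j) {
          int a = i + j * n_channels, b = i2 + j * n_channels;
          if (mask[a] && mask[a] == mask[b]) uf_union(parent, a, b);
        }
      }
    std::map<int, double> sums;
    std::map<int, std::set<int> > chs;
    for (int j = 0; j < n_time; ++j)
      for (int i = 0; i < n_channels; ++i) {
        int idx = i + j * n_channels;
        if (!mask[idx]) continue;
        int r = uf_find(parent, idx);
        sums[r] += tmats(p, idx);
        chs[r].insert(i);
      }
    double best = 0.0, tot = 0.0;
    int cnt = 0;
    for (std::map<int, double>::iterator it = sums.begin(); it != sums.end();
         ++it) {
      if ((int) chs[it->first].size() < min_channels) continue;
      double a = std::fabs(it->second);
      if (a > best) best = a;
      tot += a;
      ++cnt;
    }
    out[p] = mean_stat ? (cnt ? tot / cnt : 0.0) : best;
  }
  return out;
}
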