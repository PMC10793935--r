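#include <Rcpp.h>
#include <algorithm>
#include <utility>
#include <vector>

using namespace Rcpp;

typedef std::pair<double, int> DistIdx;  // orders by distance, then index

// Top-k selection over a row of (distance, index) pairs. Ties at the k-th
// distance break by ascending point index via the pair ordering. Small k
// uses insertion into a sorted scratch array (O(m) amortized); large k
// falls back to partial_sort.
static int count_v_among_knn(std::vector<DistIdx>& row, int k,
                             const int* vflag) {
  const int m = (int)row.size();
  int c = 0;
  if (k <= 64) {
    std::vector<DistIdx> best(row.begin(), row.begin() + k);
    std::sort(best.begin(), best.end());
    for (int j = k; j < m; ++j) {
      if (row[j] < best[k - 1]) {
        int pos = (int)(std::upper_bound(best.begin(), best.end(), row[j]) -
                        best.begin());
        for (int t = k - 1; t > pos; --t) best[t] = best[t - 1];
        best[pos] = row[j];
      }
    }
    for (int j = 0; j < k; ++j) c += vflag[best[j].second];
  } else {
    std::partial_sort(row.begin(), row.begin() + k, row.end());
    for (int j = 0; j < k; ++j) c += vflag[row[j].second];
  }
  return c;
}

// Per-row count of V-members among the k nearest neighbors within one
// bin-group pair, straight from the coordinates (squared Euclidean
// distances; ranks and ties are unchanged by the square). The query point
// itself is excluded. No m x m matrix is formed.
// [[Rcpp::export]]
IntegerVector knn_v_counts_points(NumericMatrix x, LogicalVector in_v,
                                  int k) {
  const int m = x.nrow(), d = x.ncol();
  if (k >= m) stop("k must be smaller than the pair size");
  const double* px = x.begin();
  const int* vflag = in_v.begin();
  IntegerVector out(m);
  std::vector<DistIdx> row(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = px[(size_t)c * m + i] - px[(size_t)c * m + j];
        s += diff * diff;
      }
      row[j] = DistIdx(s, j);
    }
    row[i].first = R_PosInf;  // exclude self
    out[i] = count_v_among_knn(row, k, vflag);
  }
  return out;
}

// Same counting, from a precomputed distance matrix over the pair set
// (geodesic or user-supplied metric).
// [[Rcpp::export]]
IntegerVector knn_v_counts(NumericMatrix dm, LogicalVector in_v, int k) {
  const int m = dm.nrow();
  if (k >= m) stop("k must be smaller than the pair size");
  const double* pd = dm.begin();
  const int* vflag = in_v.begin();
  IntegerVector out(m);
  std::vector<DistIdx> row(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      row[j] = DistIdx(pd[(size_t)j * m + i], j);
    }
    row[i].first = R_PosInf;
    out[i] = count_v_among_knn(row, k, vflag);
  }
  return out;
}

// Per-row radius-neighborhood tallies from the coordinates: total neighbors
// within r (self excluded) and how many belong to V.
// [[Rcpp::export]]
List radius_counts_points(NumericMatrix x, LogicalVector in_v, double r) {
  const int m = x.nrow(), d = x.ncol();
  const double r2 = r * r;
  const double* px = x.begin();
  const int* vflag = in_v.begin();
  IntegerVector n_neigh(m), n_in_v(m);
  for (int i = 0; i < m; ++i) {
    int tot = 0, inv = 0;
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = px[(size_t)c * m + i] - px[(size_t)c * m + j];
        s += diff * diff;
      }
      if (s <= r2) {
        ++tot;
        inv += vflag[j];
      }
    }
    n_neigh[i] = tot;
    n_in_v[i] = inv;
  }
  return List::create(_["n_neigh"] = n_neigh, _["n_in_v"] = n_in_v);
}

// Same tallies from a precomputed distance matrix.
// [[Rcpp::export]]
List radius_counts(NumericMatrix dm, LogicalVector in_v, double r) {
  const int m = dm.nrow();
  const double* pd = dm.begin();
  const int* vflag = in_v.begin();
  IntegerVector n_neigh(m), n_in_v(m);
  for (int i = 0; i < m; ++i) {
    int tot = 0, inv = 0;
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      if (pd[(size_t)j * m + i] <= r) {
        ++tot;
        inv += vflag[j];
      }
    }
    n_neigh[i] = tot;
    n_in_v[i] = inv;
  }
  return List::create(_["n_neigh"] = n_neigh, _["n_in_v"] = n_in_v);
}
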