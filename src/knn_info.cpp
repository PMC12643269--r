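#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Internally points are held row-major (all coordinates of a point adjacent)
// so the neighbor search and range counts stream through memory.

namespace {

std::vector<double> row_major(const NumericMatrix& X) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> P((size_t)n * d);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) P[(size_t)i * d + j] = X(i, j);
  }
  return P;
}

// k-th nearest-neighbor distances (self excluded) by a sweep over points
// ordered by the first coordinate: a candidate can be skipped once its
// first-coordinate gap alone reaches the current k-th best, because both
// metrics dominate any single-coordinate difference.
std::vector<double> knn_eps(const std::vector<double>& P, int n, int d, int k,
                            int metric_code) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return P[(size_t)a * d] < P[(size_t)b * d];
  });
  std::vector<int> pos(n);
  for (int i = 0; i < n; ++i) pos[ord[i]] = i;

  // coordinates rearranged into sweep order, one contiguous array per
  // dimension, so the candidate walk streams through memory
  std::vector<std::vector<double>> S(d, std::vector<double>(n));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) S[j][i] = P[(size_t)ord[i] * d + j];
  }

  std::vector<double> eps(n);
  std::vector<double> heap;  // max-heap of the k best distances
  heap.reserve(k + 1);
  std::vector<double> q(d);

  for (int t = 0; t < n; ++t) {
    heap.clear();
    const int p = pos[t];
    const double x0 = P[(size_t)t * d];
    for (int j = 0; j < d; ++j) q[j] = P[(size_t)t * d + j];
    int li = p - 1, ri = p + 1;
    while (li >= 0 || ri < n) {
      int cand;
      double gap;
      double lgap = (li >= 0) ? x0 - S[0][li] : R_PosInf;
      double rgap = (ri < n) ? S[0][ri] - x0 : R_PosInf;
      if (lgap <= rgap) { cand = li; gap = lgap; --li; }
      else              { cand = ri; gap = rgap; ++ri; }
      if ((int)heap.size() == k) {
        double g = (metric_code == 1) ? gap * gap : gap;
        if (g >= heap.front()) break;  // no remaining candidate can improve
      }
      double dist;
      if (metric_code == 0) {
        dist = gap;
        for (int j = 1; j < d; ++j) {
          double v = std::fabs(S[j][cand] - q[j]);
          if (v > dist) dist = v;
        }
      } else {
        dist = gap * gap;
        for (int j = 1; j < d; ++j) {
          double v = S[j][cand] - q[j];
          dist += v * v;
        }
      }
      if ((int)heap.size() < k) {
        heap.push_back(dist);
        std::push_heap(heap.begin(), heap.end());
      } else if (dist < heap.front()) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = dist;
        std::push_heap(heap.begin(), heap.end());
      }
    }
    eps[t] = (metric_code == 1) ? std::sqrt(heap.front()) : heap.front();
  }
  return eps;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_knn_eps(NumericMatrix X, int k, int metric_code) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k >= n) stop("need 1 <= k < n");
  std::vector<double> P = row_major(X);
  std::vector<double> eps = knn_eps(P, n, d, k, metric_code);
  return NumericVector(eps.begin(), eps.end());
}

// Single-neighbor-search range counts for entropy-combination estimators.
// For each point t, with eps(t) the Chebyshev distance to its k-th nearest
// neighbor in the joint space, counts the points strictly within eps(t) in
// every 1-dimensional marginal (count1) and in every (d-1)-dimensional
// marginal obtained by dropping one coordinate (countm).
// [[Rcpp::export]]
List cpp_knn_counts(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (d < 2) stop("need at least 2 columns");
  if (k < 1 || k >= n) stop("need 1 <= k < n");
  std::vector<double> P = row_major(X);
  std::vector<double> eps = knn_eps(P, n, d, k, 0);

  // per-coordinate sorted values and orderings
  std::vector<std::vector<double>> sv(d, std::vector<double>(n));
  std::vector<std::vector<int>> ord(d, std::vector<int>(n));
  std::vector<std::vector<int>> pos(d, std::vector<int>(n));
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) ord[j][i] = i;
    std::sort(ord[j].begin(), ord[j].end(), [&](int a, int b) {
      return P[(size_t)a * d + j] < P[(size_t)b * d + j];
    });
    for (int i = 0; i < n; ++i) {
      sv[j][i] = P[(size_t)ord[j][i] * d + j];
      pos[j][ord[j][i]] = i;
    }
  }

  IntegerMatrix count1(n, d), countm(n, d);

  // 1-D marginals: binary search on the sorted coordinate
  for (int j = 0; j < d; ++j) {
    const std::vector<double>& v = sv[j];
    for (int t = 0; t < n; ++t) {
      double x = P[(size_t)t * d + j], e = eps[t];
      // strictly inside (x - e, x + e), excluding the point itself
      long lo = std::upper_bound(v.begin(), v.end(), x - e) - v.begin();
      long hi = std::lower_bound(v.begin(), v.end(), x + e) - v.begin();
      count1(t, j) = (int)(hi - lo) - 1;
    }
  }

  // (d-1)-D marginals: scan a window on one retained coordinate, check the
  // remaining ones against contiguous sweep-order copies
  std::vector<int> rest;
  for (int drop = 0; drop < d; ++drop) {
    int scan = (drop == 0) ? 1 : 0;
    const std::vector<double>& v = sv[scan];
    const std::vector<int>& o = ord[scan];
    rest.clear();
    for (int j = 0; j < d; ++j) {
      if (j != drop && j != scan) rest.push_back(j);
    }
    const int nr = (int)rest.size();
    std::vector<std::vector<double>> W(nr, std::vector<double>(n));
    for (int r = 0; r < nr; ++r) {
      for (int i = 0; i < n; ++i) W[r][i] = P[(size_t)o[i] * d + rest[r]];
    }
    for (int t = 0; t < n; ++t) {
      const double e = eps[t];
      const double x = P[(size_t)t * d + scan];
      const int p = pos[scan][t];
      int cnt = 0;
      if (nr == 1) {  // 3-column clouds: one residual coordinate to check
        const double y = P[(size_t)t * d + rest[0]];
        const double* w = W[0].data();
        for (int i = p - 1; i >= 0 && x - v[i] < e; --i) {
          cnt += std::fabs(w[i] - y) < e;
        }
        for (int i = p + 1; i < n && v[i] - x < e; ++i) {
          cnt += std::fabs(w[i] - y) < e;
        }
      } else {
        const double* pt = &P[(size_t)t * d];
        auto check = [&](int i) {
          for (int r = 0; r < nr; ++r) {
            if (std::fabs(W[r][i] - pt[rest[r]]) >= e) return 0;
          }
          return 1;
        };
        for (int i = p - 1; i >= 0 && x - v[i] < e; --i) cnt += check(i);
        for (int i = p + 1; i < n && v[i] - x < e; ++i) cnt += check(i);
      }
      countm(t, drop) = cnt;
    }
  }

  return List::create(_["eps"] = NumericVector(eps.begin(), eps.end()),
                      _["count1"] = count1, _["countm"] = countm);
}
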