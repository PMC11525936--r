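#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Seeded watershed by priority flooding (Meyer). Pixels are flooded in order of
// ascending intensity; ties broken by insertion order, which is deterministic
// because seeds are enqueued in row-major scan order. Pixels outside `mask`
// are never labelled. Connectivity is 4 or 8.
struct QItem {
  double v;
  long long ord;
  int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.v != b.v) return a.v > b.v;   // lower intensity first
    return a.ord > b.ord;               // earlier insertion first
  }
};

// [[Rcpp::export]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix intensity, IntegerMatrix seeds,
                                   LogicalMatrix mask, int connectivity = 4) {
  int H = intensity.nrow(), W = intensity.ncol();
  if (seeds.nrow() != H || seeds.ncol() != W || mask.nrow() != H || mask.ncol() != W)
    stop("intensity, seeds and mask must share dimensions");
  IntegerMatrix lab(H, W);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long ord = 0;
  // enqueue seed pixels in row-major order (row fastest within column in R,
  // but we scan rows then cols explicitly for a stated deterministic order)
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      if (seeds(i, j) > 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        pq.push({intensity(i, j), ord++, i + j * H});
      }
  const int di8[8] = {-1, 0, 0, 1, -1, -1, 1, 1};
  const int dj8[8] = {0, -1, 1, 0, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int i = it.idx % H, j = it.idx / H;
    int l = lab(i, j);
    for (int d = 0; d < nn; ++d) {
      int ni = i + di8[d], nj = j + dj8[d];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = l;
      pq.push({intensity(ni, nj), ord++, ni + nj * H});
    }
  }
  return lab;
}

// Exact k-nearest neighbours by blocked brute force (Euclidean).
// Returns 1-based indices, self excluded; ties broken by lower index.
// [[Rcpp::export]]
IntegerMatrix knn_brute_cpp(NumericMatrix X, int k) {
  int n = X.nrow(), d = X.ncol();
  if (k >= n) stop("k must be smaller than the number of rows");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - X(j, c);
        s += diff * diff;
      }
      cand[j] = std::make_pair(s, j);
    }
    cand[i].first = R_PosInf; // exclude self
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
  }
  return out;
}

// Counts of unordered label pairs over an edge list, for each column of a
// label matrix (columns = permutations). Labels are 1..L. Returns an
// L*(L+1)/2 x P matrix; row index of pair (a<=b) is a + b*(b-1)/2 (1-based
// flattening of the upper triangle by column).
// [[Rcpp::export]]
IntegerMatrix pair_counts_cpp(IntegerVector ei, IntegerVector ej,
                              IntegerMatrix labels, int L) {
  int E = ei.size(), P = labels.ncol();
  int npair = L * (L + 1) / 2;
  IntegerMatrix out(npair, P);
  for (int p = 0; p < P; ++p) {
    for (int e = 0; e < E; ++e) {
      int a = labels(ei[e] - 1, p), b = labels(ej[e] - 1, p);
      if (a > b) std::swap(a, b);
      out((a - 1) + (b - 1) * b / 2, p) += 1;
    }
  }
  return out;
}
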