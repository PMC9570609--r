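#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Minimal static 3D kd-tree (median split) for nearest-neighbour queries.
// Backs the ICP correspondence step and the Hausdorff distance.

namespace {

struct KdTree {
  const double *x, *y, *z;  // column pointers into the reference matrix
  int n;
  std::vector<int> idx;     // permutation of 0..n-1, organised in-place
  std::vector<int> axis;    // split axis per node position

  double coord(int i, int ax) const {
    return ax == 0 ? x[i] : (ax == 1 ? y[i] : z[i]);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = lo + (hi - lo) / 2;
    // pick the axis with the largest spread in this block
    double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
    double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = lo; i < hi; ++i)
      for (int ax = 0; ax < 3; ++ax) {
        double v = coord(idx[i], ax);
        if (v < mn[ax]) mn[ax] = v;
        if (v > mx[ax]) mx[ax] = v;
      }
    int ax = 0;
    double best = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > best) { best = mx[a] - mn[a]; ax = a; }
    axis[mid] = ax;
    const double *cx = x, *cy = y, *cz = z;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) {
                       double va = ax == 0 ? cx[a] : (ax == 1 ? cy[a] : cz[a]);
                       double vb = ax == 0 ? cx[b] : (ax == 1 ? cy[b] : cz[b]);
                       return va < vb;
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(int lo, int hi, double qx, double qy, double qz,
             double &bestd2, int &besti) const {
    if (hi <= lo) return;
    if (hi - lo == 1) {
      int i = idx[lo];
      double dx = x[i] - qx, dy = y[i] - qy, dz = z[i] - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bestd2) { bestd2 = d2; besti = i; }
      return;
    }
    int mid = lo + (hi - lo) / 2;
    int i = idx[mid];
    double dx = x[i] - qx, dy = y[i] - qy, dz = z[i] - qz;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2) { bestd2 = d2; besti = i; }
    int ax = axis[mid];
    double qv = ax == 0 ? qx : (ax == 1 ? qy : qz);
    double sv = coord(i, ax);
    double diff = qv - sv;
    if (diff < 0) {
      query(lo, mid, qx, qy, qz, bestd2, besti);
      if (diff * diff < bestd2) query(mid + 1, hi, qx, qy, qz, bestd2, besti);
    } else {
      query(mid + 1, hi, qx, qy, qz, bestd2, besti);
      if (diff * diff < bestd2) query(lo, mid, qx, qy, qz, bestd2, besti);
    }
  }
};

}  // namespace

namespace {

// bounded max-heap of (dist2, index) pairs for k-NN queries
struct KnnHeap {
  std::vector<std::pair<double, int> > h;
  size_t k;
  explicit KnnHeap(size_t k_) : k(k_) { h.reserve(k_); }
  double worst() const { return h.size() < k ? R_PosInf : h.front().first; }
  void push(double d2, int i) {
    if (h.size() < k) {
      h.push_back(std::make_pair(d2, i));
      std::push_heap(h.begin(), h.end());
    } else if (d2 < h.front().first) {
      std::pop_heap(h.begin(), h.end());
      h.back() = std::make_pair(d2, i);
      std::push_heap(h.begin(), h.end());
    }
  }
};

void knn_query(const KdTree &tree, int lo, int hi,
               double qx, double qy, double qz, KnnHeap &heap) {
  if (hi <= lo) return;
  int mid = lo + (hi - lo) / 2;
  int i = tree.idx[mid];
  double dx = tree.x[i] - qx, dy = tree.y[i] - qy, dz = tree.z[i] - qz;
  heap.push(dx * dx + dy * dy + dz * dz, i);
  if (hi - lo == 1) return;
  int ax = tree.axis[mid];
  double qv = ax == 0 ? qx : (ax == 1 ? qy : qz);
  double diff = qv - tree.coord(i, ax);
  if (diff < 0) {
    knn_query(tree, lo, mid, qx, qy, qz, heap);
    if (diff * diff < heap.worst()) knn_query(tree, mid + 1, hi, qx, qy, qz, heap);
  } else {
    knn_query(tree, mid + 1, hi, qx, qy, qz, heap);
    if (diff * diff < heap.worst()) knn_query(tree, lo, mid, qx, qy, qz, heap);
  }
}

}  // namespace

// k nearest neighbours in `ref` for every row of `query` (1-based indices,
// sorted by increasing distance).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix ref, NumericMatrix query, int k) {
  int n = ref.nrow(), m = query.nrow();
  if (n < 1) stop("reference point set is empty");
  if (k < 1 || k > n) stop("k must be between 1 and nrow(ref)");
  KdTree tree;
  tree.x = &ref(0, 0);
  tree.y = &ref(0, 1);
  tree.z = &ref(0, 2);
  tree.n = n;
  tree.idx.resize(n);
  for (int i = 0; i < n; ++i) tree.idx[i] = i;
  tree.axis.assign(n, 0);
  tree.build(0, n, 0);

  IntegerMatrix out_idx(m, k);
  NumericMatrix out_dist(m, k);
  for (int j = 0; j < m; ++j) {
    KnnHeap heap((size_t)k);
    knn_query(tree, 0, n, query(j, 0), query(j, 1), query(j, 2), heap);
    std::sort(heap.h.begin(), heap.h.end());
    for (int c = 0; c < k; ++c) {
      out_idx(j, c) = heap.h[c].second + 1;
      out_dist(j, c) = std::sqrt(heap.h[c].first);
    }
    if (j % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["index"] = out_idx, _["distance"] = out_dist);
}

// Nearest neighbour in `ref` for every row of `query`.
// Returns 1-based indices into ref and Euclidean distances.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix ref, NumericMatrix query) {
  int n = ref.nrow(), m = query.nrow();
  if (n < 1) stop("reference point set is empty");
  KdTree tree;
  tree.x = &ref(0, 0);
  tree.y = &ref(0, 1);
  tree.z = &ref(0, 2);
  tree.n = n;
  tree.idx.resize(n);
  for (int i = 0; i < n; ++i) tree.idx[i] = i;
  tree.axis.assign(n, 0);
  tree.build(0, n, 0);

  IntegerVector out_idx(m);
  NumericVector out_dist(m);
  for (int j = 0; j < m; ++j) {
    double bestd2 = R_PosInf;
    int besti = -1;
    tree.query(0, n, query(j, 0), query(j, 1), query(j, 2), bestd2, besti);
    out_idx[j] = besti + 1;
    out_dist[j] = std::sqrt(bestd2);
    if (j % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["index"] = out_idx, _["distance"] = out_dist);
}
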