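// Exact kd-tree nearest-neighbour search and PCA normal estimation.
//
// The dense CT-derived target cloud holds tens of thousands of points and the
// refinement loop queries it repeatedly, so the spatial index and the k-NN
// covariance/eigen step live in C++. Queries are exact (no approximation);
// ties in distance resolve to the lowest point index so results are
// reproducible regardless of build order.

#include <RcppArmadillo.h>
#include <algorithm>
#include <queue>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct KDTree {
  arma::mat pts;              // N x 3
  std::vector<int> perm;      // permutation of 0..N-1, tree in-place
  int n;

  void build(const arma::mat& p) {
    pts = p;
    n = static_cast<int>(p.n_rows);
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    build_range(0, n, 0);
  }

  void build_range(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int axis = depth % 3;
    const arma::mat& P = pts;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&P, axis](int a, int b) {
                       double va = P(a, axis), vb = P(b, axis);
                       if (va != vb) return va < vb;
                       return a < b;  // deterministic total order
                     });
    build_range(lo, mid, depth + 1);
    build_range(mid + 1, hi, depth + 1);
  }

  struct Cand {
    double d2;
    int idx;
  };
  // max-heap ordering: worst candidate on top; ties -> larger index is worse
  struct CandWorse {
    bool operator()(const Cand& a, const Cand& b) const {
      if (a.d2 != b.d2) return a.d2 < b.d2;
      return a.idx < b.idx;
    }
  };

  typedef std::priority_queue<Cand, std::vector<Cand>, CandWorse> Heap;

  void knn_range(const double* q, int k, int lo, int hi, int depth,
                 Heap& heap) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int axis = depth % 3;
    int pi = perm[mid];
    double dx = pts(pi, 0) - q[0];
    double dy = pts(pi, 1) - q[1];
    double dz = pts(pi, 2) - q[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    consider(heap, k, d2, pi);
    double diff = q[axis] - pts(pi, axis);
    int first_lo = diff < 0 ? lo : mid + 1;
    int first_hi = diff < 0 ? mid : hi;
    int second_lo = diff < 0 ? mid + 1 : lo;
    int second_hi = diff < 0 ? hi : mid;
    knn_range(q, k, first_lo, first_hi, depth + 1, heap);
    double plane2 = diff * diff;
    if (static_cast<int>(heap.size()) < k || plane2 <= heap.top().d2) {
      knn_range(q, k, second_lo, second_hi, depth + 1, heap);
    }
  }

  static void consider(Heap& heap, int k, double d2, int idx) {
    if (static_cast<int>(heap.size()) < k) {
      heap.push({d2, idx});
    } else {
      const Cand& worst = heap.top();
      bool better = d2 < worst.d2 || (d2 == worst.d2 && idx < worst.idx);
      if (better) {
        heap.pop();
        heap.push({d2, idx});
      }
    }
  }

  void knn(const double* q, int k, int* out_idx, double* out_d) const {
    Heap heap;
    knn_range(q, k, 0, n, 0, heap);
    int m = static_cast<int>(heap.size());
    for (int j = m - 1; j >= 0; --j) {
      out_idx[j] = heap.top().idx;
      out_d[j] = std::sqrt(heap.top().d2);
      heap.pop();
    }
  }
};

// [[Rcpp::export(name = ".kdtree_build")]]
SEXP kdtree_build_cpp(const arma::mat& pts) {
  if (pts.n_rows == 0) stop("empty cloud: cannot build spatial index");
  if (pts.n_cols != 3) stop("points must be N x 3");
  XPtr<KDTree> tree(new KDTree(), true);
  tree->build(pts);
  return tree;
}

// [[Rcpp::export(name = ".kdtree_query")]]
List kdtree_query_cpp(SEXP tree_ptr, const arma::mat& queries, int k) {
  XPtr<KDTree> tree(tree_ptr);
  int m = static_cast<int>(queries.n_rows);
  if (k < 1) stop("k must be >= 1");
  if (k > tree->n) stop("k exceeds the number of indexed points");
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<int> ibuf(k);
  std::vector<double> dbuf(k);
  for (int i = 0; i < m; ++i) {
    double q[3] = {queries(i, 0), queries(i, 1), queries(i, 2)};
    tree->knn(q, k, ibuf.data(), dbuf.data());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = ibuf[j] + 1;  // 1-based for R
      dist(i, j) = dbuf[j];
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// [[Rcpp::export(name = ".kdtree_size")]]
int kdtree_size_cpp(SEXP tree_ptr) {
  XPtr<KDTree> tree(tree_ptr);
  return tree->n;
}

// PCA plane-fit normals: for each point, take its k nearest neighbours
// (including the point itself), form the neighbourhood covariance
// C = (1/k) * sum (x_j - xbar)(x_j - xbar)^T and return the unit eigenvector
// of the smallest eigenvalue. Sign is left unoriented.
// [[Rcpp::export(name = ".pca_normals")]]
arma::mat pca_normals_cpp(const arma::mat& pts, int k) {
  int n = static_cast<int>(pts.n_rows);
  if (k < 3) stop("k_neighbors must be >= 3");
  if (k > n) stop("cloud smaller than k_neighbors");
  KDTree tree;
  tree.build(pts);
  arma::mat normals(n, 3);
  std::vector<int> ibuf(k);
  std::vector<double> dbuf(k);
  arma::mat nb(k, 3);
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    tree.knn(q, k, ibuf.data(), dbuf.data());
    for (int j = 0; j < k; ++j) nb.row(j) = pts.row(ibuf[j]);
    arma::rowvec ctr = arma::mean(nb, 0);
    arma::mat X = nb.each_row() - ctr;
    arma::mat C = (X.t() * X) / static_cast<double>(k);
    arma::vec eigval;
    arma::mat eigvec;
    arma::eig_sym(eigval, eigvec, C);  // ascending eigenvalues
    arma::vec v = eigvec.col(0);
    normals(i, 0) = v(0);
    normals(i, 1) = v(1);
    normals(i, 2) = v(2);
  }
  return normals;
}
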