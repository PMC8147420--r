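#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Static k-d tree over the rows of a numeric matrix, built once and queried
// with axis-aligned (orthogonal) range boxes.  The tree is implicit: build()
// permutes an index array with nth_element so that the median of every
// subrange sits at its midpoint; range() recurses on the two halves, pruning
// a half whenever the box lies entirely on one side of the splitting value.
// Subranges of <= LEAF points are scanned linearly.

class KDTree {
public:
  int dim, n;
  std::vector<double> pts;  // row-major, n * dim
  std::vector<int> idx;     // permutation of 0..n-1

  static const int LEAF = 8;

  KDTree(const NumericMatrix &m) : dim(m.ncol()), n(m.nrow()), pts(n * dim), idx(n) {
    for (int i = 0; i < n; ++i) {
      idx[i] = i;
      for (int j = 0; j < dim; ++j) pts[i * dim + j] = m(i, j);
    }
    build(0, n, 0);
  }

  void build(int l, int r, int depth) {
    if (r - l <= LEAF) return;
    int axis = depth % dim;
    int m = (l + r) / 2;
    std::nth_element(idx.begin() + l, idx.begin() + m, idx.begin() + r,
                     [&](int a, int b) { return pts[a * dim + axis] < pts[b * dim + axis]; });
    build(l, m, depth + 1);
    build(m + 1, r, depth + 1);
  }

  bool inbox(int i, const double *lo, const double *hi) const {
    const double *p = &pts[i * dim];
    for (int j = 0; j < dim; ++j)
      if (p[j] < lo[j] || p[j] > hi[j]) return false;
    return true;
  }

  void range(int l, int r, int depth, const double *lo, const double *hi,
             std::vector<int> &out) const {
    if (r - l <= LEAF) {
      for (int i = l; i < r; ++i)
        if (inbox(idx[i], lo, hi)) out.push_back(idx[i]);
      return;
    }
    int axis = depth % dim;
    int m = (l + r) / 2;
    double v = pts[idx[m] * dim + axis];
    if (inbox(idx[m], lo, hi)) out.push_back(idx[m]);
    if (lo[axis] <= v) range(l, m, depth + 1, lo, hi, out);
    if (hi[axis] >= v) range(m + 1, r, depth + 1, lo, hi, out);
  }
};

// [[Rcpp::export(name = ".kdtree_build")]]
SEXP kdtree_build(NumericMatrix pts) {
  XPtr<KDTree> p(new KDTree(pts), true);
  return p;
}

// [[Rcpp::export(name = ".kdtree_range")]]
IntegerVector kdtree_range(SEXP tree, NumericVector lo, NumericVector hi) {
  XPtr<KDTree> p(tree);
  if ((int)lo.size() != p->dim || (int)hi.size() != p->dim)
    stop("query box dimensionality does not match the tree");
  std::vector<int> out;
  p->range(0, p->n, 0, lo.begin(), hi.begin(), out);
  std::sort(out.begin(), out.end());
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;  // 1-based
  return res;
}

// [[Rcpp::export(name = ".kdtree_size")]]
int kdtree_size(SEXP tree) {
  XPtr<KDTree> p(tree);
  return p->n;
}
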