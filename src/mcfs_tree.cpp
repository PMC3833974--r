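// Greedy information-gain decision trees on categorical attributes, plus the
// Monte Carlo feature-selection accumulation loop. Categories are coded
// 1..ncat[j] with 0 = missing; missing values follow the majority child at a
// split. Attribute tie-breaks keep the first-listed attribute, so the caller
// passes candidate attributes in lexicographic name order.
//
// Hot path: the null-calibration of the feature selection builds ~1e5-1e6
// trees, so node statistics are gathered in one pass per node into reused
// flat buffers and the row set is partitioned in place.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

static inline double h2(double a, double b) {
  double n = a + b;
  if (n <= 0) return 0.0;
  double h = 0.0;
  if (a > 0) h -= (a / n) * std::log2(a / n);
  if (b > 0) h -= (b / n) * std::log2(b / n);
  return h;
}

struct Node {
  int attr;        // column of X, -1 for leaf
  int major_cat;   // category missing values follow (valid if attr >= 0)
  int leaf_class;  // majority class at node (prediction fallback)
  int parent;
  int depth;
  int n, c1, c2;
  double ig;
  std::vector<int> child; // size ncat[attr]+1, -1 where no training rows
};

class Tree {
public:
  const int* X;   // column-major n_total x d
  int n_total;
  const int* y;   // 1/2 per row of X
  const IntegerVector& ncat;
  const std::vector<int>& attrs; // 0-based columns, in tie-break order
  int m, Kmax;
  int max_depth;
  double v;
  int n_root = 0;
  int root_major = 1;
  std::vector<Node> nodes;
  std::vector<double> contrib;   // per X column: IG * (n/n_root)^v summed
  std::vector<int> rows, scratch;
  std::vector<int> cnt;          // m x (Kmax+1) x 2 class-by-category counts
  std::vector<int> pos;          // Kmax+2 partition cursors

  Tree(const IntegerMatrix& X_, const int* y_, const IntegerVector& ncat_,
       const std::vector<int>& attrs_, int max_depth_, double v_)
      : X(X_.begin()), n_total(X_.nrow()), y(y_), ncat(ncat_), attrs(attrs_),
        m((int)attrs_.size()), max_depth(max_depth_), v(v_),
        contrib(X_.ncol(), 0.0) {
    Kmax = 0;
    for (int a : attrs) if (ncat[a] > Kmax) Kmax = ncat[a];
    cnt.resize((size_t)m * (Kmax + 1) * 2);
    pos.resize(Kmax + 2);
  }

  void fit(const std::vector<int>& train) {
    rows = train;
    scratch.resize(rows.size());
    n_root = (int)rows.size();
    int c1 = 0;
    for (int r : rows) if (y[r] == 1) ++c1;
    root_major = (c1 * 2 >= n_root) ? 1 : 2;
    build(0, n_root, 0, -1);
  }

  int build(int lo, int hi, int depth, int parent) {
    int n = hi - lo;
    int c1 = 0;
    for (int i = lo; i < hi; ++i) c1 += (y[rows[i]] == 1);
    int c2 = n - c1;
    int idx = (int)nodes.size();
    {
      Node nd;
      nd.attr = -1; nd.major_cat = 0;
      nd.leaf_class = (c1 > c2) ? 1 : (c2 > c1 ? 2 : root_major);
      nd.parent = parent; nd.depth = depth;
      nd.n = n; nd.c1 = c1; nd.c2 = c2; nd.ig = 0.0;
      nodes.push_back(nd);
    }
    if (c1 == 0 || c2 == 0 || depth >= max_depth) return idx;

    std::memset(cnt.data(), 0, cnt.size() * sizeof(int));
    const int stride = (Kmax + 1) * 2;
    for (int i = lo; i < hi; ++i) {
      int r = rows[i];
      int cls = y[r] - 1;
      int* base = cnt.data() + cls;
      for (int j = 0; j < m; ++j) {
        int cat = X[(size_t)attrs[j] * n_total + r];
        base[j * stride + cat * 2]++;
      }
    }

    double Hp = h2(c1, c2);
    double best_ig = 0.0;
    int best_j = -1, best_major = 0;
    for (int j = 0; j < m; ++j) {
      int K = ncat[attrs[j]];
      const int* base = cnt.data() + (size_t)j * stride;
      int miss1 = base[0], miss2 = base[1];
      // majority category over observed values; ties -> smallest code
      int major = 1, major_n = -1;
      for (int k = 1; k <= K; ++k) {
        int tot = base[2 * k] + base[2 * k + 1];
        if (tot > major_n) { major_n = tot; major = k; }
      }
      double hc = 0.0;
      for (int k = 1; k <= K; ++k) {
        double t1 = base[2 * k], t2 = base[2 * k + 1];
        if (k == major) { t1 += miss1; t2 += miss2; }
        double nk = t1 + t2;
        if (nk > 0) hc += (nk / n) * h2(t1, t2);
      }
      double ig = Hp - hc;
      if (ig > best_ig + 1e-12) {
        best_ig = ig; best_j = j; best_major = major;
      }
    }
    if (best_j < 0 || best_ig <= 1e-12) return idx;

    int best_attr = attrs[best_j];
    contrib[best_attr] += best_ig * std::pow((double)n / n_root, v);
    int K = ncat[best_attr];
    const int* base = cnt.data() + (size_t)best_j * stride;

    // stable in-place partition of rows[lo,hi) by category (missing ->
    // majority child)
    pos[1] = 0;
    for (int k = 1; k <= K; ++k) {
      int nk = base[2 * k] + base[2 * k + 1];
      if (k == best_major) nk += base[0] + base[1];
      pos[k + 1] = pos[k] + nk;
    }
    const int* col = X + (size_t)best_attr * n_total;
    std::vector<int> cursor(pos.begin() + 1, pos.begin() + K + 2);
    for (int i = lo; i < hi; ++i) {
      int r = rows[i];
      int cat = col[r];
      if (cat == 0) cat = best_major;
      scratch[cursor[cat - 1]++] = r;
    }
    std::copy(scratch.begin(), scratch.begin() + n, rows.begin() + lo);

    std::vector<int> child(K + 1, -1);
    std::vector<int> seg(pos.begin() + 1, pos.begin() + K + 2);
    for (int k = 1; k <= K; ++k) {
      int s = seg[k - 1], e = seg[k];
      if (e > s)
        child[k] = build(lo + s, lo + e, depth + 1, idx);
    }
    nodes[idx].attr = best_attr;
    nodes[idx].major_cat = best_major;
    nodes[idx].ig = best_ig;
    nodes[idx].child = std::move(child);
    return idx;
  }

  int predict(int row) const {
    int cur = 0;
    while (nodes[cur].attr >= 0) {
      int cat = X[(size_t)nodes[cur].attr * n_total + row];
      if (cat == 0 || nodes[cur].child[cat] < 0)
        cat = nodes[cur].major_cat;
      int nxt = nodes[cur].child[cat];
      if (nxt < 0) break;
      cur = nxt;
    }
    return nodes[cur].leaf_class;
  }

  // weighted accuracy (mean per-class recall) on test rows; -1 when a class
  // is absent from the test split
  double wacc(const std::vector<int>& test) const {
    int n1 = 0, n2 = 0, hit1 = 0, hit2 = 0;
    for (int r : test) {
      int pred = predict(r);
      if (y[r] == 1) { ++n1; if (pred == 1) ++hit1; }
      else { ++n2; if (pred == 2) ++hit2; }
    }
    if (n1 == 0 || n2 == 0) return -1.0;
    return 0.5 * ((double)hit1 / n1 + (double)hit2 / n2);
  }
};

static std::vector<int> to_vec0(const IntegerVector& v) {
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1; // 1-based -> 0-based
  return out;
}

// [[Rcpp::export]]
List cpp_build_tree(IntegerMatrix X, IntegerVector y, IntegerVector ncat,
                    IntegerVector attrs, IntegerVector train_rows,
                    IntegerVector test_rows, int max_depth, double v) {
  std::vector<int> a = to_vec0(attrs);
  std::vector<int> tr = to_vec0(train_rows);
  std::vector<int> te = to_vec0(test_rows);
  Tree tree(X, y.begin(), ncat, a, max_depth, v);
  tree.fit(tr);
  int nn = (int)tree.nodes.size();
  IntegerVector id(nn), parent(nn), attr(nn), nvec(nn), c1(nn), c2(nn),
      depth(nn), leaf_class(nn);
  NumericVector ig(nn);
  for (int i = 0; i < nn; ++i) {
    const Node& nd = tree.nodes[i];
    id[i] = i + 1;
    parent[i] = nd.parent + 1; // 0 for root
    attr[i] = nd.attr + 1;     // 0 for leaf
    nvec[i] = nd.n; c1[i] = nd.c1; c2[i] = nd.c2;
    depth[i] = nd.depth; ig[i] = nd.ig; leaf_class[i] = nd.leaf_class;
  }
  IntegerVector pred(te.size());
  for (size_t i = 0; i < te.size(); ++i) pred[i] = tree.predict(te[i]);
  return List::create(
      _["nodes"] = DataFrame::create(
          _["id"] = id, _["parent"] = parent, _["split_attr"] = attr,
          _["n"] = nvec, _["n_affected"] = c1, _["n_unaffected"] = c2,
          _["depth"] = depth, _["ig"] = ig, _["leaf_class"] = leaf_class),
      _["pred"] = pred,
      _["contrib"] = NumericVector(tree.contrib.begin(), tree.contrib.end()),
      _["wacc"] = te.empty() ? NA_REAL : tree.wacc(te));
}

// projections: list of list(attrs = 1-based cols in tie-break order,
//                           trains = list of 1-based row vectors,
//                           tests  = list of matching test row vectors)
// [[Rcpp::export]]
List cpp_mcfs_ri(IntegerMatrix X, IntegerVector y, IntegerVector ncat,
                 List projections, double u, double v, int max_depth) {
  int d = X.ncol();
  NumericVector ri(d);
  IntegerVector appearances(d);
  int used = 0, skipped = 0;
  for (int p = 0; p < projections.size(); ++p) {
    List proj = projections[p];
    IntegerVector attrs1 = proj["attrs"];
    std::vector<int> a = to_vec0(attrs1);
    for (int j : a) appearances[j]++;
    List trains = proj["trains"];
    List tests = proj["tests"];
    for (int s = 0; s < trains.size(); ++s) {
      std::vector<int> tr = to_vec0(trains[s]);
      std::vector<int> te = to_vec0(tests[s]);
      Tree tree(X, y.begin(), ncat, a, max_depth, v);
      tree.fit(tr);
      double w = tree.wacc(te);
      if (w < 0) { ++skipped; continue; }
      ++used;
      double wu = std::pow(w, u);
      for (int j : a)
        if (tree.contrib[j] > 0) ri[j] += wu * tree.contrib[j];
    }
  }
  return List::create(_["ri"] = ri, _["appearances"] = appearances,
                      _["trees_used"] = used, _["trees_skipped"] = skipped);
}
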