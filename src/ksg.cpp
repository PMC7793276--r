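#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Kraskov-Stögbauer-Grassberger estimator 1 of I(X;Y|Z) under the max-norm.
//
// A kd-tree (bounding-box, median split, leaf linear scan) over the joint
// space yields epsilon_i (distance to the k-th neighbour); kd-trees over the
// marginal spaces (x,z), (y,z), (z) yield the strictly-within-epsilon
// counts.  psi_tab[c] must hold digamma(c + 1) for c = 0..n-1.  With zero z
// columns the marginal count n_z is n-1 for every point and the expression
// reduces to the unconditional KSG MI estimator.

namespace {

struct KDTree {
  int n, d, leaf;
  std::vector<double> pts;   // column-major n x d
  std::vector<int> idx;      // permutation: points in node ranges
  struct Node {
    int lo, hi, left, right; // point range; children (-1 = leaf)
    std::vector<double> bmin, bmax;
  };
  std::vector<Node> nodes;

  double coord(int p, int c) const { return pts[p + (size_t)c * n]; }

  void init(const double *src_cols[], const int ncols[], int nblocks,
            int n_, int leaf_ = 16) {
    n = n_;
    leaf = leaf_;
    d = 0;
    for (int b = 0; b < nblocks; ++b) d += ncols[b];
    pts.resize((size_t)n * d);
    int c0 = 0;
    for (int b = 0; b < nblocks; ++b) {
      for (int c = 0; c < ncols[b]; ++c, ++c0)
        std::copy(src_cols[b] + (size_t)c * n, src_cols[b] + (size_t)(c + 1) * n,
                  pts.begin() + (size_t)c0 * n);
    }
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.clear();
    nodes.reserve(2 * (n / leaf + 2));
    build(0, n);
  }

  int build(int lo, int hi) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    {
      Node nd;
      nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
      nd.bmin.assign(d, R_PosInf);
      nd.bmax.assign(d, R_NegInf);
      for (int i = lo; i < hi; ++i)
        for (int c = 0; c < d; ++c) {
          double v = coord(idx[i], c);
          if (v < nd.bmin[c]) nd.bmin[c] = v;
          if (v > nd.bmax[c]) nd.bmax[c] = v;
        }
      nodes[id] = nd;
    }
    if (hi - lo > leaf) {
      // split on the widest dimension at the median
      int sc = 0;
      double w = -1.0;
      for (int c = 0; c < d; ++c) {
        double wc = nodes[id].bmax[c] - nodes[id].bmin[c];
        if (wc > w) { w = wc; sc = c; }
      }
      if (w > 0) {
        int mid = (lo + hi) / 2;
        const double *p = pts.data();
        const int nn = n;
        std::nth_element(idx.begin() + lo, idx.begin() + mid,
                         idx.begin() + hi,
                         [p, nn, sc](int a, int b) {
                           return p[a + (size_t)sc * nn] <
                                  p[b + (size_t)sc * nn];
                         });
        int l = build(lo, mid);
        int r = build(mid, hi);
        nodes[id].left = l;
        nodes[id].right = r;
      }
    }
    return id;
  }

  // smallest possible max-norm distance from point q (by index into pts)
  // to node's bounding box
  double box_min(const Node &nd, int q) const {
    double acc = 0.0;
    for (int c = 0; c < d; ++c) {
      double v = coord(q, c), lo = nd.bmin[c], hi = nd.bmax[c];
      double e = (v < lo) ? lo - v : (v > hi ? v - hi : 0.0);
      if (e > acc) acc = e;
    }
    return acc;
  }
  // largest max-norm distance from q to any corner of the box
  double box_max(const Node &nd, int q) const {
    double acc = 0.0;
    for (int c = 0; c < d; ++c) {
      double v = coord(q, c);
      double e = std::max(std::fabs(v - nd.bmin[c]),
                          std::fabs(nd.bmax[c] - v));
      if (e > acc) acc = e;
    }
    return acc;
  }
  double dist(int q, int p) const {
    double acc = 0.0;
    for (int c = 0; c < d; ++c) {
      double v = std::fabs(coord(q, c) - coord(p, c));
      if (v > acc) acc = v;
    }
    return acc;
  }

  // k-th smallest distance from point q to all points outside the excluded
  // original-index range [xlo, xhi] (the range always contains q itself).
  // seed_ids (candidate points, e.g. the previous query's neighbours) give
  // the branch-and-bound an immediately tight upper bound; ids of the
  // found neighbours are written back to seed_ids for the next query.
  double knn(int q, int k, int xlo, int xhi,
             std::vector<int> &seed_ids) const {
    // tau: k-th smallest distance among the (valid) seed candidates; the
    // seeds are a subset of all points, so tau bounds the true k-th
    // distance from above and is a sound initial pruning radius
    std::vector<double> seed_d;
    seed_d.reserve(seed_ids.size());
    for (size_t s = 0; s < seed_ids.size(); ++s) {
      int p = seed_ids[s];
      if (p < 0 || (p >= xlo && p <= xhi)) continue;
      seed_d.push_back(dist(q, p));
    }
    double tau = R_PosInf;
    if ((int)seed_d.size() >= k) {
      std::nth_element(seed_d.begin(), seed_d.begin() + (k - 1),
                       seed_d.end());
      tau = seed_d[k - 1] * (1.0 + 1e-12);
    }
    std::vector<std::pair<double, int> > best(
        k, std::make_pair(R_PosInf, -1));
    knn_rec(0, q, best, xlo, xhi, tau);
    seed_ids.resize(k);
    for (int s = 0; s < k; ++s) seed_ids[s] = best[s].second;
    return best.front().first;
  }
  void knn_rec(int id, int q, std::vector<std::pair<double, int> > &best,
               int xlo, int xhi, double tau) const {
    const Node &nd = nodes[id];
    double bound = std::min(best.front().first, tau);
    if (box_min(nd, q) >= bound) return;
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int p = idx[i];
        if (p >= xlo && p <= xhi) continue;  // Theiler exclusion (and self)
        double dv = dist(q, p);
        if (dv < best.front().first) {
          std::pop_heap(best.begin(), best.end());
          best.back() = std::make_pair(dv, p);
          std::push_heap(best.begin(), best.end());
        }
      }
      return;
    }
    double dl = box_min(nodes[nd.left], q), dr = box_min(nodes[nd.right], q);
    bound = std::min(best.front().first, tau);
    if (dl < dr) {
      knn_rec(nd.left, q, best, xlo, xhi, tau);
      if (dr < std::min(best.front().first, tau))
        knn_rec(nd.right, q, best, xlo, xhi, tau);
    } else {
      knn_rec(nd.right, q, best, xlo, xhi, tau);
      if (dl < std::min(best.front().first, tau))
        knn_rec(nd.left, q, best, xlo, xhi, tau);
    }
  }

  // number of points strictly within eps of q (q itself included)
  int count_within(int q, double eps) const { return count_rec(0, q, eps); }
  int count_rec(int id, int q, double eps) const {
    const Node &nd = nodes[id];
    if (box_min(nd, q) >= eps) return 0;
    if (box_max(nd, q) < eps) return nd.hi - nd.lo;
    if (nd.left < 0) {
      int c = 0;
      for (int i = nd.lo; i < nd.hi; ++i)
        if (dist(q, idx[i]) < eps) ++c;
      return c;
    }
    return count_rec(nd.left, q, eps) + count_rec(nd.right, q, eps);
  }
};

} // namespace

// [[Rcpp::export(name = ".ksg_cmi_cpp")]]
double ksg_cmi_cpp(NumericMatrix x, NumericMatrix y, NumericMatrix z,
                   int k, NumericVector psi_tab,
                   IntegerVector excl_lo, IntegerVector excl_hi) {
  const int n = x.nrow();
  const int dx = x.ncol(), dy = y.ncol(), dz = z.ncol();
  if (y.nrow() != n || (dz > 0 && z.nrow() != n))
    stop("x, y, z must have the same number of rows");
  if (k < 1 || n <= k) stop("need n > k >= 1");
  if (excl_lo.size() != n || excl_hi.size() != n)
    stop("exclusion bounds must cover every row");

  const double *px = REAL(x), *py = REAL(y), *pz = (dz > 0) ? REAL(z) : NULL;

  KDTree joint, txz, tyz, tz;
  {
    const double *cols3[3] = {px, py, pz};
    const int nc3[3] = {dx, dy, dz};
    joint.init(cols3, nc3, dz > 0 ? 3 : 2, n);
    const double *colsxz[2] = {px, pz};
    const int ncxz[2] = {dx, dz};
    txz.init(colsxz, ncxz, dz > 0 ? 2 : 1, n);
    const double *colsyz[2] = {py, pz};
    const int ncyz[2] = {dy, dz};
    tyz.init(colsyz, ncyz, dz > 0 ? 2 : 1, n);
    if (dz > 0) {
      const double *colsz[1] = {pz};
      const int ncz[1] = {dz};
      tz.init(colsz, ncz, 1, n);
    }
  }

  double acc = 0.0;
  std::vector<int> warm(k, -1);
  for (int i = 0; i < n; ++i) {
    const int lo = excl_lo[i], hi = excl_hi[i];
    double eps = joint.knn(i, k, lo, hi, warm);
    // bulk tree counts include the excluded rows; subtract them directly
    int exz = 0, eyz = 0, ez = 0;
    for (int j = lo; j <= hi; ++j) {
      if (txz.dist(i, j) < eps) ++exz;
      if (tyz.dist(i, j) < eps) ++eyz;
      if (dz > 0 && tz.dist(i, j) < eps) ++ez;
    }
    int nxz = txz.count_within(i, eps) - exz;
    int nyz = tyz.count_within(i, eps) - eyz;
    int nz = (dz > 0) ? tz.count_within(i, eps) - ez : n - 1 - (hi - lo);
    acc += psi_tab[nxz] + psi_tab[nyz] - psi_tab[nz];
  }
  return psi_tab[k - 1] - acc / (double)n;
}
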