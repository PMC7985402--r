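#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Park-Miller "minimal standard" Lehmer generator (a = 48271, m = 2^31 - 1).
// The update is computed as prod - trunc(prod / m) * m with prod < 2^47, so
// every intermediate is exactly representable and the quotient truncation is
// provably the exact floor (the true fractional part is at least 1/m away
// from an integer, far beyond double rounding error). The identical stream is
// therefore reproducible in pure R double arithmetic, which is what makes an
// exact explicit-loop reimplementation of the forest possible in tests.
static const double LEHMER_M = 2147483647.0;

static inline double exact_mod(double prod, double m) {
  double q = (double)(long long)(prod / m);
  return prod - q * m;
}

struct Lehmer {
  double s;
  explicit Lehmer(double seed) {
    double r = exact_mod(seed, 2147483646.0);
    if (r < 0) r += 2147483646.0;
    s = r + 1.0;
  }
  double unif() {
    s = exact_mod(48271.0 * s, LEHMER_M);
    return s / LEHMER_M;
  }
  int below(int k) { return (int)(unif() * (double)k); }
};

struct Forest {
  // flat node arrays, one tree after another
  std::vector<int> feat, left, right;
  std::vector<double> thr, value;
};

// CART-style regression tree growth with exact variance-reduction splits.
//
// Split search walks each candidate feature's globally presorted row order
// (ties broken by row index) and restricts to the node's rows via a
// node-assignment array; every bootstrap copy of a row follows the same
// path, so membership is tracked per row with a multiplicity count.
// Candidate thresholds are midpoints between consecutive distinct member
// values with at least min_leaf instances on each side; the gain
// sl^2/k + sr^2/(nn-k) - sy^2/nn is maximized (strict >, first feature in
// sampled order wins ties).
class Grower {
public:
  const double *X;  // column-major n x p
  const double *y;
  int n, p, mtry, min_leaf;
  Lehmer &rng;
  Forest &fo;
  const int *gorder;               // p x n presorted row indices per column
  const double *gvals;             // matching presorted values per column
  std::vector<int> perm;           // feature pool for per-split sampling
  std::vector<int> swaps;          // Fisher-Yates undo log (per node)
  std::vector<int> rows;           // member rows, ascending, partitioned
  std::vector<int> tmp;            // stable-partition scratch
  std::vector<int> row_count;      // bootstrap multiplicity per row
  std::vector<int> row_node;       // node index per member row
  std::vector<std::pair<double, int> > srt;  // small-node sort buffer
  std::vector<int> cmp_row;        // compacted member rows (walk path)
  std::vector<double> cmp_val;     // compacted member values (walk path)
  std::vector<int> used_feat;      // features used by the current tree

  Grower(const double *X_, const double *y_, int n_, int p_, int mtry_,
         int min_leaf_, Lehmer &rng_, Forest &fo_, const int *gorder_,
         const double *gvals_)
      : X(X_), y(y_), n(n_), p(p_), mtry(mtry_), min_leaf(min_leaf_),
        rng(rng_), fo(fo_), gorder(gorder_), gvals(gvals_) {
    perm.resize(p);
    for (int j = 0; j < p; ++j) perm[j] = j;
    swaps.resize(mtry);
    rows.resize(n);
    tmp.resize(n);
    row_count.resize(n);
    row_node.resize(n);
    srt.resize(n);
    cmp_row.resize(n);
    cmp_val.resize(n);
  }

  // grow the node whose member rows are rows[lo, hi) (ascending);
  // returns its index in the flat arrays
  int grow(int lo, int hi) {
    int idx = (int)fo.feat.size();
    fo.feat.push_back(-1);
    fo.thr.push_back(0.0);
    fo.left.push_back(-1);
    fo.right.push_back(-1);
    fo.value.push_back(0.0);

    int nn = 0;
    double sy = 0.0;
    for (int t = lo; t < hi; ++t) {
      int r = rows[t];
      row_node[r] = idx;
      for (int c = 0; c < row_count[r]; ++c) sy += y[r];
      nn += row_count[r];
    }
    fo.value[idx] = sy / nn;
    if (nn < 2 * min_leaf) return idx;

    // sample mtry features without replacement: partial Fisher-Yates,
    // undone afterwards so the pool is back in place for the next node
    for (int j = 0; j < mtry; ++j) {
      int r = j + rng.below(p - j);
      std::swap(perm[j], perm[r]);
      swaps[j] = r;
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    // Both strategies visit member rows in identical (value, row index)
    // order, so the choice is a pure speed heuristic: sort the node's rows
    // when the node is small, walk the presorted global order otherwise.
    int nr = hi - lo;
    int lg = 0;
    while ((1 << lg) < nr) ++lg;
    bool use_sort = (double)nr * (lg + 2) < (double)n;
    for (int j = 0; j < mtry; ++j) {
      int f = perm[j];
      const double *xc = X + (size_t)f * n;
      int k = 0;
      double sl = 0.0, prev_x = 0.0;
      bool have_prev = false;
      if (use_sort) {
        for (int t = 0; t < nr; ++t) {
          srt[t].first = xc[rows[lo + t]];
          srt[t].second = rows[lo + t];
        }
        std::sort(srt.begin(), srt.begin() + nr);
        for (int t = 0; t < nr; ++t) {
          int r = srt[t].second;
          double x = srt[t].first;
          if (have_prev && k >= min_leaf && nn - k >= min_leaf &&
              prev_x < x) {
            double sr = sy - sl;
            double gain = sl * sl / k + sr * sr / (nn - k) - sy * sy / nn;
            if (gain > best_gain) {
              best_gain = gain;
              best_f = f;
              double mid = (prev_x + x) / 2.0;
              if (!(mid < x)) mid = prev_x;  // guard midpoint rounding up
              best_thr = mid;
            }
          }
          for (int c = 0; c < row_count[r]; ++c) {
            sl += y[r];
            ++k;
          }
          prev_x = x;
          have_prev = true;
        }
      } else {
        // branchless compaction of the node's members out of the global
        // (value, row) order, then a tight scan over the compacted block;
        // the visit order and arithmetic are identical to the sort path
        const int *gi = gorder + (size_t)f * n;
        const double *gv = gvals + (size_t)f * n;
        int c = 0;
        for (int i = 0; i < n; ++i) {
          int r = gi[i];
          cmp_row[c] = r;
          cmp_val[c] = gv[i];
          c += (row_node[r] == idx);
        }
        for (int t = 0; t < c; ++t) {
          int r = cmp_row[t];
          double x = cmp_val[t];
          if (have_prev && k >= min_leaf && nn - k >= min_leaf &&
              prev_x < x) {
            double sr = sy - sl;
            double gain = sl * sl / k + sr * sr / (nn - k) - sy * sy / nn;
            if (gain > best_gain) {
              best_gain = gain;
              best_f = f;
              double mid = (prev_x + x) / 2.0;
              if (!(mid < x)) mid = prev_x;  // guard midpoint rounding up
              best_thr = mid;
            }
          }
          for (int cc = 0; cc < row_count[r]; ++cc) {
            sl += y[r];
            ++k;
          }
          prev_x = x;
          have_prev = true;
        }
      }
    }
    for (int j = mtry - 1; j >= 0; --j) std::swap(perm[j], perm[swaps[j]]);

    if (best_f < 0) return idx;

    // stable in-place partition keeps each child's rows ascending
    const double *xc = X + (size_t)best_f * n;
    int nl = 0, nright = 0;
    for (int t = lo; t < hi; ++t) {
      if (xc[rows[t]] <= best_thr)
        rows[lo + nl++] = rows[t];
      else
        tmp[nright++] = rows[t];
    }
    for (int t = 0; t < nright; ++t) rows[lo + nl + t] = tmp[t];

    fo.feat[idx] = best_f;
    fo.thr[idx] = best_thr;
    used_feat.push_back(best_f);
    fo.left[idx] = grow(lo, lo + nl);
    fo.right[idx] = grow(lo + nl, hi);
    return idx;
  }
};

static inline double predict_one(const Forest &fo, int root, const double *X,
                                 int n, int i, int override_f,
                                 const double *xf) {
  int node = root;
  while (fo.feat[node] >= 0) {
    int f = fo.feat[node];
    double xval = (f == override_f) ? xf[i] : X[(size_t)f * n + i];
    node = (xval <= fo.thr[node]) ? fo.left[node] : fo.right[node];
  }
  return fo.value[node];
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_leaf, double seed, bool importance,
                bool keep_forest) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, n_features]");
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (min_leaf < 1) stop("min_leaf must be >= 1");
  const double *Xp = REAL(X);
  const double *yp = REAL(y);

  // presort every column once per forest: rows ordered by (value, row index)
  std::vector<int> gorder((size_t)p * n);
  std::vector<double> gvals((size_t)p * n);
  {
    std::vector<std::pair<double, int> > buf(n);
    for (int f = 0; f < p; ++f) {
      const double *xc = Xp + (size_t)f * n;
      for (int i = 0; i < n; ++i) {
        buf[i].first = xc[i];
        buf[i].second = i;
      }
      std::sort(buf.begin(), buf.end());
      int *gi = gorder.data() + (size_t)f * n;
      double *gv = gvals.data() + (size_t)f * n;
      for (int i = 0; i < n; ++i) {
        gi[i] = buf[i].second;
        gv[i] = buf[i].first;
      }
    }
  }

  Lehmer rng(seed);
  Lehmer imp_rng(seed + 777007.0);  // separate stream: growth is invariant
                                    // to whether importance is computed
  Forest fo;
  Grower gr(Xp, yp, n, p, mtry, min_leaf, rng, fo, gorder.data(),
            gvals.data());

  NumericVector oob_sum(n), imp_sum(p), imp_ss(p);
  IntegerVector oob_cnt(n);
  std::vector<int> oob, pi;
  std::vector<double> xperm(n);
  List trees;
  if (keep_forest) trees = List(n_trees);

  for (int b = 0; b < n_trees; ++b) {
    std::fill(gr.row_count.begin(), gr.row_count.end(), 0);
    std::fill(gr.row_node.begin(), gr.row_node.end(), -1);
    for (int i = 0; i < n; ++i) gr.row_count[rng.below(n)] += 1;
    int n_rows = 0;
    for (int r = 0; r < n; ++r)
      if (gr.row_count[r] > 0) gr.rows[n_rows++] = r;

    gr.used_feat.clear();
    int node0 = (int)fo.feat.size();
    int root = gr.grow(0, n_rows);

    oob.clear();
    for (int r = 0; r < n; ++r)
      if (gr.row_count[r] == 0) oob.push_back(r);
    int m = (int)oob.size();

    double sse_base = 0.0;
    for (int t = 0; t < m; ++t) {
      double pr = predict_one(fo, root, Xp, n, oob[t], -1, nullptr);
      oob_sum[oob[t]] += pr;
      oob_cnt[oob[t]] += 1;
      double e = yp[oob[t]] - pr;
      sse_base += e * e;
    }

    if (importance && m > 0) {
      std::vector<int> uf(gr.used_feat);
      std::sort(uf.begin(), uf.end());
      uf.erase(std::unique(uf.begin(), uf.end()), uf.end());
      pi.resize(m);
      for (size_t q = 0; q < uf.size(); ++q) {
        int f = uf[q];
        for (int t = 0; t < m; ++t) pi[t] = t;
        for (int j = m - 1; j >= 1; --j) {
          int r = imp_rng.below(j + 1);
          std::swap(pi[j], pi[r]);
        }
        for (int t = 0; t < m; ++t)
          xperm[oob[t]] = Xp[(size_t)f * n + oob[pi[t]]];
        double sse = 0.0;
        for (int t = 0; t < m; ++t) {
          double e = yp[oob[t]] -
                     predict_one(fo, root, Xp, n, oob[t], f, xperm.data());
          sse += e * e;
        }
        double delta = (sse - sse_base) / m;
        imp_sum[f] += delta;
        imp_ss[f] += delta * delta;
      }
    }

    if (keep_forest) {
      int n1 = (int)fo.feat.size();
      NumericMatrix tm(n1 - node0, 5);
      for (int k = node0; k < n1; ++k) {
        tm(k - node0, 0) = fo.feat[k] < 0 ? -1 : fo.feat[k] + 1;
        tm(k - node0, 1) = fo.thr[k];
        tm(k - node0, 2) = fo.left[k] < 0 ? -1 : fo.left[k] - node0 + 1;
        tm(k - node0, 3) = fo.right[k] < 0 ? -1 : fo.right[k] - node0 + 1;
        tm(k - node0, 4) = fo.value[k];
      }
      colnames(tm) = CharacterVector::create("feature", "threshold", "left",
                                             "right", "value");
      trees[b] = tm;
    }
  }

  List out = List::create(
      _["oob_sum"] = oob_sum, _["oob_count"] = oob_cnt,
      _["n_trees"] = n_trees);
  if (importance) {
    NumericVector imp_mean(p), imp_sd(p);
    double B = (double)n_trees;
    for (int f = 0; f < p; ++f) {
      imp_mean[f] = imp_sum[f] / B;
      if (n_trees > 1) {
        double v = (imp_ss[f] - imp_sum[f] * imp_sum[f] / B) / (B - 1.0);
        imp_sd[f] = v > 0 ? std::sqrt(v) : 0.0;
      } else {
        imp_sd[f] = 0.0;
      }
    }
    out["importance_mean"] = imp_mean;
    out["importance_sd"] = imp_sd;
  }
  if (keep_forest) out["trees"] = trees;
  return out;
}
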