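// Extremely randomized bi-clustering trees over a drug-protein interaction
// matrix. A tree node holds a block (row subset x column subset) of the
// target matrix; ROW splits test a drug feature and partition the rows,
// COLUMN splits test a protein feature and partition the columns, so every
// leaf is a bicluster. Split quality is total variance reduction, with
// node "variance" measured as the summed squared deviation from each
// column's block mean (equivalently the sum of per-output population
// variances weighted by entry count), which makes the reduction
// nonnegative by construction.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// Deterministic 64-bit generator (splitmix64) with a hand-rolled uniform
// so results do not depend on the standard library's distribution code.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
  // m distinct values from 0..n-1, in draw order (partial Fisher-Yates)
  std::vector<int> sample(int n, int m) {
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    std::vector<int> out;
    out.reserve(m);
    for (int i = 0; i < m && i < n; ++i) {
      int j = i + below(n - i);
      std::swap(pool[i], pool[j]);
      out.push_back(pool[i]);
    }
    return out;
  }
};

// Orientation-dependent block impurity (total SSE = per-output population
// variance times entry count). A ROW split treats the columns as outputs
// (deviations from column means); a COLUMN split treats the rows as
// outputs (deviations from row means).
double block_sse_cols(const NumericMatrix& Y, const std::vector<int>& rows,
                      const std::vector<int>& cols) {
  double sse = 0.0;
  const int nr = static_cast<int>(rows.size());
  for (int cj : cols) {
    double s = 0.0, s2 = 0.0;
    for (int ri : rows) {
      double y = Y(ri, cj);
      s += y;
      s2 += y * y;
    }
    sse += s2 - s * s / nr;
  }
  return std::max(sse, 0.0);
}

double block_sse_rows(const NumericMatrix& Y, const std::vector<int>& rows,
                      const std::vector<int>& cols) {
  double sse = 0.0;
  const int nc = static_cast<int>(cols.size());
  for (int ri : rows) {
    double s = 0.0, s2 = 0.0;
    for (int cj : cols) {
      double y = Y(ri, cj);
      s += y;
      s2 += y * y;
    }
    sse += s2 - s * s / nc;
  }
  return std::max(sse, 0.0);
}

double block_mean(const NumericMatrix& Y, const std::vector<int>& rows,
                  const std::vector<int>& cols) {
  double s = 0.0;
  for (int cj : cols)
    for (int ri : rows) s += Y(ri, cj);
  return s / (static_cast<double>(rows.size()) * cols.size());
}

struct Candidate {
  int axis;      // 1 = ROW (drug feature), 2 = COLUMN (protein feature)
  int feature;   // 0-based column of X_d or X_p
  double threshold;
  double score;  // variance reduction
  bool valid;
};

// Score a candidate: variance reduction = parent SSE - left SSE - right
// SSE in the orientation of the split axis (columns are the outputs of a
// ROW split, rows the outputs of a COLUMN split); "goes left" iff feature
// value <= threshold. Children below min_leaf pairs invalidate the
// candidate.
Candidate score_candidate(const NumericMatrix& Y, const NumericMatrix& Xf,
                          const std::vector<int>& rows,
                          const std::vector<int>& cols, int axis, int feat,
                          double thr, double parent_sse, int min_leaf) {
  Candidate c{axis, feat, thr, -1.0, false};
  const std::vector<int>& split_idx = (axis == 1) ? rows : cols;
  std::vector<int> left, right;
  left.reserve(split_idx.size());
  right.reserve(split_idx.size());
  for (int idx : split_idx) {
    if (Xf(idx, feat) <= thr) left.push_back(idx); else right.push_back(idx);
  }
  if (left.empty() || right.empty()) return c;
  const size_t other = (axis == 1) ? cols.size() : rows.size();
  if (left.size() * other < static_cast<size_t>(min_leaf) ||
      right.size() * other < static_cast<size_t>(min_leaf)) return c;
  double sse_l, sse_r;
  if (axis == 1) {
    sse_l = block_sse_cols(Y, left, cols);
    sse_r = block_sse_cols(Y, right, cols);
  } else {
    sse_l = block_sse_rows(Y, rows, left);
    sse_r = block_sse_rows(Y, rows, right);
  }
  c.score = std::max(parent_sse - sse_l - sse_r, 0.0);
  c.valid = true;
  return c;
}

void feature_range(const NumericMatrix& Xf, const std::vector<int>& idx,
                   int feat, double& lo, double& hi) {
  lo = R_PosInf;
  hi = R_NegInf;
  for (int i : idx) {
    double v = Xf(i, feat);
    if (v < lo) lo = v;
    if (v > hi) hi = v;
  }
}

// All candidates along one axis. ERT mode: a random feature subset, one
// uniform threshold strictly inside the block's feature range. Exhaustive
// mode: every feature, midpoints between consecutive distinct values.
void axis_candidates(const NumericMatrix& Y, const NumericMatrix& Xf,
                     const std::vector<int>& rows, const std::vector<int>& cols,
                     int axis, int n_cand, bool exhaustive, double parent_sse,
                     int min_leaf, Rng& rng, std::vector<Candidate>& out) {
  // parent_sse must already be in this axis's orientation
  const std::vector<int>& idx = (axis == 1) ? rows : cols;
  if (idx.size() < 2) return;  // nothing to partition on this axis
  const int n_feat = Xf.ncol();
  std::vector<int> feats;
  if (exhaustive) {
    feats.resize(n_feat);
    for (int f = 0; f < n_feat; ++f) feats[f] = f;
  } else {
    feats = rng.sample(n_feat, std::min(n_cand, n_feat));
  }
  for (int f : feats) {
    double lo, hi;
    feature_range(Xf, idx, f, lo, hi);
    if (!(hi > lo)) continue;  // constant feature in block: skip
    if (exhaustive) {
      std::vector<double> vals;
      vals.reserve(idx.size());
      for (int i : idx) vals.push_back(Xf(i, f));
      std::sort(vals.begin(), vals.end());
      vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
      for (size_t t = 0; t + 1 < vals.size(); ++t) {
        double thr = 0.5 * (vals[t] + vals[t + 1]);
        Candidate c = score_candidate(Y, Xf, rows, cols, axis, f, thr,
                                      parent_sse, min_leaf);
        if (c.valid) out.push_back(c);
      }
    } else {
      double thr = lo + rng.unif() * (hi - lo);
      if (!(thr > lo && thr < hi)) continue;  // fp-degenerate draw
      Candidate c = score_candidate(Y, Xf, rows, cols, axis, f, thr,
                                    parent_sse, min_leaf);
      if (c.valid) out.push_back(c);
    }
  }
}

std::vector<Candidate> all_candidates(const NumericMatrix& Y,
                                      const NumericMatrix& Xd,
                                      const NumericMatrix& Xp,
                                      const std::vector<int>& rows,
                                      const std::vector<int>& cols,
                                      int n_row_cand, int n_col_cand,
                                      bool exhaustive, double sse_cols,
                                      double sse_rows, int min_leaf,
                                      Rng& rng) {
  std::vector<Candidate> out;
  axis_candidates(Y, Xd, rows, cols, 1, n_row_cand, exhaustive, sse_cols,
                  min_leaf, rng, out);
  axis_candidates(Y, Xp, rows, cols, 2, n_col_cand, exhaustive, sse_rows,
                  min_leaf, rng, out);
  return out;
}

struct TreeBuilder {
  const NumericMatrix& Y;
  const NumericMatrix& Xd;
  const NumericMatrix& Xp;
  int n_row_cand, n_col_cand, min_leaf;
  bool exhaustive;
  double purity_tol;
  Rng rng;

  std::vector<int> axis_, feature_, left_, right_;
  std::vector<double> threshold_, value_;
  std::vector<std::vector<int>> leaf_rows_, leaf_cols_;

  TreeBuilder(const NumericMatrix& Y, const NumericMatrix& Xd,
              const NumericMatrix& Xp, int nrc, int ncc, int ml, bool ex,
              uint64_t seed)
      : Y(Y), Xd(Xd), Xp(Xp), n_row_cand(nrc), n_col_cand(ncc), min_leaf(ml),
        exhaustive(ex), purity_tol(1e-12), rng(seed) {}

  int new_node() {
    axis_.push_back(0);
    feature_.push_back(NA_INTEGER);
    left_.push_back(NA_INTEGER);
    right_.push_back(NA_INTEGER);
    threshold_.push_back(NA_REAL);
    value_.push_back(NA_REAL);
    leaf_rows_.emplace_back();
    leaf_cols_.emplace_back();
    return static_cast<int>(axis_.size()) - 1;
  }

  void make_leaf(int id, const std::vector<int>& rows,
                 const std::vector<int>& cols) {
    axis_[id] = 0;
    value_[id] = block_mean(Y, rows, cols);
    leaf_rows_[id] = rows;
    leaf_cols_[id] = cols;
  }

  int build(const std::vector<int>& rows, const std::vector<int>& cols) {
    int id = new_node();
    double sse_cols = block_sse_cols(Y, rows, cols);
    double sse_rows = block_sse_rows(Y, rows, cols);
    // pure only when constant in both orientations (all entries equal)
    if (sse_cols <= purity_tol && sse_rows <= purity_tol) {
      make_leaf(id, rows, cols);
      return id;
    }
    std::vector<Candidate> cands =
        all_candidates(Y, Xd, Xp, rows, cols, n_row_cand, n_col_cand,
                       exhaustive, sse_cols, sse_rows, min_leaf, rng);
    // first strict maximum in draw order wins
    int best = -1;
    for (size_t i = 0; i < cands.size(); ++i) {
      if (best < 0 || cands[i].score > cands[best].score) {
        best = static_cast<int>(i);
      }
    }
    if (best < 0) {  // no admissible split
      make_leaf(id, rows, cols);
      return id;
    }
    const Candidate& c = cands[best];
    std::vector<int> rows_l = rows, rows_r = rows, cols_l = cols,
                     cols_r = cols;
    if (c.axis == 1) {
      rows_l.clear();
      rows_r.clear();
      for (int r : rows) {
        if (Xd(r, c.feature) <= c.threshold) rows_l.push_back(r);
        else rows_r.push_back(r);
      }
    } else {
      cols_l.clear();
      cols_r.clear();
      for (int cc : cols) {
        if (Xp(cc, c.feature) <= c.threshold) cols_l.push_back(cc);
        else cols_r.push_back(cc);
      }
    }
    axis_[id] = c.axis;
    feature_[id] = c.feature + 1;  // 1-based for R
    threshold_[id] = c.threshold;
    int l = build(rows_l, cols_l);
    int r = build(rows_r, cols_r);
    left_[id] = l + 1;
    right_[id] = r + 1;
    return id;
  }

  List as_list() {
    int n = static_cast<int>(axis_.size());
    List lr(n), lc(n);
    for (int i = 0; i < n; ++i) {
      if (axis_[i] == 0) {
        IntegerVector r(leaf_rows_[i].begin(), leaf_rows_[i].end());
        IntegerVector cvec(leaf_cols_[i].begin(), leaf_cols_[i].end());
        lr[i] = r + 1;  // 1-based
        lc[i] = cvec + 1;
      } else {
        lr[i] = R_NilValue;
        lc[i] = R_NilValue;
      }
    }
    return List::create(
        _["axis"] = IntegerVector(axis_.begin(), axis_.end()),
        _["feature"] = IntegerVector(feature_.begin(), feature_.end()),
        _["threshold"] = NumericVector(threshold_.begin(), threshold_.end()),
        _["left"] = IntegerVector(left_.begin(), left_.end()),
        _["right"] = IntegerVector(right_.begin(), right_.end()),
        _["value"] = NumericVector(value_.begin(), value_.end()),
        _["leaf_rows"] = lr, _["leaf_cols"] = lc);
  }
};

std::vector<int> seq0(int n) {
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) v[i] = i;
  return v;
}

double traverse(const IntegerVector& axis, const IntegerVector& feature,
                const NumericVector& threshold, const IntegerVector& left,
                const IntegerVector& right, const NumericVector& value,
                const double* xd, const double* xp) {
  int node = 0;
  while (axis[node] != 0) {
    double v = (axis[node] == 1) ? xd[feature[node] - 1]
                                 : xp[feature[node] - 1];
    node = (v <= threshold[node]) ? left[node] - 1 : right[node] - 1;
  }
  return value[node];
}

}  // namespace

// [[Rcpp::export]]
double cpp_node_variance(NumericMatrix M) {
  std::vector<int> rows = seq0(M.nrow());
  std::vector<int> cols = seq0(M.ncol());
  return block_sse_cols(M, rows, cols);
}

// [[Rcpp::export]]
DataFrame cpp_candidate_splits(NumericMatrix Y, NumericMatrix Xd,
                               NumericMatrix Xp, IntegerVector rows,
                               IntegerVector cols, int n_row_cand,
                               int n_col_cand, bool exhaustive, double seed) {
  std::vector<int> r(rows.begin(), rows.end());
  std::vector<int> c(cols.begin(), cols.end());
  for (int& i : r) --i;
  for (int& i : c) --i;
  Rng rng(static_cast<uint64_t>(seed));
  double sse_cols = block_sse_cols(Y, r, c);
  double sse_rows = block_sse_rows(Y, r, c);
  std::vector<Candidate> cands =
      all_candidates(Y, Xd, Xp, r, c, n_row_cand, n_col_cand, exhaustive,
                     sse_cols, sse_rows, 1, rng);
  int n = static_cast<int>(cands.size());
  IntegerVector axis(n), feat(n);
  NumericVector thr(n), score(n);
  for (int i = 0; i < n; ++i) {
    axis[i] = cands[i].axis;
    feat[i] = cands[i].feature + 1;
    thr[i] = cands[i].threshold;
    score[i] = cands[i].score;
  }
  return DataFrame::create(_["axis"] = axis, _["feature"] = feat,
                           _["threshold"] = thr, _["score"] = score);
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix Y, NumericMatrix Xd, NumericMatrix Xp,
                   int n_row_cand, int n_col_cand, int min_leaf,
                   bool exhaustive, double seed) {
  if (Y.nrow() == 0 || Y.ncol() == 0) stop("empty training matrix");
  TreeBuilder tb(Y, Xd, Xp, n_row_cand, n_col_cand, min_leaf, exhaustive,
                 static_cast<uint64_t>(seed));
  tb.build(seq0(Y.nrow()), seq0(Y.ncol()));
  return tb.as_list();
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_ensemble(List trees, NumericMatrix Xd_new,
                                   NumericMatrix Xp_new) {
  const int nd = Xd_new.nrow(), np = Xp_new.nrow();
  const int nt = trees.size();
  NumericMatrix out(nd, np);
  std::vector<double> xd(Xd_new.ncol()), xp(Xp_new.ncol());
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector axis = tr["axis"], feature = tr["feature"],
                  left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < nd; ++i) {
      for (size_t k = 0; k < xd.size(); ++k) xd[k] = Xd_new(i, k);
      for (int j = 0; j < np; ++j) {
        for (size_t k = 0; k < xp.size(); ++k) xp[k] = Xp_new(j, k);
        out(i, j) += traverse(axis, feature, threshold, left, right, value,
                              xd.data(), xp.data());
      }
    }
  }
  for (int i = 0; i < nd; ++i)
    for (int j = 0; j < np; ++j) out(i, j) /= nt;
  return out;
}
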