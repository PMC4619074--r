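// Maximal Information Coefficient (MIC), approximated by the MINE scheme:
// for each grid shape (k columns x q rows) within the budget B(n), the
// q-axis is mass-equipartitioned and the k-axis partition is optimized by
// dynamic programming over clump boundaries; the characteristic-matrix
// entry is the maximal mutual information normalized by log2(min(k, q)).
// Both axis orientations are searched so the statistic is exactly symmetric.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

// Mass-equipartition of sorted values into at most k groups; tied values are
// never split across a boundary. Returns 0-based group id per sorted position.
std::vector<int> equipartition_sorted(const std::vector<double>& vals, int k,
                                      int& ngroups) {
  const int n = static_cast<int>(vals.size());
  std::vector<int> grp(n);
  int i = 0, currRow = 0, rowsize = 0;
  double desired = static_cast<double>(n) / k;
  while (i < n) {
    int j = i;
    while (j < n && vals[j] == vals[i]) ++j;
    const int s = j - i;
    const double t1 = std::fabs(rowsize + s - desired);
    const double t2 = std::fabs(rowsize - desired);
    if (rowsize != 0 && t1 >= t2 && currRow + 1 < k) {
      ++currRow;
      rowsize = 0;
      desired = static_cast<double>(n - i) / (k - currRow);
    }
    for (int t = i; t < j; ++t) grp[t] = currRow;
    rowsize += s;
    i = j;
  }
  ngroups = currRow + 1;
  return grp;
}

// Clumps: maximal runs of a-sorted points lying in one q-row; points sharing
// an a value are atomic, and a tie group spanning several rows becomes its
// own clump. Returns clump id (0-based, nondecreasing) per a-sorted position.
std::vector<int> clump_ids(const std::vector<double>& a_sorted,
                           const std::vector<int>& row_sorted, int& nclumps) {
  const int n = static_cast<int>(a_sorted.size());
  std::vector<int> cid(n);
  int clump = -1;
  int prevRow = -2;  // sentinel: no open clump
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && a_sorted[j] == a_sorted[i]) ++j;
    bool mixed = false;
    for (int t = i + 1; t < j; ++t)
      if (row_sorted[t] != row_sorted[i]) { mixed = true; break; }
    if (mixed) {
      ++clump;
      prevRow = -2;  // force a break after a mixed tie group
    } else {
      if (row_sorted[i] != prevRow) ++clump;
      prevRow = row_sorted[i];
    }
    for (int t = i; t < j; ++t) cid[t] = clump;
    i = j;
  }
  nclumps = clump + 1;
  return cid;
}

struct AxisOrder {
  std::vector<double> a;  // values to partition, sorted ascending
  std::vector<int> row;   // q-row of each a-sorted point
};

// Best normalized MI over k = 2..maxL columns for a fixed q-row assignment.
void optimize_axis(const AxisOrder& ord, int q, int maxL, int clumpFactor,
                   double hq, double& best) {
  const int n = static_cast<int>(ord.a.size());
  int nclumps = 0;
  std::vector<int> cid = clump_ids(ord.a, ord.row, nclumps);

  // Cap the number of candidate boundaries at clumpFactor * maxL by merging
  // adjacent clumps (superclumps); merged clumps are never split later.
  const int khat = std::max(2, clumpFactor * maxL);
  if (nclumps > khat) {
    std::vector<double> asclump(cid.begin(), cid.end());
    int ng = 0;
    cid = equipartition_sorted(asclump, khat, ng);
    nclumps = ng;
  }
  if (nclumps < 2) return;

  // cumulative per-row counts after clump t (t = 0..k)
  const int k = nclumps;
  std::vector<std::vector<int> > cum(k + 1, std::vector<int>(q, 0));
  {
    int pos = 0;
    for (int t = 0; t < k; ++t) {
      cum[t + 1] = cum[t];
      while (pos < n && cid[pos] == t) {
        ++cum[t + 1][ord.row[pos]];
        ++pos;
      }
    }
  }
  std::vector<int> tot(k + 1, 0);
  for (int t = 0; t <= k; ++t)
    for (int r = 0; r < q; ++r) tot[t] += cum[t][r];

  // bin score for clumps (s, t]: sum_r m log2(m / m_tot)
  auto score = [&](int s, int t) {
    const int m_tot = tot[t] - tot[s];
    double sc = 0.0;
    for (int r = 0; r < q; ++r) {
      const int m = cum[t][r] - cum[s][r];
      if (m > 0) sc += m * std::log2(static_cast<double>(m) / m_tot);
    }
    return sc;
  };

  const int L = std::min(maxL, k);
  // F[t][l]: best sum of bin scores partitioning clumps 1..t into l bins
  std::vector<std::vector<double> > F(k + 1, std::vector<double>(L + 1, NEG_INF));
  for (int t = 1; t <= k; ++t) F[t][1] = score(0, t);
  for (int l = 2; l <= L; ++l)
    for (int t = l; t <= k; ++t)
      for (int s = l - 1; s < t; ++s) {
        if (F[s][l - 1] == NEG_INF) continue;
        const double cand = F[s][l - 1] + score(s, t);
        if (cand > F[t][l]) F[t][l] = cand;
      }

  for (int l = 2; l <= L; ++l) {
    if (F[k][l] == NEG_INF) continue;
    const double mi = hq + F[k][l] / n;  // I(P;Q) in bits
    const double val = mi / std::log2(static_cast<double>(std::min(l, q)));
    if (val > best) best = val;
  }
}

// Score one fixed q-row assignment (given in b-sorted order) by optimizing
// the a-axis partition for every column count up to B/q.
void score_row_assignment(const std::vector<double>& a,
                          const std::vector<int>& aidx,
                          const std::vector<int>& rowOf, int nrows, int B,
                          int clumpFactor, int maxAxis, double& best) {
  const int n = static_cast<int>(a.size());
  if (nrows < 2) return;
  const int maxL = std::min(B / nrows, maxAxis);
  if (maxL < 2) return;

  AxisOrder ord;
  ord.a.resize(n);
  ord.row.resize(n);
  for (int i = 0; i < n; ++i) {
    ord.a[i] = a[aidx[i]];
    ord.row[i] = rowOf[aidx[i]];
  }
  std::vector<int> rc(nrows, 0);
  for (int i = 0; i < n; ++i) ++rc[rowOf[i]];
  double hq = 0.0;
  for (int r = 0; r < nrows; ++r)
    if (rc[r] > 0) {
      const double p = static_cast<double>(rc[r]) / n;
      hq -= p * std::log2(p);
    }
  optimize_axis(ord, nrows, maxL, clumpFactor, hq, best);
}

// One orientation: partition b into q rows (q = 2..B/2) and optimize the
// a-axis. For n <= exhaustiveN every admissible b-partition is tried (the
// DP is exact given rows, so this orientation pass is exact); above that
// the b-axis is mass-equipartitioned (the scalable heuristic).
void mic_one_orientation(const std::vector<double>& a,
                         const std::vector<double>& b, int B, int clumpFactor,
                         int maxAxis, int exhaustiveN, double& best) {
  const int n = static_cast<int>(a.size());

  std::vector<int> bidx(n);
  for (int i = 0; i < n; ++i) bidx[i] = i;
  std::stable_sort(bidx.begin(), bidx.end(),
                   [&](int u, int v) { return b[u] < b[v]; });
  std::vector<double> bs(n);
  for (int i = 0; i < n; ++i) bs[i] = b[bidx[i]];

  std::vector<int> aidx(n);
  for (int i = 0; i < n; ++i) aidx[i] = i;
  std::stable_sort(aidx.begin(), aidx.end(),
                   [&](int u, int v) { return a[u] < a[v]; });

  const int qmax = std::min(B / 2, maxAxis);
  std::vector<int> rowOf(n);

  if (n <= exhaustiveN) {
    // cut positions: after sorted index g when bs[g] != bs[g+1]
    std::vector<int> gaps;
    for (int g = 0; g + 1 < n; ++g)
      if (bs[g] != bs[g + 1]) gaps.push_back(g);
    for (int q = 2; q <= qmax; ++q) {
      const int ncuts = q - 1;
      if (ncuts > static_cast<int>(gaps.size())) break;
      std::vector<int> pick(ncuts);
      for (int i = 0; i < ncuts; ++i) pick[i] = i;
      while (true) {
        std::vector<int> rowSorted(n);
        int row = 0, nextCut = 0;
        for (int i = 0; i < n; ++i) {
          rowSorted[i] = row;
          if (nextCut < ncuts && i == gaps[pick[nextCut]]) {
            ++row;
            ++nextCut;
          }
        }
        for (int i = 0; i < n; ++i) rowOf[bidx[i]] = rowSorted[i];
        score_row_assignment(a, aidx, rowOf, q, B, clumpFactor, maxAxis, best);
        // next combination of gap indices
        int pos = ncuts - 1;
        while (pos >= 0 &&
               pick[pos] == static_cast<int>(gaps.size()) - ncuts + pos)
          --pos;
        if (pos < 0) break;
        ++pick[pos];
        for (int i = pos + 1; i < ncuts; ++i) pick[i] = pick[i - 1] + 1;
      }
    }
    return;
  }

  for (int q = 2; q <= qmax; ++q) {
    int nrows = 0;
    std::vector<int> rowSorted = equipartition_sorted(bs, q, nrows);
    if (nrows < 2) continue;
    for (int i = 0; i < n; ++i) rowOf[bidx[i]] = rowSorted[i];
    score_row_assignment(a, aidx, rowOf, nrows, B, clumpFactor, maxAxis, best);
  }
}

bool is_constant(const std::vector<double>& v) {
  for (size_t i = 1; i < v.size(); ++i)
    if (v[i] != v[0]) return false;
  return true;
}

double mic_core(const std::vector<double>& x, const std::vector<double>& y,
                int B, int clumpFactor, int maxAxis, int exhaustiveN) {
  double best = 0.0;
  mic_one_orientation(x, y, B, clumpFactor, maxAxis, exhaustiveN, best);
  mic_one_orientation(y, x, B, clumpFactor, maxAxis, exhaustiveN, best);
  if (best > 1.0) best = 1.0;  // numeric guard
  if (best < 0.0) best = 0.0;
  return best;
}

int grid_budget(int n, double alpha) {
  const int b = static_cast<int>(std::floor(std::pow(static_cast<double>(n), alpha)));
  return std::max(4, b);
}

double pearson_core(const std::vector<double>& x, const std::vector<double>& y) {
  const int n = static_cast<int>(x.size());
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  double r = sxy / std::sqrt(sxx * syy);
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".mic_pair_cpp")]]
double mic_pair_cpp(NumericVector x, NumericVector y, double alpha,
                    int clumpFactor, int maxAxis, int exhaustiveN) {
  std::vector<double> xv, yv;
  const int n = x.size();
  xv.reserve(n); yv.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i]) || NumericVector::is_na(y[i])) continue;
    xv.push_back(x[i]);
    yv.push_back(y[i]);
  }
  if (xv.size() < 2) return NA_REAL;
  if (is_constant(xv) || is_constant(yv)) return NA_REAL;
  const int B = grid_budget(static_cast<int>(xv.size()), alpha);
  return mic_core(xv, yv, B, clumpFactor, maxAxis, exhaustiveN);
}

// [[Rcpp::export(name = ".pearson_pair_cpp")]]
double pearson_pair_cpp(NumericVector x, NumericVector y) {
  std::vector<double> xv, yv;
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i]) || NumericVector::is_na(y[i])) continue;
    xv.push_back(x[i]);
    yv.push_back(y[i]);
  }
  if (xv.size() < 3) return NA_REAL;
  return pearson_core(xv, yv);
}

// All unordered row pairs of a feature-by-sample matrix: pairwise-complete
// Pearson r and MIC. Rows indexed 1-based in the output.
// [[Rcpp::export(name = ".allpairs_cpp")]]
List allpairs_cpp(NumericMatrix m, double alpha, int clumpFactor, int maxAxis,
                  int minPairwiseN, int exhaustiveN) {
  const int nf = m.nrow(), ns = m.ncol();
  const R_xlen_t npair = static_cast<R_xlen_t>(nf) * (nf - 1) / 2;
  IntegerVector ia(npair), ib(npair), nused(npair);
  NumericVector rr(npair), mic(npair);
  R_xlen_t k = 0;
  std::vector<double> xv, yv;
  for (int i = 0; i < nf - 1; ++i) {
    for (int j = i + 1; j < nf; ++j) {
      xv.clear(); yv.clear();
      for (int s = 0; s < ns; ++s) {
        const double a = m(i, s), b = m(j, s);
        if (NumericVector::is_na(a) || NumericVector::is_na(b)) continue;
        xv.push_back(a);
        yv.push_back(b);
      }
      const int n = static_cast<int>(xv.size());
      ia[k] = i + 1;
      ib[k] = j + 1;
      nused[k] = n;
      const bool cx = n > 0 && is_constant(xv);
      const bool cy = n > 0 && is_constant(yv);
      rr[k] = (n >= 3 && !cx && !cy) ? pearson_core(xv, yv) : NA_REAL;
      if (n >= minPairwiseN && !cx && !cy) {
        const int B = grid_budget(n, alpha);
        mic[k] = mic_core(xv, yv, B, clumpFactor, maxAxis, exhaustiveN);
      } else {
        mic[k] = NA_REAL;
      }
      ++k;
    }
  }
  return List::create(_["i"] = ia, _["j"] = ib, _["n_used"] = nused,
                      _["pearson_r"] = rr, _["mic"] = mic);
}
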