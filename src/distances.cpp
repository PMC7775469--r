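#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Elastic distances for short, equal- or unequal-length series. All dynamic
// programs are unconstrained (no warping window); series here are at most a
// few dozen points, so full O(nm) tables are cheap.

static double ed_raw(const double* x, const double* y, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = x[i] - y[i];
    s += d * d;
  }
  return std::sqrt(s);
}

// DTW with squared local cost; the reported distance is the optimal path sum
// (no final square root).
static double dtw_raw(const double* x, int n, const double* y, int m) {
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    const double d = x[0] - y[j];
    prev[j] = d * d + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double d = x[i] - y[j];
      double best = prev[j];                       // insertion step
      if (j > 0) {
        if (cur[j - 1] < best) best = cur[j - 1];  // deletion step
        if (prev[j - 1] < best) best = prev[j - 1];// diagonal step
      }
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// complexity estimate: root of the summed squared first differences
static double complexity_raw(const double* x, int n) {
  double s = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    const double d = x[i + 1] - x[i];
    s += d * d;
  }
  return std::sqrt(s);
}

static double cid_raw(const double* x, const double* y, int n) {
  const double ce_x = complexity_raw(x, n), ce_y = complexity_raw(y, n);
  double cf;
  if (ce_x == 0.0 && ce_y == 0.0) {
    cf = 1.0;
  } else {
    const double hi = ce_x > ce_y ? ce_x : ce_y;
    double lo = ce_x > ce_y ? ce_y : ce_x;
    if (lo < 1e-9) lo = 1e-9;  // floor when exactly one complexity vanishes
    cf = hi / lo;
  }
  return ed_raw(x, y, n) * cf;
}

// derivative estimate (slope of the point and the surrounding chord);
// endpoints copy their neighbour so the length is preserved
static void deriv_raw(const double* x, int n, double* d) {
  for (int i = 1; i + 1 < n; ++i) {
    d[i] = ((x[i] - x[i - 1]) + (x[i + 1] - x[i - 1]) / 2.0) / 2.0;
  }
  d[0] = d[1];
  d[n - 1] = d[n - 2];
}

// split/merge cost: c if the inserted/removed value lies between its two
// neighbours, else c plus the distance to the nearer neighbour
static double msm_edit_cost(double u, double v, double w, double c) {
  if ((v <= u && u <= w) || (v >= u && u >= w)) return c;
  const double a = std::fabs(u - v), b = std::fabs(u - w);
  return c + (a < b ? a : b);
}

static double msm_raw(const double* x, int n, const double* y, int m,
                      double c) {
  std::vector<double> prev(m), cur(m);
  prev[0] = std::fabs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) {
    prev[j] = prev[j - 1] + msm_edit_cost(y[j], x[0], y[j - 1], c);
  }
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + msm_edit_cost(x[i], x[i - 1], y[0], c);
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1] + std::fabs(x[i] - y[j]);
      const double up = prev[j] + msm_edit_cost(x[i], x[i - 1], y[j], c);
      const double left = cur[j - 1] + msm_edit_cost(y[j], x[i], y[j - 1], c);
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export]]
double ed_cpp(NumericVector x, NumericVector y) {
  return ed_raw(x.begin(), y.begin(), x.size());
}

// [[Rcpp::export]]
double dtw_cpp(NumericVector x, NumericVector y) {
  return dtw_raw(x.begin(), x.size(), y.begin(), y.size());
}

// [[Rcpp::export]]
double cid_cpp(NumericVector x, NumericVector y) {
  return cid_raw(x.begin(), y.begin(), x.size());
}

// [[Rcpp::export]]
double msm_cpp(NumericVector x, NumericVector y, double c) {
  return msm_raw(x.begin(), x.size(), y.begin(), y.size(), c);
}

// [[Rcpp::export]]
NumericVector deriv_cpp(NumericVector x) {
  const int n = x.size();
  NumericVector d(n);
  deriv_raw(x.begin(), n, d.begin());
  return d;
}

// Pairwise distance matrix between the rows of A and the rows of B.
// method: 1 = ED, 2 = DTW, 3 = DDTW, 4 = CID, 5 = MSM.
// [[Rcpp::export]]
NumericMatrix pairwise_cpp(NumericMatrix A, NumericMatrix B, int method,
                           double msm_cost) {
  const int na = A.nrow(), nb = B.nrow(), L = A.ncol();
  NumericMatrix out(na, nb);
  std::vector<double> ar(L), br(L);
  // For DDTW, differentiate every row once up front.
  std::vector<std::vector<double> > Ad, Bd;
  if (method == 3) {
    Ad.assign(na, std::vector<double>(L));
    Bd.assign(nb, std::vector<double>(L));
    std::vector<double> row(L);
    for (int i = 0; i < na; ++i) {
      for (int k = 0; k < L; ++k) row[k] = A(i, k);
      deriv_raw(row.data(), L, Ad[i].data());
    }
    for (int j = 0; j < nb; ++j) {
      for (int k = 0; k < L; ++k) row[k] = B(j, k);
      deriv_raw(row.data(), L, Bd[j].data());
    }
  }
  for (int i = 0; i < na; ++i) {
    for (int k = 0; k < L; ++k) ar[k] = A(i, k);
    for (int j = 0; j < nb; ++j) {
      for (int k = 0; k < L; ++k) br[k] = B(j, k);
      double d;
      switch (method) {
        case 1: d = ed_raw(ar.data(), br.data(), L); break;
        case 2: d = dtw_raw(ar.data(), L, br.data(), L); break;
        case 3: d = dtw_raw(Ad[i].data(), L, Bd[j].data(), L); break;
        case 4: d = cid_raw(ar.data(), br.data(), L); break;
        case 5: d = msm_raw(ar.data(), L, br.data(), L, msm_cost); break;
        default: stop("unknown distance method code");
      }
      out(i, j) = d;
    }
  }
  return out;
}
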