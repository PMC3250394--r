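// Pinball-loss (quantile regression) solver for the two-parameter model
// y ~ a + b x, plus the paired-bootstrap driver used by fit_profile().
//
// Strategy: an optimal solution of the convex pinball problem is attained at
// a line interpolating two data points. For small n we enumerate all pairs
// (exact). For large n we run iteratively reweighted least squares on a
// smoothed |.| with a shrinking floor, then "polish" by refitting through
// every pair among the lowest-|residual| points and keeping the best loss.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline double pinball_loss(const double *y, const double *x, int n,
                                  double tau, double a, double b) {
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    double u = y[i] - a - b * x[i];
    loss += (u >= 0.0) ? tau * u : (tau - 1.0) * u;
  }
  return loss;
}

// exact minimizer over all lines through pairs of data points
static void fit_enumerate(const double *y, const double *x, int n, double tau,
                          double &a_out, double &b_out, double &loss_out) {
  double best = R_PosInf, best_a = 0.0, best_b = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j];
      if (std::fabs(dx) < 1e-12) continue;
      double b = (y[i] - y[j]) / dx;
      double a = y[i] - b * x[i];
      double l = pinball_loss(y, x, n, tau, a, b);
      if (l < best) { best = l; best_a = a; best_b = b; }
    }
  }
  a_out = best_a; b_out = best_b; loss_out = best;
}

// one weighted least-squares step; returns false on singular system
static bool wls_step(const double *y, const double *x, int n, double tau,
                     double eps, double &a, double &b) {
  double sw = 0, swx = 0, swxx = 0, swy = 0, swxy = 0;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - a - b * x[i];
    double w = ((r > 0.0) ? tau : (1.0 - tau)) / std::max(std::fabs(r), eps);
    sw += w; swx += w * x[i]; swxx += w * x[i] * x[i];
    swy += w * y[i]; swxy += w * x[i] * y[i];
  }
  double det = sw * swxx - swx * swx;
  if (std::fabs(det) < 1e-300 || !R_FINITE(det)) return false;
  a = (swxx * swy - swx * swxy) / det;
  b = (sw * swxy - swx * swy) / det;
  return true;
}

// IRLS with shrinking smoothing floor, then pair polish among the m
// lowest-|residual| points. a/b carry the warm start on entry; warm starts
// (adjacent grid quantiles) begin with a smaller floor so few iterations
// are needed.
static void fit_irls_polish(const double *y, const double *x, int n,
                            double tau, double &a, double &b,
                            double &loss_out, bool warm, int m_polish,
                            int max_iter = 40) {
  // scale for the smoothing floor
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::fabs(y[i] - a - b * x[i]);
  s = std::max(s / n, 1e-12);
  double eps = warm ? s * 1e-2 : s;
  const double eps_min = s * 1e-11 + 1e-300;
  double prev_a = a, prev_b = b;
  for (int it = 0; it < max_iter; ++it) {
    if (!wls_step(y, x, n, tau, eps, a, b)) break;
    bool settled = std::fabs(a - prev_a) <= 1e-11 * (1.0 + std::fabs(a)) &&
                   std::fabs(b - prev_b) <= 1e-11 * (1.0 + std::fabs(b));
    if (settled && eps <= eps_min * 1.01) break;
    prev_a = a; prev_b = b;
    eps = std::max(eps * 0.25, eps_min);
  }
  double best = pinball_loss(y, x, n, tau, a, b);
  double best_a = a, best_b = b;

  // Iterated pair polish: refit through every pair among the m smallest
  // |residual| points of the current best line; repeat while it improves
  // (a descent over interpolating vertices of the convex objective).
  int m = std::min(m_polish, n);
  std::vector<double> ar(n);
  std::vector<int> idx(n);
  for (int pass = 0; pass < 10; ++pass) {
    for (int i = 0; i < n; ++i) ar[i] = std::fabs(y[i] - best_a - best_b * x[i]);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::partial_sort(idx.begin(), idx.begin() + m, idx.end(),
                      [&ar](int u, int v) { return ar[u] < ar[v]; });
    bool improved = false;
    for (int ii = 0; ii < m - 1; ++ii) {
      for (int jj = ii + 1; jj < m; ++jj) {
        int i = idx[ii], j = idx[jj];
        double dx = x[i] - x[j];
        if (std::fabs(dx) < 1e-12) continue;
        double bb = (y[i] - y[j]) / dx;
        double aa = y[i] - bb * x[i];
        double l = pinball_loss(y, x, n, tau, aa, bb);
        if (l < best * (1.0 - 1e-15) - 1e-300) {
          best = l; best_a = aa; best_b = bb; improved = true;
        }
      }
    }
    if (!improved) break;
  }
  a = best_a; b = best_b; loss_out = best;
}

static void fit_one(const double *y, const double *x, int n, double tau,
                    double &a, double &b, double &loss, bool warm,
                    int m_polish = 10) {
  if (n <= 60) {
    fit_enumerate(y, x, n, tau, a, b, loss);
    return;
  }
  if (!warm) {
    // OLS start
    double sx = 0, sy = 0, sxx = 0, sxy = 0;
    for (int i = 0; i < n; ++i) {
      sx += x[i]; sy += y[i]; sxx += x[i] * x[i]; sxy += x[i] * y[i];
    }
    double det = n * sxx - sx * sx;
    if (std::fabs(det) > 1e-300) {
      b = (n * sxy - sx * sy) / det;
      a = (sy - b * sx) / n;
    } else { a = 0.0; b = 0.0; }
  }
  fit_irls_polish(y, x, n, tau, a, b, loss, warm, m_polish);
}

// [[Rcpp::export]]
NumericVector rq_fit_cpp(NumericVector y, NumericVector x, double tau) {
  int n = y.size();
  double a = 0.0, b = 0.0, loss = 0.0;
  fit_one(REAL(y), REAL(x), n, tau, a, b, loss, false);
  return NumericVector::create(_["intercept"] = a, _["slope"] = b,
                               _["loss"] = loss);
}

// point fits over a tau grid (warm-started along the grid)
// [[Rcpp::export]]
NumericMatrix rq_grid_cpp(NumericVector y, NumericVector x,
                          NumericVector taus) {
  int n = y.size(), K = taus.size();
  NumericMatrix out(K, 3);
  double a = 0.0, b = 0.0, loss = 0.0;
  for (int k = 0; k < K; ++k) {
    fit_one(REAL(y), REAL(x), n, taus[k], a, b, loss, k > 0);
    out(k, 0) = a; out(k, 1) = b; out(k, 2) = loss;
  }
  colnames(out) = CharacterVector::create("intercept", "slope", "loss");
  return out;
}

// Paired bootstrap: resample subjects with replacement (R's RNG), refit all
// taus on the same replicate (shared indices, as a cross-quantile covariance
// requires). Replicates with constant x are redrawn and counted.
// [[Rcpp::export]]
List rq_boot_cpp(NumericVector y, NumericVector x, NumericVector taus,
                 int B, int max_redraw) {
  int n = y.size(), K = taus.size();
  NumericMatrix slopes(B, K);
  std::vector<double> yb(n), xb(n);
  int redraws = 0;
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    bool ok = false;
    while (!ok) {
      double xmin = R_PosInf, xmax = R_NegInf;
      for (int i = 0; i < n; ++i) {
        int j = (int)(n * unif_rand());
        if (j == n) j = n - 1;
        yb[i] = y[j]; xb[i] = x[j];
        if (xb[i] < xmin) xmin = xb[i];
        if (xb[i] > xmax) xmax = xb[i];
      }
      ok = (xmax - xmin) > 1e-12;
      if (!ok && ++redraws > max_redraw)
        stop("too many bootstrap replicates with constant score");
    }
    double a = 0.0, bb = 0.0, loss = 0.0;
    // lighter polish inside the bootstrap: the solver is already within
    // O(1e-10) of the optimum and only the resampling noise matters
    for (int k = 0; k < K; ++k) {
      fit_one(yb.data(), xb.data(), n, taus[k], a, bb, loss, k > 0, 4);
      slopes(b, k) = bb;
    }
  }
  return List::create(_["slopes"] = slopes, _["redraws"] = redraws);
}
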