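// Gradient-boosted regression stumps used for sparse covariate selection.
//
// Squared-error loss, depth-1 trees, shrinkage, and per-iteration row
// subsampling without replacement driven by a private mt19937 stream so a
// fit is a pure function of (X, y, hyperparameters, seed).  The quantity of
// interest downstream is not the prediction but which column each tree
// split on: split counts feed the "selected in at least 1% of iterations"
// rule.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(rng = false)]]
List boost_stumps_cpp(NumericMatrix X, NumericVector y, int nrounds,
                      double learning_rate, double subsample, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (n < 2 || p < 1) stop("need at least 2 rows and 1 column");

  // Pre-sort each column once; keep sorted values contiguous so the
  // per-round scans are sequential in memory.
  std::vector<std::vector<int>> order(p, std::vector<int>(n));
  std::vector<std::vector<double>> xs(p, std::vector<double>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& o = order[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
    for (int k = 0; k < n; ++k) xs[j][k] = col[o[k]];
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  int m = static_cast<int>(subsample * n + 0.5);
  if (m < 2) m = 2;
  if (m > n) m = n;

  std::vector<double> resid(n);
  double init = 0.0;
  for (int i = 0; i < n; ++i) init += y[i];
  init /= n;
  for (int i = 0; i < n; ++i) resid[i] = y[i] - init;

  std::vector<int> pool(n);
  std::vector<char> in_bag(n);
  IntegerVector split_count(p);
  int fitted = 0;

  for (int t = 0; t < nrounds; ++t) {
    // partial Fisher-Yates draw of m distinct rows
    for (int i = 0; i < n; ++i) pool[i] = i;
    std::fill(in_bag.begin(), in_bag.end(), 0);
    for (int i = 0; i < m; ++i) {
      int j = i + static_cast<int>(rng() % static_cast<unsigned int>(n - i));
      std::swap(pool[i], pool[j]);
      in_bag[pool[i]] = 1;
    }

    double tot_sum = 0.0;
    for (int i = 0; i < n; ++i)
      if (in_bag[i]) tot_sum += resid[i];

    int best_j = -1;
    double best_gain = 0.0, best_thr = 0.0, best_lmean = 0.0, best_rmean = 0.0;
    const double base = tot_sum * tot_sum / m;

    for (int j = 0; j < p; ++j) {
      const int* o = order[j].data();
      const double* xv = xs[j].data();
      double lsum = 0.0;
      int lcnt = 0;
      double prev_x = 0.0;
      bool have_prev = false;
      for (int k = 0; k < n; ++k) {
        const int i = o[k];
        if (!in_bag[i]) continue;
        const double x = xv[k];
        if (have_prev && x > prev_x && lcnt < m) {
          const double rsum = tot_sum - lsum;
          const int rcnt = m - lcnt;
          const double gain = lsum * lsum / lcnt + rsum * rsum / rcnt - base;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_j = j;
            best_thr = 0.5 * (prev_x + x);
            best_lmean = lsum / lcnt;
            best_rmean = rsum / rcnt;
          }
        }
        lsum += resid[i];
        ++lcnt;
        prev_x = x;
        have_prev = true;
      }
    }

    if (best_j < 0) continue;  // every column constant in the bag
    ++split_count[best_j];
    ++fitted;
    const double* col = &X(0, best_j);
    for (int i = 0; i < n; ++i) {
      double step = learning_rate * (col[i] <= best_thr ? best_lmean : best_rmean);
      resid[i] -= step;
    }
  }

  return List::create(_["split_count"] = split_count,
                      _["n_fitted"] = fitted,
                      _["nrounds"] = nrounds);
}
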