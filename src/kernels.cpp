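// Inner loops for KDE bandwidth selection / rate evaluation, regularized-LDA
// leave-one-out decoding (single bins, curves, shuffle nulls, train/test and
// cross-temporal variants), and spike-pair correlograms. All randomness stays
// on the R side: permutations and resample draws are passed in as index
// matrices so results are governed by R's RNG alone.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SQRT_PI = 1.7724538509055160273;
static const double SQRT_2PI = 2.5066282746310005024;

// Closed-form least-squares cross-validation error for a Gaussian-kernel
// density estimate, evaluated on a grid of bandwidths. spikes must be sorted.
// CVE(h) = (1/n^2) sum_ij phi_{sqrt2 h}(dij) - 2/(n(n-1)) sum_{i!=j} phi_h(dij)
// [[Rcpp::export]]
arma::vec kde_cve_grid_cpp(const arma::vec& spikes, const arma::vec& bandwidths) {
  const int n = spikes.n_elem;
  arma::vec out(bandwidths.n_elem);
  for (arma::uword b = 0; b < bandwidths.n_elem; ++b) {
    const double h = bandwidths[b];
    // the sqrt(2)h kernel decays slowest: 12h = 8.5 of its SDs (exp(-36))
    const double cutoff = 12.0 * h;
    double s1 = 0.0, s2 = 0.0;      // off-diagonal sums (each unordered pair once)
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double d = spikes[j] - spikes[i];
        if (d > cutoff) break;
        const double q = d * d / (h * h);
        s1 += std::exp(-0.25 * q);
        s2 += std::exp(-0.5 * q);
      }
    }
    const double int_f2 = (n + 2.0 * s1) / (2.0 * h * SQRT_PI * (double)n * n);
    const double loo = (4.0 * s2) / ((double)n * (n - 1.0) * h * SQRT_2PI);
    out[b] = int_f2 - loo;
  }
  return out;
}

// Gaussian-kernel rate estimate (Hz) at arbitrary times; spikes sorted.
// [[Rcpp::export]]
arma::vec kde_eval_cpp(const arma::vec& spikes, const arma::vec& times, double h) {
  const int n = spikes.n_elem, m = times.n_elem;
  arma::vec out(m, arma::fill::zeros);
  if (n == 0) return out;
  const double cutoff = 8.0 * h;
  const double norm = 1.0 / (h * SQRT_2PI);
  for (int t = 0; t < m; ++t) {
    const double* lo = std::lower_bound(spikes.memptr(), spikes.memptr() + n,
                                        times[t] - cutoff);
    double acc = 0.0;
    for (const double* p = lo; p < spikes.memptr() + n && *p <= times[t] + cutoff; ++p) {
      const double d = (times[t] - *p) / h;
      acc += std::exp(-0.5 * d * d);
    }
    out[t] = acc * norm;
  }
  return out;
}

// ---- regularized LDA ----------------------------------------------------

// Fit on rows of X with labels y in {0,1}; returns weights, midpoint bias.
static void lda_fit(const arma::mat& X, const arma::ivec& y, double lambda,
                    arma::vec& w, double& b) {
  arma::uvec i0 = arma::find(y == 0), i1 = arma::find(y == 1);
  arma::rowvec m0 = arma::mean(X.rows(i0), 0), m1 = arma::mean(X.rows(i1), 0);
  arma::mat C0 = X.rows(i0); C0.each_row() -= m0;
  arma::mat C1 = X.rows(i1); C1.each_row() -= m1;
  const double df = (double)X.n_rows - 2.0;
  arma::mat S = (C0.t() * C0 + C1.t() * C1) / std::max(df, 1.0);
  S.diag() += lambda;
  w = arma::solve(S, (m1 - m0).t(), arma::solve_opts::likely_sympd);
  b = arma::dot(w, 0.5 * (m0 + m1).t());
}

// [[Rcpp::export]]
List lda_fit_cpp(const arma::mat& X, const arma::ivec& y, double lambda) {
  arma::vec w; double b;
  lda_fit(X, y, lambda, w, b);
  return List::create(_["w"] = w, _["b"] = b);
}

// Leave-one-out CP for one bin.
static double loocv_cp_one(const arma::mat& X, const arma::ivec& y, double lambda) {
  const int n = X.n_rows;
  int correct = 0, used = 0;
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = 0; i < n; ++i) {
    arma::uvec keep = arma::find(all != (arma::uword)i);
    arma::ivec ytr = y(keep);
    if (arma::all(ytr == 0) || arma::all(ytr == 1)) continue;  // class lost
    arma::vec w; double b;
    lda_fit(X.rows(keep), ytr, lambda, w, b);
    const int pred = (arma::dot(w, X.row(i).t()) > b) ? 1 : 0;
    correct += (pred == y[i]);
    ++used;
  }
  return used > 0 ? (double)correct / used : NA_REAL;
}

// [[Rcpp::export]]
double lda_loocv_cp_cpp(const arma::mat& X, const arma::ivec& y, double lambda) {
  return loocv_cp_one(X, y, lambda);
}

// LOOCV CP per time bin of a trials x units x bins cube.
// [[Rcpp::export]]
arma::vec lda_loocv_curve_cpp(const arma::cube& R, const arma::ivec& y, double lambda) {
  arma::vec cp(R.n_slices);
  for (arma::uword t = 0; t < R.n_slices; ++t)
    cp[t] = loocv_cp_one(R.slice(t), y, lambda);
  return cp;
}

// Shuffle null: columns of perms are 0-based permutations applied to y.
// [[Rcpp::export]]
arma::mat lda_loocv_null_cpp(const arma::cube& R, const arma::ivec& y,
                             const arma::umat& perms, double lambda) {
  arma::mat out(R.n_slices, perms.n_cols);
  for (arma::uword k = 0; k < perms.n_cols; ++k) {
    arma::ivec yp = y(perms.col(k));
    for (arma::uword t = 0; t < R.n_slices; ++t)
      out(t, k) = loocv_cp_one(R.slice(t), yp, lambda);
  }
  return out;
}

// Train on train_idx, test on test_idx (0-based), per bin.
// [[Rcpp::export]]
arma::vec lda_train_test_curve_cpp(const arma::cube& R, const arma::ivec& y,
                                   const arma::uvec& train_idx,
                                   const arma::uvec& test_idx, double lambda) {
  arma::vec cp(R.n_slices);
  arma::ivec ytr = y(train_idx), yte = y(test_idx);
  for (arma::uword t = 0; t < R.n_slices; ++t) {
    arma::mat Xtr = R.slice(t).rows(train_idx);
    arma::mat Xte = R.slice(t).rows(test_idx);
    arma::vec w; double b;
    lda_fit(Xtr, ytr, lambda, w, b);
    arma::vec sc = Xte * w;
    int correct = 0;
    for (arma::uword i = 0; i < sc.n_elem; ++i)
      correct += ((sc[i] > b ? 1 : 0) == yte[i]);
    cp[t] = (double)correct / sc.n_elem;
  }
  return cp;
}

// Cross-temporal decoding. draws: (2*k) x n_resamples matrix of 0-based trial
// indices, first k rows class 0, next k rows class 1. Within each resample,
// leave-one-pair-out: fold j holds out the j-th trial of each class, trains on
// the remaining 2(k-1) at t_train, tests the pair at every t_test.
// [[Rcpp::export]]
arma::mat cross_temporal_cpp(const arma::cube& R, const arma::ivec& y,
                             const arma::umat& draws, double lambda) {
  const arma::uword T = R.n_slices, p = R.n_cols;
  const arma::uword k = draws.n_rows / 2, nres = draws.n_cols;
  arma::mat acc(T, T, arma::fill::zeros);
  arma::mat cnt(T, T, arma::fill::zeros);
  for (arma::uword r = 0; r < nres; ++r) {
    arma::uvec idx = draws.col(r);
    // flatten the drawn sub-cube once: rows = 2k trials
    arma::cube sub(2 * k, p, T);
    for (arma::uword t = 0; t < T; ++t) sub.slice(t) = R.slice(t).rows(idx);
    arma::ivec ysub = y(idx);
    for (arma::uword j = 0; j < k; ++j) {
      arma::uvec hold = {j, k + j};
      arma::uvec keep(2 * k - 2);
      arma::uword c = 0;
      for (arma::uword i = 0; i < 2 * k; ++i)
        if (i != j && i != k + j) keep[c++] = i;
      arma::ivec ytr = ysub(keep), yte = ysub(hold);
      for (arma::uword t1 = 0; t1 < T; ++t1) {
        arma::vec w; double b;
        lda_fit(sub.slice(t1).rows(keep), ytr, lambda, w, b);
        for (arma::uword t2 = 0; t2 < T; ++t2) {
          arma::vec sc = sub.slice(t2).rows(hold) * w;
          double corr = ((sc[0] > b ? 1 : 0) == yte[0]) +
                        ((sc[1] > b ? 1 : 0) == yte[1]);
          acc(t1, t2) += corr;
          cnt(t1, t2) += 2.0;
        }
      }
    }
  }
  return acc / cnt;
}

// Spike-pair correlogram: counts of (b - a) lags in centered bins spanning
// [-max_lag, max_lag]. Self-pairs (same index) excluded when same_train.
// [[Rcpp::export]]
arma::vec correlogram_cpp(const arma::vec& a, const arma::vec& b,
                          double bin, double max_lag, bool same_train) {
  const int nb = 2 * (int)std::round(max_lag / bin) + 1;
  const int half = nb / 2;
  arma::vec counts(nb, arma::fill::zeros);
  const double lo = -max_lag - bin / 2.0, hi = max_lag + bin / 2.0;
  for (arma::uword i = 0; i < a.n_elem; ++i) {
    const double* start = std::lower_bound(b.memptr(), b.memptr() + b.n_elem,
                                           a[i] + lo);
    for (const double* p = start; p < b.memptr() + b.n_elem && *p < a[i] + hi; ++p) {
      if (same_train && *p == a[i]) continue;
      const double lag = *p - a[i];
      int idx = half + (int)std::lround(lag / bin);
      if (idx >= 0 && idx < nb) counts[idx] += 1.0;
    }
  }
  return counts;
}
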