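#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pair counts for sample entropy (Richman-Moorman convention): templates of
// length m start at i = 0..n-m-1, so every counted m-template has an (m+1)th
// point. B = matched m-template pairs (i < j, Chebyshev distance <= r,
// self-matches excluded), A = pairs additionally matching at the next point.
static void sampen_pair_counts(const double* x, int n, int m, double r,
                               double& A, double& B) {
  A = 0.0;
  B = 0.0;
  const int nt = n - m; // number of extensible m-templates
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for pattern length m");
  for (int i = 0; i < n; ++i)
    if (!R_finite(x[i])) stop("non-finite value in input series");
  double A, B;
  sampen_pair_counts(REAL(x), n, m, r, A, B);
  return NumericVector::create(A, B);
}

// Coarse-grain into non-overlapping window means, then count pairs at each
// scale with a single fixed tolerance r. Returns entropies (NA when A or B
// is zero). `out` must have length n_scales.
static void mse_series(const double* x, int n, int m, double r, int n_scales,
                       double* out, std::vector<double>& buf) {
  for (int tau = 1; tau <= n_scales; ++tau) {
    int nc = n / tau;
    if (nc <= m + 1) { out[tau - 1] = NA_REAL; continue; }
    if (tau == 1) {
      double A, B;
      sampen_pair_counts(x, n, m, r, A, B);
      out[0] = (A > 0.0 && B > 0.0) ? -std::log(A / B) : NA_REAL;
      continue;
    }
    buf.resize(nc);
    for (int j = 0; j < nc; ++j) {
      double s = 0.0;
      for (int k = 0; k < tau; ++k) s += x[j * tau + k];
      buf[j] = s / tau;
    }
    double A, B;
    sampen_pair_counts(buf.data(), nc, m, r, A, B);
    out[tau - 1] = (A > 0.0 && B > 0.0) ? -std::log(A / B) : NA_REAL;
  }
}

// [[Rcpp::export]]
NumericVector mse_trial_cpp(NumericVector x, int m, double r_abs, int n_scales) {
  int n = x.size();
  NumericVector out(n_scales);
  std::vector<double> buf;
  mse_series(REAL(x), n, m, r_abs, n_scales, REAL(out), buf);
  return out;
}

// Whole epoch-set MSE: arr is trials x channels x samples (column-major,
// trial index fastest). r is set per trial-channel series as
// r_fraction * SD(original series); zero-SD series yield all-NA rows.
// [[Rcpp::export]]
NumericVector mse_epochs_cpp(NumericVector arr, IntegerVector dims, int m,
                             double r_fraction, int n_scales) {
  int n_tr = dims[0], n_ch = dims[1], n_sm = dims[2];
  NumericVector out(static_cast<R_xlen_t>(n_tr) * n_ch * n_scales);
  out.attr("dim") = IntegerVector::create(n_tr, n_ch, n_scales);
  std::vector<double> series(n_sm), buf, ent(n_scales);
  const double* a = REAL(arr);
  for (int c = 0; c < n_ch; ++c) {
    for (int t = 0; t < n_tr; ++t) {
      double s1 = 0.0, s2 = 0.0;
      for (int k = 0; k < n_sm; ++k) {
        double v = a[t + static_cast<R_xlen_t>(n_tr) * (c + static_cast<R_xlen_t>(n_ch) * k)];
        if (!R_finite(v)) stop("non-finite value in epoch data");
        series[k] = v;
        s1 += v;
        s2 += v * v;
      }
      double var = (s2 - s1 * s1 / n_sm) / (n_sm - 1);
      double sd = var > 0.0 ? std::sqrt(var) : 0.0;
      if (sd <= 0.0) {
        for (int sc = 0; sc < n_scales; ++sc)
          out[t + static_cast<R_xlen_t>(n_tr) * (c + static_cast<R_xlen_t>(n_ch) * sc)] = NA_REAL;
        continue;
      }
      mse_series(series.data(), n_sm, m, r_fraction * sd, n_scales,
                 ent.data(), buf);
      for (int sc = 0; sc < n_scales; ++sc)
        out[t + static_cast<R_xlen_t>(n_tr) * (c + static_cast<R_xlen_t>(n_ch) * sc)] = ent[sc];
    }
  }
  return out;
}
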