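#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// EM iterations for the two-group mixture with a discrete non-null prior.
//
// Inputs are per-SNP component densities already shifted in log space:
// S0[j]     = exp(log f0(y_j) - M[j])          (null component)
// S1t(k, j) = exp(log N(y_j; b_k, v_j) - M[j]) (grid components, B x m,
//             transposed so one SNP's densities are contiguous)
// M[j]      = per-SNP max log density, so log f_j = M[j] + log of the
//             shifted mixture; the shift cancels in all responsibilities.
//
// Each iteration makes a single pass over S1t (the matrix is far larger
// than cache, so memory traffic dominates): for SNP j it computes the
// mixture density, accumulates the log-likelihood, and accumulates the
// unnormalized mass-point responsibilities.  Stopping rule: relative
// log-likelihood change below tol, checked before the parameter update so
// the returned (pi, p) are the ones that produced the last trace entry.
// [[Rcpp::export(name = ".em_run_cpp")]]
List em_run_cpp(NumericVector S0, NumericMatrix S1t, NumericVector M,
                double pi0, NumericVector p0, double tol, int max_iter) {
  const int m = S0.size();
  const int B = S1t.nrow();
  if (S1t.ncol() != m || M.size() != m || p0.size() != B)
    stop("inconsistent dimensions in EM kernel inputs");

  std::vector<double> p(p0.begin(), p0.end()), pacc(B);
  double pi = pi0;
  double ll_old = R_NegInf;
  std::vector<double> trace;
  trace.reserve(512);
  bool converged = false;
  int it = 0;

  while (it < max_iter) {
    ++it;
    double ll = 0.0, wsum = 0.0;
    std::fill(pacc.begin(), pacc.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      const double* col = &S1t(0, j);
      double f1 = 0.0;
      for (int k = 0; k < B; ++k) f1 += col[k] * p[k];
      const double ff = (1.0 - pi) * S0[j] + pi * f1;
      ll += M[j] + std::log(ff);
      const double r = pi / ff;  // responsibility scale for grid components
      wsum += r * f1;            // total non-null responsibility of SNP j
      for (int k = 0; k < B; ++k) pacc[k] += col[k] * r;
    }
    if (!std::isfinite(ll)) {  // cold path: locate the offending SNP
      for (int j = 0; j < m; ++j) {
        const double* col = &S1t(0, j);
        double f1 = 0.0;
        for (int k = 0; k < B; ++k) f1 += col[k] * p[k];
        const double ff = (1.0 - pi) * S0[j] + pi * f1;
        if (!(ff > 0.0) || !std::isfinite(ff))
          stop("non-finite mixture density at SNP index %d", j + 1);
      }
      stop("non-finite log-likelihood in EM iteration %d", it);
    }
    trace.push_back(ll);
    if (it > 1 && (ll - ll_old) < tol * std::fabs(ll_old)) {
      converged = true;
      break;
    }
    ll_old = ll;
    const double pin = wsum / m;  // M-step: mean non-null responsibility
    if (pin > 0.0) {
      double s = 0.0;
      for (int k = 0; k < B; ++k) {
        p[k] = p[k] * pacc[k] / (m * pin);
        s += p[k];
      }
      for (int k = 0; k < B; ++k) p[k] /= s;  // guard against drift
    }
    pi = pin;
  }

  return List::create(
      _["pi"] = pi,
      _["masses"] = NumericVector(p.begin(), p.end()),
      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
      _["n_iter"] = it,
      _["converged"] = converged);
}

// Column-wise max of a B x m matrix against a floor vector; used to build
// the per-SNP log-density shift without materializing intermediates in R.
// [[Rcpp::export(name = ".colmax_floor_cpp")]]
NumericVector colmax_floor_cpp(NumericMatrix S1t, NumericVector floor_vec) {
  const int m = S1t.ncol(), B = S1t.nrow();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double* col = &S1t(0, j);
    double mx = floor_vec[j];
    for (int k = 0; k < B; ++k)
      if (col[k] > mx) mx = col[k];
    out[j] = mx;
  }
  return out;
}
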