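// Panel mixed logit simulated log-likelihood and analytic gradient.
//
// Data layout contract (enforced on the R side):
//  - Xt is the transposed model matrix (K x n_rows), 3 consecutive rows
//    (columns of Xt) per respondent-task in order A, B, opt-out;
//  - tasks are grouped by respondent;
//  - theta = [means over the K model columns, sds over the rand_cols].
// Individual coefficients for draw r of respondent i are
//   beta = means; beta[rand_cols] += sds * Z(r, ., i)
// The per-respondent likelihood is the draw average of the product over the
// respondent's tasks of the chosen alternative's logit probability; products
// are accumulated in log space and averaged by log-sum-exp.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List msl_loglik_cpp(const arma::vec& theta,
                          const arma::mat& Xt,               // K x n_rows
                          const arma::ivec& chosen,          // length n_tasks, 0..2
                          const arma::ivec& resp_task_start, // length N+1, 0-based
                          const arma::cube& Z,               // R x Kr x N
                          const arma::uvec& rand_cols,       // 0-based
                          const bool want_grad) {
  const uword K = Xt.n_rows;
  const uword Kr = rand_cols.n_elem;
  const uword R = Z.n_rows;
  const uword N = resp_task_start.n_elem - 1;
  if (theta.n_elem != K + Kr) Rcpp::stop("theta has wrong length");
  if (Z.n_cols != Kr) Rcpp::stop("draw cube has wrong width");
  if (Z.n_slices != N) Rcpp::stop("draw cube has wrong depth");

  const vec b = theta.subvec(0, K - 1);
  const vec w = (Kr > 0) ? theta.subvec(K, K + Kr - 1) : vec();

  double ll = 0.0;
  vec grad(K + Kr, fill::zeros);

  vec beta(K), logP(R), gmean(K);
  mat Gb;                      // K x R, d logP_ir / d beta
  if (want_grad) Gb.set_size(K, R);

  for (uword i = 0; i < N; ++i) {
    const uword t0 = (uword)resp_task_start[i];
    const uword t1 = (uword)resp_task_start[i + 1];
    const double* zi = Z.slice_memptr(i);   // R x Kr, column-major
    for (uword r = 0; r < R; ++r) {
      beta = b;
      for (uword k = 0; k < Kr; ++k)
        beta[rand_cols[k]] += w[k] * zi[r + R * k];
      const double* bp = beta.memptr();
      double lp = 0.0;
      double* gp = nullptr;
      if (want_grad) { Gb.col(r).zeros(); gp = Gb.colptr(r); }
      for (uword t = t0; t < t1; ++t) {
        const uword row0 = 3 * t;
        double V[3];
        for (uword j = 0; j < 3; ++j) {
          const double* x = Xt.colptr(row0 + j);
          double v = 0.0;
          for (uword k = 0; k < K; ++k) v += x[k] * bp[k];
          V[j] = v;
        }
        const double vmax = std::max(V[0], std::max(V[1], V[2]));
        double e[3];
        double denom = 0.0;
        for (uword j = 0; j < 3; ++j) { e[j] = std::exp(V[j] - vmax); denom += e[j]; }
        const uword c = (uword)chosen[t];
        lp += V[c] - vmax - std::log(denom);
        if (want_grad) {
          for (uword j = 0; j < 3; ++j) {
            const double wgt = (j == c ? 1.0 : 0.0) - e[j] / denom;
            const double* x = Xt.colptr(row0 + j);
            for (uword k = 0; k < K; ++k) gp[k] += wgt * x[k];
          }
        }
      }
      logP[r] = lp;
    }
    const double m = logP.max();
    const double lse = m + std::log(accu(exp(logP - m)));
    ll += lse - std::log((double)R);
    if (want_grad) {
      const vec s = exp(logP - lse);   // weights, sum to 1
      grad.subvec(0, K - 1) += Gb * s;
      for (uword k = 0; k < Kr; ++k) {
        double gw = 0.0;
        const uword col = rand_cols[k];
        for (uword r = 0; r < R; ++r)
          gw += s[r] * Gb(col, r) * zi[r + R * k];
        grad[K + k] += gw;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("gradient") = grad);
}
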