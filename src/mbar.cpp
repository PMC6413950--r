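// Self-consistent MBAR solver with adaptive Newton acceleration.
// All exponentials are taken in the log domain; reduced potentials of any
// magnitude are handled without overflow.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// column-wise log-sum-exp of A (rows = states); returns length-N row vector
static rowvec col_logsumexp(const mat& A) {
  rowvec m = max(A, 0);
  mat B = A;
  B.each_row() -= m;
  return m + log(sum(exp(B), 0));
}

// log denominator per sample: ln sum_l N_l exp(f_l - u_ln)
static rowvec log_denominator(const mat& u, const vec& f, const vec& logN) {
  mat A = -u;
  A.each_col() += (f + logN);
  return col_logsumexp(A);
}

// one self-consistent update; returns f with f[0] = 0
static vec scf_update(const mat& u, const rowvec& logdenom) {
  const uword K = u.n_rows;
  vec fnew(K);
  for (uword k = 0; k < K; ++k) {
    rowvec b = -u.row(k) - logdenom;
    double m = b.max();
    fnew(k) = -(m + std::log(accu(exp(b - m))));
  }
  return fnew - fnew(0);
}

// gradient of the MBAR objective restricted to sampled states
static vec mbar_gradient(const mat& u, const vec& f, const vec& counts,
                         const vec& logN, rowvec& logdenom) {
  logdenom = log_denominator(u, f, logN);
  const uword K = u.n_rows;
  vec g(K, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    if (counts(k) <= 0) continue;
    rowvec lw = f(k) - u.row(k) - logdenom;     // ln W_nk
    double m = lw.max();
    double ck = std::exp(m) * accu(exp(lw - m)); // sum_n W_nk
    g(k) = counts(k) * (ck - 1.0);
  }
  return g;
}

// [[Rcpp::export]]
Rcpp::List mbar_solve_cpp(const arma::mat& u, const arma::vec& counts,
                          const arma::vec& f0, double tol, int max_iter) {
  const uword K = u.n_rows;
  vec f = f0 - f0(0);
  vec logN(K);
  for (uword k = 0; k < K; ++k)
    logN(k) = counts(k) > 0 ? std::log(counts(k)) : -datum::inf;

  uvec sampled = find(counts > 0);
  // indices among sampled states excluding the anchor state 0
  uvec freeidx = sampled(find(sampled > 0));

  rowvec logdenom;
  double delta = datum::inf;
  int it = 0;
  bool converged = false;

  while (it < max_iter) {
    ++it;
    logdenom = log_denominator(u, f, logN);
    vec fscf = scf_update(u, logdenom);
    delta = abs(fscf - f).max();
    if (delta < tol) { f = fscf; converged = true; break; }

    vec fnext = fscf;
    // Newton acceleration once the iterate is in the basin
    if (delta < 0.5 && freeidx.n_elem > 0) {
      // W restricted to sampled states (others have zero weight in H)
      mat lW = -u;
      lW.each_col() += f;
      lW.each_row() -= logdenom;
      mat W = exp(lW);                       // K x N
      vec c = sum(W, 1);                     // sum_n W_nk
      vec g = counts % (c - 1.0);
      mat NW = W;
      NW.each_col() %= counts;               // N_k W_nk
      mat H = diagmat(counts % c) - NW * NW.t();
      mat Hr = H(freeidx, freeidx);
      vec gr = g(freeidx);
      vec step;
      bool ok = solve(step, Hr, gr, solve_opts::no_approx);
      if (ok && step.is_finite()) {
        // damp very large steps to preserve global convergence
        double smax = abs(step).max();
        if (smax > 2.0) step *= 2.0 / smax;
        vec ftry = f;
        for (uword j = 0; j < freeidx.n_elem; ++j)
          ftry(freeidx(j)) -= step(j);
        // accept if the Newton iterate does not increase the SCF residual
        rowvec ld_try = log_denominator(u, ftry, logN);
        vec fscf_try = scf_update(u, ld_try);
        double d_try = abs(fscf_try - ftry).max();
        if (std::isfinite(d_try) && d_try <= delta) fnext = ftry;
      }
    }
    f = fnext - fnext(0);
  }

  logdenom = log_denominator(u, f, logN);
  return Rcpp::List::create(
    Rcpp::Named("f") = f,
    Rcpp::Named("log_denominator") = vec(logdenom.t()),
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("residual") = delta);
}

// Weight matrix W (N x K), W_nk = exp(f_k - u_kn - logdenom_n), as its
// crossproduct W'W (K x K) plus column sums, computed in one pass.
// [[Rcpp::export]]
Rcpp::List mbar_weights_cpp(const arma::mat& u, const arma::vec& f,
                            const arma::vec& counts) {
  vec logN(u.n_rows);
  for (uword k = 0; k < u.n_rows; ++k)
    logN(k) = counts(k) > 0 ? std::log(counts(k)) : -datum::inf;
  rowvec logdenom = log_denominator(u, f, logN);
  mat lW = -u;
  lW.each_col() += f;
  lW.each_row() -= logdenom;
  mat W = exp(lW);          // K x N
  mat WtW = W * W.t();      // = (N x K weights)' (N x K weights)
  vec colsum = sum(W, 1);
  return Rcpp::List::create(
    Rcpp::Named("wtw") = WtW,
    Rcpp::Named("colsum") = colsum);
}
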