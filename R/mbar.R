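#' Reduced-potential sample matrix
#'
#' Container for the input of multistate free-energy estimators: the matrix
#' `u` of reduced (dimensionless, u = U/kT) potentials, where entry (k, n)
#' is state k's reduced potential evaluated on sample n, together with the
#' per-state sample counts and the lambda schedule. Samples are ordered by
#' origin state: the first `counts[1]` columns were drawn from state 1, and
#' so on. States with zero counts are allowed as "virtual" evaluation
#' states.
#'
#' @param u numeric matrix, K states x N samples, all finite
#' @param counts integer vector of length K, sum equal to ncol(u)
#' @param lambdas strictly increasing schedule in [0, 1]; defaults to
#'   equidistant values
#' @return an object of class `reduced_potentials`
#' @export
reduced_potentials <- function(u, counts, lambdas = NULL) {
  u <- as.matrix(u)
  K <- nrow(u)
  if (K < 2L) stop("need at least two states")
  if (!all(is.finite(u))) stop("reduced potentials must be finite")
  counts <- as.integer(counts)
  if (length(counts) != K || any(counts < 0) || sum(counts) != ncol(u)) {
    stop("`counts` must have length K, be non-negative and sum to ncol(u)")
  }
  if (sum(counts > 0) < 2L) stop("need at least two sampled states")
  if (is.null(lambdas)) lambdas <- seq(0, 1, length.out = K)
  if (length(lambdas) != K || any(diff(lambdas) <= 0)) {
    stop("`lambdas` must be strictly increasing with one value per state")
  }
  structure(list(u = u, counts = counts, lambdas = lambdas),
            class = "reduced_potentials")
}

#' @export
print.reduced_potentials <- function(x, ...) {
  cat(sprintf("<reduced_potentials> K = %d states, N = %d samples\n",
              nrow(x$u), ncol(x$u)))
  invisible(x)
}

# warm start: ladder of forward exponential-averaging estimates
exp_ladder_start <- function(u, counts) {
  K <- nrow(u)
  f <- numeric(K)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  for (k in seq_len(K - 1L)) {
    # samples from the nearest sampled state at or below k
    ko <- max(which(counts[seq_len(k)] > 0))
    idx <- seq.int(starts[ko], ends[ko])
    dU <- u[k + 1L, idx] - u[ko, idx]
    f[k + 1L] <- f[ko] - (logsumexp(-dU) - log(length(idx)))
  }
  f
}

#' MBAR free energies from reduced-potential samples
#'
#' Solves the multistate Bennett acceptance ratio self-consistency
#' equations \deqn{f_k = -\ln \sum_n \frac{e^{-u_{kn}}}{\sum_l N_l
#' e^{f_l - u_{ln}}}} for the dimensionless free energies of all states
#' (anchored at f(1) = 0). Self-consistent iteration is warm-started from
#' an exponential-averaging ladder and accelerated with damped
#' Newton-Raphson steps once near the solution; all exponentials are taken
#' in the log domain. The asymptotic covariance of f is estimated from the
#' weight matrix (see Details).
#'
#' @details The N x K weight matrix W with \eqn{W_{nk} = e^{f_k - u_{kn}} /
#'   \sum_l N_l e^{f_l - u_{ln}}} satisfies column sums of 1 at the
#'   solution. Its covariance estimator is \eqn{\Theta = V S (I - S V' N V
#'   S)^+ S V'} where \eqn{W = U S V'} and N is the diagonal matrix of
#'   sample counts; uncertainties of differences follow as
#'   \eqn{\sigma^2(f_j - f_i) = \Theta_{ii} + \Theta_{jj} - 2\Theta_{ij}}.
#'
#' @param u a [reduced_potentials()] object
#' @param tolerance convergence threshold on the maximum absolute change in
#'   f between self-consistent iterations
#' @param max_iterations iteration cap; non-convergence returns the last
#'   iterate with `converged = FALSE` and a warning, never a silent success
#' @param compute_covariance set FALSE to skip the covariance estimate
#' @return an object of class `mbar_result`: list with `f` (length K,
#'   f[1] = 0), `covariance` (K x K), `iterations`, `converged`
#' @export
mbar <- function(u, tolerance = 1e-10, max_iterations = 10000L,
                 compute_covariance = TRUE) {
  stopifnot(inherits(u, "reduced_potentials"))
  f0 <- exp_ladder_start(u$u, u$counts)
  sol <- mbar_solve_cpp(u$u, as.numeric(u$counts), f0, tolerance,
                        as.integer(max_iterations))
  if (!sol$converged) {
    warning(sprintf(
      "MBAR did not converge in %d iterations (residual %.3g)",
      sol$iterations, sol$residual))
  }
  res <- structure(
    list(f = as.numeric(sol$f), covariance = NULL,
         iterations = sol$iterations, converged = sol$converged,
         counts = u$counts),
    class = "mbar_result")
  if (compute_covariance) res$covariance <- mbar_covariance(res, u)
  res
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("<mbar_result> K = %d, iterations = %d, converged = %s\n",
              length(x$f), x$iterations, x$converged))
  cat("f:", format(x$f, digits = 6), "\n")
  invisible(x)
}

#' Asymptotic covariance of MBAR free energies
#'
#' @param result an `mbar_result`
#' @param u the [reduced_potentials()] object the result was estimated from
#' @return K x K symmetric positive semidefinite covariance matrix of the
#'   dimensionless free energies
#' @export
mbar_covariance <- function(result, u) {
  stopifnot(inherits(result, "mbar_result"), inherits(u, "reduced_potentials"))
  wts <- mbar_weights_cpp(u$u, result$f, as.numeric(u$counts))
  K <- nrow(u$u)
  eg <- eigen(wts$wtw, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  S <- sqrt(pmax(eg$values[pos], 0))
  V <- eg$vectors[, pos, drop = FALSE]
  # Theta = V S (I - S V' N V S)^+ S V'
  M <- diag(length(S)) - (S * t(V)) %*% (u$counts * V) %*% diag(S, length(S))
  Minv <- MASS::ginv((M + t(M)) / 2)
  theta <- V %*% diag(S, length(S)) %*% Minv %*% diag(S, length(S)) %*% t(V)
  theta <- (theta + t(theta)) / 2
  dimnames(theta) <- NULL
  theta
}

#' Uncertainty of the end-to-end free-energy difference
#'
#' @param result converged `mbar_result` with covariance
#' @param i,j state indices (default the two end states)
#' @return standard uncertainty of f(j) - f(i), dimensionless
#' @export
mbar_deltaf_sigma <- function(result, i = 1L, j = length(result$f)) {
  th <- result$covariance
  if (is.null(th)) stop("result carries no covariance")
  sqrt(max(th[i, i] + th[j, j] - 2 * th[i, j], 0))
}

#' Per-leg free energy in physical units
#'
#' Runs MBAR on a leg's reduced-potential samples and converts the
#' end-state difference to kcal/mol: value = kT (f_K - f_1).
#'
#' @param u a [reduced_potentials()] object for one leg
#' @param temperature temperature in kelvin
#' @param ... passed to [mbar()]
#' @return `fe_value` of kind `"leg"`; carries a `converged` attribute
#' @export
leg_free_energy <- function(u, temperature = 300, ...) {
  res <- mbar(u, ...)
  kt <- kT_kcal(temperature)
  K <- length(res$f)
  out <- fe_value(kt * (res$f[K] - res$f[1]),
                  kt * mbar_deltaf_sigma(res), kind = "leg")
  attr(out, "converged") <- res$converged
  out
}

#' Bennett acceptance ratio for a two-state system
#'
#' Solves the BAR self-consistency condition by one-dimensional
#' root-finding; algebraically identical to MBAR restricted to K = 2.
#'
#' @param u a [reduced_potentials()] object with exactly two sampled states
#' @param tolerance root-finding tolerance on Delta f
#' @return `fe_value` (dimensionless value stored in kcal-free form; use
#'   `kT_kcal()` to convert) of kind `"leg"`; here the value is the
#'   dimensionless Delta f
#' @export
bar_two_state <- function(u, tolerance = 1e-12) {
  stopifnot(inherits(u, "reduced_potentials"))
  if (nrow(u$u) != 2L) stop("BAR needs exactly two states")
  n0 <- u$counts[1]; n1 <- u$counts[2]
  if (n0 < 1L || n1 < 1L) stop("both states need samples")
  i0 <- seq_len(n0); i1 <- n0 + seq_len(n1)
  wF <- u$u[2, i0] - u$u[1, i0]   # forward work, samples from state 1
  wR <- u$u[1, i1] - u$u[2, i1]   # reverse work, samples from state 2
  M <- log(n0 / n1)
  # sum_F logistic(-(M + wF - x)) - sum_R logistic(-(-M + wR + x)) = 0
  g <- function(x) {
    sum(stats::plogis(-(M + wF - x))) - sum(stats::plogis(-(-M + wR + x)))
  }
  lo <- -1; hi <- 1
  while (g(lo) > 0 && lo > -1e4) lo <- lo * 2
  while (g(hi) < 0 && hi < 1e4) hi <- hi * 2
  if (g(lo) > 0 || g(hi) < 0) {
    stop("BAR root not bracketed: no overlap between the two states")
  }
  root <- uniroot(g, c(lo, hi), tol = tolerance)$root
  fe_value(root, 0, kind = "leg")
}

#' Zwanzig exponential-averaging estimator (two states)
#'
#' Unidirectional free-energy perturbation: \eqn{\Delta f = -\ln\langle
#' e^{-\Delta u}\rangle} over the chosen direction's samples. Biased at
#' finite sample size; used as a directional oracle bracketing BAR/MBAR.
#'
#' @param u a [reduced_potentials()] with exactly two states
#' @param direction `"forward"` (samples from state 1) or `"reverse"`
#' @return dimensionless Delta f estimate (state 2 minus state 1)
#' @export
exp_averaging <- function(u, direction = c("forward", "reverse")) {
  stopifnot(inherits(u, "reduced_potentials"))
  direction <- match.arg(direction)
  if (nrow(u$u) != 2L) stop("exponential averaging needs exactly two states")
  n0 <- u$counts[1]; n1 <- u$counts[2]
  if (direction == "forward") {
    if (n0 < 1L) stop("no samples from state 1")
    dU <- u$u[2, seq_len(n0)] - u$u[1, seq_len(n0)]
    -(logsumexp(-dU) - log(n0))
  } else {
    if (n1 < 1L) stop("no samples from state 2")
    dU <- u$u[1, n0 + seq_len(n1)] - u$u[2, n0 + seq_len(n1)]
    logsumexp(-dU) - log(n1)
  }
}
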