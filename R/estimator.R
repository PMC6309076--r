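#' Symmetric vectorizer
#'
#' Index map between symmetric p x p matrices and their p(p+1)/2 free
#' parameters theta (upper triangle including the diagonal, column-major
#' order over pairs j <= k). This is the duplication map Gamma with
#' `Gamma[jk, jk] = Gamma[kj, jk] = 1` and zeros elsewhere; parameterizing
#' the optimization by theta makes symmetry of the estimated difference
#' matrix exact by construction and halves the problem dimension.
#'
#' @param p matrix dimension.
#' @return a `sym_vectorizer` object with fields `p`, `d = p(p+1)/2`,
#'   `rows`, `cols` (the (j, k) pair for each theta coordinate) and
#'   `diag` (logical mask of diagonal coordinates).
#' @export
sym_vectorizer <- function(p) {
  p <- as.integer(p)
  if (p < 1L) stop("p must be a positive integer")
  cols <- rep.int(seq_len(p), seq_len(p))
  rows <- unlist(lapply(seq_len(p), seq_len), use.names = FALSE)
  structure(list(p = p, d = as.integer(p * (p + 1L) / 2L),
                 rows = rows, cols = cols,
                 diag = rows == cols),
            class = "sym_vectorizer")
}

#' @rdname sym_vectorizer
#' @param theta length-`p(p+1)/2` coefficient vector.
#' @param vectorizer a [sym_vectorizer()].
#' @export
theta_to_matrix <- function(theta, vectorizer) {
  stopifnot(length(theta) == vectorizer$d)
  m <- matrix(0, vectorizer$p, vectorizer$p)
  m[cbind(vectorizer$rows, vectorizer$cols)] <- theta
  m[cbind(vectorizer$cols, vectorizer$rows)] <- theta
  m
}

#' @rdname sym_vectorizer
#' @param m symmetric matrix.
#' @export
matrix_to_theta <- function(m, vectorizer) {
  stopifnot(nrow(m) == vectorizer$p)
  m[cbind(vectorizer$rows, vectorizer$cols)]
}

#' Apply the quadratic operator of the difference estimator
#'
#' Computes `Gamma' (s1 (x) s2) Gamma theta` without materializing the
#' Kronecker product, as the sandwich `vec(s2 Delta(theta) s1)` followed by
#' the Gamma'-projection. Memory is O(p^2).
#'
#' @param vectorizer a [sym_vectorizer()].
#' @param s1,s2 the two groups' correlation matrix estimates.
#' @param theta coefficient vector of length `p(p+1)/2`.
#' @return vector of length `p(p+1)/2`.
#' @export
apply_quadratic_operator <- function(vectorizer, s1, s2, theta) {
  s1 <- corr_matrix_of(s1); s2 <- corr_matrix_of(s2)
  if (!all(dim(s1) == dim(s2)) || nrow(s1) != vectorizer$p ||
      length(theta) != vectorizer$d)
    stop("dimension mismatch")
  as.numeric(cpp_apply_quadratic_operator(s1, s2, as.numeric(theta)))
}

#' Project onto the split constraint box
#'
#' Coordinate-wise clipping used by the ADMM z-update: off-diagonal theta
#' coordinates to `[-lambda, lambda]`, diagonal coordinates to
#' `[-lambda/2, lambda/2]`.
#'
#' @param v vector of length `p(p+1)/2`.
#' @param lambda nonnegative constraint level.
#' @param vectorizer a [sym_vectorizer()].
#' @return the projected vector.
#' @export
project_z <- function(v, lambda, vectorizer) {
  if (lambda < 0) stop("lambda must be nonnegative")
  bound <- ifelse(vectorizer$diag, lambda / 2, lambda)
  .clip(v, -bound, bound)
}

#' Solve the l1-penalized theta-subproblem
#'
#' Minimizes `|v - A theta|_2^2 + (2/rho) |theta|_1` where `A` is the
#' quadratic operator for `(s1, s2)`, by cyclic coordinate descent over an
#' active set with full Karush-Kuhn-Tucker screening passes. Every coordinate
#' update is an exact scalar minimization, so the objective is non-increasing
#' across iterations.
#'
#' @param s1,s2 correlation matrix estimates.
#' @param v target vector.
#' @param rho positive ADMM penalty parameter.
#' @param theta0 warm start (defaults to zero).
#' @param inner_tol stop when the max-abs coordinate change falls below this.
#' @param inner_max iteration cap.
#' @return list with `theta` and `iterations`.
#' @export
update_theta <- function(s1, s2, v, rho, theta0 = NULL, inner_tol = 1e-8,
                         inner_max = 500L) {
  s1 <- corr_matrix_of(s1); s2 <- corr_matrix_of(s2)
  if (rho <= 0) stop("rho must be positive")
  d <- nrow(s1) * (nrow(s1) + 1) / 2
  if (is.null(theta0)) theta0 <- numeric(d)
  out <- cpp_update_theta(s1, s2, as.numeric(v), rho, as.numeric(theta0),
                          inner_tol, as.integer(inner_max))
  list(theta = as.numeric(out$theta), iterations = out$iterations)
}

new_difference_estimate <- function(fit, p, names = NULL) {
  vz <- sym_vectorizer(p)
  delta <- theta_to_matrix(as.numeric(fit$theta), vz)
  if (!is.null(names)) dimnames(delta) <- list(names, names)
  structure(list(delta_hat = delta, theta = as.numeric(fit$theta),
                 lambda = fit$lambda, iterations = fit$iterations,
                 converged = fit$converged,
                 primal_residual = fit$primal_residual,
                 dual_residual = fit$dual_residual,
                 residuals = fit$residuals),
            class = "difference_estimate")
}

#' @export
print.difference_estimate <- function(x, ...) {
  cat(sprintf(
    "difference_estimate: p = %d, lambda = %.4g, %d nonzero entries, %s (%d iterations)\n",
    nrow(x$delta_hat), x$lambda, sum(abs(x$delta_hat) > 1e-5),
    if (isTRUE(x$converged)) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Direct difference-of-precision-matrices estimate at one lambda
#'
#' Solves
#' \deqn{\min |\Delta|_1 \ \mathrm{s.t.}\
#'   |\hat S^X \Delta \hat S^Y - \hat S^X + \hat S^Y|_\infty \le \lambda}
#' in symmetric-vectorized form (off-diagonal constraint level `lambda`,
#' diagonal level `lambda/2`) by ADMM. The two correlation estimates can be
#' rank-based latent correlations or Pearson correlations; sparsity is
#' required only of the difference, not of the individual precision matrices,
#' so the individual networks may contain hub nodes.
#'
#' The outer loop stops when both the primal and dual residual sup-norms fall
#' below `tol`; the theta-subproblem is solved by [update_theta()].
#'
#' @param s1,s2 the two groups' correlation matrix estimates
#'   ([latent_correlation()] objects or plain matrices); group 1 plays the
#'   role of \eqn{\hat S^X}.
#' @param lambda nonnegative constraint level.
#' @param rho positive ADMM penalty parameter (default 1).
#' @param max_iter outer iteration cap.
#' @param tol outer stopping tolerance on the residual sup-norms.
#' @param inner_tol,inner_max theta-subproblem controls: coordinate-descent
#'   sweep tolerance and sweep budget per outer iteration. The default budget
#'   of 5 sweeps gives an inexact ADMM whose iterates converge to the same
#'   solution at a fraction of the cost of exact inner solves.
#' @param warm optional list with `theta`, `z`, `u` to warm-start from.
#' @return a `difference_estimate`: symmetric `delta_hat`, the packed
#'   `theta`, `lambda`, iteration/convergence metadata and residual
#'   histories.
#' @export
admm_solve <- function(s1, s2, lambda, rho = 1, max_iter = 2000L,
                       tol = 1e-5, inner_tol = 1e-8, inner_max = 5L,
                       warm = NULL) {
  m1 <- corr_matrix_of(s1); m2 <- corr_matrix_of(s2)
  if (!all(dim(m1) == dim(m2))) stop("s1 and s2 must have equal dimension")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (rho <= 0) stop("rho must be positive")
  fit <- cpp_admm_solve(m1, m2, lambda, rho, as.integer(max_iter), tol,
                        inner_tol, as.integer(inner_max),
                        theta0 = warm$theta, z0 = warm$z, u0 = warm$u)
  new_difference_estimate(fit, nrow(m1), colnames(m1))
}

#' Largest useful constraint level
#'
#' The smallest lambda at which `theta = 0` is feasible:
#' `max(|c_O|inf, 2 |c_D|inf)` for `c = Gamma' vec(s1 - s2)`. Above it the
#' solution is exactly zero.
#'
#' @param s1,s2 correlation matrix estimates.
#' @return nonnegative scalar.
#' @export
lambda_max <- function(s1, s2) {
  m1 <- corr_matrix_of(s1); m2 <- corr_matrix_of(s2)
  cvec <- as.numeric(cpp_gamma_t_vec(m1 - m2))
  vz <- sym_vectorizer(nrow(m1))
  max(abs(cvec[!vz$diag]), 2 * abs(cvec[vz$diag]), 0)
}

#' Default lambda grid
#'
#' `nlambda` log-spaced values spanning `[lambda_min_ratio, 0.95]` times
#' [lambda_max()], in decreasing order (as expected by [solve_path()] warm
#' starts). The grid starts just below `lambda_max` so that every candidate
#' fit contains at least one coordinate: the all-zero solution carries no
#' information about the fit-complexity trade-off and would otherwise sit on
#' the tuning path as a degenerate candidate.
#'
#' @param s1,s2 correlation matrix estimates.
#' @param nlambda grid length (default 50).
#' @param lambda_min_ratio ratio of smallest grid value to `lambda_max`
#'   (default 0.01).
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(s1, s2, nlambda = 50L, lambda_min_ratio = 0.01) {
  lmax <- lambda_max(s1, s2)
  if (lmax <= 0) return(rep(0, nlambda))
  exp(seq(log(lmax * 0.95), log(lmax * lambda_min_ratio),
          length.out = nlambda))
}

#' Warm-started solution path over a lambda grid
#'
#' Runs [admm_solve()] along a decreasing lambda grid, carrying the ADMM
#' state from each solution to the next. Deterministic given its inputs.
#'
#' @inheritParams admm_solve
#' @param lambdas decreasing grid of constraint levels; by default
#'   [lambda_grid()] with `nlambda` points.
#' @param nlambda grid length when `lambdas` is not supplied.
#' @param lambda_min_ratio see [lambda_grid()].
#' @return list of `difference_estimate` objects, one per lambda.
#' @export
solve_path <- function(s1, s2, lambdas = NULL, rho = 1, max_iter = 2000L,
                       tol = 1e-5, inner_tol = 1e-8, inner_max = 5L,
                       nlambda = 50L, lambda_min_ratio = 0.01) {
  m1 <- corr_matrix_of(s1); m2 <- corr_matrix_of(s2)
  if (is.null(lambdas))
    lambdas <- lambda_grid(m1, m2, nlambda, lambda_min_ratio)
  if (is.unsorted(rev(lambdas)))
    lambdas <- sort(lambdas, decreasing = TRUE)
  fits <- cpp_admm_path(m1, m2, as.numeric(lambdas), rho,
                        as.integer(max_iter), tol, inner_tol,
                        as.integer(inner_max))
  lapply(fits, new_difference_estimate, p = nrow(m1), names = colnames(m1))
}

#' Rate-based support threshold
#'
#' The sign-recovery theory for the direct difference estimator keeps entries
#' whose magnitude exceeds a multiple of the estimation-error rate
#' \eqn{\sqrt{\log p / \min(n_1, n_2)}}. This helper returns
#' `const` times that rate. It is the appropriate threshold in the consistent
#' regime (`min(n) >> log p`), where the estimate separates true entries from
#' noise-fit entries by a wide magnitude gap; at `n` comparable to `p` the
#' shrunk true entries may fall below it, and the numerical-zero default of
#' [threshold_support()] is the better choice.
#'
#' @param p number of variables.
#' @param n1,n2 group sample sizes.
#' @param const rate multiple (default 5; noise-fit entries concentrate
#'   within about three rate units while recoverable entries sit an order of
#'   magnitude above the rate, so the default leaves a safety margin on both
#'   sides).
#' @return nonnegative scalar threshold.
#' @export
support_threshold <- function(p, n1, n2, const = 5) {
  const * sqrt(log(p) / min(n1, n2))
}

#' Threshold a difference estimate for support recovery
#'
#' Keeps entries with `|delta_hat| > tau_threshold` (with their signs) and
#' zeroes the rest. The default threshold is numerical zero; the larger
#' theoretically-motivated threshold is exposed through `tau_threshold`.
#'
#' @param delta_hat a `difference_estimate` or numeric matrix.
#' @param tau_threshold nonnegative threshold (default `1e-5`).
#' @return list with `delta` (thresholded matrix), `signs` (sign matrix) and
#'   `support` (logical matrix of retained off-diagonal entries).
#' @export
threshold_support <- function(delta_hat, tau_threshold = 1e-5) {
  if (tau_threshold < 0) stop("tau_threshold must be nonnegative")
  m <- if (inherits(delta_hat, "difference_estimate")) delta_hat$delta_hat
       else as.matrix(delta_hat)
  keep <- abs(m) > tau_threshold
  out <- m * keep
  supp <- keep
  diag(supp) <- FALSE
  list(delta = out, signs = sign(out), support = supp)
}
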