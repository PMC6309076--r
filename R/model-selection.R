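#' Loss of a difference estimate
#'
#' Norms of the residual matrix
#' \eqn{\hat S^X \hat\Delta \hat S^Y - \hat S^X + \hat S^Y}:
#' elementwise sup-norm (`"Linf"`), Frobenius norm (`"F"`), spectral norm
#' (`"spectral"`), or elementwise l1 norm (`"L1"`, an additional option for
#' tuning comparable to the others).
#'
#' @param s1,s2 the two groups' correlation matrix estimates.
#' @param delta_hat a `difference_estimate` or numeric matrix.
#' @param loss one of `"Linf"`, `"F"`, `"spectral"`, `"L1"`.
#' @return nonnegative scalar.
#' @export
loss_value <- function(s1, s2, delta_hat, loss = c("Linf", "F", "spectral", "L1")) {
  loss <- match.arg(loss)
  m1 <- corr_matrix_of(s1); m2 <- corr_matrix_of(s2)
  d <- if (inherits(delta_hat, "difference_estimate")) delta_hat$delta_hat
       else as.matrix(delta_hat)
  r <- m1 %*% d %*% m2 - m1 + m2
  switch(loss,
         Linf = max(abs(r)),
         F = norm(r, "F"),
         spectral = norm(r, "2"),
         L1 = sum(abs(r)))
}

#' AIC-style tuning over a solution path
#'
#' Selects the constraint level minimizing
#' \deqn{(n_1 + n_2)\,L(\lambda) + 2k(\lambda),}
#' where `L` is one of the losses in [loss_value()] and `k` is the effective
#' degrees of freedom, approximated by the number of nonzero theta
#' coordinates (upper triangle including the diagonal, counted above
#' numerical zero `1e-5`). Non-converged path points are excluded; ties are
#' broken toward the larger lambda.
#'
#' @param path list of `difference_estimate`s from [solve_path()].
#' @param s1,s2 the correlation estimates the path was fit to.
#' @param n1,n2 the two group sample sizes.
#' @param loss loss name, see [loss_value()].
#' @return a `tuning_result`: list with `lambda_selected`, `index`,
#'   `estimate` (the selected `difference_estimate`), `loss_name` and a
#'   `table` (lambda, loss, k, aic, converged).
#' @export
aic_select <- function(path, s1, s2, n1, n2,
                       loss = c("Linf", "F", "spectral", "L1")) {
  loss <- match.arg(loss)
  if (!length(path)) stop("empty path")
  lam <- vapply(path, `[[`, numeric(1), "lambda")
  conv <- vapply(path, function(f) isTRUE(f$converged), logical(1))
  lv <- vapply(path, function(f) loss_value(s1, s2, f, loss), numeric(1))
  k <- vapply(path, function(f) sum(abs(f$theta) > 1e-5), numeric(1))
  aic <- (n1 + n2) * lv + 2 * k
  cand <- which(conv)
  if (!length(cand)) stop("no converged estimates on the path")
  # minimal AIC; ties toward larger lambda
  best <- cand[order(aic[cand], -lam[cand])][1L]
  structure(list(lambda_selected = lam[best], index = best,
                 estimate = path[[best]], loss_name = loss,
                 table = data.frame(lambda = lam, loss = lv, k = k,
                                    aic = aic, converged = conv)),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("tuning_result (%s loss): lambda = %.4g (index %d of %d)\n",
              x$loss_name, x$lambda_selected, x$index, nrow(x$table)))
  invisible(x)
}
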