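#' Bivariate standard normal CDF
#'
#' \eqn{\Phi_2(u, v, t) = P(Z_1 \le u, Z_2 \le v)} for a standard bivariate
#' normal vector with correlation `t`, vectorized over all three arguments
#' (recycled to a common length). Computed by Genz's hybrid quadrature
#' algorithm to double precision.
#'
#' @param u,v upper integration limits.
#' @param t correlation(s) in `[-1, 1]`.
#' @return numeric vector of probabilities.
#' @export
pbvn <- function(u, v, t) {
  if (any(abs(t) > 1)) stop("correlation must lie in [-1, 1]")
  cpp_pbvn(as.numeric(u), as.numeric(v), as.numeric(t))
}

#' Kendall's tau-a concordance statistic
#'
#' The pairwise concordance statistic
#' \deqn{\hat\tau = \frac{2}{n(n-1)} \sum_{i < i'}
#'   \mathrm{sign}(x_i - x_{i'}) \, \mathrm{sign}(y_i - y_{i'}),}
#' in which tied pairs contribute zero (tau-a, not the tie-normalized tau-b).
#' This is the form the bridge functions for binary and mixed pairs assume:
#' their population versions are expectations of exactly this statistic.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return tau in `[-1, 1]`.
#' @examples
#' kendall_tau(1:3, 1:3)   # 1: all pairs concordant
#' kendall_tau(1:3, 3:1)   # -1
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  cpp_kendall_tau_a(as.numeric(x), as.numeric(y))
}

#' Nonparanormal correlation from Kendall's tau
#'
#' For a continuous Gaussian-copula pair the latent correlation is
#' \eqn{\sin(\pi \tau / 2)}.
#'
#' @param tau Kendall's tau value(s) in `[-1, 1]`.
#' @return latent correlation value(s).
#' @examples
#' npn_correlation_entry(1 / 3)  # sin(pi/6) = 0.5
#' @export
npn_correlation_entry <- function(tau) {
  if (any(abs(tau) > 1)) stop("tau must lie in [-1, 1]")
  sin(pi * tau / 2)
}

#' Bridge function for a binary-binary pair
#'
#' Population Kendall's tau of two 0/1 indicators obtained by thresholding a
#' latent bivariate normal pair with correlation `t` at (standard-normal
#' scale) cutoffs `lam_j`, `lam_k`:
#' \deqn{F(t; \Lambda_j, \Lambda_k) =
#'   2\{\Phi_2(\Lambda_j, \Lambda_k, t) - \Phi(\Lambda_j)\Phi(\Lambda_k)\}.}
#' Strictly increasing in `t` for fixed cutoffs.
#'
#' @param t latent correlation(s), `|t| < 1`.
#' @param lam_j,lam_k cutoffs on the standard-normal scale.
#' @return population tau value(s).
#' @export
bridge_F <- function(t, lam_j, lam_k) {
  if (any(abs(t) >= 1)) stop("t must lie strictly inside (-1, 1)")
  2 * (pbvn(lam_j, lam_k, t) - pnorm(lam_j) * pnorm(lam_k))
}

#' Bridge function for a binary-continuous pair
#'
#' Population Kendall's tau between a dichotomized latent coordinate (cutoff
#' `lam_j`) and a continuous latent coordinate with latent correlation `t`:
#' \deqn{H(t; \Lambda_j) = 4\Phi_2(\Lambda_j, 0, t/\sqrt{2}) - 2\Phi(\Lambda_j).}
#'
#' @param t latent correlation(s), `|t| < 1`.
#' @param lam_j cutoff of the binary coordinate.
#' @return population tau value(s).
#' @export
bridge_H <- function(t, lam_j) {
  if (any(abs(t) >= 1)) stop("t must lie strictly inside (-1, 1)")
  4 * pbvn(lam_j, 0, t / sqrt(2)) - 2 * pnorm(lam_j)
}

# Vectorized monotone bisection for the bridge inversions. `fn(t)` must be
# elementwise strictly increasing in t; tau outside the attainable range
# (fn evaluated at the interval ends) is clipped to the nearest endpoint,
# which keeps small-sample estimates finite instead of failing.
.bridge_invert <- function(fn, tau, tol = 1e-8) {
  eps <- .CORR_EPS
  n <- length(tau)
  lo <- rep(-1 + eps, n)
  hi <- rep(1 - eps, n)
  flo <- fn(lo)
  fhi <- fn(hi)
  out <- numeric(n)
  below <- tau <= flo
  above <- tau >= fhi
  active <- !(below | above)
  out[below] <- -1 + eps
  out[above] <- 1 - eps
  if (any(active)) {
    lo <- lo[active]; hi <- hi[active]; tv <- tau[active]
    # bisection: interval halves each step, run until width < tol
    steps <- ceiling(log2(2 / tol)) + 2L
    for (s in seq_len(steps)) {
      mid <- (lo + hi) / 2
      fm <- fn_sub(fn, mid, active)
      up <- fm < tv
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    root <- (lo + hi) / 2
    if (any(!is.finite(root)))
      stop("bridge inversion failed to converge (non-finite iterate)")
    out[active] <- root
  }
  out
}

# evaluate fn on the active subset (fn closes over full-length cutoff
# vectors; it receives the active index set to subset them)
fn_sub <- function(fn, mid, active) fn(mid, active)

#' Invert the binary-binary bridge function
#'
#' Finds the latent correlation `t` with `bridge_F(t, lam_j, lam_k) = tau` by
#' bracketed monotone bisection on `[-1 + 1e-6, 1 - 1e-6]` to absolute
#' tolerance `1e-8`. `tau` outside the attainable range is mapped to the
#' nearest interval endpoint.
#'
#' @param tau observed Kendall's tau value(s).
#' @param lam_j,lam_k cutoffs on the standard-normal scale.
#' @return latent correlation value(s) in `[-1 + 1e-6, 1 - 1e-6]`.
#' @export
bridge_F_inverse <- function(tau, lam_j, lam_k) {
  n <- max(length(tau), length(lam_j), length(lam_k))
  tau <- rep_len(tau, n); lj <- rep_len(lam_j, n); lk <- rep_len(lam_k, n)
  act <- seq_len(n)
  .bridge_invert(function(t, active = act) {
    bridge_F(t, lj[active], lk[active])
  }, tau)
}

#' Invert the binary-continuous bridge function
#'
#' As [bridge_F_inverse()] for the mixed-pair bridge `H`.
#'
#' @param tau observed Kendall's tau value(s).
#' @param lam_j cutoff of the binary coordinate.
#' @return latent correlation value(s).
#' @export
bridge_H_inverse <- function(tau, lam_j) {
  n <- max(length(tau), length(lam_j))
  tau <- rep_len(tau, n); lj <- rep_len(lam_j, n)
  act <- seq_len(n)
  .bridge_invert(function(t, active = act) bridge_H(t, lj[active]), tau)
}

#' Estimate transformed cutoffs of binary variables
#'
#' For a binary column with sample mean \eqn{\bar B_j}, the identifiable
#' cutoff on the standard-normal scale is estimated by
#' \eqn{\hat\Lambda_j = \Phi^{-1}(1 - \bar B_j)}. The mean is clamped to
#' `[1/(2n), 1 - 1/(2n)]` first so that constant columns yield finite cutoffs.
#'
#' @param data a [data_matrix()] (or matrix coerced with `types = "auto"`).
#' @return numeric vector of length `p`: estimated cutoffs for binary
#'   variables, `NA` for continuous ones.
#' @export
estimate_cutoffs <- function(data) {
  data <- as_data_matrix(data)
  n <- nrow(data$values)
  lam <- rep(NA_real_, ncol(data$values))
  bin <- data$types == "binary"
  if (any(bin)) {
    bbar <- colMeans(data$values[, bin, drop = FALSE])
    bbar <- .clip(bbar, 1 / (2 * n), 1 - 1 / (2 * n))
    lam[bin] <- qnorm(1 - bbar)
  }
  names(lam) <- colnames(data$values)
  lam
}

#' Rank-based latent correlation matrix
#'
#' Estimates the latent correlation matrix of one group under the (latent)
#' Gaussian copula model, dispatching per pair of column types:
#' continuous-continuous entries are \eqn{\sin(\pi\hat\tau/2)},
#' binary-binary entries invert the `F` bridge at the estimated cutoffs, and
#' binary-continuous entries invert the `H` bridge. All entries use the tau-a
#' statistic; the diagonal is exactly 1 and off-diagonals are clipped into
#' `[-1 + 1e-6, 1 - 1e-6]`.
#'
#' The estimate is not projected to positive semidefiniteness by default (the
#' direct difference estimator does not require it); set `psd = TRUE` to
#' project onto the nearest PSD matrix (eigenvalue truncation, diagonal
#' restored to 1) for downstream reuse.
#'
#' For binary-binary pairs the sample tau is computed from the
#' continuity-corrected 2x2 contingency table (one half added to each cell,
#' the standard small-sample correction for tetrachoric-type estimators).
#' Without it, a pair with an empty cell — routine when `n` is small and a
#' cutoff is far from the median — sits exactly on the boundary of the
#' attainable tau range and the inversion saturates at `+/-1`, polluting the
#' estimate with gross entries. The correction vanishes as `n` grows.
#'
#' @param data a [data_matrix()] (or plain matrix, typed with `"auto"`).
#' @param psd project the estimate to the nearest positive semidefinite
#'   correlation matrix (default `FALSE`).
#' @param continuity_correction use the corrected contingency table for
#'   binary-binary pairs (default `TRUE`).
#' @return a `latent_correlation` object: list with `matrix` (p x p),
#'   `source` (`"npn"`, `"binary"` or `"mixed"`), `cutoffs`.
#' @export
latent_correlation <- function(data, psd = FALSE,
                               continuity_correction = TRUE) {
  data <- as_data_matrix(data)
  x <- data$values
  n <- nrow(x)
  p <- ncol(x)
  bin <- data$types == "binary"
  tau <- cpp_kendall_tau_a_matrix(x)
  if (continuity_correction && sum(bin) >= 2L) {
    b <- x[, bin, drop = FALSE]
    n11 <- crossprod(b) + 0.5
    ones <- colSums(b)
    n10 <- outer(ones, rep(1, ncol(b))) - n11 + 1
    n01 <- t(n10)
    n00 <- n - outer(ones, ones, "+") + n11
    nn <- n + 2
    tau_bb <- 2 * (n00 * n11 - n01 * n10) / (nn * (nn - 1))
    tau[bin, bin] <- tau_bb
    diag(tau) <- 1
  }
  lam <- estimate_cutoffs(data)
  est <- matrix(1, p, p)
  ut <- which(upper.tri(tau), arr.ind = TRUE)
  j <- ut[, 1L]; k <- ut[, 2L]
  tv <- tau[ut]
  kind <- bin[j] + bin[k]  # 0 = cc, 1 = mixed, 2 = bb
  val <- numeric(length(tv))
  if (any(kind == 0)) val[kind == 0] <- npn_correlation_entry(tv[kind == 0])
  if (any(kind == 2)) {
    idx <- kind == 2
    val[idx] <- bridge_F_inverse(tv[idx], lam[j[idx]], lam[k[idx]])
  }
  if (any(kind == 1)) {
    idx <- kind == 1
    lam_b <- ifelse(bin[j[idx]], lam[j[idx]], lam[k[idx]])
    val[idx] <- bridge_H_inverse(tv[idx], lam_b)
  }
  val <- .clip(val, -1 + .CORR_EPS, 1 - .CORR_EPS)
  est[ut] <- val
  est[cbind(k, j)] <- val
  dimnames(est) <- list(colnames(x), colnames(x))
  if (psd) est <- nearest_psd_correlation(est)
  src <- if (!any(bin)) "npn" else if (all(bin)) "binary" else "mixed"
  structure(list(matrix = est, source = src, cutoffs = lam),
            class = "latent_correlation")
}

#' @export
print.latent_correlation <- function(x, ...) {
  cat(sprintf("latent_correlation (%s): %d x %d\n", x$source,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# eigenvalue truncation at a small floor, then rescale to unit diagonal
nearest_psd_correlation <- function(m, floor = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}

corr_matrix_of <- function(x) {
  if (inherits(x, "latent_correlation")) x$matrix else as.matrix(x)
}

#' Pearson correlation matrix of a data matrix
#'
#' Convenience wrapper used by the Pearson-based direct estimator (the
#' baseline that plugs sample correlations, rather than rank-based latent
#' correlations, into the difference estimator).
#'
#' @param data a [data_matrix()] or numeric matrix.
#' @return correlation matrix with unit diagonal.
#' @export
pearson_correlation <- function(data) {
  data <- as_data_matrix(data)
  m <- cor(data$values)
  # constant columns yield NA; treat them as uncorrelated
  m[!is.finite(m)] <- 0
  diag(m) <- 1
  m
}
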