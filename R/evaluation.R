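#' Support-recovery and estimation-error metrics
#'
#' Support sets are ordered off-diagonal pairs, so every undirected edge is
#' counted twice and the true-negative denominator is `p(p-1) - |S0|`:
#' \deqn{\mathrm{tpr} = \mathrm{tp}/|S_0|, \quad
#'       \mathrm{tnr} = \mathrm{tn}/(p(p-1) - |S_0|), \quad
#'       \mathrm{td} = \mathrm{tp}/|\hat S|.}
#' The true-discovery rate is undefined (reported `NA`) when the estimated
#' support is empty; it is excluded from averages rather than set to zero.
#' Estimation errors are the elementwise sup-norm and Frobenius norm of
#' `delta_hat - delta_true`.
#'
#' @param delta_true true difference matrix, or a `graph_pair` (its `delta0`
#'   and exact `support` are then used).
#' @param delta_hat estimated difference matrix or `difference_estimate`.
#' @param threshold support threshold applied to `delta_hat` (default
#'   numerical zero, `1e-5`).
#' @return list with `tp`, `tn`, `tpr`, `tnr`, `td`, `n_selected`,
#'   `linf_error`, `frobenius_error`.
#' @export
recovery_metrics <- function(delta_true, delta_hat, threshold = 1e-5) {
  if (inherits(delta_true, "graph_pair")) {
    s0 <- delta_true$support
    dt <- delta_true$delta0
  } else {
    dt <- as.matrix(delta_true)
    s0 <- abs(dt) > 1e-8
    diag(s0) <- FALSE
  }
  dh <- if (inherits(delta_hat, "difference_estimate")) delta_hat$delta_hat
        else as.matrix(delta_hat)
  if (!all(dim(dt) == dim(dh))) stop("dimension mismatch")
  sh <- threshold_support(dh, threshold)$support
  p <- nrow(dt)
  off <- !diag(TRUE, p)
  tp <- sum(s0 & sh)
  tn <- sum(!s0 & !sh & off)
  n_sel <- sum(sh)
  list(tp = tp, tn = tn,
       tpr = tp / sum(s0),
       tnr = tn / (p * (p - 1) - sum(s0)),
       td = if (n_sel > 0) tp / n_sel else NA_real_,
       n_selected = n_sel,
       linf_error = max(abs(dh - dt)),
       frobenius_error = sqrt(sum((dh - dt)^2)))
}

#' ROC points along a solution path
#'
#' One `(1 - tnr, tpr)` point per path estimate (support taken at numerical
#' zero, no additional thresholding), sorted by false-positive rate. The
#' recovery path need not be monotone in lambda; only the sorting is
#' guaranteed.
#'
#' @param path list of `difference_estimate`s from [solve_path()].
#' @param delta_true true difference matrix or `graph_pair`.
#' @return data frame with columns `lambda`, `fpr`, `tpr`.
#' @export
roc_curve <- function(path, delta_true) {
  pts <- lapply(path, function(f) {
    m <- recovery_metrics(delta_true, f, threshold = 1e-5)
    data.frame(lambda = f$lambda, fpr = 1 - m$tnr, tpr = m$tpr)
  })
  out <- do.call(rbind, pts)
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Area under an ROC curve
#'
#' Trapezoidal area of a [roc_curve()] result, with the curve anchored at
#' (0, 0) and extended horizontally to (1, max tpr).
#'
#' @param roc data frame from [roc_curve()].
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  x <- c(0, roc$fpr, 1)
  y <- c(0, roc$tpr, max(roc$tpr))
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# correlation estimates for one method name; latent-copula estimates with
# binary variables are PSD-projected (see latent_correlation docs)
method_correlations <- function(method, dat) {
  proj <- any(dat$group1$types == "binary")
  switch(method,
    "RDN" = list(latent_correlation(dat$group1, psd = proj)$matrix,
                 latent_correlation(dat$group2, psd = proj)$matrix),
    "DDN" = list(pearson_correlation(dat$group1),
                 pearson_correlation(dat$group2)),
    "ZP-DDN" = list(pearson_correlation(dat$latent1),
                    pearson_correlation(dat$latent2)),
    "ZR-RDN" = list(latent_correlation(dat$latent1)$matrix,
                    latent_correlation(dat$latent2)$matrix),
    stop("unknown method: ", method))
}

#' Replication study of support recovery and estimation error
#'
#' Repeats a simulation scenario, fits the requested estimators, tunes each
#' over one warm-started lambda path with the AIC under each requested loss,
#' and aggregates the true-discovery rate and elementwise sup-norm estimation
#' error. The ground-truth graph pair is built once from the master seed and
#' held fixed; replication `r` redraws the data under `seed + r`. Undefined
#' TD values (empty estimated support) are dropped from the averages.
#'
#' Methods: `"RDN"` (rank-based latent correlations of the observed data),
#' `"DDN"` (Pearson correlations of the observed data), `"ZP-DDN"` (Pearson
#' correlations of the latent draws; an oracle baseline) and `"ZR-RDN"`
#' (rank-based correlations of the latent draws).
#'
#' @param spec a [scenario_spec()].
#' @param methods subset of `c("RDN", "DDN", "ZP-DDN", "ZR-RDN")`.
#' @param reps number of replications.
#' @param seed master seed (defaults to the spec seed).
#' @param losses losses used for AIC tuning.
#' @param nlambda path length per fit.
#' @param threshold support threshold for the recovery metrics.
#' @param rho,max_iter,tol solver controls passed to [solve_path()]; the
#'   harness default `tol = 1e-3` reproduces the same supports and metrics as
#'   tighter solves at a fraction of the cost (see the package vignette).
#' @param lambda_min_ratio grid floor passed to [solve_path()]; the harness
#'   default 0.25 brackets every tuning optimum observed for these designs
#'   while avoiding the dense tail of the path, and a warning is raised if a
#'   selection ever lands on the smallest grid point.
#' @return list with `summary` (tidy data frame: method, p, scenario, loss,
#'   metric, mean, sd, reps) and `replicates` (per-replication records).
#' @export
run_replication_study <- function(spec, methods = "RDN", reps = 20L,
                                  seed = NULL, losses = c("Linf", "F"),
                                  nlambda = 12L, threshold = 1e-5,
                                  rho = 1, max_iter = 1500L, tol = 1e-3,
                                  lambda_min_ratio = 0.25) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(seed)) seed <- spec$seed
  pair <- make_differential_pair(spec$p, seed)
  rows <- list()
  for (r in seq_len(reps)) {
    dat <- make_scenario(spec, pair = pair, data_seed = seed + r)
    for (m in methods) {
      ss <- method_correlations(m, dat)
      path <- solve_path(ss[[1]], ss[[2]], nlambda = nlambda, rho = rho,
                         max_iter = max_iter, tol = tol,
                         lambda_min_ratio = lambda_min_ratio)
      for (loss in losses) {
        sel <- aic_select(path, ss[[1]], ss[[2]], spec$n1, spec$n2, loss)
        if (sel$index == length(path))
          warning("AIC selection at the smallest grid lambda; consider a ",
                  "lower lambda_min_ratio", call. = FALSE)
        met <- recovery_metrics(pair, sel$estimate, threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          rep = r, method = m, loss = loss, lambda = sel$lambda_selected,
          td = met$td, tpr = met$tpr, tnr = met$tnr,
          linf_error = met$linf_error,
          frobenius_error = met$frobenius_error,
          n_selected = met$n_selected)
      }
    }
  }
  reps_df <- do.call(rbind, rows)
  agg <- function(metric, value) {
    parts <- split(reps_df, list(reps_df$method, reps_df$loss), drop = TRUE)
    do.call(rbind, lapply(parts, function(d) {
      v <- value(d)
      v <- v[!is.na(v)]
      data.frame(method = d$method[1], p = spec$p, scenario = spec$scenario,
                 loss = d$loss[1], metric = metric,
                 mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                 reps = length(v))
    }))
  }
  summary <- rbind(agg("td_percent", function(d) 100 * d$td),
                   agg("linf_error", function(d) d$linf_error))
  rownames(summary) <- NULL
  list(summary = summary, replicates = reps_df)
}
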