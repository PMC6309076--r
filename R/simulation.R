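#' Hub-structured precision matrix
#'
#' Partitions the `p` variables into 5 equally sized consecutive blocks and
#' connects the smallest index of each block (the hub) to every other member
#' of its block. Nonzero off-diagonal entries are drawn uniformly from
#' `[-0.75, -0.25] U [0.25, 0.75]`; the diagonal is then shifted by
#' `0.2 + |lambda_min|` to guarantee positive definiteness.
#'
#' @param p dimension, divisible by 5.
#' @param seed integer seed.
#' @return list with `omega` (p x p positive-definite precision matrix),
#'   `edges` (two-column matrix of hub edges, j < k) and `hubs` (the 5 hub
#'   indices).
#' @export
generate_hub_precision <- function(p, seed = 1L) {
  if (p %% 5 != 0) stop("p must be divisible by 5")
  set.seed(seed)
  bs <- p / 5
  hubs <- seq(1L, p, by = bs)
  edges <- do.call(rbind, lapply(hubs, function(h) {
    members <- setdiff(seq(h, h + bs - 1L), h)
    cbind(h = rep(h, length(members)), members = members)
  }))
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  omega <- matrix(0, p, p)
  if (nrow(edges)) {
    vals <- runif(nrow(edges), 0.25, 0.75) * sample(c(-1, 1), nrow(edges),
                                                    replace = TRUE)
    omega[edges] <- vals
    omega[edges[, c(2, 1)]] <- vals
  }
  shift <- 0.2 + abs(min(eigen(omega, symmetric = TRUE,
                               only.values = TRUE)$values))
  diag(omega) <- diag(omega) + shift
  list(omega = omega, edges = edges, hubs = hubs)
}

#' Differential pair of hub networks
#'
#' Builds the ground truth for one simulated experiment: a hub precision
#' matrix for group 1, a group-2 precision matrix equal to it except that the
#' connections of two randomly chosen hub nodes change sign, both rescaled so
#' the implied covariance matrices are correlation matrices, and the true
#' difference `delta0` of the rescaled precision matrices. Because the sign
#' flip is a similarity transform by a diagonal sign matrix, group 2 inherits
#' positive definiteness; the diagonal shift is re-applied defensively if
#' numerical rescaling ever breaks it.
#'
#' @param p dimension, divisible by 5.
#' @param seed integer seed; one seed fixes the pair, so replications can
#'   share a single ground truth while redrawing data.
#' @return a `graph_pair`: list with `omega1`, `omega2`, `sigma1`, `sigma2`
#'   (correlation matrices), `delta0` (recomputed from the rescaled
#'   correlation matrices), `hub_ids` (the two flipped hubs), `support`
#'   (logical p x p matrix of nonzero off-diagonal `delta0` entries) and
#'   `edges`.
#' @export
make_differential_pair <- function(p, seed = 1L) {
  gen <- generate_hub_precision(p, seed)
  omega1 <- gen$omega
  # generate_hub_precision consumed the stream deterministically; the hub
  # selection continues from the same seeded stream
  flip <- sort(sample(gen$hubs, 2L))
  dsign <- rep(1, p)
  dsign[flip] <- -1
  omega2 <- omega1 * tcrossprod(dsign)
  ev <- min(eigen(omega2, symmetric = TRUE, only.values = TRUE)$values)
  shifted <- FALSE
  if (ev <= 1e-10) {
    diag(omega2) <- diag(omega2) + 0.2 + abs(ev)
    shifted <- TRUE
  }
  sigma1 <- stats::cov2cor(solve(omega1))
  sigma2 <- stats::cov2cor(solve(omega2))
  delta0 <- solve(sigma2) - solve(sigma1)
  thr <- 1e-6 * max(abs(delta0 - diag(diag(delta0))))
  support <- abs(delta0) > thr
  diag(support) <- FALSE
  structure(list(omega1 = omega1, omega2 = omega2, sigma1 = sigma1,
                 sigma2 = sigma2, delta0 = delta0, hub_ids = flip,
                 support = support, edges = gen$edges,
                 reshifted = shifted),
            class = "graph_pair")
}

#' @export
print.graph_pair <- function(x, ...) {
  cat(sprintf("graph_pair: p = %d, flipped hubs = (%d, %d), |support| = %d ordered pairs\n",
              nrow(x$delta0), x$hub_ids[1], x$hub_ids[2], sum(x$support)))
  invisible(x)
}

#' Sample from a (nonparanormal) Gaussian copula distribution
#'
#' Draws `n` observations of `Z ~ N(0, sigma)` and applies the monotone
#' marginal map `g` columnwise. `"gaussian_cdf"` uses `g = pnorm`, the
#' standard-normal CDF transform; `"identity"` returns the Gaussian draws.
#' Any strictly increasing `g` leaves Kendall's tau (and hence the rank-based
#' estimator) unchanged; the choice only affects moment-based baselines.
#'
#' @param sigma positive-definite correlation matrix.
#' @param n sample size.
#' @param transform `"gaussian_cdf"` or `"identity"`.
#' @param seed integer seed.
#' @return a [data_matrix()] of continuous variables with the latent Gaussian
#'   draws attached as attribute `"latent"`.
#' @export
sample_npn <- function(sigma, n, transform = c("gaussian_cdf", "identity"),
                       seed = 1L) {
  transform <- match.arg(transform)
  set.seed(seed)
  z <- MASS::mvrnorm(n, mu = rep(0, nrow(sigma)), Sigma = sigma)
  x <- if (transform == "gaussian_cdf") pnorm(z) else z
  colnames(x) <- colnames(z) <- paste0("V", seq_len(ncol(x)))
  out <- data_matrix(x, types = rep("continuous", ncol(x)))
  attr(out, "latent") <- z
  out
}

#' Dichotomize columns at cutoffs
#'
#' Replaces the indicated columns by the indicators `1{value > cutoff}`.
#' Cutoffs default to independent `Unif[0, 1]` draws (one per dichotomized
#' column), matching data generated on the copula scale.
#'
#' @param data a [data_matrix()] or matrix.
#' @param cutoffs per-column cutoffs for the dichotomized columns (recycled);
#'   drawn `Unif[0, 1]` under `seed` when `NULL`.
#' @param columns column indices to dichotomize (default: all).
#' @param seed seed used only when cutoffs are drawn.
#' @return a [data_matrix()] with those columns binary; the cutoffs used are
#'   attached as attribute `"cutoffs"`.
#' @export
dichotomize <- function(data, cutoffs = NULL, columns = NULL, seed = 1L) {
  data <- as_data_matrix(data)
  x <- data$values
  if (is.null(columns)) columns <- seq_len(ncol(x))
  if (is.null(cutoffs)) {
    set.seed(seed)
    cutoffs <- runif(length(columns))
  }
  cutoffs <- rep_len(cutoffs, length(columns))
  x[, columns] <- t(t(x[, columns, drop = FALSE]) > cutoffs) + 0
  types <- data$types
  types[columns] <- "binary"
  out <- data_matrix(x, types = types, group_label = data$group_label)
  attr(out, "cutoffs") <- setNames(cutoffs, colnames(x)[columns])
  out
}

#' Replace random entries by gross outliers
#'
#' Replaces `k` randomly chosen entries by `-value` or `+value` with equal
#' probability: by default `k` entries in the whole matrix (a handful of
#' gross cells, enough to poison moment-based estimators while leaving
#' rank-based ones intact); with `per_row = TRUE`, `k` entries in every
#' observation row. Used before dichotomization to emulate latent outliers
#' that misclassify the binarized values.
#'
#' @param latent a [data_matrix()] or matrix of latent continuous draws.
#' @param k number of entries replaced (per row when `per_row = TRUE`,
#'   `0 <= k <= p`; in total otherwise, `0 <= k <= n * p`).
#' @param seed integer seed.
#' @param value outlier magnitude (default 5).
#' @param per_row contaminate each row separately (default `FALSE`).
#' @return object of the same shape with outliers inserted.
#' @export
contaminate <- function(latent, k, seed = 1L, value = 5, per_row = FALSE) {
  is_dm <- inherits(latent, "data_matrix")
  x <- if (is_dm) latent$values else as.matrix(latent)
  kmax <- if (per_row) ncol(x) else length(x)
  if (k < 0 || k > kmax)
    stop(if (per_row) "k must lie in [0, p]" else "k must lie in [0, n*p]")
  if (k > 0) {
    set.seed(seed)
    if (per_row) {
      for (i in seq_len(nrow(x))) {
        idx <- sample.int(ncol(x), k)
        x[i, idx] <- value * sample(c(-1, 1), k, replace = TRUE)
      }
    } else {
      idx <- sample.int(length(x), k)
      x[idx] <- value * sample(c(-1, 1), k, replace = TRUE)
    }
  }
  if (is_dm) data_matrix(x, types = latent$types,
                         group_label = latent$group_label)
  else x
}

#' Simulation scenario specification
#'
#' Configuration of one synthetic experiment. `"copula"` draws continuous
#' Gaussian-copula data for both groups; `"s1_binary"` dichotomizes every
#' copula-transformed column at shared `Unif[0, 1]` cutoffs; `"s2_mixed"`
#' keeps the first half of the columns continuous and dichotomizes the second
#' half; `"s3_outlier"` draws plain Gaussian latent data, inserts
#' `contamination_count` gross outliers (+/-5) per observation, then
#' dichotomizes every column.
#'
#' @param p dimension, divisible by 5.
#' @param n1,n2 group sample sizes.
#' @param scenario one of `"copula"`, `"s1_binary"`, `"s2_mixed"`,
#'   `"s3_outlier"` (aliases `"1"`, `"2"`, `"3"` accepted).
#' @param transform marginal transform for copula sampling.
#' @param contamination_count outliers per row in `"s3_outlier"`.
#' @param seed master seed; fixes the ground-truth graph pair.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(p, n1 = 100L, n2 = 100L,
                          scenario = c("copula", "s1_binary", "s2_mixed",
                                       "s3_outlier"),
                          transform = c("gaussian_cdf", "identity"),
                          contamination_count = 10L, seed = 1L) {
  scenario <- as.character(scenario[1L])
  scenario <- switch(scenario, "1" = "s1_binary", "2" = "s2_mixed",
                     "3" = "s3_outlier", scenario)
  scenario <- match.arg(scenario, c("copula", "s1_binary", "s2_mixed",
                                    "s3_outlier"))
  transform <- match.arg(transform)
  if (p %% 5 != 0) stop("p must be divisible by 5")
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (contamination_count > p) stop("contamination_count must be <= p")
  structure(list(p = as.integer(p), n1 = as.integer(n1), n2 = as.integer(n2),
                 scenario = scenario, transform = transform,
                 contamination_count = as.integer(contamination_count),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate one scenario data set
#'
#' Draws both groups' observed data plus the ground truth. The graph pair is
#' derived from the master seed of the spec (or passed in, so replications
#' share one fixed ground truth while redrawing data under `data_seed`); one
#' cutoff vector is shared by the two groups.
#'
#' @param spec a [scenario_spec()].
#' @param pair optional pre-built [make_differential_pair()] ground truth.
#' @param data_seed seed for the data draw (defaults to the spec seed).
#' @return list with `group1`, `group2` ([data_matrix()] objects), `latent1`,
#'   `latent2` (the latent Gaussian draws as seen by oracle baselines:
#'   contaminated in `"s3_outlier"`), `pair`, `cutoffs` and `spec`.
#' @export
make_scenario <- function(spec, pair = NULL, data_seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(pair)) pair <- make_differential_pair(spec$p, spec$seed)
  if (is.null(data_seed)) data_seed <- spec$seed
  p <- spec$p
  transform <- if (spec$scenario == "s3_outlier") "identity" else spec$transform
  g1 <- sample_npn(pair$sigma1, spec$n1, transform, seed = data_seed)
  g2 <- sample_npn(pair$sigma2, spec$n2, transform, seed = data_seed + 500000L)
  z1 <- attr(g1, "latent")
  z2 <- attr(g2, "latent")
  set.seed(data_seed + 1000000L)
  cutoffs <- runif(p)
  if (spec$scenario == "s3_outlier") {
    g1 <- contaminate(g1, spec$contamination_count, seed = data_seed + 1500000L,
                      per_row = TRUE)
    g2 <- contaminate(g2, spec$contamination_count, seed = data_seed + 2000000L,
                      per_row = TRUE)
    z1 <- g1$values
    z2 <- g2$values
  }
  # cutoffs are C ~ Unif[0, 1] on the latent-Gaussian scale (the scale the
  # outlier scenario prints); for copula-transformed observations the
  # equivalent observed-scale cutoff is g(C)
  obs_cut <- if (transform == "gaussian_cdf") pnorm(cutoffs) else cutoffs
  obs <- switch(spec$scenario,
    copula = list(g1, g2),
    s1_binary = ,
    s3_outlier = list(dichotomize(g1, obs_cut), dichotomize(g2, obs_cut)),
    s2_mixed = {
      cols <- seq(p / 2 + 1L, p)
      list(dichotomize(g1, obs_cut[cols], cols),
           dichotomize(g2, obs_cut[cols], cols))
    })
  obs[[1]]$group_label <- "group1"
  obs[[2]]$group_label <- "group2"
  list(group1 = obs[[1]], group2 = obs[[2]], latent1 = z1, latent2 = z2,
       pair = pair, cutoffs = cutoffs, spec = spec)
}
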