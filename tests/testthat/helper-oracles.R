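# Independent oracles used across the suite.

# Brute-force tau-a by explicit enumeration of all pairs.
tau_brute <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
  2 * s / (n * (n - 1))
}

# Bivariate normal CDF by 1-D quadrature (conditioning on the second
# coordinate), independent of the package's closed-form algorithm.
pbvn_quad <- function(u, v, t) {
  stats::integrate(function(y) dnorm(y) * pnorm((u - t * y) / sqrt(1 - t^2)),
                   -Inf, v, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# Explicitly formed quadratic operator A = Gamma' (s1 (x) s2) Gamma via the
# literal Kronecker product and duplication matrix; O(p^4) memory, tiny p only.
explicit_operator <- function(s1, s2) {
  p <- nrow(s1)
  d <- p * (p + 1) / 2
  gamma <- matrix(0, p^2, d)
  m <- 0
  for (k in seq_len(p))
    for (j in seq_len(k)) {
      m <- m + 1
      gamma[(k - 1) * p + j, m] <- 1
      gamma[(j - 1) * p + k, m] <- 1
    }
  list(A = t(gamma) %*% (s1 %x% s2) %*% gamma,
       cvec = t(gamma) %*% as.vector(s1 - s2),
       gamma = gamma)
}

# LP oracle for min |theta|_1 subject to the split box constraints, solved by
# an external simplex/IPM implementation (scipy HiGHS) through the system
# python -- fully independent of the package's ADMM.
lp_difference_oracle <- function(s1, s2, lambda) {
  ex <- explicit_operator(s1, s2)
  p <- nrow(s1)
  vz <- sym_vectorizer(p)
  b <- ifelse(vz$diag, lambda / 2, lambda)
  dir <- tempfile()
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  jsonlite::write_json(
    list(A = ex$A, cvec = as.numeric(ex$cvec), b = as.numeric(b)),
    file.path(dir, "in.json"), digits = NA, matrix = "rowmajor")
  script <- file.path(dir, "lp.py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("d = json.load(open(%s))", deparse(file.path(dir, "in.json"))),
    "A = np.array(d['A']); c = np.array(d['cvec']); b = np.array(d['b'])",
    "n = A.shape[1]",
    "# theta = xp - xm, xp, xm >= 0; |A theta - c| <= b (per-coordinate)",
    "Aub = np.vstack([np.hstack([A, -A]), np.hstack([-A, A])])",
    "bub = np.concatenate([b + c, b - c])",
    "res = linprog(np.ones(2 * n), A_ub=Aub, b_ub=bub, method='highs')",
    "theta = res.x[:n] - res.x[n:]",
    sprintf("json.dump({'theta': theta.tolist(), 'status': int(res.status), 'obj': float(res.fun)}, open(%s, 'w'))",
            deparse(file.path(dir, "out.json")))),
    script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  out <- jsonlite::read_json(file.path(dir, "out.json"), simplifyVector = TRUE)
  stopifnot(out$status == 0)
  out
}

# small random correlation-like symmetric PD matrix with unit diagonal
random_corr <- function(p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(3 * p * p), 3 * p, p)
  stats::cov2cor(crossprod(x) / (3 * p))
}
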