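test_that("bivariate normal CDF matches closed forms and a quadrature oracle", {
  # independence factorization at t = 0
  u <- c(-1.3, 0, 0.7)
  v <- c(0.4, -0.2, 2.1)
  expect_equal(pbvn(u, v, 0), pnorm(u) * pnorm(v), tolerance = 1e-12)
  # orthant closed form at zero thresholds
  for (t in c(-0.8, -0.3, 0.5, 0.9))
    expect_equal(pbvn(0, 0, t), 1 / 4 + asin(t) / (2 * pi), tolerance = 1e-12)
  # general values against numerical integration
  set.seed(42)
  for (i in 1:20) {
    u <- rnorm(1); v <- rnorm(1); t <- runif(1, -0.99, 0.99)
    expect_equal(pbvn(u, v, t), pbvn_quad(u, v, t), tolerance = 1e-9)
  }
  # symmetry in the arguments
  expect_equal(pbvn(0.3, -1.2, 0.6), pbvn(-1.2, 0.3, 0.6), tolerance = 1e-14)
})

test_that("kendall_tau is the tau-a statistic with ties contributing zero", {
  expect_identical(kendall_tau(1:3, 1:3), 1)
  expect_identical(kendall_tau(1:3, 3:1), -1)
  # brute-force enumeration over all 6 pairs of a tied binary example
  x <- c(0, 0, 1, 1); y <- c(0, 1, 0, 1)
  expect_equal(kendall_tau(x, y), tau_brute(x, y))
  set.seed(3)
  for (i in 1:10) {
    a <- sample(0:2, 12, replace = TRUE)
    b <- rnorm(12)
    expect_equal(kendall_tau(a, b), tau_brute(a, b))
  }
  # agreement with the classical estimator when there are no ties
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(kendall_tau(a, b), cor(a, b, method = "kendall"),
               tolerance = 1e-12)
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_error(kendall_tau(1, 1), "at least 2")
})

test_that("npn correlation entry is sin(pi tau / 2)", {
  expect_identical(npn_correlation_entry(0), 0)
  expect_identical(npn_correlation_entry(1), 1)
  expect_equal(npn_correlation_entry(1 / 3), 0.5, tolerance = 1e-12)
  expect_error(npn_correlation_entry(1.2), "\\[-1, 1\\]")
})

test_that("bridge functions match closed forms and the quadrature oracle", {
  # t = 0: dichotomized coordinates are independent
  expect_equal(bridge_F(0, 0.7, -1.1), 0, tolerance = 1e-14)
  expect_equal(bridge_H(0, 0.4), 0, tolerance = 1e-14)
  # orthant closed form at zero cutoffs
  expect_equal(bridge_F(0.5, 0, 0), asin(0.5) / pi, tolerance = 1e-12)
  # mixed bridge at t -> 1, zero cutoff: 2 asin(1/sqrt 2)/pi = 1/2
  expect_equal(bridge_H(1 - 1e-12, 0), 0.5, tolerance = 1e-6)
  # general values against numerical integration
  expect_equal(bridge_F(0.3, 0.5, -0.2),
               2 * (pbvn_quad(0.5, -0.2, 0.3) - pnorm(0.5) * pnorm(-0.2)),
               tolerance = 1e-9)
  expect_equal(bridge_H(0.4, 0.8),
               4 * pbvn_quad(0.8, 0, 0.4 / sqrt(2)) - 2 * pnorm(0.8),
               tolerance = 1e-9)
  expect_error(bridge_F(1, 0, 0), "strictly inside")
  expect_error(bridge_H(-1, 0), "strictly inside")
})

test_that("bridges are increasing in t over the working range", {
  # near |t| = 1 with extreme cutoffs the population tau saturates at its
  # attainable limit and increments fall below double precision; assert no
  # real decrease anywhere plus strict increase where increments resolve
  tg <- seq(-0.999, 0.999, length.out = 201)
  strict <- abs(tg) <= 0.85
  strict <- strict[-length(strict)]
  for (lam in c(-2, -0.5, 0, 1.3, 2)) {
    dh <- diff(bridge_H(tg, lam))
    expect_true(all(dh > -1e-15))
    expect_true(all(dh[strict] > 0))
    for (lam2 in c(-2, 0, 2)) {
      df <- diff(bridge_F(tg, lam, lam2))
      expect_true(all(df > -1e-15))
      expect_true(all(df[strict] > 0))
    }
  }
})

test_that("bridge inversion round-trips to 1e-6 and clips out-of-range tau", {
  tg <- seq(-0.9, 0.9, by = 0.1)
  for (lam in c(-1.5, 0, 0.8)) {
    for (lam2 in c(-0.7, 0.3))
      expect_equal(bridge_F_inverse(bridge_F(tg, lam, lam2), lam, lam2), tg,
                   tolerance = 1e-6)
    expect_equal(bridge_H_inverse(bridge_H(tg, lam), lam), tg,
                 tolerance = 1e-6)
  }
  expect_equal(bridge_F_inverse(0, 0.4, -0.9), 0, tolerance = 1e-8)
  expect_equal(bridge_H_inverse(0, 1.1), 0, tolerance = 1e-8)
  # inverse of the closed-form example
  expect_equal(bridge_F_inverse(asin(0.5) / pi, 0, 0), 0.5, tolerance = 1e-6)
  # attainable range of H at lam = 0 is (-1/2, 1/2): tau beyond it clips
  expect_equal(bridge_H_inverse(0.5, 0), 1 - 1e-6, tolerance = 2e-6)
  expect_equal(bridge_H_inverse(-0.9, 0), -1 + 1e-6, tolerance = 2e-6)
})

test_that("cutoff estimation applies the normal quantile with mean clamping", {
  x <- cbind(b1 = rep(c(0, 1), each = 10), c1 = rnorm(20))
  dm <- data_matrix(x, types = c("binary", "continuous"))
  lam <- estimate_cutoffs(dm)
  expect_equal(unname(lam["b1"]), 0)          # mean 1/2 -> qnorm(1/2)
  expect_true(is.na(lam["c1"]))
  # mean 1 - pnorm(1) gives cutoff 1
  n <- 10000
  x2 <- cbind(b = c(rep(1, round(n * (1 - pnorm(1)))),
                    rep(0, n - round(n * (1 - pnorm(1))))))
  expect_equal(unname(estimate_cutoffs(data_matrix(x2))["b"]), 1,
               tolerance = 1e-3)
  # constant column: mean clamped to 1 - 1/(2n)
  x3 <- cbind(b = rep(1, 50), c = rnorm(50))
  expect_equal(unname(estimate_cutoffs(data_matrix(x3, c("binary", "continuous")))["b"]),
               qnorm(1 / 100), tolerance = 1e-12)
})

test_that("latent correlation dispatches by pair type and composes the bridges", {
  set.seed(11)
  # all-continuous: entrywise sin(pi tau / 2)
  x <- matrix(rnorm(60), 20, 3)
  lc <- latent_correlation(data_matrix(x, "continuous"))
  tau <- ldnet:::cpp_kendall_tau_a_matrix(x)
  expect_equal(lc$matrix[upper.tri(tau)],
               sin(pi * tau[upper.tri(tau)] / 2), tolerance = 1e-12)
  expect_identical(diag(lc$matrix), setNames(rep(1, 3), colnames(lc$matrix)))
  expect_identical(lc$source, "npn")

  # toy binary matrix: end-to-end against hand-composed oracle pieces
  b <- cbind(a = c(0, 1, 1, 0, 1, 0), b = c(1, 1, 0, 0, 1, 0))
  lcb <- latent_correlation(data_matrix(b), continuity_correction = FALSE)
  tau_ab <- tau_brute(b[, 1], b[, 2])
  lam <- qnorm(1 - pmin(pmax(colMeans(b), 1 / 12), 11 / 12))
  expect_equal(lcb$matrix[1, 2],
               bridge_F_inverse(tau_ab, lam[1], lam[2]), tolerance = 1e-8)
  expect_identical(lcb$source, "binary")
  # with the continuity correction: tau from the half-count-corrected table
  n11 <- sum(b[, 1] & b[, 2]) + 0.5
  n10 <- sum(b[, 1] & !b[, 2]) + 0.5
  n01 <- sum(!b[, 1] & b[, 2]) + 0.5
  n00 <- sum(!b[, 1] & !b[, 2]) + 0.5
  tau_cc <- 2 * (n00 * n11 - n01 * n10) / (8 * 7)
  lcc <- latent_correlation(data_matrix(b))
  expect_equal(lcc$matrix[1, 2],
               bridge_F_inverse(tau_cc, lam[1], lam[2]), tolerance = 1e-8)

  # mixed pair: H-inverse of tau at the binary column's cutoff
  m <- cbind(bin = c(0, 1, 0, 1, 1, 0, 1, 0), cont = rnorm(8))
  lcm <- latent_correlation(data_matrix(m))
  expect_equal(lcm$matrix[1, 2],
               bridge_H_inverse(kendall_tau(m[, 1], m[, 2]),
                                estimate_cutoffs(data_matrix(m))["bin"]),
               tolerance = 1e-8)
  expect_identical(lcm$source, "mixed")
  expect_true(isSymmetric(lcm$matrix))
})

test_that("latent correlation recovers the truth as n grows", {
  sig <- matrix(0.6, 5, 5) ^ abs(outer(1:5, 1:5, "-"))
  errs <- sapply(c(200, 2000), function(n) {
    dat <- sample_npn(sig, n, "gaussian_cdf", seed = 99)
    max(abs(latent_correlation(dat)$matrix - sig))
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.1)
  # npn estimate agrees with Pearson correlation for truly Gaussian data
  dat <- sample_npn(sig, 2000, "identity", seed = 7)
  expect_lt(max(abs(latent_correlation(dat)$matrix - cor(dat$values))), 0.05)
})

test_that("mixed and binary estimators recover a known latent correlation", {
  sig <- matrix(0.5, 4, 4); diag(sig) <- 1
  z <- sample_npn(sig, 4000, "gaussian_cdf", seed = 123)
  bin <- dichotomize(z, columns = 1:2, cutoffs = c(0.35, 0.6))
  est <- latent_correlation(bin)$matrix
  expect_lt(max(abs(est - sig)), 0.1)
})

test_that("PSD projection toggle returns a PSD correlation matrix", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- -0.9  # indefinite
  proj <- ldnet:::nearest_psd_correlation(m)
  ev <- eigen(proj, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  expect_equal(diag(proj), rep(1, 3))
})
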