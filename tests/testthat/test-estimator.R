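test_that("symmetric vectorizer round-trips and indexes the upper triangle", {
  vz <- sym_vectorizer(4)
  expect_identical(vz$d, 10L)
  set.seed(1)
  m <- matrix(rnorm(16), 4)
  m <- m + t(m)
  expect_equal(theta_to_matrix(matrix_to_theta(m, vz), vz), m)
  th <- rnorm(10)
  expect_equal(matrix_to_theta(theta_to_matrix(th, vz), vz), th)
})

test_that("quadratic operator equals the explicit Kronecker form", {
  # identity inputs: Gamma' Gamma doubles off-diagonal coordinates
  vz <- sym_vectorizer(3)
  th <- numeric(vz$d)
  th[which(vz$rows == 1 & vz$cols == 2)] <- 1
  out <- apply_quadratic_operator(vz, diag(3), diag(3), th)
  expect_equal(out, c(0, 2, 0, 0, 0, 0))

  for (p in 2:6) {
    vz <- sym_vectorizer(p)
    s1 <- random_corr(p, seed = 100 + p)
    s2 <- random_corr(p, seed = 200 + p)
    ex <- explicit_operator(s1, s2)
    set.seed(p)
    for (i in 1:3) {
      th <- rnorm(vz$d)
      expect_equal(apply_quadratic_operator(vz, s1, s2, th),
                   as.numeric(ex$A %*% th), tolerance = 1e-12)
    }
    # linearity
    t1 <- rnorm(vz$d); t2 <- rnorm(vz$d)
    expect_equal(apply_quadratic_operator(vz, s1, s2, 2 * t1 - 3 * t2),
                 2 * apply_quadratic_operator(vz, s1, s2, t1) -
                   3 * apply_quadratic_operator(vz, s1, s2, t2),
                 tolerance = 1e-12)
    # the target vector matches Gamma' vec(s1 - s2)
    expect_equal(as.numeric(ldnet:::cpp_gamma_t_vec(s1 - s2)),
                 as.numeric(ex$cvec), tolerance = 1e-14)
  }
})

test_that("operator norm matches a dense spectral norm", {
  for (p in c(3, 5)) {
    s1 <- random_corr(p, seed = p)
    s2 <- random_corr(p, seed = 10 + p)
    ex <- explicit_operator(s1, s2)
    expect_equal(ldnet:::cpp_operator_norm(s1, s2),
                 max(abs(eigen(ex$A, symmetric = TRUE)$values)),
                 tolerance = 1e-7)
  }
})

test_that("project_z clips off-diagonal and diagonal coordinates separately", {
  vz <- sym_vectorizer(2)  # coords: (1,1), (1,2), (2,2)
  lam <- 0.4
  expect_equal(project_z(c(0.1, 0.1, -0.1), lam, vz), c(0.1, 0.1, -0.1))
  expect_equal(project_z(c(0, 3 * lam, 0), lam, vz), c(0, lam, 0))
  expect_equal(project_z(c(-lam, 0, lam), lam, vz), c(-lam / 2, 0, lam / 2))
  expect_error(project_z(c(0, 0, 0), -1, vz), "nonnegative")
})

test_that("theta subproblem solves the scalar soft-threshold closed form", {
  # p = 1: A = a^2 for s1 = s2 = (a); min (b - a^2 theta)^2 + (2/rho)|theta|
  a <- 1.3; rho <- 2; b <- 0.7
  fit <- update_theta(matrix(a), matrix(a), v = b, rho = rho)
  aa <- a^2
  closed <- sign(b / aa) * max(abs(b / aa) - (1 / rho) / aa^2, 0)
  expect_equal(fit$theta, closed, tolerance = 1e-10)
  # zero target stays at zero
  expect_identical(update_theta(matrix(a), matrix(a), v = 0, rho = 1)$theta, 0)
})

test_that("theta subproblem is monotone in objective and reaches the optimum", {
  p <- 4
  s1 <- random_corr(p, seed = 5); s2 <- random_corr(p, seed = 6)
  vz <- sym_vectorizer(p)
  set.seed(2)
  v <- rnorm(vz$d)
  rho <- 1.5
  obj <- function(th) {
    r <- v - apply_quadratic_operator(vz, s1, s2, th)
    sum(r^2) + (2 / rho) * sum(abs(th))
  }
  # objective across increasing iteration budgets never increases
  objs <- sapply(c(1, 2, 5, 20, 200), function(im)
    obj(update_theta(s1, s2, v, rho, inner_max = im)$theta))
  expect_true(all(diff(objs) <= 1e-10))
  # compare with a long proximal-gradient reference solve
  ex <- explicit_operator(s1, s2)
  L <- 2 * max(abs(eigen(ex$A, symmetric = TRUE)$values))^2
  th <- numeric(vz$d)
  for (i in 1:20000) {
    g <- 2 * as.numeric(ex$A %*% (as.numeric(ex$A %*% th) - v))
    th <- th - g / L
    th <- sign(th) * pmax(abs(th) - (2 / rho) / L, 0)
  }
  expect_equal(obj(update_theta(s1, s2, v, rho, inner_max = 500)$theta),
               obj(th), tolerance = 1e-7)
})

test_that("identical groups give a zero difference estimate at any lambda", {
  s <- random_corr(6, seed = 9)
  for (lam in c(0, 0.3, 2)) {
    fit <- admm_solve(s, s, lam)
    expect_true(fit$converged)
    expect_equal(fit$delta_hat, matrix(0, 6, 6))
  }
})

test_that("ADMM agrees with the LP oracle on small seeded instances", {
  for (p in 2:4) {
    s1 <- random_corr(p, seed = 30 + p)
    s2 <- random_corr(p, seed = 40 + p)
    lam <- 0.3 * lambda_max(s1, s2)
    fit <- admm_solve(s1, s2, lam, max_iter = 10000L, tol = 1e-7)
    lp <- lp_difference_oracle(s1, s2, lam)
    expect_true(fit$converged)
    expect_equal(fit$theta, lp$theta, tolerance = 1e-4)
  }
})

test_that("feasibility holds at convergence within the stated slack", {
  p <- 8
  s1 <- random_corr(p, seed = 71); s2 <- random_corr(p, seed = 72)
  lam <- 0.25 * lambda_max(s1, s2)
  tol <- 1e-5
  fit <- admm_solve(s1, s2, lam, tol = tol)
  expect_true(fit$converged)
  vz <- sym_vectorizer(p)
  resid <- apply_quadratic_operator(vz, s1, s2, fit$theta) -
    as.numeric(ldnet:::cpp_gamma_t_vec(s1 - s2))
  expect_lte(max(abs(resid[!vz$diag])), lam + 1.1 * tol)
  expect_lte(max(abs(resid[vz$diag])), lam / 2 + 1.1 * tol)
})

test_that("solution path is warm-start consistent and ends at zero", {
  p <- 10
  s1 <- random_corr(p, seed = 81); s2 <- random_corr(p, seed = 82)
  grid <- lambda_grid(s1, s2, nlambda = 8, lambda_min_ratio = 0.1)
  path <- solve_path(s1, s2, lambdas = grid)
  expect_length(path, 8)
  # lambda at or above lambda_max admits theta = 0
  expect_equal(admm_solve(s1, s2, lambda_max(s1, s2))$delta_hat,
               matrix(0, p, p))
  expect_equal(admm_solve(s1, s2, 1.5 * lambda_max(s1, s2))$delta_hat,
               matrix(0, p, p))
  # warm-started and cold-started solutions agree
  cold <- admm_solve(s1, s2, grid[5])
  expect_equal(path[[5]]$theta, cold$theta, tolerance = 1e-4)
  # singleton grid equals a single solve
  single <- solve_path(s1, s2, lambdas = grid[3])
  expect_equal(single[[1]]$theta, admm_solve(s1, s2, grid[3])$theta,
               tolerance = 1e-6)
  # l1 norm is non-increasing in lambda
  l1 <- vapply(path, function(f) sum(abs(f$theta)), numeric(1))
  expect_true(all(diff(l1) >= -1e-6))
})

test_that("threshold_support keeps signed entries above the threshold", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2)
  out <- threshold_support(m, 0.4)
  expect_equal(sum(out$support), 2)  # one undirected edge, both orientations
  expect_equal(out$signs[1, 2], 1)
  expect_equal(threshold_support(m, 0.6)$delta, matrix(0, 2, 2))
  full <- threshold_support(m, 0)
  expect_equal(sum(full$support), 2)
  expect_error(threshold_support(m, -0.1), "nonnegative")
})
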