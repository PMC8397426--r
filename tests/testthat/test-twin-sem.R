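test_that("expected covariance blocks follow the twin model algebra", {
  # E only: no cross-twin covariance for either zygosity
  p0 <- ace_paths(a = 0, c = 0, e = diag(3))
  for (z in c("MZ", "DZ")) {
    S <- expected_covariance(p0, z)
    expect_equal(S[1:3, 4:6], matrix(0, 3, 3), ignore_attr = TRUE)
  }
  # C = 0, MZ: cross block equals A exactly
  pa <- ace_paths(a = lt_vec_to_mat(c(1, .5, .2, .8, .1, .6), 3),
                  c = 0, e = diag(3))
  S <- expected_covariance(pa, "MZ")
  expect_equal(S[1:3, 4:6], tcrossprod(pa$a), ignore_attr = TRUE)
  # DZ halves the genetic block
  S_dz <- expected_covariance(pa, "DZ")
  expect_equal(S_dz[1:3, 4:6], 0.5 * tcrossprod(pa$a),
               ignore_attr = TRUE)
  expect_error(expected_covariance(
    ace_paths(a = matrix(c(Inf, 0, 0, 0, 0, 0, 0, 0, 0), 3), n_visits = 3)),
    "finite")
})

test_that("expected covariance matches a latent-variable simulation oracle", {
  set.seed(20)
  p <- ace_paths(a = lt_vec_to_mat(runif(6, 0.1, 0.6), 3),
                 c = lt_vec_to_mat(runif(6, 0.1, 0.6), 3),
                 e = lt_vec_to_mat(c(runif(1, 0.3, 0.6), runif(2, 0, .3),
                                     runif(1, 0.3, 0.6), runif(1, 0, .3),
                                     runif(1, 0.3, 0.6)), 3))
  ndraw <- 1e6
  for (z in c("MZ", "DZ")) {
    rho <- if (z == "MZ") 1 else 0.5
    zA1 <- matrix(rnorm(3 * ndraw), 3)
    zA2 <- rho * zA1 + sqrt(1 - rho^2) * matrix(rnorm(3 * ndraw), 3)
    zC <- matrix(rnorm(3 * ndraw), 3)
    y1 <- t(p$a %*% zA1 + p$c %*% zC + p$e %*% matrix(rnorm(3 * ndraw), 3))
    y2 <- t(p$a %*% zA2 + p$c %*% zC + p$e %*% matrix(rnorm(3 * ndraw), 3))
    emp <- cov(cbind(y1, y2))
    expect_lt(max(abs(emp - expected_covariance(p, z))), 0.01)
  }
})

test_that("expected covariance is symmetric PSD for random valid paths", {
  set.seed(21)
  for (r in 1:25) {
    p <- ace_paths(a = lt_vec_to_mat(rnorm(6, 0, 0.5), 3),
                   c = lt_vec_to_mat(rnorm(6, 0, 0.5), 3),
                   e = lt_vec_to_mat(rnorm(6, 0, 0.5), 3))
    for (z in c("MZ", "DZ")) {
      S <- expected_covariance(p, z)
      expect_equal(S, t(S))
      expect_gt(min(eigen(S, symmetric = TRUE,
                          only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("standardized squared coefficients: identity case and manual 2-visit example", {
  p1 <- ace_paths(a = diag(3), c = 0, e = 0 * diag(3))
  # zero e is singular for fitting but standardization is pure algebra
  std <- standardize_paths(p1)
  expect_equal(diag(std$A), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(std$C == 0) && all(std$E == 0))

  # hand-computed: a = [[1,0],[.5,1]], c = 0, e = I
  p2 <- ace_paths(a = matrix(c(1, 0.5, 0, 1), 2), c = 0, e = diag(2),
                  n_visits = 2)
  std2 <- standardize_paths(p2)
  expect_equal(std2$A[2, 1], 0.25 / 2.25)
  expect_equal(std2$A[2, 2], 1 / 2.25)
  expect_equal(std2$E[2, 2], 1 / 2.25)
  expect_equal(std2$visit_totals, c(1, 1), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("per-visit standardized proportions always sum to one", {
  set.seed(22)
  for (r in 1:10) {
    p <- ace_paths(a = lt_vec_to_mat(rnorm(6, 0.3, 0.2), 3),
                   c = lt_vec_to_mat(rnorm(6, 0.3, 0.2), 3),
                   e = lt_vec_to_mat(c(0.6, rnorm(1, 0, .2), rnorm(1, 0, .2),
                                       0.6, rnorm(1, 0, .2), 0.6), 3))
    std <- standardize_paths(p)
    expect_equal(std$visit_totals, rep(1, 3), ignore_attr = TRUE,
                 tolerance = 1e-6)
  }
})

test_that("an E-only generator is recovered with near-zero A and C", {
  p <- ace_paths(a = 0, c = 0, e = t(chol(0.4 * diag(3) + 0.3)))
  pr <- simulate_twin_pairs(p, 2000, 2000, seed = 23)
  fit <- fit_cholesky_ace(pr, restarts = 2)
  std <- standardize_paths(fit)
  expect_true(all(rowSums(std$A) < 0.05))
  expect_true(all(rowSums(std$C) < 0.05))
})

test_that("generating visit-1 proportions A=0.4 C=0.3 E=0.3 are recovered", {
  gen <- common_factor_paths(0.3, 0.2, 0.1, 0.4)
  # rescale visit-1 split: use explicit paths with known proportions
  gen <- ace_paths(a = sqrt(0.4) * lt_vec_to_mat(c(1, .7, .6, .5, .3, .5), 3),
                   c = sqrt(0.3) * lt_vec_to_mat(c(1, .6, .5, .6, .2, .6), 3),
                   e = sqrt(0.3) * lt_vec_to_mat(c(1, .3, .2, .9, .3, .9), 3))
  pr <- simulate_twin_pairs(gen, 2000, 2000, seed = 24)
  fit <- fit_cholesky_ace(pr, restarts = 2)
  std <- standardize_paths(fit)
  expect_lt(abs(std$A[1, 1] - 0.4), 0.05)
  expect_lt(abs(std$C[1, 1] - 0.3), 0.05)
  expect_lt(abs(std$E[1, 1] - 0.3), 0.05)
})

test_that("the ML solution is at least as good as the truth, and nested under the saturated model", {
  gen <- ace_paths(a = sqrt(0.4) * diag(3), c = sqrt(0.3) * diag(3),
                   e = sqrt(0.3) * diag(3))
  fac_true <- lt_mat_to_vec(gen$a)
  for (s in 1:3) {
    pr <- simulate_twin_pairs(gen, 150, 150, seed = 24 + s)
    fit <- fit_cholesky_ace(pr, restarts = 2)
    fac <- fit$factory
    th_true <- c(lt_mat_to_vec(gen$a), lt_mat_to_vec(gen$c),
                 lt_mat_to_vec(gen$e), rep(0, 3))
    expect_lte(fit$minus2LL, fac$obj(th_true) + 1e-6)
    expect_lte(fit_saturated(pr)$minus2LL, fit$minus2LL + 1e-6)
  }
})

test_that("the fit is invariant to swapping twin order within pairs", {
  gen <- ace_paths(a = sqrt(0.4) * diag(3), c = sqrt(0.3) * diag(3),
                   e = sqrt(0.3) * diag(3))
  pr <- simulate_twin_pairs(gen, 120, 80, seed = 30)
  f1 <- fit_cholesky_ace(pr, restarts = 2)
  pr2 <- pr
  pr2$y <- pr$y[, c(4:6, 1:3)]
  f2 <- fit_cholesky_ace(pr2, restarts = 2)
  expect_equal(f1$minus2LL, f2$minus2LL, tolerance = 1e-3)
})

test_that("profile confidence intervals bracket the estimate and shrink with n", {
  gen <- ace_paths(a = sqrt(0.4) * lt_vec_to_mat(c(1, .7, .6, .5, .3, .5), 3),
                   c = sqrt(0.3) * lt_vec_to_mat(c(1, .6, .5, .6, .2, .6), 3),
                   e = sqrt(0.3) * lt_vec_to_mat(c(1, .3, .2, .9, .3, .9), 3))
  which_coef <- data.frame(component = "a", visit = 1, factor = 1)
  pr_small <- simulate_twin_pairs(gen, 200, 200, seed = 31)
  pr_big <- simulate_twin_pairs(gen, 2000, 2000, seed = 31)
  f_small <- fit_cholesky_ace(pr_small, restarts = 1)
  f_big <- fit_cholesky_ace(pr_big, restarts = 1)
  ci_small <- confidence_intervals(f_small, coefficients = which_coef)
  ci_big <- confidence_intervals(f_big, coefficients = which_coef)
  for (ci in list(ci_small, ci_big)) {
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
    expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
  }
  expect_lt(ci_big$upper - ci_big$lower, ci_small$upper - ci_small$lower)
})

test_that("a coefficient estimated at zero gets a boundary lower bound of zero", {
  gen <- ace_paths(a = 0, c = sqrt(0.6), e = sqrt(0.4), n_visits = 1)
  pr <- simulate_twin_pairs(gen, 300, 300, seed = 32)
  fit <- fit_cholesky_ace(pr, restarts = 2)
  ci <- confidence_intervals(fit,
                             coefficients = data.frame(component = "a",
                                                       visit = 1, factor = 1))
  if (ci$estimate < 0.005) {
    expect_equal(ci$lower, 0)
    expect_true(ci$boundary)
  } else {
    expect_gte(ci$lower, 0)
  }
})

test_that("assumption checks: calibrated under exchangeable data, powered against order shifts", {
  gen <- ace_paths(a = sqrt(0.3) * diag(3), c = sqrt(0.3) * diag(3),
                   e = sqrt(0.4) * diag(3))
  reps <- 40
  rej <- matrix(FALSE, reps, 3)
  for (r in 1:reps) {
    pr <- simulate_twin_pairs(gen, 44, 20, seed = 100 + r)
    rep_out <- check_assumptions(pr)
    rej[r, ] <- rep_out$p_value < 0.05
  }
  # each test should reject around 5% of the time (binomial 2.5 SE bands)
  for (j in 1:3)
    expect_lt(mean(rej[, j]), 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))

  # shift twin 2 by 1 SD: the order-equality test must fire
  hits <- 0
  for (r in 1:20) {
    pr <- simulate_twin_pairs(gen, 44, 20, seed = 300 + r)
    pr$y[, 4:6] <- pr$y[, 4:6] + 1
    rep_out <- check_assumptions(pr)
    hits <- hits + (rep_out$p_value[1] < 0.05)
  }
  expect_gt(hits / 20, 0.9)
})

test_that("assumption LRT statistics are non-negative and single-zygosity input warns", {
  gen <- ace_paths(a = sqrt(0.3) * diag(3), c = sqrt(0.2) * diag(3),
                   e = sqrt(0.5) * diag(3))
  pr <- simulate_twin_pairs(gen, 60, 40, seed = 33)
  rep_out <- check_assumptions(pr)
  expect_true(all(rep_out$statistic >= 0))
  pr_mz <- simulate_twin_pairs(gen, 60, 0, seed = 34)
  expect_warning(check_assumptions(pr_mz), "single zygosity")
})

test_that("power simulation size and asymptotic behaviour", {
  p0 <- simulate_power(44, 20, A = 0, C = 0.5, reps = 150, seed = 35)
  expect_lte(p0$power, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 150))
  p1 <- simulate_power(300, 300, A = 0.95, C = 0, reps = 100, seed = 36)
  expect_gt(p1$power, 0.99)
  expect_error(simulate_power(44, 20, A = 0.5, C = 0.2, E = 0.5),
               "degenerate")
  expect_error(simulate_power(44, 20, A = 0.77, C = 0, reps = 50),
               "at least 100")
})
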