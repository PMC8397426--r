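test_that("ICC arithmetic follows the variance-component formula", {
  expect_equal(compute_icc(c(sigma_B2 = 1, sigma_F2 = 1, sigma_W2 = 1)),
               2 / 3)
  expect_equal(compute_icc(c(sigma_B2 = 0, sigma_F2 = 0, sigma_W2 = 2)), 0)
  expect_equal(compute_icc(c(sigma_B2 = 0.3, sigma_F2 = 0.2,
                             sigma_W2 = 0.5)), 0.5)
  expect_error(compute_icc(c(sigma_B2 = 0, sigma_F2 = 0, sigma_W2 = 0)),
               "undefined")
  expect_error(compute_icc(c(sigma_B2 = -1, sigma_F2 = 0, sigma_W2 = 1)),
               ">= 0")
})

test_that("identical repeated visits give sigma_W = 0 and ICC = 1", {
  fx <- toy_lmm_data(n_mz = 6, n_dz = 2, seed = 3)
  d <- fx$data
  # overwrite: visits identical within individual, individuals distinct
  base <- rnorm(length(unique(d$individual_id)))
  names(base) <- unique(d$individual_id)
  d$value <- base[d$individual_id]
  fit <- fit_bin_lmm(value ~ 1, d)
  expect_lt(fit$components[["sigma_W2"]], 1e-6)
  expect_gt(compute_icc(fit), 0.999)
})

test_that("pure noise across many individuals gives near-zero ICC", {
  fx <- toy_lmm_data(n_mz = 150, n_dz = 100, seed = 4)   # 500 individuals
  d <- fx$data
  set.seed(5)
  d$value <- rnorm(nrow(d))
  fit <- fit_bin_lmm(value ~ 1, d)
  tot <- fit$components[["sigma_T2"]]
  expect_lt(fit$components[["sigma_B2"]], 0.05 * tot)
  expect_lt(fit$components[["sigma_F2"]], 0.05 * tot)
  expect_lt(compute_icc(fit), 0.1)
})

test_that("REML and ML estimates match lme4 on the same data", {
  skip_if_not_installed("lme4")
  p <- common_factor_paths(0.2, 0.2, 0.1, 0.5)
  fx <- toy_lmm_data(n_mz = 20, n_dz = 10, paths = p,
                     effects = c(age = 0.02), seed = 6)
  d <- fx$data
  for (method in c("REML", "ML")) {
    mine <- fit_bin_lmm(value ~ age + sex, d, method = method)
    ref <- lme4::lmer(value ~ age + sex + (1 | individual_id) +
                        (1 | family_id), d, REML = method == "REML")
    vc <- as.data.frame(lme4::VarCorr(ref))
    expect_equal(mine$components[["sigma_B2"]],
                 vc$vcov[vc$grp == "individual_id"], tolerance = 1e-4)
    expect_equal(mine$components[["sigma_F2"]],
                 vc$vcov[vc$grp == "family_id"], tolerance = 1e-4)
    expect_equal(mine$components[["sigma_W2"]],
                 vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
    expect_equal(unname(mine$fixed_effects),
                 unname(lme4::fixef(ref)), tolerance = 1e-4)
    expect_equal(mine$criterion, -2 * as.numeric(logLik(ref)),
                 tolerance = 1e-6)
  }
})

test_that("estimates agree with a brute-force criterion grid on a small balanced instance", {
  p <- common_factor_paths(0.4, 0.3, 0.3, 1)   # sB ~ .3, sF ~ .55, sW = 1
  fx <- toy_lmm_data(n_mz = 5, n_dz = 3, paths = p, seed = 7)
  d <- fx$data
  fit <- fit_bin_lmm(value ~ 1, d)
  st <- fit$struct
  oracle <- grid_search_lmm(st$y, st$X, st$individual, st$family, "REML")
  expect_lt(max(abs(fit$components[1:3] - oracle$par)), 0.02)
})

test_that("generated covariate slopes are recovered", {
  p <- ace_paths(e = diag(3) * sqrt(0.5))
  fx <- toy_lmm_data(n_mz = 150, n_dz = 100, paths = p,
                     effects = c(age = 0.5), seed = 8)
  fit <- fit_bin_lmm(value ~ age + sex + ffm + hei, fx$data)
  expect_lt(abs(fit$fixed_effects[["age"]] - 0.5), 0.1)
})

test_that("constant covariates reduce to the null model", {
  fx <- toy_lmm_data(n_mz = 10, n_dz = 5, seed = 9)
  d <- fx$data
  d$age <- 40
  expect_error(fit_bin_lmm(value ~ age, d), "collinear")
  null_fit <- fit_bin_lmm(value ~ 1, d)
  expect_equal(length(null_fit$fixed_effects), 1L)
})

test_that("ICC is invariant to affine transformation of the values", {
  p <- common_factor_paths(0.2, 0.2, 0.1, 0.5)
  fx <- toy_lmm_data(n_mz = 20, n_dz = 10, paths = p, seed = 10)
  d <- fx$data
  f1 <- fit_bin_lmm(value ~ 1, d)
  d$value <- 3.7 * d$value - 12
  f2 <- fit_bin_lmm(value ~ 1, d)
  expect_equal(compute_icc(f1), compute_icc(f2), tolerance = 1e-4)
})

test_that("non-identifiable designs are rejected", {
  d <- data.frame(value = rnorm(6), individual_id = letters[1:6],
                  family_id = rep(LETTERS[1:6]), visit = 1)
  expect_error(fit_bin_lmm(value ~ 1, d), "non-identifiable")
  expect_error(fit_bin_lmm(value ~ 1,
                           data.frame(value = rnorm(4),
                                      individual_id = c("a", "a", "b", "b"),
                                      family_id = "F1")),
               "2 families")
})

test_that("Benjamini-Hochberg adjustment and significance flags are correct", {
  # construct four fits sharing one dataset but force known p-values via
  # p.adjust equivalence: the BH arithmetic itself
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  p <- ace_paths(e = diag(3))
  fx <- toy_lmm_data(n_mz = 15, n_dz = 10, paths = p,
                     effects = c(age = 0.4), seed = 11)
  fits <- list("0.01" = fit_bin_lmm(value ~ age + sex, fx$data))
  tc <- test_covariates(fits)
  expect_true(all(tc$q_value >= tc$p_value))
  expect_true(tc$significant[tc$covariate == "age"])
  expect_equal(sort(unique(tc$covariate)), c("age", "sex"))
})

test_that("covariate R2 captures saturated, null and intermediate signals", {
  fx <- toy_lmm_data(n_mz = 20, n_dz = 10, seed = 12)
  d <- fx$data
  # saturated: response exactly 2*age
  d$value <- 2 * d$age
  fit <- fit_bin_lmm(value ~ age, d)
  expect_gt(covariate_r2(fit, "age"), 99.5)

  # null: independent covariate
  p <- ace_paths(e = diag(3))
  fx2 <- toy_lmm_data(n_mz = 150, n_dz = 100, paths = p, seed = 13)
  fit2 <- fit_bin_lmm(value ~ age, fx2$data)
  expect_lt(covariate_r2(fit2, "age"), 1)
  expect_error(covariate_r2(fit2, "hei"), "not in the fitted model")
})

test_that("a generated 15% age share of total variance is recovered", {
  # age slope chosen so var(age*beta) ~ 0.15 of total
  design <- cohort_design(n_mz_pairs = 150, n_dz_pairs = 100)
  coh <- generate_cohort(design, seed = 14)
  beta <- sqrt(0.15 / 0.85 / var(coh$age))
  tab <- simulate_bin_values(coh, ace_paths(e = diag(3)),
                             effects = c(age = beta), seed = 15)
  d <- merge(tab, coh, by = "individual_id")
  fit <- fit_bin_lmm(value ~ age, d)
  expect_lt(abs(covariate_r2(fit, "age") - 15), 4)
})

test_that("null and covariate models agree when generated covariate effects are zero", {
  p <- common_factor_paths(0.2, 0.2, 0.1, 0.5)
  fx <- toy_lmm_data(n_mz = 60, n_dz = 40, paths = p, seed = 17)
  f0 <- fit_bin_lmm(value ~ 1, fx$data)
  f1 <- fit_bin_lmm(value ~ age + sex + ffm + hei, fx$data)
  expect_lt(max(abs(f0$components[1:3] - f1$components[1:3])), 0.05)
  expect_lt(abs(compute_icc(f0) - compute_icc(f1)), 0.03)
})

test_that("increasing within-person noise decreases estimated ICC", {
  iccs <- sapply(c(0.3, 0.8, 1.6), function(eun) {
    p <- common_factor_paths(0.25, 0.2, 0.1, eun)
    fx <- toy_lmm_data(n_mz = 60, n_dz = 40, paths = p, seed = 16)
    compute_icc(fit_bin_lmm(value ~ 1, fx$data))
  })
  expect_true(all(diff(iccs) < 0))
})
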