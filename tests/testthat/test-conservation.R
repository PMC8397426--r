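make_profiles <- function(n = 10, p = 8, seed = 50, noise = 0.3) {
  set.seed(seed)
  b <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("I%02d", 1:n), sprintf("%.2f", 1:p)))
  f <- b + noise * matrix(rnorm(n * p), n, p)
  list(baseline = b, followup = f)
}

test_that("identical profiles give unit diagonal correlations and all indices 1", {
  pf <- make_profiles(noise = 0)
  M <- profile_correlations(pf$baseline, pf$followup)
  expect_equal(unname(diag(M)), rep(1, 10))
  res <- conservation_index(M)
  expect_true(all(res$index == 1))
  expect_true(all(res$band == "1.00"))
})

test_that("uniform weights reproduce the unweighted matrix exactly", {
  pf <- make_profiles()
  M1 <- profile_correlations(pf$baseline, pf$followup)
  M2 <- profile_correlations(pf$baseline, pf$followup,
                             weights = rep(3.7, 8))
  expect_equal(M1, M2, tolerance = 1e-12)
})

test_that("profile correlations match a brute-force per-pair computation", {
  pf <- make_profiles(n = 3, p = 4)
  M <- profile_correlations(pf$baseline, pf$followup)
  for (i in 1:3) for (j in 1:3)
    expect_equal(M[i, j], cor(pf$baseline[i, ], pf$followup[j, ]),
                 tolerance = 1e-10)
  # weighted variant against an explicit weighted-moment calculation
  w <- c(0.1, 0.4, 0.2, 0.3)
  Mw <- profile_correlations(pf$baseline, pf$followup, weights = w)
  wc <- function(x, y) {
    mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
    sum(w * (x - mx) * (y - my)) /
      sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(Mw[i, j], wc(pf$baseline[i, ], pf$followup[j, ]),
                 tolerance = 1e-10)
})

test_that("zero-variance profiles are reported by individual", {
  pf <- make_profiles(n = 4, p = 5)
  pf$baseline[2, ] <- 1
  expect_error(profile_correlations(pf$baseline, pf$followup), "I02")
})

test_that("the conservation index follows the rank formula", {
  pf <- make_profiles(n = 128, p = 10, noise = 0.05)
  M <- profile_correlations(pf$baseline, pf$followup)
  res <- conservation_index(M)
  expect_equal(res$N, rep(128, 128))
  top <- res[res$rank == 1, ]
  expect_true(nrow(top) > 0)
  expect_true(all(top$index == 1))
  # direct formula spot checks
  expect_equal(1 - (39 - 1) / (128 - 1), 0.7007874, tolerance = 1e-7)
  worst <- res[which.max(res$rank), ]
  expect_equal(worst$index, 1 - (worst$rank - 1) / 127)
  mid <- res[res$rank == 39, ]
  if (nrow(mid)) expect_true(all(mid$band == "0.70-0.89"))
})

test_that("index is invariant to monotone transformation of a row", {
  pf <- make_profiles(n = 12, p = 9)
  M <- profile_correlations(pf$baseline, pf$followup)
  r5 <- conservation_index(M)[5, ]
  M2 <- M
  M2[5, ] <- tanh(3 * M[5, ]) + 0.1   # strictly increasing map
  r5b <- conservation_index(M2)[5, ]
  expect_equal(r5$rank, r5b$rank)
  expect_equal(r5$index, r5b$index)
})

test_that("ties get average ranks and propagate to the index", {
  M <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(M) <- c(0.9, 0.5, 0.1)
  res <- conservation_index(M)
  expect_equal(res$rank[1], 1)
  expect_equal(res$index[1], 1)
  expect_equal(res$rank[2], 2)      # average of ranks 1,2,3
  expect_equal(res$rank[3], 3)
  expect_equal(res$index[3], 0)
})

test_that("longitudinal weights: plain correlation, confounder removal, recovery", {
  pf <- make_profiles(n = 60, p = 6)
  w0 <- longitudinal_bin_weights(pf$baseline, pf$followup)
  r_plain <- sapply(1:6, function(j) cor(pf$baseline[, j], pf$followup[, j]))
  expect_equal(as.numeric(w0), pmax(pmin(r_plain, 1), 0),
               tolerance = 1e-12)

  # a bin driven by age at both time points loses its weight after adjustment
  set.seed(51)
  n <- 200
  age <- rnorm(n, 35, 12)
  b <- cbind(0.5 * age + rnorm(n), matrix(rnorm(3 * n), n))
  f <- cbind(0.5 * age + rnorm(n), matrix(rnorm(3 * n), n))
  colnames(b) <- colnames(f) <- sprintf("%.2f", 1:4)
  rownames(b) <- rownames(f) <- sprintf("I%03d", 1:n)
  raw <- longitudinal_bin_weights(b, f)
  adj <- longitudinal_bin_weights(b, f, covariates = data.frame(age = age))
  expect_gt(raw[1], 0.8)
  expect_lt(adj[1], 0.2)

  # test-retest correlation 0.6 recovered within 0.1 at n = 500
  set.seed(52)
  n <- 500
  common <- matrix(rnorm(n * 4), n, 4)
  b2 <- sqrt(0.6) * common + sqrt(0.4) * matrix(rnorm(n * 4), n, 4)
  f2 <- sqrt(0.6) * common + sqrt(0.4) * matrix(rnorm(n * 4), n, 4)
  dimnames(b2) <- dimnames(f2) <- list(sprintf("I%03d", 1:n),
                                       sprintf("%.2f", 1:4))
  w2 <- longitudinal_bin_weights(b2, f2)
  expect_true(all(abs(w2 - 0.6) < 0.1))

  expect_error(longitudinal_bin_weights(b2[1:5, ], f2[1:5, ]),
               "at least 8")
  expect_error(longitudinal_bin_weights(b2, f2,
                                        covariates = data.frame(x = rep(1, n))),
               "singular")
})

test_that("weighting by the stable-set indicator equals subsetting to the stable set", {
  pf <- make_profiles(n = 15, p = 10)
  stable <- colnames(pf$baseline)[c(1, 3, 5, 7)]
  ind <- as.numeric(colnames(pf$baseline) %in% stable)
  M_sub <- profile_correlations(pf$baseline, pf$followup, bins = stable)
  M_w <- profile_correlations(pf$baseline, pf$followup, weights = ind)
  expect_equal(M_sub, M_w, tolerance = 1e-12)
})

test_that("band summaries count and percentage correctly", {
  s <- summarize_conservation(c(1.0, 0.95, 0.80, 0.60))
  expect_equal(s$n, c(1, 1, 1, 1))
  expect_equal(sum(s$percent), 100)
  s2 <- summarize_conservation(rep(1, 7))
  expect_equal(s2$percent[1], 100)
  # a constructed band mix is reproduced exactly
  idx <- c(rep(1, 44), runif(51, 0.90, 0.99), runif(22, 0.70, 0.89),
           runif(11, 0, 0.69))
  s3 <- summarize_conservation(idx)
  expect_equal(s3$n, c(44, 51, 22, 11))
  expect_equal(s3$percent, c(34.4, 39.8, 17.2, 8.6))
})
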