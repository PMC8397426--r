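#' Twin-model assumption checks
#'
#' Before structural modelling, the classic twin design assumes that
#' sampling is exchangeable: means and variances should not differ by
#' twin order (who is "twin 1") or by zygosity.  This function runs
#' likelihood-ratio tests of (i) equal means across twin order,
#' (ii) equal means across zygosity, and (iii) equal per-visit
#' variances across twin order and zygosity, each against the saturated
#' per-zygosity multivariate-normal model.
#'
#' With a single zygosity group the zygosity tests are skipped with a
#' warning.
#'
#' @param pairs A [twin_pairs()] object.
#' @return `data.frame` with columns `test`, `statistic`, `df`,
#'   `p_value`.
#' @export
check_assumptions <- function(pairs) {
  stopifnot(inherits(pairs, "twin_pairs"))
  gstats <- pair_group_stats(pairs)
  if (any(vapply(gstats, function(g) g$n, 1) < 2))
    stop_ts("need at least 2 pairs per zygosity group")
  v <- pairs$n_visits
  k <- 2L * v
  sat <- fit_saturated(pairs)
  res <- list()

  # (i) equal means across twin order, zygosity-specific covariances
  m2_order <- sum(vapply(names(gstats), function(g)
    mvn_fit_mean_constrained(gstats[[g]], type = "order")$minus2LL, 1))
  lrt <- max(0, m2_order - sat$minus2LL)
  res$mean_order <- data.frame(test = "equal means across twin order",
                               statistic = lrt, df = length(gstats) * v,
                               p_value = stats::pchisq(lrt, length(gstats) * v,
                                                       lower.tail = FALSE))

  if (length(gstats) == 2) {
    # (ii) equal means across zygosity
    m2_zyg <- mvn_fit_common_mean(gstats)$minus2LL
    lrt <- max(0, m2_zyg - sat$minus2LL)
    res$mean_zyg <- data.frame(test = "equal means across zygosity",
                               statistic = lrt, df = k,
                               p_value = stats::pchisq(lrt, k,
                                                       lower.tail = FALSE))
    # (iii) equal variances across twin order and zygosity
    m2_var <- mvn_fit_equal_variances(gstats, v)$minus2LL
    lrt <- max(0, m2_var - sat$minus2LL)
    dfv <- 2 * k - v          # free variances saturated minus constrained
    res$var <- data.frame(test = "equal variances across order and zygosity",
                          statistic = lrt, df = dfv,
                          p_value = stats::pchisq(lrt, dfv,
                                                  lower.tail = FALSE))
  } else {
    warning("single zygosity group: zygosity tests skipped")
    m2_var <- mvn_fit_equal_variances(gstats, v)$minus2LL
    lrt <- max(0, m2_var - sat$minus2LL)
    dfv <- k - v
    res$var <- data.frame(test = "equal variances across twin order",
                          statistic = lrt, df = dfv,
                          p_value = stats::pchisq(lrt, dfv,
                                                  lower.tail = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# MLE with mean constrained (equal across twin order), Sigma unstructured:
# iterative GLS, converges in a few passes
mvn_fit_mean_constrained <- function(st, type = "order") {
  k <- length(st$xbar); v <- k / 2
  # design: mu = D m with D stacking two identity blocks
  D <- rbind(diag(v), diag(v))
  Y <- st$Y; n <- st$n
  mu <- drop(D %*% ((st$xbar[1:v] + st$xbar[v + 1:v]) / 2))
  for (it in 1:25) {
    Yc <- sweep(Y, 2, mu)
    S <- crossprod(Yc) / n
    Si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Si)) break
    m <- solve(t(D) %*% Si %*% D, t(D) %*% Si %*% colMeans(Y))
    mu_new <- drop(D %*% m)
    if (max(abs(mu_new - mu)) < 1e-10) { mu <- mu_new; break }
    mu <- mu_new
  }
  Yc <- sweep(Y, 2, mu)
  S <- crossprod(Yc) / n
  ld <- determinant(S, logarithm = TRUE)
  list(minus2LL = n * (k * log(2 * pi) + as.numeric(ld$modulus) + k),
       mean = mu, cov = S)
}

# MLE with a common mean across zygosity groups, per-group Sigma
mvn_fit_common_mean <- function(gstats) {
  k <- length(gstats[[1]]$xbar)
  mu <- Reduce(`+`, lapply(gstats, function(g) g$n * g$xbar)) /
    sum(vapply(gstats, function(g) g$n, 1))
  for (it in 1:25) {
    A <- matrix(0, k, k); b <- numeric(k)
    Sis <- lapply(gstats, function(g) {
      Yc <- sweep(g$Y, 2, mu)
      S <- crossprod(Yc) / g$n
      solve(S)
    })
    for (i in seq_along(gstats)) {
      A <- A + gstats[[i]]$n * Sis[[i]]
      b <- b + gstats[[i]]$n * drop(Sis[[i]] %*% gstats[[i]]$xbar)
    }
    mu_new <- drop(solve(A, b))
    if (max(abs(mu_new - mu)) < 1e-10) { mu <- mu_new; break }
    mu <- mu_new
  }
  m2 <- 0
  for (g in gstats) {
    Yc <- sweep(g$Y, 2, mu)
    S <- crossprod(Yc) / g$n
    ld <- determinant(S, logarithm = TRUE)
    m2 <- m2 + g$n * (k * log(2 * pi) + as.numeric(ld$modulus) + k)
  }
  list(minus2LL = m2, mean = mu)
}

# MLE with per-visit variances equal across twin order (and zygosity
# when two groups): free means, correlation structure free per group.
# Sigma_g = D R_g D with shared D; R_g parameterised by a row-normalised
# Cholesky factor.
mvn_fit_equal_variances <- function(gstats, v) {
  k <- 2L * v
  ng <- length(gstats)
  ncor <- k * (k - 1) / 2
  corr_chol <- function(w) {
    W <- diag(k)
    W[lower.tri(W)] <- w
    Wn <- W / sqrt(rowSums(W^2))
    Wn
  }
  # start values from pooled variances and per-group correlations
  pool_var <- Reduce(`+`, lapply(gstats, function(g)
    g$n * (diag(g$S)[1:v] + diag(g$S)[v + 1:v]) / 2)) /
    sum(vapply(gstats, function(g) g$n, 1))
  w0 <- unlist(lapply(gstats, function(g) {
    R <- stats::cov2cor(g$S + diag(1e-8, k))
    Lc <- t(chol(R))
    Lc[lower.tri(Lc)]
  }))
  par0 <- c(log(sqrt(pmax(pool_var, 1e-8))), w0)
  obj <- function(par) {
    sds <- exp(par[1:v])
    dvec <- rep(sds, 2L)
    tot <- 0
    for (i in seq_along(gstats)) {
      w <- par[v + (i - 1L) * ncor + seq_len(ncor)]
      Lc <- corr_chol(w)
      R <- tcrossprod(Lc)
      Sg <- outer(dvec, dvec) * R
      ch <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      Si <- chol2inv(ch)
      st <- gstats[[i]]
      val <- st$n * (k * log(2 * pi) + 2 * sum(log(diag(ch))) +
                       sum(Si * st$S))
      if (!is.finite(val)) return(1e10)
      tot <- tot + val
    }
    tot
  }
  f <- stats::optim(par0, obj, method = "L-BFGS-B",
                    lower = c(rep(-10, v), rep(-20, ng * ncor)),
                    upper = c(rep(10, v), rep(20, ng * ncor)),
                    control = list(maxit = 1000))
  list(minus2LL = f$value, convergence = f$convergence)
}

#' Simulated power of the likelihood-ratio test for additive genetics
#'
#' Repeatedly simulates univariate twin-pair data with the stated
#' additive-genetic (A), shared-environment (C) and unique-environment
#' (E) variance proportions, fits ACE and CE models by maximum
#' likelihood, and tests the drop of A with the boundary-corrected
#' 50:50 chi-squared(0)/chi-squared(1) mixture reference distribution
#' (a plain chi-squared(1) is selectable).  Returns the rejection
#' fraction at the requested alpha.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs per replicate.
#' @param A,C Generating variance proportions; `E` defaults to
#'   `1 - A - C`.
#' @param E Unique-environment proportion.
#' @param alpha Test level.
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @param mixture Use the 50:50 boundary mixture (default) or plain
#'   chi-squared(1).
#' @return Object of class `"ace_power"`: list with `power`,
#'   `rejections`, `reps`, `alpha`, and the generating proportions.
#' @export
#' @examples
#' \donttest{
#' simulate_power(44, 20, A = 0.77, C = 0, reps = 100, seed = 7)
#' }
simulate_power <- function(n_mz, n_dz, A, C, E = 1 - A - C, alpha = 0.05,
                           reps = 500, seed = 1L, mixture = TRUE) {
  if (abs(A + C + E - 1) > 1e-8 || A < 0 || C < 0 || E < 0)
    stop_ts("degenerate proportions: A, C, E must be >= 0 and sum to 1")
  if (reps < 100) stop_ts("reps must be at least 100")
  gen <- ace_paths(a = sqrt(A), c = sqrt(C), e = sqrt(max(E, 1e-12)),
                   n_visits = 1)
  crit <- if (mixture) stats::qchisq(1 - 2 * alpha, 1) else
    stats::qchisq(1 - alpha, 1)
  rej <- 0L
  for (r in seq_len(reps)) {
    pr <- simulate_twin_pairs(gen, n_mz, n_dz,
                              seed = split_seed(seed, 20000L + r))
    ace <- fit_cholesky_ace(pr, model = "ACE", restarts = 2)
    ce <- fit_cholesky_ace(pr, model = "CE", restarts = 2)
    T <- max(0, ce$minus2LL - ace$minus2LL)
    if (T > crit) rej <- rej + 1L
  }
  structure(list(power = rej / reps, rejections = rej, reps = reps,
                 alpha = alpha, A = A, C = C, E = E,
                 n_mz = n_mz, n_dz = n_dz, mixture = mixture),
            class = "ace_power")
}

#' @export
print.ace_power <- function(x, ...) {
  cat(sprintf(
    "power to detect A = %.2f (C = %.2f): %.3f (%d/%d rejections at alpha = %.2f, %d MZ + %d DZ pairs)\n",
    x$A, x$C, x$power, x$rejections, x$reps, x$alpha, x$n_mz, x$n_dz))
  invisible(x)
}
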