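# shared builders for small deterministic fixtures

# long bin table + cohort merged, for mixed-model tests
toy_lmm_data <- function(n_mz = 8, n_dz = 4, paths = NULL, effects = NULL,
                         n_bins = 1, seed = 1) {
  coh <- generate_cohort(cohort_design(n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                                       seed = seed))
  if (is.null(paths)) paths <- ace_paths(e = 1)
  tab <- simulate_bin_values(coh, paths, effects = effects,
                             n_bins = n_bins, seed = seed)
  list(cohort = coh, table = tab,
       data = merge(tab, coh, by = "individual_id"))
}

# generating paths where the stable (cross-visit) variance splits into
# A/C/E common components plus visit noise; unit total variance
common_factor_paths <- function(Acm, Ccm, Ecm, Eun, n_visits = 3) {
  col1 <- function(x) cbind(rep(sqrt(x), n_visits),
                            matrix(0, n_visits, n_visits - 1))
  e_cov <- Ecm * matrix(1, n_visits, n_visits) + Eun * diag(n_visits)
  ace_paths(a = col1(Acm), c = col1(Ccm), e = t(chol(e_cov)))
}

# naive dense REML/ML criterion for the 3-component nested model,
# independent of the package's whitened implementation: builds each
# family covariance explicitly and uses solve()
naive_lmm_criterion <- function(theta, y, X, ind, fam, method = "REML") {
  sB <- theta[1]; sF <- theta[2]; sW <- theta[3]
  fams <- unique(fam)
  n <- length(y); p <- ncol(X)
  logdet <- 0
  XtViX <- matrix(0, p, p); XtViy <- numeric(p); ytViy <- 0
  blocks <- list()
  for (f in fams) {
    i <- which(fam == f)
    s <- length(i)
    Z <- outer(ind[i], unique(ind[i]), `==`) * 1
    Sg <- sF * matrix(1, s, s) + sB * tcrossprod(Z) + sW * diag(s)
    Si <- tryCatch(solve(Sg), error = function(e) NULL)
    if (is.null(Si)) return(1e10)
    dt <- determinant(Sg, logarithm = TRUE)
    if (dt$sign <= 0) return(1e10)
    logdet <- logdet + as.numeric(dt$modulus)
    Xi <- X[i, , drop = FALSE]; yi <- y[i]
    XtViX <- XtViX + t(Xi) %*% Si %*% Xi
    XtViy <- XtViy + t(Xi) %*% Si %*% yi
    ytViy <- ytViy + drop(t(yi) %*% Si %*% yi)
    blocks[[f]] <- list(i = i, Si = Si)
  }
  beta <- solve(XtViX, XtViy)
  rss <- ytViy - 2 * sum(beta * XtViy) + drop(t(beta) %*% XtViX %*% beta)
  val <- n * log(2 * pi) + logdet + rss
  if (method == "REML")
    val <- val + as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) -
      p * log(2 * pi)
  val
}

# two-stage brute-force grid search of the criterion (coarse then fine)
grid_search_lmm <- function(y, X, ind, fam, method = "REML",
                            coarse = seq(0.05, 3, by = 0.1), fine_step = 0.01) {
  best <- NULL
  for (sB in coarse) for (sF in coarse) for (sW in coarse) {
    v <- naive_lmm_criterion(c(sB, sF, sW), y, X, ind, fam, method)
    if (is.null(best) || v < best$value)
      best <- list(par = c(sB, sF, sW), value = v)
  }
  ctr <- best$par
  rng <- function(x) seq(max(fine_step, x - 0.12), x + 0.12, by = fine_step)
  for (sB in rng(ctr[1])) for (sF in rng(ctr[2])) for (sW in rng(ctr[3])) {
    v <- naive_lmm_criterion(c(sB, sF, sW), y, X, ind, fam, method)
    if (v < best$value) best <- list(par = c(sB, sF, sW), value = v)
  }
  best
}

reference_stable_icc <- function() {
  path <- system.file("extdata", "stable_bins_icc.csv",
                      package = "twinstable")
  read.csv(path, colClasses = c("character", "numeric"))
}
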