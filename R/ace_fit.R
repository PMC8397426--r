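#' Assemble complete twin-pair data for one bin
#'
#' Reshapes a long bin table into the pair-level layout used by the
#' twin structural equation model: one row per family holding both
#' co-twins' visit vectors side by side, plus zygosity and the
#' pair-level mean-model covariates (age, sex).  Families with a
#' missing co-twin or missing visits are dropped (complete-pair
#' analysis); the number dropped is reported via a message.
#'
#' @param table Long bin table (see [simulate_bin_values()]).
#' @param cohort Cohort `data.frame`.
#' @param bin Bin ppm label (numeric) to extract; not needed if the
#'   table contains a single bin.
#' @param covariates Mean-model covariates, a subset of
#'   `c("age", "sex")`; co-twins share both.
#' @return Object of class `"twin_pairs"`: list with `y` (n_pairs x 2v
#'   matrix: twin-1 visits then twin-2 visits), `zygosity`, `covars`,
#'   `n_visits`.
#' @export
twin_pairs <- function(table, cohort, bin = NULL,
                       covariates = c("age", "sex")) {
  covariates <- intersect(covariates, c("age", "sex"))
  if (!is.null(bin)) table <- table[table$bin_ppm == bin, , drop = FALSE]
  if (!nrow(table)) stop_ts("no rows for the requested bin")
  if (length(unique(table$bin_ppm)) > 1)
    stop_ts("table holds several bins; pass `bin`")
  v <- max(table$visit)
  key <- paste(table$individual_id, table$visit)
  co <- cohort[order(cohort$family_id, cohort$twin_order), , drop = FALSE]
  fams <- unique(co$family_id)
  rows <- list(); zyg <- character(); covs <- list()
  dropped <- 0L
  for (f in fams) {
    mem <- co[co$family_id == f, , drop = FALSE]
    if (nrow(mem) != 2L) { dropped <- dropped + 1L; next }
    vals <- sapply(mem$individual_id, function(id)
      table$value[match(paste(id, seq_len(v)), key)])
    if (any(is.na(vals))) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- c(vals[, 1], vals[, 2])
    zyg <- c(zyg, mem$zygosity[1])
    covs[[length(rows)]] <- mem[1, covariates, drop = FALSE]
  }
  if (dropped) message(dropped, " incomplete families dropped")
  if (!length(rows)) stop_ts("no complete twin pairs")
  y <- do.call(rbind, rows)
  covars <- if (length(covariates)) do.call(rbind, covs) else NULL
  structure(list(y = y, zygosity = zyg, covars = covars, n_visits = v),
            class = "twin_pairs")
}

# direct simulation of a twin_pairs object from generating paths
#' Simulate twin-pair visit vectors from ACE paths
#'
#' Generates complete pairs with zero mean directly from the generating
#' model, bypassing the cohort bookkeeping; convenient for power and
#' calibration studies.
#'
#' @param paths An [ace_paths()] object.
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param seed Integer seed.
#' @return A `"twin_pairs"` object without covariates.
#' @export
simulate_twin_pairs <- function(paths, n_mz, n_dz, seed = 1L) {
  stopifnot(inherits(paths, "ace_paths"))
  n <- n_mz + n_dz
  if (n < 1) stop_ts("need at least one pair")
  is_dz <- rep(c(FALSE, TRUE), c(n_mz, n_dz))
  vals <- with_seed(split_seed(seed, "pairs"),
                    draw_pair_values(paths, n, is_dz))
  v <- paths$n_visits
  i1 <- seq(1, 2 * n, 2)
  y <- cbind(vals[i1, , drop = FALSE], vals[i1 + 1, , drop = FALSE])
  structure(list(y = y, zygosity = ifelse(is_dz, "DZ", "MZ"),
                 covars = NULL, n_visits = v),
            class = "twin_pairs")
}

#' @export
print.twin_pairs <- function(x, ...) {
  cat(sprintf("twin pairs: %d MZ + %d DZ over %d visits\n",
              sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ"), x$n_visits))
  invisible(x)
}

# per-zygosity sufficient statistics (and covariate matrices if present)
pair_group_stats <- function(pairs) {
  k <- 2L * pairs$n_visits
  out <- list()
  for (g in c("MZ", "DZ")) {
    i <- pairs$zygosity == g
    if (!any(i)) next
    Y <- pairs$y[i, , drop = FALSE]
    xb <- colMeans(Y)
    Yc <- sweep(Y, 2, xb)
    out[[g]] <- list(n = nrow(Y), xbar = xb, S = crossprod(Yc) / nrow(Y),
                     Y = Y,
                     covars = if (!is.null(pairs$covars))
                       pairs$covars[i, , drop = FALSE] else NULL)
  }
  out
}

# -2 log-likelihood of a Cholesky ACE parameter vector
ace_objective_factory <- function(pairs, model, covariates) {
  v <- pairs$n_visits
  k <- 2L * v
  L <- v * (v + 1L) / 2L
  gstats <- pair_group_stats(pairs)
  has_cov <- length(covariates) > 0
  covm <- if (has_cov)
    lapply(gstats, function(g) as.matrix(g$covars[, covariates, drop = FALSE]))
  else NULL
  n_a <- if (model == "ACE") L else 0L
  npar <- n_a + 2L * L + v + length(covariates)
  unpack <- function(th) {
    a <- if (model == "ACE") lt_vec_to_mat(th[seq_len(L)], v) else
      matrix(0, v, v)
    cc <- lt_vec_to_mat(th[n_a + seq_len(L)], v)
    e <- lt_vec_to_mat(th[n_a + L + seq_len(L)], v)
    mu <- th[n_a + 2L * L + seq_len(v)]
    beta <- if (has_cov) th[n_a + 2L * L + v + seq_along(covariates)] else
      numeric(0)
    list(a = a, c = cc, e = e, mu = mu, beta = beta)
  }
  obj <- function(th) {
    p <- unpack(th)
    paths <- structure(list(a = p$a, c = p$c, e = p$e, dz_genetic = 0.5,
                            n_visits = v), class = "ace_paths")
    tot <- 0
    for (g in names(gstats)) {
      st <- gstats[[g]]
      Sg <- expected_covariance(paths, g)
      R <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(R)) return(1e10)
      logdet <- 2 * sum(log(diag(R)))
      Si <- chol2inv(R)
      mu_k <- rep(p$mu, 2L)
      if (!has_cov) {
        d <- st$xbar - mu_k
        val <- st$n * (k * log(2 * pi) + logdet + sum(Si * st$S) +
                         drop(t(d) %*% Si %*% d))
      } else {
        shift <- drop(covm[[g]] %*% p$beta)
        Rmat <- sweep(st$Y, 2, mu_k) - shift   # shift same for all visits
        Z <- backsolve(R, t(Rmat), transpose = TRUE)
        val <- st$n * (k * log(2 * pi) + logdet) + sum(Z^2)
      }
      if (!is.finite(val)) return(1e10)
      tot <- tot + val
    }
    tot
  }
  list(obj = obj, unpack = unpack, npar = npar, L = L, n_a = n_a,
       v = v, gstats = gstats)
}

ace_bounds <- function(fac, model, covariates) {
  v <- fac$v; L <- fac$L
  lo_block <- function(diag_lo) {
    lo <- rep(-20, L)
    lo[lt_diag_pos(v)] <- diag_lo
    lo
  }
  lo <- c(if (model == "ACE") lo_block(0), lo_block(0), lo_block(1e-4),
          rep(-50, v), rep(-50, length(covariates)))
  hi <- rep(c(20, 50), c(fac$npar - v - length(covariates),
                         v + length(covariates)))
  list(lower = lo, upper = hi)
}

ace_start <- function(fac, model, covariates, jitter = 0) {
  v <- fac$v
  # pooled per-visit covariance across twins and groups
  Vh <- matrix(0, v, v); ntot <- 0
  mu0 <- numeric(v)
  for (st in fac$gstats) {
    Vh <- Vh + st$n * (st$S[1:v, 1:v] + st$S[v + 1:v, v + 1:v]) / 2
    mu0 <- mu0 + st$n * (st$xbar[1:v] + st$xbar[v + 1:v]) / 2
    ntot <- ntot + st$n
  }
  Vh <- Vh / ntot + diag(1e-3, v)
  mu0 <- mu0 / ntot
  Lh <- t(chol(Vh / 3))
  s <- lt_mat_to_vec(Lh)
  th <- c(if (model == "ACE") s, s, s, mu0, rep(0, length(covariates)))
  if (jitter > 0) th <- th * stats::runif(length(th), 1 - jitter, 1 + jitter) +
      stats::rnorm(length(th), 0, 0.01 * jitter)
  th
}

#' Fit a longitudinal Cholesky ACE twin model
#'
#' Maximises the joint MZ + DZ multivariate-normal likelihood of the
#' stacked twin-pair visit vectors over lower-triangular additive
#' genetic (a), shared environmental (c) and unique environmental (e)
#' path matrices plus a mean model (per-visit intercepts, optionally
#' age and sex entering the means only).  The first latent factor of
#' each source loads on every visit, so variance present at baseline
#' can persist, while later factors capture newly emerging variance.
#' The expected pair covariance is `[[V, R], [R', V]]` with
#' `V = A + C + E` and `R = A + C` (MZ) or `0.5 A + C` (DZ).
#'
#' Sign indeterminacy of the Cholesky columns is resolved by
#' constraining diagonals to be non-negative.  Optimisation is bounded
#' quasi-Newton (L-BFGS-B) from several start values; the best
#' converged solution is kept.
#'
#' @param pairs A [twin_pairs()] object with both zygosity groups.
#' @param model `"ACE"` (default) or `"CE"` (additive genetic paths
#'   fixed at zero, used for likelihood-ratio tests of A).
#' @param covariates Mean-model covariates among `c("age", "sex")`;
#'   used only when present in `pairs`.
#' @param restarts Number of additional jittered starts.
#' @return Object of class `"cholesky_ace"` with elements `paths`
#'   ([ace_paths()]), `mean_model`, `minus2LL`, `npar`, `n_pairs`,
#'   `pairs`, `convergence`.
#' @seealso [standardize_paths()], [confidence_intervals()],
#'   [expected_covariance()]
#' @export
fit_cholesky_ace <- function(pairs, model = c("ACE", "CE"),
                             covariates = NULL, restarts = 4) {
  model <- match.arg(model)
  stopifnot(inherits(pairs, "twin_pairs"))
  if (is.null(covariates))
    covariates <- if (!is.null(pairs$covars)) colnames(pairs$covars) else
      character(0)
  if (length(covariates) && is.null(pairs$covars))
    stop_ts("pairs carry no covariates")
  fac <- ace_objective_factory(pairs, model, covariates)
  bd <- ace_bounds(fac, model, covariates)
  starts <- list(ace_start(fac, model, covariates))
  if (restarts > 0) {
    starts <- c(starts, with_seed(split_seed(1L, "ace_restarts"), {
      lapply(seq_len(restarts), function(i)
        ace_start(fac, model, covariates, jitter = 0.3))
    }))
  }
  best <- NULL
  for (s0 in starts) {
    f <- tryCatch(
      stats::optim(s0, fac$obj, method = "L-BFGS-B",
                   lower = bd$lower, upper = bd$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best))
    stop_ts("Cholesky ACE optimisation failed from every start")
  p <- fac$unpack(best$par)
  paths <- ace_paths(a = p$a, c = p$c, e = p$e, dz_genetic = 0.5,
                     n_visits = fac$v)
  mm <- list(intercepts = p$mu)
  if (length(covariates)) mm$beta <- stats::setNames(p$beta, covariates)
  structure(list(paths = paths, mean_model = mm, minus2LL = best$value,
                 npar = fac$npar, model = model,
                 n_pairs = c(MZ = sum(pairs$zygosity == "MZ"),
                             DZ = sum(pairs$zygosity == "DZ")),
                 pairs = pairs, covariates = covariates,
                 convergence = best$convergence,
                 factory = fac, bounds = bd, par = best$par),
            class = "cholesky_ace")
}

#' @export
print.cholesky_ace <- function(x, ...) {
  cat(sprintf("Longitudinal Cholesky %s twin model (%d MZ + %d DZ pairs, %d visits)\n",
              x$model, x$n_pairs[["MZ"]], x$n_pairs[["DZ"]],
              x$paths$n_visits))
  cat(sprintf("  -2 log-likelihood: %.3f (%d parameters)\n",
              x$minus2LL, x$npar))
  sd <- standardize_paths(x)
  cat("  squared standardized coefficients (per-visit rows):\n")
  print(round(sd$table, 3))
  invisible(x)
}

#' @export
coef.cholesky_ace <- function(object, ...) {
  c(a = lt_mat_to_vec(object$paths$a), c = lt_mat_to_vec(object$paths$c),
    e = lt_mat_to_vec(object$paths$e),
    mu = object$mean_model$intercepts, object$mean_model$beta)
}

#' @export
logLik.cholesky_ace <- function(object, ...) {
  val <- -object$minus2LL / 2
  attr(val, "df") <- object$npar
  class(val) <- "logLik"
  val
}

#' @export
summary.cholesky_ace <- function(object, ...) {
  std <- standardize_paths(object)
  res <- list(model = object$model, n_pairs = object$n_pairs,
              minus2LL = object$minus2LL, std = std,
              implied = implied_covariance(object$paths))
  class(res) <- "summary.cholesky_ace"
  res
}

#' @export
print.summary.cholesky_ace <- function(x, ...) {
  cat(sprintf("Cholesky %s model: -2LL = %.3f (%d MZ + %d DZ pairs)\n",
              x$model, x$minus2LL, x$n_pairs[["MZ"]], x$n_pairs[["DZ"]]))
  cat("implied per-visit variances:",
      paste(sprintf("%.3f", diag(x$implied)), collapse = ", "), "\n")
  print(round(x$std$table, 3))
  invisible(x)
}

#' @export
simulate.cholesky_ace <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(i)
    simulate_twin_pairs(object$paths, object$n_pairs[["MZ"]],
                        object$n_pairs[["DZ"]],
                        seed = split_seed(seed, i)))
}

#' Squared standardized path coefficients
#'
#' Divides every path coefficient by the implied standard deviation of
#' its visit and squares it, giving the proportion of that visit's
#' variance attributable to each latent factor: `A1..Av` (additive
#' genetic), `C1..Cv` (shared environment), `E1..Ev` (unique
#' environment) in the lower-triangular visit-by-factor layout.  Within
#' each visit the proportions sum to one by construction.
#'
#' @param fit A `"cholesky_ace"` fit or an [ace_paths()] object.
#' @return Object of class `"ace_std"`: list with matrices `A`, `C`,
#'   `E` (visit rows, factor columns) and a combined `table`.
#' @export
standardize_paths <- function(fit) {
  paths <- if (inherits(fit, "cholesky_ace")) fit$paths else fit
  stopifnot(inherits(paths, "ace_paths"))
  v <- paths$n_visits
  V <- implied_covariance(paths)
  tv <- diag(V)
  if (any(tv <= 0)) stop_ts("zero implied variance at a visit")
  std2 <- function(m) sweep(m^2, 1, tv, `/`)
  A <- std2(paths$a); C <- std2(paths$c); E <- std2(paths$e)
  dimnames(A) <- list(paste0("visit", 1:v), paste0("A", 1:v))
  dimnames(C) <- list(paste0("visit", 1:v), paste0("C", 1:v))
  dimnames(E) <- list(paste0("visit", 1:v), paste0("E", 1:v))
  structure(list(A = A, C = C, E = E, table = cbind(A, C, E),
                 visit_totals = rowSums(A) + rowSums(C) + rowSums(E)),
            class = "ace_std")
}

#' @export
print.ace_std <- function(x, ...) {
  print(round(x$table, 3))
  invisible(x)
}

# squared standardized coefficient as a smooth function of the raw
# parameter vector, for profiling
ace_coef_fun <- function(fac, model, component, i, j) {
  v <- fac$v; L <- fac$L; n_a <- fac$n_a
  offs <- switch(component, a = 0L, c = n_a, e = n_a + L)
  if (component == "a" && model == "CE")
    stop_ts("CE model has no additive genetic paths")
  pos <- match((j - 1L) * v + i, lt_index(v))
  if (is.na(pos)) stop_ts("requested coefficient is not lower-triangular")
  function(th) {
    p_a <- if (model == "ACE") lt_vec_to_mat(th[seq_len(L)], v) else
      matrix(0, v, v)
    p_c <- lt_vec_to_mat(th[n_a + seq_len(L)], v)
    p_e <- lt_vec_to_mat(th[n_a + L + seq_len(L)], v)
    tv <- sum(p_a[i, ]^2 + p_c[i, ]^2 + p_e[i, ]^2)
    if (tv <= 0) return(NA_real_)
    th[offs + pos]^2 / tv
  }
}

#' Profile-likelihood confidence intervals for standardized coefficients
#'
#' Intervals for the squared standardized path coefficients on the
#' proportion-of-variance scale, obtained by profiling the likelihood:
#' a bound is the coefficient value at which the profiled -2
#' log-likelihood rises by the chi-squared(1) quantile of the requested
#' level.  The constrained refits use a quadratic penalty pinning the
#' coefficient, warm-started along a bisection search.  Intervals are
#' clipped to `[0, 1]`; estimates at 0 are flagged as boundary cases
#' with a lower bound of exactly 0.
#'
#' @param fit A converged `"cholesky_ace"` fit.
#' @param level Confidence level.
#' @param coefficients Optional `data.frame` with columns `component`
#'   (`"a"`, `"c"`, `"e"`), `visit` (row index) and `factor` (column
#'   index) selecting which coefficients to profile; default all
#'   lower-triangular cells.
#' @param tol Bisection tolerance on the proportion scale.
#' @return `data.frame` with columns `component`, `visit`, `factor`,
#'   `label`, `estimate`, `lower`, `upper`, `boundary`.
#' @export
confidence_intervals <- function(fit, level = 0.95, coefficients = NULL,
                                 tol = 0.005) {
  stopifnot(inherits(fit, "cholesky_ace"))
  fac <- fit$factory; bd <- fit$bounds
  v <- fac$v
  if (is.null(coefficients)) {
    idx <- which(lower.tri(diag(v), diag = TRUE), arr.ind = TRUE)
    comps <- if (fit$model == "ACE") c("a", "c", "e") else c("c", "e")
    coefficients <- do.call(rbind, lapply(comps, function(cm)
      data.frame(component = cm, visit = idx[, 1], factor = idx[, 2])))
  }
  qcrit <- stats::qchisq(level, df = 1)
  w <- 2e5
  m2ll0 <- fit$minus2LL
  out <- vector("list", nrow(coefficients))
  for (r in seq_len(nrow(coefficients))) {
    cm <- as.character(coefficients$component[r])
    i <- coefficients$visit[r]; j <- coefficients$factor[r]
    gfun <- ace_coef_fun(fac, fit$model, cm, i, j)
    ghat <- gfun(fit$par)
    prof <- function(t0, start) {
      pen <- function(th) {
        g <- gfun(th)
        if (is.na(g)) return(1e10)
        fac$obj(th) + w * (g - t0)^2
      }
      f <- tryCatch(
        stats::optim(start, pen, method = "L-BFGS-B", lower = bd$lower,
                     upper = bd$upper,
                     control = list(maxit = 150, factr = 1e9)),
        error = function(e) list(value = Inf, par = start))
      list(excess = f$value - m2ll0, par = f$par)
    }
    # trace the profile outwards with warm starts, then refine by
    # bisection once the chi-squared threshold is bracketed
    search_bound <- function(direction) {
      limit <- if (direction > 0) 1 else 0
      step <- 0.04
      t_in <- ghat; par0 <- fit$par
      bracket <- NULL
      for (it in 1:40) {
        t_out <- t_in + direction * step
        if ((direction > 0 && t_out >= limit) ||
            (direction < 0 && t_out <= limit)) {
          p <- prof(limit, par0)
          if (p$excess < qcrit) return(list(bound = limit, boundary = TRUE))
          bracket <- c(t_in, limit); break
        }
        p <- prof(t_out, par0)
        if (p$excess >= qcrit) { bracket <- c(t_in, t_out); break }
        t_in <- t_out; par0 <- p$par
      }
      if (is.null(bracket)) return(list(bound = t_in, boundary = TRUE))
      lo <- bracket[1]; hi <- bracket[2]
      while (abs(hi - lo) > tol) {
        mid <- (lo + hi) / 2
        p <- prof(mid, par0)
        par0 <- p$par
        if (p$excess < qcrit) lo <- mid else hi <- mid
      }
      list(bound = (lo + hi) / 2, boundary = FALSE)
    }
    up <- search_bound(+1)
    lo <- if (ghat <= tol) list(bound = 0, boundary = TRUE)
    else search_bound(-1)
    out[[r]] <- data.frame(
      component = cm, visit = i, factor = j,
      label = paste0(toupper(cm), j, "@visit", i),
      estimate = ghat,
      lower = max(0, min(lo$bound, ghat)),
      upper = min(1, max(up$bound, ghat)),
      boundary = lo$boundary || up$boundary,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Saturated multivariate-normal fit of twin-pair data
#'
#' Unstructured per-zygosity means and covariances (the least
#' constrained comparison model); closed-form maximum likelihood.
#'
#' @param pairs A `"twin_pairs"` object.
#' @return List with `minus2LL`, per-group `mean` and `cov`, and `npar`.
#' @export
fit_saturated <- function(pairs) {
  gstats <- pair_group_stats(pairs)
  k <- 2L * pairs$n_visits
  m2ll <- 0; means <- list(); covs <- list(); npar <- 0
  for (g in names(gstats)) {
    st <- gstats[[g]]
    ld <- determinant(st$S, logarithm = TRUE)
    if (ld$sign <= 0) stop_ts("singular sample covariance in group ", g)
    m2ll <- m2ll + st$n * (k * log(2 * pi) + as.numeric(ld$modulus) + k)
    means[[g]] <- st$xbar; covs[[g]] <- st$S
    npar <- npar + k + k * (k + 1) / 2
  }
  list(minus2LL = m2ll, means = means, covs = covs, npar = npar)
}
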