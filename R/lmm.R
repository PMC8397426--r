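#' Fit the per-bin variance-components mixed model
#'
#' Fits, for one metabolomic bin, the linear mixed model
#' `y_ij = mu + x'beta + B_ij + F_j + e`, with a random intercept for
#' the individual (`B_ij`, variance `sigma_B^2`, the stable "usual
#' level"), a random intercept for the family (`F_j`, variance
#' `sigma_F^2`, unobserved familial heterogeneity shared by co-twins)
#' and residual visit-to-visit noise (variance `sigma_W^2`).  Fixed
#' effects come from the model formula; `value ~ 1` is the unadjusted
#' (null) decomposition and `value ~ age + sex + ffm + hei` the
#' covariate-adjusted one.
#'
#' Estimation maximises the exact multivariate-normal likelihood over
#' the three variance components with the fixed effects profiled out by
#' generalised least squares; components are constrained non-negative
#' by bounded optimisation (never truncated after the fact).  REML is
#' the default for reported components; ML is used for likelihood-ratio
#' tests.  Unbalanced visit counts are handled; each family forms an
#' independent block.
#'
#' @param formula Model formula, e.g. `value ~ 1` or
#'   `value ~ age + sex + ffm + hei`.  All right-hand-side variables
#'   must be columns of `data`.
#' @param data Long `data.frame` with one row per observation and
#'   columns for the response, covariates, and the grouping identifiers.
#' @param individual,family Names of the individual and family id
#'   columns.
#' @param method `"REML"` (default) or `"ML"`.
#' @return Object of class `"bin_lmm"` with components, fixed effects,
#'   the optimised criterion, and the model frame (for refits).
#' @seealso [compute_icc()], [test_covariates()], [covariate_r2()]
#' @export
#' @examples
#' coh <- generate_cohort(cohort_design(n_mz_pairs = 8, n_dz_pairs = 4))
#' tab <- simulate_bin_values(coh,
#'   ace_paths(a = cbind(c(.5,.5,.5), 0, 0), e = 0.7 * diag(3)), seed = 2)
#' d <- merge(tab, coh, by = "individual_id")
#' fit <- fit_bin_lmm(value ~ 1, d)
#' fit$components
fit_bin_lmm <- function(formula, data, individual = "individual_id",
                        family = "family_id",
                        method = c("REML", "ML"), start = NULL) {
  method <- match.arg(method)
  struct <- build_lmm_struct(formula, data, individual, family)
  est <- fit_lmm_core(struct, method, start = start)
  out <- structure(list(
    components = est$components,
    fixed_effects = est$beta,
    fixed_se = est$se,
    criterion = est$value,
    method = method,
    n_obs = struct$n,
    formula = formula,
    covariates = struct$covariates,
    struct = struct,
    convergence = est$convergence
  ), class = "bin_lmm")
  out
}

#' @export
print.bin_lmm <- function(x, ...) {
  cat(sprintf("Variance-components mixed model (%s), %d observations\n",
              x$method, x$n_obs))
  cmp <- x$components
  cat(sprintf("  sigma_B^2 = %.4f  sigma_F^2 = %.4f  sigma_W^2 = %.4f\n",
              cmp[["sigma_B2"]], cmp[["sigma_F2"]], cmp[["sigma_W2"]]))
  cat(sprintf("  total = %.4f   ICC = %.3f\n", cmp[["sigma_T2"]],
              compute_icc(x)))
  if (length(x$fixed_effects) > 1) {
    cat("  fixed effects:\n")
    print(round(x$fixed_effects, 4))
  }
  invisible(x)
}

#' @export
summary.bin_lmm <- function(object, ...) {
  tab <- cbind(estimate = object$fixed_effects, se = object$fixed_se)
  res <- list(components = object$components, icc = compute_icc(object),
              fixed = tab, method = object$method, n_obs = object$n_obs)
  class(res) <- "summary.bin_lmm"
  res
}

#' @export
print.summary.bin_lmm <- function(x, ...) {
  cat(sprintf("Mixed-model variance decomposition (%s, n = %d)\n",
              x$method, x$n_obs))
  print(round(rbind(x$components), 4))
  cat(sprintf("ICC = %.4f\n", x$icc))
  cat("Fixed effects:\n"); print(round(x$fixed, 4))
  invisible(x)
}

#' @export
coef.bin_lmm <- function(object, ...) object$fixed_effects

#' @export
logLik.bin_lmm <- function(object, ...) {
  val <- -object$criterion / 2
  attr(val, "df") <- length(object$fixed_effects) + 3
  attr(val, "method") <- object$method
  class(val) <- "logLik"
  val
}

# ---- internal machinery ----------------------------------------------------

build_lmm_struct <- function(formula, data, individual, family) {
  vars <- all.vars(formula)
  miss <- setdiff(c(vars, individual, family), names(data))
  if (length(miss))
    stop_ts("data is missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ind <- as.character(data[[individual]])
  fam <- as.character(data[[family]])
  if (length(unique(fam)) < 2)
    stop_ts("need at least 2 families")
  vis_per_ind <- table(ind)
  if (max(vis_per_ind) < 2)
    stop_ts("non-identifiable: no individual has repeated visits")
  # condition check on (scaled) design
  if (ncol(X) > 1) {
    Xs <- scale(X[, -1, drop = FALSE])
    Xs[is.nan(Xs)] <- 0
    sv <- svd(cbind(1, Xs))$d
    if (sv[length(sv)] < 1e-8 * sv[1])
      stop_ts("collinear covariates: design condition number too large")
  }
  # order rows family-major, individual within family
  o <- order(fam, ind)
  y <- y[o]; X <- X[o, , drop = FALSE]; ind <- ind[o]; fam <- fam[o]
  fam_rle <- rle(fam)
  fam_sizes <- fam_rle$lengths
  # pattern signature per family: visit counts per member
  starts <- cumsum(c(1, fam_sizes))[seq_along(fam_sizes)]
  pat <- character(length(fam_sizes))
  for (j in seq_along(fam_sizes)) {
    rows <- seq(starts[j], length.out = fam_sizes[j])
    pat[j] <- paste(rle(ind[rows])$lengths, collapse = ",")
  }
  upat <- unique(pat)
  groups <- lapply(upat, function(pp) {
    fams <- which(pat == pp)
    counts <- as.integer(strsplit(pp, ",")[[1]])
    s <- sum(counts)
    rows <- unlist(lapply(fams, function(j)
      seq(starts[j], length.out = fam_sizes[j])))
    list(counts = counts, s = s, K = length(fams), rows = rows)
  })
  list(y = y, X = X, groups = groups, n = length(y), p = ncol(X),
       covariates = setdiff(colnames(X), "(Intercept)"),
       individual = ind, family = fam)
}

# family covariance for a member-visit-count pattern
pattern_sigma <- function(counts, sB, sF, sW) {
  s <- sum(counts)
  Sg <- matrix(sF, s, s)
  at <- 1L
  for (nv in counts) {
    idx <- at:(at + nv - 1L)
    Sg[idx, idx] <- Sg[idx, idx] + sB
    at <- at + nv
  }
  diag(Sg) <- diag(Sg) + sW
  Sg
}

# -2 log-likelihood (ML) or REML criterion, fixed effects profiled by GLS
lmm_neg2ll <- function(theta, struct, method) {
  sB <- theta[1]; sF <- theta[2]; sW <- theta[3]
  y <- struct$y; X <- struct$X; p <- struct$p; n <- struct$n
  logdet <- 0
  XtWX <- matrix(0, p, p); XtWy <- numeric(p); ytWy <- 0
  wy_list <- vector("list", length(struct$groups))
  wx_list <- vector("list", length(struct$groups))
  for (gi in seq_along(struct$groups)) {
    g <- struct$groups[[gi]]
    Sg <- pattern_sigma(g$counts, sB, sF, sW)
    L <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(L)) return(list(value = 1e10))
    logdet <- logdet + 2 * g$K * sum(log(diag(L)))
    Ym <- matrix(y[g$rows], g$s, g$K)
    Wy <- backsolve(L, Ym, transpose = TRUE)
    Xg <- X[g$rows, , drop = FALSE]
    # stack family design blocks side by side for one triangular solve
    Xm <- matrix(t(Xg), g$s * p, g$K)
    dim(Xm) <- c(p, g$s, g$K)
    Xm <- matrix(aperm(Xm, c(2, 1, 3)), g$s, p * g$K)
    Wx <- backsolve(L, Xm, transpose = TRUE)
    dim(Wx) <- c(g$s, p, g$K)
    WX <- matrix(aperm(Wx, c(1, 3, 2)), g$s * g$K, p)
    wyv <- as.vector(Wy)
    XtWX <- XtWX + crossprod(WX)
    XtWy <- XtWy + drop(crossprod(WX, wyv))
    ytWy <- ytWy + sum(wyv^2)
    wy_list[[gi]] <- wyv; wx_list[[gi]] <- WX
  }
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10))
  beta <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
  rss <- ytWy - 2 * sum(beta * XtWy) + drop(t(beta) %*% XtWX %*% beta)
  val <- n * log(2 * pi) + logdet + rss
  if (method == "REML")
    val <- val + 2 * sum(log(diag(ch))) - p * log(2 * pi)
  list(value = val, beta = beta, XtWX_chol = ch)
}

fit_lmm_core <- function(struct, method, start = NULL) {
  obj <- function(th) lmm_neg2ll(th, struct, method)$value
  vt <- stats::var(stats::lm.fit(struct$X, struct$y)$residuals)
  if (!is.finite(vt) || vt <= 0) vt <- stats::var(struct$y)
  if (!is.finite(vt) || vt <= 0) vt <- 1e-6
  starts <- if (!is.null(start)) list(pmax(start[1:3], 0))
  else list(vt * c(.25, .25, .5), vt * c(.05, .05, .9),
            vt * c(.45, .45, .1))
  best <- NULL
  for (s0 in starts) {
    f <- stats::nlminb(s0, obj, lower = c(0, 0, 1e-12),
                       upper = rep(vt * 50 + 1, 3),
                       control = list(iter.max = 300))
    if (is.null(best) || f$objective < best$objective) best <- f
  }
  th <- best$par
  fin <- lmm_neg2ll(th, struct, method)
  beta <- drop(fin$beta); names(beta) <- colnames(struct$X)
  Vb <- chol2inv(fin$XtWX_chol)
  se <- sqrt(pmax(diag(Vb), 0)); names(se) <- names(beta)
  comps <- c(sigma_B2 = th[1], sigma_F2 = th[2], sigma_W2 = th[3],
             sigma_T2 = sum(th))
  list(components = comps, beta = beta, se = se, value = fin$value,
       convergence = best$convergence)
}

#' Intraclass correlation from variance components
#'
#' The ICC is the proportion of total biological variance due to
#' between-individual plus between-family variation,
#' `(sigma_B^2 + sigma_F^2) / (sigma_B^2 + sigma_F^2 + sigma_W^2)`:
#' the fraction of variance that is stable across repeat visits.
#'
#' @param x A `"bin_lmm"` fit, or a named vector/list with elements
#'   `sigma_B2`, `sigma_F2`, `sigma_W2`.
#' @return ICC in `[0, 1]`.
#' @export
#' @examples
#' compute_icc(c(sigma_B2 = 1, sigma_F2 = 1, sigma_W2 = 1))  # 2/3
compute_icc <- function(x) {
  if (inherits(x, "bin_lmm")) x <- x$components
  x <- as.list(x)
  sB <- x$sigma_B2; sF <- x$sigma_F2; sW <- x$sigma_W2
  stopifnot(is.numeric(sB), is.numeric(sF), is.numeric(sW))
  if (any(c(sB, sF, sW) < 0)) stop_ts("variance components must be >= 0")
  tot <- sB + sF + sW
  if (tot <= 0) stop_ts("ICC undefined: total variance is zero")
  (sB + sF) / tot
}

#' Proportion of total variance explained by one covariate
#'
#' The variance over observations of the covariate's fitted fixed-effect
#' contribution, as a percentage of the total variance defined as the
#' variance of the full fixed-effect predictor plus the three random
#' components.
#'
#' @param fit A `"bin_lmm"` covariate-model fit.
#' @param covariate Covariate name present in the fit.
#' @return Percentage in `[0, 100]`.
#' @export
covariate_r2 <- function(fit, covariate) {
  stopifnot(inherits(fit, "bin_lmm"))
  if (!covariate %in% fit$covariates)
    stop_ts("covariate '", covariate, "' is not in the fitted model")
  X <- fit$struct$X
  b <- fit$fixed_effects
  contrib <- X[, covariate] * b[[covariate]]
  fixed_all <- drop(X %*% b)
  denom <- stats::var(fixed_all) + sum(fit$components[c("sigma_B2",
                                                        "sigma_F2",
                                                        "sigma_W2")])
  if (denom <= 0) return(0)
  min(100, 100 * stats::var(contrib) / denom)
}

# ML refit dropping one covariate (or none); reuses the stored frame and
# warm-starts from the parent fit's variance components
refit_ml <- function(fit, drop = NULL) {
  covs <- setdiff(fit$covariates, drop)
  rhs <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  struct <- fit$struct
  df <- data.frame(.y = struct$y, struct$X[, -1, drop = FALSE],
                   individual_id = struct$individual,
                   family_id = struct$family,
                   check.names = FALSE, stringsAsFactors = FALSE)
  fit_bin_lmm(stats::as.formula(paste(".y ~", rhs)), df, method = "ML",
              start = fit$components[1:3])
}

#' Likelihood-ratio tests of covariates across bins with FDR control
#'
#' For every fitted bin and every covariate, compares the full
#' covariate model against the model with that covariate dropped, both
#' refitted by maximum likelihood, giving a 1-df likelihood-ratio
#' chi-squared p-value.  Benjamini-Hochberg adjustment is applied
#' across the whole bin-by-covariate family (or per covariate).
#'
#' @param fits Named list of `"bin_lmm"` covariate-model fits (names =
#'   bin labels), or a single fit.
#' @param fdr Significance cutoff on the adjusted p-value.
#' @param family `"joint"` (default: all bins x covariates adjusted
#'   together) or `"per_covariate"`.
#' @return `data.frame` with columns `bin`, `covariate`, `beta`,
#'   `p_value`, `q_value`, `r2`, `significant`.
#' @export
test_covariates <- function(fits, fdr = 0.05,
                            family = c("joint", "per_covariate")) {
  family <- match.arg(family)
  if (inherits(fits, "bin_lmm")) fits <- list(bin = fits)
  if (!length(fits)) stop_ts("no fits supplied")
  if (is.null(names(fits))) names(fits) <- seq_along(fits)
  rows <- list()
  for (bn in names(fits)) {
    fit <- fits[[bn]]
    stopifnot(inherits(fit, "bin_lmm"))
    if (!length(fit$covariates))
      stop_ts("fit for bin ", bn, " has no covariates to test")
    full <- if (fit$method == "ML") fit else refit_ml(fit)
    for (cv in fit$covariates) {
      red <- refit_ml(fit, drop = cv)
      lrt <- max(0, red$criterion - full$criterion)
      p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = bn, covariate = cv, beta = fit$fixed_effects[[cv]],
        p_value = p, r2 = covariate_r2(fit, cv),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (family == "joint") {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$q_value <- NA_real_
    for (cv in unique(out$covariate)) {
      i <- out$covariate == cv
      out$q_value[i] <- stats::p.adjust(out$p_value[i], method = "BH")
    }
  }
  out$significant <- out$q_value < fdr
  out[, c("bin", "covariate", "beta", "p_value", "q_value", "r2",
          "significant")]
}
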