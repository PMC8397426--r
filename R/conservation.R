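#' Baseline-to-follow-up profile correlation matrix
#'
#' Entry (i, j) is the Pearson correlation, across the selected bins,
#' between individual i's baseline profile and individual j's follow-up
#' profile; the diagonal holds each individual's own (intraindividual)
#' correlation.  When per-bin weights are supplied, the weighted
#' Pearson correlation is used (weighted means, variances and
#' covariance across bins).
#'
#' @param baseline,followup Numeric matrices, individuals in rows and
#'   bins in columns, sharing row and column names.
#' @param bins Optional subset of bin labels (column names) to use.
#' @param weights Optional non-negative per-bin weights, named by bin.
#' @return N x N matrix of correlations with individual ids as
#'   dimnames (not symmetric in general).
#' @export
#' @examples
#' b <- matrix(rnorm(12), 3, 4, dimnames = list(letters[1:3], 1:4))
#' diag(profile_correlations(b, b))
profile_correlations <- function(baseline, followup, bins = NULL,
                                 weights = NULL) {
  stopifnot(is.matrix(baseline), is.matrix(followup))
  if (!identical(rownames(baseline), rownames(followup)))
    stop_ts("baseline and follow-up must share individuals (row names)")
  if (!identical(colnames(baseline), colnames(followup)))
    stop_ts("baseline and follow-up must share bins (column names)")
  if (!is.null(bins)) {
    bins <- as.character(bins)
    miss <- setdiff(bins, colnames(baseline))
    if (length(miss))
      stop_ts("bins not present: ", paste(utils::head(miss, 5),
                                          collapse = ", "))
    baseline <- baseline[, bins, drop = FALSE]
    followup <- followup[, bins, drop = FALSE]
  }
  if (ncol(baseline) < 3) stop_ts("need at least 3 bins")
  if (is.null(weights)) {
    w <- rep(1, ncol(baseline))
  } else {
    w <- if (!is.null(names(weights))) {
      unname(weights[colnames(baseline)])
    } else weights
    if (length(w) != ncol(baseline) || any(is.na(w)))
      stop_ts("weights must cover every selected bin")
    if (any(w < 0)) stop_ts("weights must be non-negative")
    if (sum(w > 0) < 3) stop_ts("need at least 3 positive weights")
  }
  w <- w / sum(w)
  center <- function(m) m - drop(m %*% w)
  Bc <- center(baseline); Fc <- center(followup)
  sdw <- function(mc) sqrt(drop(mc^2 %*% w))
  sb <- sdw(Bc); sf <- sdw(Fc)
  if (any(sb == 0))
    stop_ts("zero-variance baseline profile for individual(s): ",
            paste(utils::head(rownames(baseline)[sb == 0], 5),
                  collapse = ", "))
  if (any(sf == 0))
    stop_ts("zero-variance follow-up profile for individual(s): ",
            paste(utils::head(rownames(followup)[sf == 0], 5),
                  collapse = ", "))
  covw <- Bc %*% (w * t(Fc))
  M <- covw / outer(sb, sf)
  dimnames(M) <- list(rownames(baseline), rownames(baseline))
  M
}

conservation_band <- function(index) {
  ifelse(index == 1, "1.00",
         ifelse(index >= 0.90, "0.90-0.99",
                ifelse(index >= 0.70, "0.70-0.89", "<0.70")))
}

#' Metabolome conservation indices
#'
#' For each individual i, the intraindividual correlation (diagonal
#' entry of the profile correlation matrix) is ranked against the
#' correlations of individual i's baseline profile with every
#' individual's follow-up profile (row i, descending, average ranks on
#' ties), and the conservation index is `1 - (rank - 1) / (N - 1)`:
#' 1 means the individual is most similar to themselves over time.
#' Indices are assigned to the reporting bands `1.00` (exactly 1),
#' `0.90-0.99`, `0.70-0.89` and `<0.70`.
#'
#' @param M Profile correlation matrix from [profile_correlations()].
#' @param individuals Optional subset of individual ids (default all).
#' @return `data.frame` with columns `individual_id`,
#'   `intra_correlation`, `rank`, `N`, `index`, `band`.
#' @export
#' @examples
#' M <- diag(0.9, 3) + 0.1
#' dimnames(M) <- list(letters[1:3], letters[1:3])
#' conservation_index(M)
conservation_index <- function(M, individuals = NULL) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  N <- nrow(M)
  if (N < 2) stop_ts("need at least 2 individuals")
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(N))
  if (is.null(individuals)) individuals <- ids
  out <- lapply(individuals, function(id) {
    i <- match(id, ids)
    if (is.na(i)) stop_ts("unknown individual: ", id)
    row <- M[i, ]
    if (any(!is.finite(row)))
      stop_ts("non-finite correlation in row for individual ", id)
    rk <- rank(-row, ties.method = "average")[i]
    idx <- 1 - (rk - 1) / (N - 1)
    data.frame(individual_id = id, intra_correlation = unname(M[i, i]),
               rank = unname(rk), N = N, index = unname(idx),
               band = conservation_band(idx), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Covariate-adjusted longitudinal bin weights
#'
#' For every bin, the Pearson correlation between its baseline and
#' follow-up values across individuals, adjusted for covariates by
#' residualising both time points on the covariate design (a partial
#' correlation); negative correlations are clipped to 0 since a
#' negative test-retest correlation carries no conservation signal.
#'
#' @param baseline,followup Individual-by-bin matrices sharing
#'   dimnames.
#' @param covariates Optional `data.frame`/matrix of covariates (rows
#'   aligned with the individuals); `NULL` gives plain correlations.
#' @return Named numeric weight vector in `[0, 1]`, with attribute
#'   `clipped` naming bins whose negative correlation was clipped.
#' @export
longitudinal_bin_weights <- function(baseline, followup, covariates = NULL) {
  stopifnot(is.matrix(baseline), is.matrix(followup),
            identical(dim(baseline), dim(followup)))
  n <- nrow(baseline)
  if (n < 8) stop_ts("need at least 8 individuals")
  if (!is.null(covariates)) {
    Z <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    if (nrow(Z) != n) stop_ts("covariates must have one row per individual")
    if (qr(Z)$rank < ncol(Z)) stop_ts("singular covariate design")
    resid_all <- function(m) stats::lm.fit(Z, m)$residuals
    baseline <- resid_all(baseline)
    followup <- resid_all(followup)
  }
  r <- vapply(seq_len(ncol(baseline)), function(j)
    stats::cor(baseline[, j], followup[, j]), 1)
  names(r) <- colnames(baseline)
  clipped <- names(r)[!is.na(r) & r < 0]
  r[is.na(r)] <- 0
  w <- pmin(1, pmax(r, 0))
  if (all(w == 0)) stop_ts("no bin has a positive longitudinal correlation")
  attr(w, "clipped") <- clipped
  w
}

#' Summarise conservation indices by band
#'
#' @param results `data.frame` from [conservation_index()], or a
#'   numeric vector of indices.
#' @return `data.frame` with `band`, `n`, `percent` over the four
#'   reporting bands.
#' @export
summarize_conservation <- function(results) {
  idx <- if (is.data.frame(results)) results$index else as.numeric(results)
  if (!length(idx)) stop_ts("no conservation results")
  bands <- c("1.00", "0.90-0.99", "0.70-0.89", "<0.70")
  bd <- factor(conservation_band(idx), levels = bands)
  tab <- table(bd)
  data.frame(band = bands, n = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(idx), 1))
}
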