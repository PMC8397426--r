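#' Lower-triangular ACE path specification
#'
#' Bundles the three lower-triangular path matrices of a longitudinal
#' Cholesky ACE model: additive genetic (`a`), shared environmental
#' (`c`) and unique environmental (`e`) paths over `n_visits` occasions.
#' The implied within-person covariance across visits is
#' `a %*% t(a) + c %*% t(c) + e %*% t(e)`; the cross-twin covariance is
#' `A + C` for MZ pairs and `dz_genetic * A + C` for DZ pairs, where
#' `A = a %*% t(a)` and `C = c %*% t(c)`.
#'
#' Scalars are expanded to `x * diag(n_visits)`.
#'
#' @param a,c,e Lower-triangular `n_visits x n_visits` matrices (or
#'   scalars, expanded to scaled identities).
#' @param dz_genetic Fraction of additive genetic variance shared by DZ
#'   co-twins; 0.5 under the classic twin design.
#' @param n_visits Number of visits; inferred from matrix inputs.
#' @return An object of class `"ace_paths"`.
#' @export
#' @examples
#' p <- ace_paths(a = sqrt(0.5), c = 0, e = sqrt(0.5))
#' implied_covariance(p)
ace_paths <- function(a = 0, c = 0, e = 1, dz_genetic = 0.5, n_visits = 3) {
  expand <- function(x) {
    if (is.matrix(x)) x else x * diag(n_visits)
  }
  if (is.matrix(a)) n_visits <- nrow(a)
  else if (is.matrix(c)) n_visits <- nrow(c)
  else if (is.matrix(e)) n_visits <- nrow(e)
  a <- expand(a); c <- expand(c); e <- expand(e)
  for (m in list(a, c, e)) {
    if (!is.matrix(m) || nrow(m) != n_visits || ncol(m) != n_visits)
      stop_ts("path matrices must all be ", n_visits, "x", n_visits)
    if (any(m[upper.tri(m)] != 0))
      stop_ts("path matrices must be lower-triangular")
    if (any(!is.finite(m)))
      stop_ts("path matrices must be finite")
  }
  if (!is.numeric(dz_genetic) || dz_genetic < 0 || dz_genetic > 1)
    stop_ts("dz_genetic must lie in [0, 1]")
  structure(list(a = a, c = c, e = e, dz_genetic = dz_genetic,
                 n_visits = n_visits),
            class = "ace_paths")
}

#' @export
print.ace_paths <- function(x, ...) {
  cat(sprintf("ACE Cholesky paths over %d visits (DZ genetic coefficient %.2f)\n",
              x$n_visits, x$dz_genetic))
  V <- implied_covariance(x)
  cat("implied per-visit variances:",
      paste(sprintf("%.3f", diag(V)), collapse = ", "), "\n")
  invisible(x)
}

#' Implied within-person covariance of an ACE path specification
#'
#' @param paths An [ace_paths()] object.
#' @return The `n_visits x n_visits` matrix
#'   `a %*% t(a) + c %*% t(c) + e %*% t(e)`.
#' @export
implied_covariance <- function(paths) {
  stopifnot(inherits(paths, "ace_paths"))
  tcrossprod(paths$a) + tcrossprod(paths$c) + tcrossprod(paths$e)
}

# cross-twin covariance block for a zygosity group
cross_twin_block <- function(paths, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  A <- tcrossprod(paths$a); C <- tcrossprod(paths$c)
  if (zygosity == "MZ") A + C else paths$dz_genetic * A + C
}

#' Expected twin-pair covariance under an ACE model
#'
#' Assembles the `2v x 2v` covariance of the stacked (twin 1, twin 2)
#' visit vectors implied by lower-triangular ACE paths: the within-twin
#' block is `V = A + C + E` and the cross-twin block is `A + C` (MZ) or
#' `dz_genetic * A + C` (DZ).
#'
#' @param paths An [ace_paths()] object or a fitted [fit_cholesky_ace()]
#'   model (its estimated paths are used).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return Symmetric positive semi-definite `2v x 2v` matrix.
#' @export
#' @examples
#' expected_covariance(ace_paths(a = sqrt(0.4), c = sqrt(0.3), e = sqrt(0.3),
#'                               n_visits = 1), "DZ")
expected_covariance <- function(paths, zygosity = c("MZ", "DZ")) {
  if (inherits(paths, "cholesky_ace")) paths <- paths$paths
  stopifnot(inherits(paths, "ace_paths"))
  zygosity <- match.arg(zygosity)
  if (any(!is.finite(paths$a)) || any(!is.finite(paths$c)) ||
      any(!is.finite(paths$e)))
    stop_ts("non-finite path parameters")
  V <- implied_covariance(paths)
  R <- cross_twin_block(paths, zygosity)
  rbind(cbind(V, R), cbind(t(R), V))
}
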