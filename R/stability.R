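#' Classify ICC values into stability bands
#'
#' Bands follow the conventional repeatability cutoffs: excellent
#' stability for ICC >= 0.75, good for 0.51-0.74, fair for 0.40-0.50
#' and poor below 0.40.  The printed band edges leave `[0.74, 0.75)`
#' and `[0.50, 0.51)` ambiguous; the implementation uses the half-open
#' partition poor = `[0, 0.40)`, fair = `[0.40, 0.51)`, good =
#' `[0.51, 0.75)`, excellent = `[0.75, 1]`, so every ICC in `[0, 1]`
#' receives exactly one band.
#'
#' @param icc Numeric vector of ICC values in `[0, 1]`.
#' @return Factor with levels `poor < fair < good < excellent`.
#' @export
#' @examples
#' classify_icc(c(0.39, 0.40, 0.645, 0.75))
classify_icc <- function(icc) {
  if (!is.numeric(icc) || any(!is.finite(icc)))
    stop_ts("icc must be finite numeric")
  if (any(icc < 0 | icc > 1))
    stop_ts("icc values must lie in [0, 1]")
  cut(icc, breaks = c(-Inf, 0.40, 0.51, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"),
      right = FALSE, ordered_result = TRUE)
}

#' Assemble the stable metabolome
#'
#' Selects the bins whose ICC reaches the stability cutoff (default
#' 0.51, the lower edge of the good band) and reports them sorted by
#' descending ICC (ties broken by ascending ppm), together with the
#' fraction of the analysed profile they represent.
#'
#' @param icc Named numeric vector of ICC values (names = bin ppm
#'   labels), or a `data.frame` with columns `bin_ppm` and `icc`.
#' @param cutoff Minimum ICC for stability.
#' @return Object of class `"stable_set"`: list with `bins` (sorted
#'   `data.frame` of stable bins), `n_stable`, `n_total`,
#'   `fraction_of_profile` (percent) and `cutoff`.
#' @export
#' @examples
#' s <- select_stable(c("3.35" = 0.645, "4.99" = 0.20, "1.71" = 0.62))
#' s$bins$bin_ppm
select_stable <- function(icc, cutoff = 0.51) {
  if (is.data.frame(icc)) {
    stopifnot(all(c("bin_ppm", "icc") %in% names(icc)))
    labs <- as.numeric(icc$bin_ppm); vals <- icc$icc
  } else {
    if (!length(icc)) stop_ts("empty ICC map")
    if (is.null(names(icc))) stop_ts("icc vector must be named by bin")
    labs <- as.numeric(names(icc)); vals <- as.numeric(icc)
  }
  if (!length(vals)) stop_ts("empty ICC map")
  if (any(!is.finite(vals))) stop_ts("non-finite ICC values")
  keep <- vals >= cutoff
  o <- order(-vals[keep], labs[keep])
  bins <- data.frame(bin_ppm = labs[keep][o], icc = vals[keep][o])
  structure(list(bins = bins, n_stable = nrow(bins),
                 n_total = length(vals),
                 fraction_of_profile = 100 * nrow(bins) / length(vals),
                 cutoff = cutoff),
            class = "stable_set")
}

#' @export
print.stable_set <- function(x, ...) {
  cat(sprintf(
    "stable metabolome: %d of %d bins (%.2f%%, ~%.0f%%) with ICC >= %.2f\n",
    x$n_stable, x$n_total, x$fraction_of_profile,
    round(x$fraction_of_profile), x$cutoff))
  if (x$n_stable) {
    cat("top bins:\n")
    print(utils::head(x$bins, 5), row.names = FALSE)
  }
  invisible(x)
}
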