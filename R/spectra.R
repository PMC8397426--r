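#' Chemical-shift bin grid
#'
#' Defines the fixed-width binning of a 1D NMR spectrum: by default 500
#' bins of 0.02 ppm covering 0.00-10.00 ppm, each labelled by its center
#' `c` and covering the half-open window `[c - width/2, c + width/2)`.
#' Excluded regions (by default the water/urea window 4.50-6.50 ppm,
#' removing 100 bins) are dropped from the analysed set but still binned.
#'
#' @param ppm_min,ppm_max Grid limits in ppm.
#' @param width Bin width in ppm.
#' @param exclude Two-column matrix (or length-2 vector) of `[lo, hi)`
#'   ppm intervals whose bins are excluded from analysis; `NULL` keeps
#'   all bins.
#' @return Object of class `"bin_grid"` with elements `edges`, `centers`,
#'   `retained` (logical), `width`.
#' @export
#' @examples
#' g <- bin_grid()
#' length(g$centers)        # 500
#' sum(g$retained)          # 400
bin_grid <- function(ppm_min = 0, ppm_max = 10, width = 0.02,
                     exclude = c(4.5, 6.5)) {
  stopifnot(ppm_max > ppm_min, width > 0)
  n <- (ppm_max - ppm_min) / width
  if (abs(n - round(n)) > 1e-8)
    stop_ts("grid width must divide the ppm range evenly")
  n <- round(n)
  edges <- ppm_min + width * (0:n)
  centers <- round((edges[-1] + edges[-(n + 1)]) / 2, 6)
  retained <- rep(TRUE, n)
  if (!is.null(exclude)) {
    if (!is.matrix(exclude)) exclude <- matrix(exclude, ncol = 2, byrow = TRUE)
    for (i in seq_len(nrow(exclude))) {
      lo <- exclude[i, 1]; hi <- exclude[i, 2]
      if (lo < ppm_min - 1e-9 || hi > ppm_max + 1e-9 || hi <= lo)
        stop_ts("excluded regions must be valid intervals inside the grid")
      retained[centers >= lo & centers < hi] <- FALSE
    }
  }
  structure(list(edges = edges, centers = centers, retained = retained,
                 width = width, exclude = exclude),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin grid: %d bins of %.3g ppm on [%.2f, %.2f]; %d retained\n",
              length(x$centers), x$width, min(x$edges), max(x$edges),
              sum(x$retained)))
  invisible(x)
}

#' Integrate a spectrum into fixed-width bins
#'
#' Computes the trapezoidal area of the spectrum inside every bin of the
#' grid.  All bins are returned (exclusion is applied downstream); the
#' result is named by the 2-decimal bin-center label.
#'
#' @param spectrum `data.frame` (or 2-column matrix) with columns `ppm`
#'   and `intensity`; the ppm axis must be strictly monotone and cover
#'   the grid.
#' @param grid A [bin_grid()].
#' @return Named numeric vector of bin areas, one per grid bin.
#' @export
#' @examples
#' sp <- data.frame(ppm = seq(10, 0, by = -0.01), intensity = 1)
#' b <- bin_spectrum(sp, bin_grid())
#' all(abs(b - 0.02) < 1e-9)
bin_spectrum <- function(spectrum, grid = bin_grid()) {
  spectrum <- as.data.frame(spectrum)
  if (!all(c("ppm", "intensity") %in% names(spectrum)))
    stop_ts("spectrum needs columns 'ppm' and 'intensity'")
  x <- spectrum$ppm; y <- spectrum$intensity
  if (is.unsorted(x, strictly = TRUE) && is.unsorted(rev(x), strictly = TRUE))
    stop_ts("spectrum ppm axis must be strictly monotone")
  if (x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
  lo <- min(grid$edges); hi <- max(grid$edges)
  if (x[1] > lo + 1e-9 || x[length(x)] < hi - 1e-9)
    stop_ts(sprintf(
      "spectrum does not cover the grid: data span [%.4f, %.4f], grid needs [%.2f, %.2f]",
      x[1], x[length(x)], lo, hi))
  edges <- grid$edges
  allx <- sort(unique(c(x, edges)))
  ally <- stats::approx(x, y, xout = allx, rule = 2)$y
  # cumulative trapezoid, then difference at bin edges
  ct <- c(0, cumsum(diff(allx) * (ally[-1] + ally[-length(ally)]) / 2))
  at_edges <- ct[match(edges, allx)]
  areas <- diff(at_edges)
  names(areas) <- sprintf("%.2f", grid$centers)
  areas
}

#' Bin a set of spectra into a sample-by-bin matrix
#'
#' @param spectra Named list of spectra (see [bin_spectrum()]).
#' @param grid A [bin_grid()].
#' @param retained_only Keep only non-excluded bins.
#' @return Matrix with one row per spectrum.
#' @export
bin_spectra <- function(spectra, grid = bin_grid(), retained_only = TRUE) {
  m <- t(vapply(spectra, function(s) bin_spectrum(s, grid),
                numeric(length(grid$centers))))
  if (retained_only) m <- m[, grid$retained, drop = FALSE]
  m
}

#' Normalize each sample to its total spectral integral
#'
#' Divides every row by its sum so each spectrum's retained bins sum to
#' one, removing overall concentration/acquisition scale differences.
#'
#' @param x Numeric matrix (rows = samples) or vector.
#' @return Object of the same shape with unit row sums.
#' @export
#' @examples
#' normalize_total_area(matrix(c(2, 2, 4), 1))
normalize_total_area <- function(x) {
  if (is.null(dim(x))) {
    s <- sum(x)
    if (s <= 0) stop_ts("sample has non-positive total area")
    return(x / s)
  }
  s <- rowSums(x)
  if (any(s <= 0))
    stop_ts("sample(s) with non-positive total area: ",
            paste(utils::head(which(s <= 0), 5), collapse = ", "))
  sweep(x, 1, s, `/`)
}

#' Simulate spectra from a bin table
#'
#' Inverse of the binning step, used to exercise the preprocessing stage
#' on data with known ground truth: each bin value is rendered as a
#' narrow triangular peak (base 0.012 ppm) centred inside its bin whose
#' integral equals the bin value, on a regular descending ppm axis, plus
#' optional Gaussian intensity noise (clipped at zero).  With zero noise
#' the round trip through [bin_spectrum()] recovers the bin values to
#' numerical quadrature accuracy, because every peak breakpoint lies on
#' the simulated ppm lattice.
#'
#' @param table Long bin table (see [simulate_bin_values()]).
#' @param peak_map Optional named numeric vector mapping the 2-decimal
#'   bin label to the peak center ppm (defaults to the bin center); all
#'   centers must lie in (0, 10).
#' @param noise_sd Gaussian intensity noise SD.
#' @param ppm_step Spacing of the simulated ppm axis.
#' @param seed Integer seed for the noise stream.
#' @return Named list of `data.frame(ppm, intensity)` spectra (ppm
#'   descending 10 to 0), one per `individual:visit` sample.
#' @export
simulate_spectra <- function(table, peak_map = NULL, noise_sd = 0,
                             ppm_step = 0.002, seed = 1L) {
  m <- bin_table_to_matrix(table)
  centers <- as.numeric(colnames(m))
  if (is.null(peak_map)) {
    peak <- centers
  } else {
    peak <- unname(peak_map[colnames(m)])
    if (any(is.na(peak))) stop_ts("peak_map must cover every bin label")
  }
  if (any(peak <= 0 | peak >= 10))
    stop_ts("peak centers must lie strictly inside (0, 10) ppm")
  half <- 0.006                       # triangular half-base, on-lattice
  ppm <- seq(10, 0, by = -ppm_step)
  np <- length(ppm)
  idx_of <- function(p) round((10 - p) / ppm_step) + 1
  out <- vector("list", nrow(m))
  names(out) <- rownames(m)
  for (i in seq_len(nrow(m))) {
    intensity <- numeric(np)
    for (k in seq_along(centers)) {
      val <- m[i, k]
      if (is.na(val) || val == 0) next
      j <- idx_of(peak[k] + half):idx_of(peak[k] - half)
      tri <- 1 - abs(ppm[j] - peak[k]) / half
      intensity[j] <- intensity[j] + val / half * pmax(tri, 0)
    }
    if (noise_sd > 0) {
      intensity <- with_seed(split_seed(seed, 5000L + i), {
        pmax(intensity + stats::rnorm(np, 0, noise_sd), 0)
      })
    }
    out[[i]] <- data.frame(ppm = ppm, intensity = intensity)
  }
  out
}

#' Write / read a spectrum CSV
#' @param spectrum `data.frame(ppm, intensity)`.
#' @param path File path.
#' @return `read_spectrum()` returns the `data.frame`.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(spectrum, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ppm", "intensity") %in% names(x)))
    stop_ts("spectrum file needs columns 'ppm' and 'intensity'")
  x
}
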