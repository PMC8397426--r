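#' Simulate longitudinal metabolomic bin values for a twin cohort
#'
#' Forward model for the whole analysis pipeline: for every bin, each
#' individual's visit vector is the sum of covariate fixed effects and
#' latent additive-genetic (A), shared-environmental (C) and
#' unique-environmental (E) draws generated from lower-triangular
#' Cholesky paths.  Co-twins share the C draw exactly; their A draws
#' correlate 1 (MZ) or `dz_genetic` (DZ); E draws are independent.  The
#' marginal within-person visit covariance therefore equals
#' `a a' + c c' + e e'` and the cross-twin covariance equals `A + C`
#' (MZ) or `dz_genetic A + C` (DZ).
#'
#' Each bin consumes its own derived RNG stream, so adding bins does not
#' perturb earlier bins or the cohort draws.
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @param paths An [ace_paths()] object, or a list of one per bin.
#' @param effects Optional covariate fixed effects: numeric vector with
#'   any of the names `age`, `sex`, `ffm`, `hei` (slopes on the bin
#'   scale), or an `n_bins x 4` matrix with those column names.  `NULL`
#'   means no covariate effects.
#' @param bins Bin labels (ppm centers, numeric); defaults to the first
#'   `n_bins` centers of the default 0.02-ppm grid.
#' @param n_bins Number of bins when `bins` is `NULL`.
#' @param seed Integer master seed.
#' @return Long-format `data.frame` with columns `individual_id`,
#'   `visit`, `bin_ppm`, `value`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_design(n_mz_pairs = 4, n_dz_pairs = 2))
#' tab <- simulate_bin_values(coh, ace_paths(e = 1), n_bins = 2, seed = 1)
#' head(tab)
simulate_bin_values <- function(cohort, paths, effects = NULL, bins = NULL,
                                n_bins = 1, seed = 1L) {
  if (!nrow(cohort)) stop_ts("cohort is empty")
  if (inherits(paths, "ace_paths")) paths <- list(paths)
  stopifnot(all(vapply(paths, inherits, TRUE, "ace_paths")))
  if (is.null(bins)) {
    n_bins <- max(n_bins, length(paths),
                  if (is.matrix(effects)) nrow(effects) else 0L)
    bins <- round(seq(0.01, by = 0.02, length.out = n_bins), 2)
  }
  n_bins <- length(bins)
  if (length(paths) == 1L) paths <- rep(paths, n_bins)
  if (length(paths) != n_bins)
    stop_ts("need one ace_paths per bin (or a single one recycled)")
  eff <- effect_matrix(effects, n_bins)

  v <- paths[[1]]$n_visits
  fam <- unique(cohort$family_id)
  n_fam <- length(fam)
  ord <- order(match(cohort$family_id, fam), cohort$twin_order)
  co <- cohort[ord, , drop = FALSE]
  if (!all(table(co$family_id) == 2L))
    stop_ts("every family must contain exactly two co-twins")
  zyg_fam <- co$zygosity[match(fam, co$family_id)]
  is_dz <- zyg_fam == "DZ"

  X <- as.matrix(co[, c("age", "sex", "ffm", "hei")])
  out <- vector("list", n_bins)
  for (k in seq_len(n_bins)) {
    p <- paths[[k]]
    if (p$n_visits != v) stop_ts("all bins must share n_visits")
    check_generator(p)
    vals <- with_seed(split_seed(seed, 1000L + k), {
      draw_pair_values(p, n_fam, is_dz)      # (2*n_fam) x v
    })
    fixed <- drop(X %*% eff[k, ])            # per individual
    vals <- vals + fixed
    out[[k]] <- data.frame(
      individual_id = rep(co$individual_id, times = v),
      visit = rep(seq_len(v), each = 2L * n_fam),
      bin_ppm = bins[k],
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

effect_matrix <- function(effects, n_bins) {
  nm <- c("age", "sex", "ffm", "hei")
  eff <- matrix(0, n_bins, 4, dimnames = list(NULL, nm))
  if (is.null(effects)) return(eff)
  if (is.matrix(effects) || is.data.frame(effects)) {
    effects <- as.matrix(effects)
    if (nrow(effects) != n_bins)
      stop_ts("effects matrix must have one row per bin")
    bad <- setdiff(colnames(effects), nm)
    if (length(bad)) stop_ts("unknown covariates: ", paste(bad, collapse = ", "))
    eff[, colnames(effects)] <- effects
  } else {
    bad <- setdiff(names(effects), nm)
    if (length(bad) || is.null(names(effects)))
      stop_ts("effects must be named with covariates among: ",
              paste(nm, collapse = ", "))
    for (j in names(effects)) eff[, j] <- effects[[j]]
  }
  if (any(!is.finite(eff))) stop_ts("covariate effects must be finite")
  eff
}

check_generator <- function(p) {
  V <- implied_covariance(p)
  if (any(diag(V) < 0) || min(eigen(V, symmetric = TRUE,
                                    only.values = TRUE)$values) < -1e-10)
    stop_ts("implied within-person covariance is not positive semi-definite")
  invisible(TRUE)
}

# latent ACE draws for n_fam twin pairs; returns (2*n_fam) x v matrix,
# rows interleaved (twin 1 of family 1, twin 2 of family 1, ...)
draw_pair_values <- function(p, n_fam, is_dz) {
  v <- p$n_visits
  rz <- function() matrix(stats::rnorm(n_fam * v), v, n_fam)
  zA1 <- rz(); zA2raw <- rz()
  rho <- ifelse(is_dz, p$dz_genetic, 1)
  zA2 <- sweep(zA1, 2, rho, `*`) +
    sweep(zA2raw, 2, sqrt(1 - rho^2), `*`)
  zC <- rz()
  zE1 <- rz(); zE2 <- rz()
  y1 <- t(p$a %*% zA1 + p$c %*% zC + p$e %*% zE1)
  y2 <- t(p$a %*% zA2 + p$c %*% zC + p$e %*% zE2)
  out <- matrix(0, 2L * n_fam, v)
  out[seq(1, 2L * n_fam, 2), ] <- y1
  out[seq(2, 2L * n_fam, 2), ] <- y2
  out
}

#' Reshape a long bin table to a sample-by-bin matrix
#'
#' @param table Long `data.frame` from [simulate_bin_values()] (columns
#'   `individual_id`, `visit`, `bin_ppm`, `value`).
#' @param visit Optional single visit to extract; `NULL` keeps all
#'   visits as separate rows.
#' @return Numeric matrix with rows named `individual_id` (single visit)
#'   or `individual_id:visit`, and columns named by the 2-decimal bin
#'   ppm label.
#' @export
bin_table_to_matrix <- function(table, visit = NULL) {
  if (!is.null(visit)) table <- table[table$visit == visit, , drop = FALSE]
  rid <- if (is.null(visit))
    paste(table$individual_id, table$visit, sep = ":")
  else table$individual_id
  cols <- sprintf("%.2f", sort(unique(table$bin_ppm)))
  rows <- unique(rid)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(rid, rows), match(sprintf("%.2f", table$bin_ppm), cols))] <-
    table$value
  m
}

#' Write / read a long bin table
#' @param table Long bin `data.frame`.
#' @param path File path.
#' @return `read_bin_table()` returns the long `data.frame`.
#' @export
write_bin_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bin_table
#' @export
read_bin_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "visit", "bin_ppm", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_ts("bin table is missing columns: ", paste(miss, collapse = ", "))
  x
}
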