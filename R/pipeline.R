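#' Pipeline configuration
#'
#' Flat configuration object controlling every stage of the end-to-end
#' analysis.  Defaults follow the reference protocol: 0.02-ppm bins on
#' 0-10 ppm with the 4.50-6.50 ppm water/urea window excluded,
#' stability cutoff 0.51, FDR 0.05, REML components, joint BH family,
#' 3 visits.
#'
#' @param n_mz_pairs,n_dz_pairs,n_visits Simulated cohort layout.
#' @param n_bins Number of simulated bins.
#' @param stable_fraction Fraction of simulated bins generated stable.
#' @param grid_width Bin width (ppm).
#' @param exclude_lo,exclude_hi Excluded ppm window.
#' @param cutoff Stability ICC cutoff.
#' @param fdr FDR level for covariate tests.
#' @param estimation `"REML"` or `"ML"` for reported components.
#' @param bh_family `"joint"` or `"per_covariate"`.
#' @param covariates Comma-separated covariates to adjust for.
#' @param sem_max_bins Number of top stable bins to model with the
#'   Cholesky ACE SEM.
#' @param sem_ci Compute profile-likelihood CIs in the SEM stage.
#' @param sem_restarts Optimiser restarts for the SEM stage.
#' @param conservation_method `"stable"`, `"weighted"` or `"both"`.
#' @param seed Master seed.
#' @return Object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(n_mz_pairs = 44, n_dz_pairs = 20, n_visits = 3,
                            n_bins = 40, stable_fraction = 0.2,
                            grid_width = 0.02,
                            exclude_lo = 4.5, exclude_hi = 6.5,
                            cutoff = 0.51, fdr = 0.05,
                            estimation = "REML", bh_family = "joint",
                            covariates = "age,sex,ffm,hei",
                            sem_max_bins = 10, sem_ci = FALSE,
                            sem_restarts = 2,
                            conservation_method = "both", seed = 1L) {
  cfg <- list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
              n_visits = n_visits, n_bins = n_bins,
              stable_fraction = stable_fraction, grid_width = grid_width,
              exclude_lo = exclude_lo, exclude_hi = exclude_hi,
              cutoff = cutoff, fdr = fdr, estimation = estimation,
              bh_family = bh_family, covariates = covariates,
              sem_max_bins = sem_max_bins, sem_ci = sem_ci,
              sem_restarts = sem_restarts,
              conservation_method = conservation_method,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  num <- c("n_mz_pairs", "n_dz_pairs", "n_visits", "n_bins",
           "stable_fraction", "grid_width", "exclude_lo", "exclude_hi",
           "cutoff", "fdr", "sem_max_bins", "sem_restarts", "seed")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || !is.finite(cfg[[f]]))
      stop_ts("config field '", f, "' must be numeric")
  if (!cfg$estimation %in% c("REML", "ML"))
    stop_ts("estimation must be REML or ML")
  if (!cfg$bh_family %in% c("joint", "per_covariate"))
    stop_ts("bh_family must be joint or per_covariate")
  if (!cfg$conservation_method %in% c("stable", "weighted", "both"))
    stop_ts("conservation_method must be stable, weighted or both")
  if (!is.logical(cfg$sem_ci)) stop_ts("sem_ci must be logical")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline configuration:\n")
  for (f in names(x)) cat(sprintf("  %s = %s\n", f, as.character(x[[f]])))
  invisible(x)
}

#' Write / read a pipeline configuration file
#'
#' Flat `key = value` text format; unknown keys are an error (fail
#' fast) and the round trip is lossless.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(f)
    sprintf("%s = %s", f, format(config[[f]], scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  dflt <- pipeline_config()
  unknown <- setdiff(keys, names(dflt))
  if (length(unknown))
    stop_ts("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- unclass(dflt)
  for (i in seq_along(keys)) {
    f <- keys[i]
    cfg[[f]] <- if (is.numeric(dflt[[f]])) as.numeric(vals[i])
    else if (is.logical(dflt[[f]])) as.logical(vals[i])
    else vals[i]
  }
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("n_mz_pairs", "n_dz_pairs", "n_visits", "n_bins",
              "sem_max_bins", "sem_restarts"))
    cfg[[f]] <- as.integer(cfg[[f]])
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

pipeline_covariates <- function(cfg) {
  cv <- trimws(strsplit(cfg$covariates, ",")[[1]])
  cv[nzchar(cv)]
}

#' Run the full twin metabolome stability pipeline
#'
#' Executes every stage on simulated data (or user-supplied cohort and
#' bin tables): cohort generation, bin-value simulation, per-bin
#' variance decomposition with covariate tests and ICC, stability
#' classification, longitudinal Cholesky ACE modelling of the top
#' stable bins, and conservation indices (stable-subset and/or
#' weighted variant).  All outputs are written as CSV under `out_dir`
#' together with a run manifest (package version, seed, config hash);
#' reruns with an identical config and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort,bins Optional pre-existing cohort and long bin table;
#'   `NULL` simulates both from the config.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `bins`, `icc`, `stable`, `sem`, `conservation`, `manifest_path`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".",
                         cohort = NULL, bins = NULL) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  covs <- pipeline_covariates(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ts("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  if (is.null(cohort)) {
    cohort <- stage("simulate-cohort",
      generate_cohort(cohort_design(config$n_mz_pairs, config$n_dz_pairs,
                                    config$n_visits, seed = config$seed)))
  }
  if (is.null(bins)) {
    gen <- stage("simulate-generators",
      default_bin_generators(config$n_bins, config$stable_fraction,
                             config$n_visits,
                             effects = c(age = 0.02, hei = 0.01),
                             seed = config$seed))
    bins <- stage("simulate-bins",
      simulate_bin_values(cohort, gen$paths, gen$effects,
                          seed = config$seed))
  }
  message("cohort: ", nrow(cohort), " individuals; bins: ",
          length(unique(bins$bin_ppm)))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  write_bin_table(bins, file.path(out_dir, "bins.csv"))

  icc <- stage("decompose",
    decompose_bins(bins, cohort, covariates = covs, fdr = config$fdr,
                   bh_family = config$bh_family,
                   method = config$estimation))
  utils::write.csv(as.data.frame(icc), file.path(out_dir, "icc.csv"),
                   row.names = FALSE, quote = FALSE)

  stable <- stage("classify",
    select_stable(stats::setNames(icc$icc, sprintf("%.2f", icc$bin_ppm)),
                  cutoff = config$cutoff))
  stab_df <- data.frame(bin_ppm = sprintf("%.2f", icc$bin_ppm),
                        icc = icc$icc, band = icc$band,
                        stable = as.integer(icc$icc >= config$cutoff))
  utils::write.csv(stab_df, file.path(out_dir, "stable.csv"),
                   row.names = FALSE, quote = FALSE)
  message("stable metabolome: ", stable$n_stable, "/", stable$n_total,
          " bins (", sprintf("%.1f", stable$fraction_of_profile), "%)")

  sem_bins <- utils::head(stable$bins$bin_ppm, config$sem_max_bins)
  sem <- stage("sem", {
    rows <- lapply(sem_bins, function(b) {
      pr <- suppressMessages(twin_pairs(bins, cohort, bin = b))
      fit <- fit_cholesky_ace(pr, restarts = config$sem_restarts)
      fmt_sem_rows(b, fit, if (config$sem_ci)
        confidence_intervals(fit) else NULL)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(bin_ppm = numeric(0))
  })
  utils::write.csv(sem, file.path(out_dir, "sem.csv"),
                   row.names = FALSE, quote = FALSE)

  conservation <- stage("conservation", {
    base_m <- johnsonised_matrix(bins, visit = 1)
    fup_m <- johnsonised_matrix(bins, visit = config$n_visits)
    out <- list()
    if (config$conservation_method %in% c("stable", "both")) {
      if (stable$n_stable >= 3) {
        M <- profile_correlations(base_m, fup_m,
                                  bins = sprintf("%.2f", stable$bins$bin_ppm))
        ci <- conservation_index(M)
        ci$method <- "stable"
        out$stable <- ci
      } else {
        message("fewer than 3 stable bins; stable-set conservation skipped")
      }
    }
    if (config$conservation_method %in% c("weighted", "both")) {
      cvd <- cohort[match(rownames(base_m), cohort$individual_id),
                    intersect(covs, c("age", "sex", "ffm", "hei")),
                    drop = FALSE]
      w <- longitudinal_bin_weights(base_m, fup_m,
                                    covariates = if (ncol(cvd)) cvd else NULL)
      M <- profile_correlations(base_m, fup_m, weights = w)
      ci <- conservation_index(M)
      ci$method <- "weighted"
      out$weighted <- ci
    }
    do.call(rbind, out)
  })
  utils::write.csv(conservation, file.path(out_dir, "conservation.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest_path <- file.path(out_dir, "manifest.txt")
  cfg_tmp <- tempfile()
  write_pipeline_config(config, cfg_tmp)
  cfg_hash <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  writeLines(c(
    sprintf("package_version = %s",
            as.character(utils::packageVersion("twinstable"))),
    sprintf("seed = %d", config$seed),
    sprintf("config_md5 = %s", cfg_hash),
    sprintf("n_individuals = %d", nrow(cohort)),
    sprintf("n_bins = %d", length(unique(bins$bin_ppm))),
    sprintf("n_stable = %d", stable$n_stable)
  ), manifest_path)

  invisible(list(cohort = cohort, bins = bins, icc = icc, stable = stable,
                 sem = sem, conservation = conservation,
                 manifest_path = manifest_path))
}

# per-visit matrix on the Johnson-transformed scale (per-bin transform)
johnsonised_matrix <- function(bins, visit) {
  m <- bin_table_to_matrix(bins, visit = visit)
  for (j in seq_len(ncol(m))) {
    mj <- suppressWarnings(try(johnson_transform(m[, j]), silent = TRUE))
    if (!inherits(mj, "try-error")) m[, j] <- as.numeric(mj)
  }
  m
}

# one report block (one row per visit) for a fitted bin
fmt_sem_rows <- function(bin, fit, ci = NULL) {
  std <- standardize_paths(fit)
  v <- fit$paths$n_visits
  fmt <- function(comp, i, j) {
    est <- std[[toupper(comp)]][i, j]
    if (j > i) return("")
    if (is.null(ci)) return(sprintf("%.2f", est))
    row <- ci[ci$component == comp & ci$visit == i & ci$factor == j, ]
    if (!nrow(row)) return(sprintf("%.2f", est))
    sprintf("%.2f (%.2f, %.2f)", est, row$lower, row$upper)
  }
  blocks <- lapply(seq_len(v), function(i) {
    vals <- c(lapply(seq_len(v), function(j) fmt("a", i, j)),
              lapply(seq_len(v), function(j) fmt("c", i, j)),
              lapply(seq_len(v), function(j) fmt("e", i, j)))
    names(vals) <- c(paste0("A", seq_len(v)), paste0("C", seq_len(v)),
                     paste0("E", seq_len(v)))
    data.frame(bin_ppm = sprintf("%.2f", bin), visit = i, vals,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  do.call(rbind, blocks)
}
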