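#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation so that independent stages (cohort
# draws, per-bin latent draws, spectral noise) consume independent RNG
# streams: adding bins never perturbs the cohort stream.  The mixing is
# deliberately nonlinear (iterated multiply + square modulo 2^31) so
# that arithmetic progressions of (seed, stream) do not map to
# arithmetic progressions of derived seeds, which would risk correlated
# generator states.  All derived seeds stay below 2^31 - 1.
split_seed <- function(seed, stream) {
  if (is.character(stream)) {
    cp <- utf8ToInt(stream)
    stream <- sum(cp * seq_along(cp))
  }
  stopifnot(is.finite(seed), is.finite(stream))
  m <- 2147483647
  mulmod <- function(a, b) {
    # exact (a * b) %% m in doubles: split b into 15-bit halves
    b1 <- b %/% 32768; b0 <- b %% 32768
    (((a * b1) %% m) * 32768 + a * b0) %% m
  }
  x <- abs(seed) %% m
  x <- (mulmod(x, 48271) + abs(stream)) %% m
  x <- mulmod(x, (x + 104729) %% m)
  x <- (mulmod(x, 69621) + 30011) %% m
  x <- mulmod(x, (x + 65537) %% m)
  as.integer(x)
}

# run expr with a local RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

stop_ts <- function(...) stop(..., call. = FALSE)

# lower-triangular (incl. diagonal) vectorisation helpers, column-major
lt_index <- function(k) which(lower.tri(diag(k), diag = TRUE))

lt_vec_to_mat <- function(v, k) {
  m <- matrix(0, k, k)
  m[lt_index(k)] <- v
  m
}

lt_mat_to_vec <- function(m) m[lt_index(nrow(m))]

# positions of diagonal entries inside the lower-triangular vector
lt_diag_pos <- function(k) {
  idx <- lt_index(k)
  match((seq_len(k) - 1L) * k + seq_len(k), idx)
}

sample_skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / (mean(x^2)^1.5)
}

sample_kurtosis_excess <- function(x) {
  x <- x - mean(x)
  mean(x^4) / (mean(x^2)^2) - 3
}
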