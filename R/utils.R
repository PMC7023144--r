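# internal helpers: unit constants, noise model, seed substreams, conditions

# nm -> cm; ug -> g
.NM_PER_CM <- 1e7
.UG_PER_G <- 1e6

#' @importFrom rlang abort warn %||%
NULL

abort_validation <- function(msg, field = NULL) {
  rlang::abort(msg, class = "ntx_validation_error", field = field)
}

abort_schema <- function(msg, missing = NULL) {
  rlang::abort(msg, class = "ntx_schema_error", missing = missing)
}

abort_insufficient <- function(msg) {
  rlang::abort(msg, class = "ntx_insufficient_data_error")
}

abort_degenerate <- function(msg) {
  rlang::abort(msg, class = "ntx_degenerate_data_error")
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
# sdlog^2 = log(1 + cv^2); meanlog = -sdlog^2/2 so E[noise] = 1 exactly.
rlnorm_cv <- function(n, cv) {
  if (cv < 0) abort_validation("noise_cv must be >= 0", field = "noise_cv")
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Counter-based substream seed: one base seed plus (particle, reporter)
# indices give a reproducible per-cell stream independent of row order.
# Kept strictly below 2^31 - 1.
substream_seed <- function(seed, i, j = 0L) {
  (as.numeric(seed) * 48271 + i * 65537 + j * 257) %% 2147483647
}

# columns `need` must be present in data frame `df` (named for error messages)
check_columns <- function(df, need, what = "input table") {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort_schema(
      paste0(what, " is missing required column(s): ",
             paste(miss, collapse = ", ")),
      missing = miss
    )
  }
  invisible(df)
}
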