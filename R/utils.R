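# Internal helpers shared across modules.

# Draw log-uniformly on [lo, hi]; lo must be > 0.
runif_log <- function(n, lo, hi) {
  stopifnot(lo > 0, hi >= lo)
  exp(runif(n, log(lo), log(hi)))
}

# Multiplicative log-normal noise with a given coefficient of variation.
# Parameterised so the expected multiplicative factor is exactly 1
# (mean-preserving): sdlog^2 = log(1 + cv^2), meanlog = -sdlog^2 / 2.
lognormal_factor <- function(n, cv) {
  if (cv < 0) abort("`cv` must be >= 0.")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Scoped RNG: run `code` under `seed` without disturbing the caller's RNG state.
with_rng <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    abort("A `seed` is required for simulation; pass an explicit integer seed.")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Sample standard deviation / mean, in percent. NA when fewer than two
# non-missing values are available.
#' Percent coefficient of variation
#'
#' `100 * sd(x) / mean(x)` over the non-missing values, the dispersion
#' statistic used throughout for technical and between-patient variability.
#' Returns `NA` when fewer than two non-missing values are available.
#'
#' @param x Numeric vector of positive values.
#' @return A single numeric %CV (scale-invariant: `percent_cv(k * x)` equals
#'   `percent_cv(x)` for any `k > 0`).
#' @examples
#' percent_cv(c(1, 1, 1, 1, 2)) # 37.27
#' @export
percent_cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}
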