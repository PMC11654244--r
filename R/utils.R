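#' Geometric mean
#'
#' Geometric mean of strictly positive values, the scale used throughout
#' per-cell fluorescence summaries (cell intensity distributions are
#' right-skewed and roughly log-normal).
#'
#' @param x Numeric vector of positive values.
#' @param na.rm Drop `NA`s before computing.
#' @return A single positive number; `NaN` for empty input.
#' @examples
#' geo_mean(c(100, 400)) # 200
#' @export
geo_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NaN)
  if (any(x <= 0)) abort("geo_mean() requires strictly positive values.")
  exp(mean(log(x)))
}

# validate a single positive scalar
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(x)
}

# log-normal draws parameterised by mean and coefficient of variation on the
# natural scale; cv = 0 degenerates to the constant `mean`
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

round_half_up <- function(x) floor(x + 0.5)

# stable short hash of an R object (provenance stamps); rlang's xxhash
config_hash <- function(x) rlang::hash(x)
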