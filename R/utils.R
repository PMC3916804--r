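#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (so 0.25 -> 0.3 at one
#' decimal), matching how bioanalytical report tables are conventionally
#' printed. Base R's [round()] rounds ties to even, which disagrees with
#' printed validation tables on exact half-values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be negative).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25, 103.55), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sdlog of a lognormal with unit mean and coefficient of variation cv (%)
cv_to_sdlog <- function(cv) sqrt(log1p((cv / 100)^2))

# multiplicative lognormal noise factors with E[factor] = 1 and given CV (%)
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# evaluate code under a fixed seed, then restore the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# sample coefficient of variation in percent; NA for n < 2
pct_cv_of <- function(x) {
  if (length(x) < 2) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_quantpk <- function(...) stop(..., call. = FALSE)
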