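#' Round half away from zero
#'
#' Commercial ("round half up") rounding, as used when reporting percentages:
#' `round_half_up(0.685, 2)` is 0.69, whereas [base::round()] rounds half to
#' even. Needed so printed percentage tables are reproduced digit-for-digit.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.25, 0.35), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total, rounded half up
#'
#' @param n Numerator(s).
#' @param total Denominator.
#' @param digits Decimal places to keep (default 1).
#' @return `100 * n / total`, rounded half up.
#' @examples
#' percent_of(733, 9386) # 7.8
#' @export
percent_of <- function(n, total, digits = 1) {
  stopifnot(is.numeric(n), is.numeric(total), all(total != 0))
  round_half_up(100 * n / total, digits)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# abort helpers keep error classes consistent across the package
abort_config <- function(msg) abort(msg, class = "hybridmode_config_error")
abort_format <- function(msg) abort(msg, class = "hybridmode_format_error")

stop_if_not_prop <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort_config(sprintf("`%s` must be a single proportion in [0, 1]", name))
  invisible(x)
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    abort_config(sprintf("`%s` must be a single positive integer", name))
  invisible(x)
}
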