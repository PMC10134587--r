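# Small shared helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all displayed proportions and
#' percentages, so that e.g. 0.875 prints as 0.88. `base::round()` rounds
#' half to even, which disagrees with how clinical tables are printed.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.875, 2)  # 0.88, not 0.87
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a p-value the way clinical tables print it
#'
#' Values below 0.001 are reported as `"< .001"`; otherwise three decimals
#' with no leading zero.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector.
#' @export
format_p <- function(p) {
  out <- ifelse(p < 0.001, "< .001",
                sub("^0", "", sprintf("%.3f", p)))
  out[is.na(p)] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# check a probability-like scalar/vector
check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  }
  invisible(TRUE)
}
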