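#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all printed percentages and
#' summary ratios. Differs from [base::round()], which rounds half to even.
#' A small relative epsilon absorbs binary floating-point representation of
#' exact halves arising from integer ratios.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(13.793, 1)  # 13.8
#' round_half_up(2.25, 1)    # 2.3 (base round() gives 2.2)
round_half_up <- function(x, digits = 0) {
  p <- x * 10^digits
  sign(p) * floor(abs(p) + 0.5 + sqrt(.Machine$double.eps) * abs(p)) / 10^digits
}

# stop() with a class so callers/tests can distinguish failure modes
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "trialpubs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != trunc(x))
    abort(sprintf("`%s` must be a single non-negative integer", name), "trialpubs_config_error")
  as.integer(x)
}

# collapse a possibly-empty character vector to a single NA-safe string
chr1 <- function(x) {
  if (length(x) == 0L || all(is.na(x))) NA_character_ else as.character(x[[1L]])
}
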