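#' Round half away from zero
#'
#' Fixed-decimal rounding where a trailing 5 always rounds up (the convention
#' of printed clinical tables), unlike [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# stop() with the call suppressed; all user-facing errors go through here
abort_sdca <- function(...) stop(..., call. = FALSE)

is_fraction <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

# record tables are plain tibbles with a fixed column contract
RECORD_COLUMNS <- c("record_id", "true_class", "predicted_class", "model_name")
NORMAL_CLASS <- "normal"
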