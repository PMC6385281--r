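#' Round half away from zero
#'
#' Commercial ("half-up") rounding as used throughout the printed tables:
#' 36.5 rounds to 37, 30.25 to 30.  `base::round()` rounds half to even and
#' would give 36 for 36.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(36.5)        # 37
#' round_half_up(15.45, 1)    # 15.5
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # the 1e-9 guard absorbs binary representation error in e.g. 4.45 * 10
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

mbd_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mbdfam_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
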