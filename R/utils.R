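#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going away from zero
#' (the convention used by most clinical-statistics report tables),
#' rather than R's default round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.835, 2)  # 0.84, where round() gives 0.83 or 0.84 by parity
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with a class so callers/tests can distinguish validation errors
oed_stop <- function(msg, class = "oedprog_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
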