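## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-precision rounding used for reported allele fractions; ties go up
#' (0.5475 -> 0.548) rather than to even as in [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  # tiny nudge guards against 547.4999999 representations of 547.5
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

stop_f1 <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "f1loh_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_counts <- function(x, what, lines = NULL) {
  bad <- which(!is.finite(x) | x < 0 | x != floor(x))
  if (length(bad)) {
    where <- if (is.null(lines)) bad else lines[bad]
    stop_f1(what, " must be non-negative integers; offending line(s): ",
            paste(utils::head(where, 5), collapse = ", "),
            class = "f1loh_format_error")
  }
  invisible(TRUE)
}

## Derive per-sample RNG stream seeds from a master seed (kept < 2^31).
derive_stream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
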