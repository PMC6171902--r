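# Shared numeric and logging helpers.

#' Round half away from zero
#'
#' Commercial rounding to a whole number (0.5 always moves away from zero),
#' as opposed to the banker's rounding of [base::round()]. Used wherever an
#' integer percentage or cell dose is reported.
#'
#' @param x Numeric vector.
#' @return Numeric vector of whole numbers.
#' @examples
#' roundHalfUp(c(82.5, 83.4, -2.5))
#' @export
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Tolerance used when checking the equal log10 spacing of a dose grid.
.GRID_TOL <- 1e-9

# INFO-level logging to stderr; suppressible via options(teratopd.quiet = TRUE).
.logInfo <- function(...) {
  if (!isTRUE(getOption("teratopd.quiet", FALSE))) {
    message("[teratopd] ", ...)
  }
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("'", name, "' must be > 0", call. = FALSE)
  }
  invisible(x)
}
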