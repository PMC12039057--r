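#' Mass tolerance specification
#'
#' A matching tolerance combining an absolute component (Da) and a relative
#' component (ppm). The effective window at m/z `x` is
#' `max(absolute, ppm * x * 1e-6)`: the permissive reading of a
#' "(10 mDa or 25 ppm)" instrument tolerance. The two components coincide at
#' m/z 400 Th for the defaults.
#'
#' @param absolute absolute tolerance in Da (default 0.010).
#' @param ppm relative tolerance in parts per million (default 25).
#' @return an object of class `Tolerance`.
#' @examples
#' tol <- tolerance()
#' tol_window(tol, 400) # 0.01
#' @export
tolerance <- function(absolute = 0.010, ppm = 25) {
  stopifnot(is.numeric(absolute), length(absolute) == 1L, absolute > 0,
            is.numeric(ppm), length(ppm) == 1L, ppm > 0)
  structure(list(absolute = absolute, ppm = ppm), class = "Tolerance")
}

#' Effective tolerance window at a given m/z
#'
#' @param tol a [tolerance()] object.
#' @param mz numeric vector of m/z values (Th).
#' @return numeric vector of window half-widths in Da.
#' @export
tol_window <- function(tol, mz) {
  stopifnot(inherits(tol, "Tolerance"))
  pmax(tol$absolute, tol$ppm * mz * 1e-6)
}

#' @export
print.Tolerance <- function(x, ...) {
  cat(sprintf("<Tolerance> %.4g Da or %.4g ppm (max rule)\n",
              x$absolute, x$ppm))
  invisible(x)
}

# round half away from zero at `digits` decimals (base round() is
# round-half-even, which would make harmonized m/z depend on the parity of
# the 4th decimal)
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
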