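# Pressure-unit conversion constants (all to pascal).
.PA_PER <- c(
  Pa   = 1,
  psi  = 6894.757,
  mmHg = 133.322,
  hPa  = 100
)

#' Convert pressures between units
#'
#' Converts pressure values between pascal, psi, mmHg and hPa using the fixed
#' constants 1 psi = 6894.757 Pa, 1 mmHg = 133.322 Pa, 1 hPa = 100 Pa. All
#' pressures in this package are gauge pressures (relative to atmosphere), so
#' conversion is purely multiplicative.
#'
#' @param value Numeric vector of pressure values.
#' @param from Unit of `value`: one of `"Pa"`, `"psi"`, `"mmHg"`, `"hPa"`.
#' @param to Unit to convert to (default `"Pa"`).
#' @return Numeric vector in the `to` unit.
#' @examples
#' convert_pressure(30, "mmHg", "psi")  # ~0.58 psi
#' convert_pressure(500, "hPa", "psi")  # ~7.25 psi
#' @export
convert_pressure <- function(value, from, to = "Pa") {
  stopifnot(is.numeric(value))
  from <- as.character(from)[1]
  to <- as.character(to)[1]
  if (!from %in% names(.PA_PER)) {
    stop("unknown pressure unit: ", from, call. = FALSE)
  }
  if (!to %in% names(.PA_PER)) {
    stop("unknown pressure unit: ", to, call. = FALSE)
  }
  value * .PA_PER[[from]] / .PA_PER[[to]]
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' reproducing the printed flow and duration tables), unlike [round()] which
#' rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
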