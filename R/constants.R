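#' Physical constants used throughout the package
#'
#' Molar gas constant (J mol-1 K-1) and Faraday constant (C mol-1),
#' CODATA values.
#'
#' @format Named numeric scalars.
#' @keywords internal
#' @name constants
NULL

GAS_CONSTANT <- 8.314462618   # J mol-1 K-1
FARADAY <- 96485.33212        # C mol-1

#' Thermal voltage RT/F
#'
#' @param temperature_K temperature in kelvin.
#' @return RT/F in volts.
#' @keywords internal
thermal_voltage <- function(temperature_K) {
  GAS_CONSTANT * temperature_K / FARADAY
}

# internal guard: stop with a consistent message prefix
stop_invalid <- function(...) {
  stop("invalid input: ", ..., call. = FALSE)
}
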