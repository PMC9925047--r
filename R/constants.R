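#' Physical model constants
#'
#' Bundles the temperature and the derived thermal voltage kB*T/e0 used by
#' every voltage-dependent expression in the package (rate laws, Boltzmann
#' curves, tau-voltage fits, Nernst potentials).
#'
#' @param temperature_K Absolute temperature in Kelvin. Default 298.15 K
#'   (room temperature, ~25 C).
#' @return An object of class `model_constants` with fields `temperature_K`
#'   and `thermal_voltage_mV` (kB*T/e0 in millivolts; 25.693 mV at 298.15 K).
#' @examples
#' model_constants()$thermal_voltage_mV  # 25.693
#' @export
model_constants <- function(temperature_K = 298.15) {
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be a positive finite number", call. = FALSE)
  # kB/e0 = 8.617333262e-5 V/K -> mV/K
  structure(
    list(
      temperature_K = temperature_K,
      thermal_voltage_mV = 8.617333262e-2 * temperature_K
    ),
    class = "model_constants"
  )
}

#' @export
print.model_constants <- function(x, ...) {
  cat(sprintf("model_constants: T = %.2f K, kT/e0 = %.4f mV\n",
              x$temperature_K, x$thermal_voltage_mV))
  invisible(x)
}

kT_mV <- function(constants) {
  stopifnot(inherits(constants, "model_constants"))
  constants$thermal_voltage_mV
}
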