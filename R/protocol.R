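#' Voltage-step protocol
#'
#' An ordered list of constant-voltage epochs, plus the holding potential and
#' acquisition bookkeeping. Protocols here are step protocols; within an
#' epoch the command voltage is constant.
#'
#' @param epochs Data frame with columns `voltage_mV` and `duration_ms`.
#' @param holding_mV Holding potential between sweeps (mV).
#' @param sweep_interval_ms Interval between test pulses; default 45000 ms.
#' @param sample_rate_kHz Current sampling rate; default 20 kHz.
#' @param camera_Hz Fluorescence frame rate; default 10 Hz.
#' @return A `voltage_protocol` object.
#' @export
voltage_protocol <- function(epochs, holding_mV = -60,
                             sweep_interval_ms = 45000,
                             sample_rate_kHz = 20, camera_Hz = 10) {
  epochs <- as.data.frame(epochs)
  if (!all(c("voltage_mV", "duration_ms") %in% names(epochs)))
    stop("epochs needs columns voltage_mV and duration_ms", call. = FALSE)
  if (any(!is.finite(epochs$duration_ms)) || any(epochs$duration_ms <= 0))
    stop("epoch durations must be positive", call. = FALSE)
  if (any(abs(epochs$voltage_mV) > 500))
    stop("epoch voltages outside +-500 mV", call. = FALSE)
  structure(
    list(epochs = epochs[, c("voltage_mV", "duration_ms")],
         holding_mV = holding_mV,
         sweep_interval_ms = sweep_interval_ms,
         sample_rate_kHz = sample_rate_kHz,
         camera_Hz = camera_Hz),
    class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "voltage_protocol: %d epochs, holding %g mV, %g kHz / camera %g Hz\n",
    nrow(x$epochs), x$holding_mV, x$sample_rate_kHz, x$camera_Hz))
  print(x$epochs)
  invisible(x)
}

protocol_total_ms <- function(protocol) sum(protocol$epochs$duration_ms)

#' Voltage at each time point of a protocol
#'
#' @param protocol A [voltage_protocol()].
#' @param times_ms Times from protocol start (ms).
#' @return Voltage (mV) at each time; times at an epoch boundary take the
#'   incoming epoch's voltage.
#' @export
protocol_voltage_at <- function(protocol, times_ms) {
  edges <- cumsum(protocol$epochs$duration_ms)
  idx <- findInterval(times_ms, c(0, edges), rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[times_ms <= 0] <- 1L
  idx[idx > nrow(protocol$epochs)] <- nrow(protocol$epochs)
  protocol$epochs$voltage_mV[idx]
}

#' Standard activation protocol family
#'
#' The canonical stimulation family used throughout: from the holding
#' potential, one test pulse per sweep from -100 to +120 mV in 20 mV steps,
#' followed by a repolarizing tail epoch at the holding potential. One
#' [voltage_protocol()] is returned per sweep.
#'
#' @param dpH pH gradient condition tag carried through to metadata (does
#'   not alter voltages).
#' @param holding_mV Holding potential (default -60 mV).
#' @param test_mV Test voltages; default `seq(-100, 120, by = 20)`.
#' @param pre_ms,pulse_ms,tail_ms Durations of the pre-pulse holding epoch,
#'   test pulse and tail epoch (ms).
#' @param ... Passed to [voltage_protocol()].
#' @return A list of [voltage_protocol()] objects, one per test voltage,
#'   with attribute `dpH`.
#' @export
standard_protocol <- function(dpH = 1, holding_mV = -60,
                              test_mV = seq(-100, 120, by = 20),
                              pre_ms = 500, pulse_ms = 3000, tail_ms = 2000,
                              ...) {
  protos <- lapply(test_mV, function(v) voltage_protocol(
    data.frame(voltage_mV = c(holding_mV, v, holding_mV),
               duration_ms = c(pre_ms, pulse_ms, tail_ms)),
    holding_mV = holding_mV, ...))
  names(protos) <- paste0("V", test_mV)
  attr(protos, "dpH") <- dpH
  protos
}

#' Read / write a protocol as a YAML file
#'
#' @param path File path.
#' @param protocol A [voltage_protocol()].
#' @return `read_protocol` returns a [voltage_protocol()].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path))
    stop("protocol file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  voltage_protocol(
    epochs = data.frame(
      voltage_mV = vapply(doc$epochs, `[[`, 0, "voltage_mV"),
      duration_ms = vapply(doc$epochs, `[[`, 0, "duration_ms")),
    holding_mV = doc$holding_mV %||% -60,
    sweep_interval_ms = doc$sweep_interval_ms %||% 45000,
    sample_rate_kHz = doc$sample_rate_kHz %||% 20,
    camera_Hz = doc$camera_Hz %||% 10)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  doc <- list(
    epochs = lapply(seq_len(nrow(protocol$epochs)), function(i) list(
      voltage_mV = protocol$epochs$voltage_mV[i],
      duration_ms = protocol$epochs$duration_ms[i])),
    holding_mV = protocol$holding_mV,
    sweep_interval_ms = protocol$sweep_interval_ms,
    sample_rate_kHz = protocol$sample_rate_kHz,
    camera_Hz = protocol$camera_Hz)
  yaml::write_yaml(doc, path)
  invisible(path)
}
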