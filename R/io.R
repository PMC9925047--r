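#' Write / read a recording as a long-format delimited table
#'
#' One row per sample: `construct, pHo, pHi, sweep, voltage_mV, time_ms,
#' variable, value` with `variable` either `current_pA` or `fluor_au`.
#' Recording-level metadata (v_rev, pulse window, seed) travels in a
#' `# key: value` comment header.
#'
#' @param recording A [pcf_recording()].
#' @param path Output file path (CSV).
#' @return `read_recording` returns a [pcf_recording()].
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "pcf_recording"))
  rows <- lapply(seq_along(recording$sweeps), function(s) {
    sw <- recording$sweeps[[s]]
    cur <- data.frame(sweep = s, voltage_mV = sw$voltage_mV,
                      time_ms = sw$current$time_ms,
                      variable = "current_pA",
                      value = sw$current$current_pA)
    if (!is.null(sw$fluor) && nrow(sw$fluor)) {
      fl <- data.frame(sweep = s, voltage_mV = sw$voltage_mV,
                       time_ms = sw$fluor$time_ms,
                       variable = "fluor_au", value = sw$fluor$fluor_au)
      rbind(cur, fl)
    } else cur
  })
  df <- do.call(rbind, rows)
  df <- cbind(construct = recording$construct, pHo = recording$pHo,
              pHi = recording$pHi, df)
  hdr <- c(
    sprintf("# v_rev_mV: %.10g", recording$v_rev_mV %||% NA),
    sprintf("# pulse_start_ms: %.10g", recording$pulse_window_ms[1] %||% NA),
    sprintf("# pulse_end_ms: %.10g", recording$pulse_window_ms[2] %||% NA),
    sprintf("# seed: %s", recording$meta$seed %||% "NA"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param path File path to read.
#' @export
read_recording <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(sub(".*: ", "", ln[1])))
  }
  df <- utils::read.csv(path, comment.char = "#")
  sweeps <- lapply(sort(unique(df$sweep)), function(s) {
    d <- df[df$sweep == s, ]
    cur <- d[d$variable == "current_pA", ]
    fl <- d[d$variable == "fluor_au", ]
    list(voltage_mV = cur$voltage_mV[1],
         current = data.frame(time_ms = cur$time_ms,
                              current_pA = cur$value),
         fluor = if (nrow(fl))
           data.frame(time_ms = fl$time_ms, fluor_au = fl$value)
         else NULL)
  })
  pw <- c(getv("pulse_start_ms"), getv("pulse_end_ms"))
  pcf_recording(
    sweeps, construct = as.character(df$construct[1]),
    pHo = df$pHo[1], pHi = df$pHi[1],
    v_rev_mV = getv("v_rev_mV"),
    pulse_window_ms = if (all(is.finite(pw))) pw else NULL,
    meta = list(seed = getv("seed")))
}
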