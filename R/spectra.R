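#' Emission spectrum record
#'
#' Wavelength-indexed intensity samples from a spectrograph line scan, with
#' an optional background spectrum recorded from a cell-free region of the
#' same image on the same wavelength grid.
#'
#' @param wavelength_nm Strictly increasing wavelengths, within 400-700 nm.
#' @param intensity Intensities (a.u.), same length.
#' @param background Optional background intensities, same grid.
#' @param roi Optional descriptor (e.g. line-scan width, membrane tag).
#' @return A `spectrum_record`.
#' @export
spectrum_record <- function(wavelength_nm, intensity, background = NULL,
                            roi = NULL) {
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength and intensity lengths differ", call. = FALSE)
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(wavelength_nm < 400) || any(wavelength_nm > 700))
    stop("wavelengths outside the 400-700 nm instrument range",
         call. = FALSE)
  if (!is.null(background) && length(background) != length(intensity))
    stop("background must share the wavelength grid", call. = FALSE)
  structure(
    list(wavelength_nm = as.numeric(wavelength_nm),
         intensity = as.numeric(intensity),
         background = if (is.null(background)) NULL else
           as.numeric(background),
         roi = roi),
    class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf(
    "spectrum_record: %d points, %.0f-%.0f nm%s\n",
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
    if (is.null(x$background)) "" else ", background attached"))
  invisible(x)
}

#' Subtract the cell-free background spectrum
#'
#' Pointwise subtraction on the shared wavelength grid. Negative residuals
#' are retained, not clipped.
#'
#' @param spec A [spectrum_record()] with background attached.
#' @return A background-free `spectrum_record`.
#' @export
subtract_background <- function(spec) {
  stopifnot(inherits(spec, "spectrum_record"))
  if (is.null(spec$background))
    stop("no background attached; interpolation from a different grid is ",
         "not performed implicitly", call. = FALSE)
  spectrum_record(spec$wavelength_nm, spec$intensity - spec$background,
                  background = NULL, roi = spec$roi)
}

#' Peak emission within a wavelength band
#'
#' Argmax of the (optionally moving-average smoothed) intensity within a
#' band. A flat band ties to the lowest wavelength and is flagged.
#'
#' @param spec A [spectrum_record()].
#' @param band Length-2 wavelength window (nm).
#' @param smooth_pts Moving-average width in samples (0 or 1 = none).
#' @return List `peak_nm`, `peak_intensity`, `flat` (logical tie flag).
#' @export
peak_emission <- function(spec, band = c(440, 540), smooth_pts = 0) {
  stopifnot(inherits(spec, "spectrum_record"))
  if (band[1] < min(spec$wavelength_nm) || band[2] > max(spec$wavelength_nm))
    stop("band outside the recorded wavelength range", call. = FALSE)
  y <- spec$intensity
  if (smooth_pts > 1) {
    k <- rep(1 / smooth_pts, smooth_pts)
    y <- as.numeric(stats::filter(y, k, sides = 2))
    # edges: fall back to raw values where the window is incomplete
    y[is.na(y)] <- spec$intensity[is.na(y)]
  }
  sel <- spec$wavelength_nm >= band[1] & spec$wavelength_nm <= band[2]
  yb <- y[sel]; wb <- spec$wavelength_nm[sel]
  flat <- diff(range(yb)) < 1e-12 * max(abs(yb), 1)
  i <- which.max(yb)  # ties resolve to the lowest wavelength
  list(peak_nm = wb[i], peak_intensity = yb[i], flat = flat)
}

#' Anap / mCherry peak intensity ratio
#'
#' Ratio of the peak intensity in the Anap band to the peak intensity in
#' the mCherry band; the expression-normalized brightness measure.
#'
#' @param spec A [spectrum_record()] (background-corrected).
#' @param anap_band Anap search band, default 440-540 nm (~480 nm peak).
#' @param mcherry_band mCherry search band, default 590-640 nm (~610 nm).
#' @param smooth_pts Passed to [peak_emission()].
#' @return The dimensionless ratio.
#' @export
anap_mcherry_ratio <- function(spec, anap_band = c(440, 540),
                               mcherry_band = c(590, 640), smooth_pts = 0) {
  anap <- peak_emission(spec, anap_band, smooth_pts)
  mch <- peak_emission(spec, mcherry_band, smooth_pts)
  if (mch$peak_intensity <= 0)
    stop("mCherry peak intensity is not positive; ratio undefined",
         call. = FALSE)
  anap$peak_intensity / mch$peak_intensity
}

#' Welch's t statistic from group summaries
#'
#' Unpaired t test with Welch's correction computed from printed summary
#' statistics: t = (mean2 - mean1) / sqrt(sem1^2 + sem2^2) with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,mean2 Group means.
#' @param sem1,sem2 Standard errors of the means (> 0).
#' @param n1,n2 Group sizes (>= 2).
#' @return List `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sem1 <= 0 || sem2 <= 0) stop("sems must be positive", call. = FALSE)
  v1 <- sem1^2; v2 <- sem2^2
  t <- (mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Test brightness invariance across pH
#'
#' Two-way ANOVA of peak intensity with pH as the factor of interest and
#' cell identity as a blocking factor; reports the pH-factor F statistic,
#' its degrees of freedom and p value. Cells missing any pH level are
#' dropped listwise with a warning.
#'
#' @param data Data frame with columns `intensity`, `pH`, `cell`.
#' @return List `F`, `df`, `df_resid`, `p`.
#' @export
ph_invariance_test <- function(data) {
  need <- c("intensity", "pH", "cell")
  if (!all(need %in% names(data)))
    stop("data needs columns intensity, pH, cell", call. = FALSE)
  data$pH <- factor(data$pH); data$cell <- factor(data$cell)
  if (nlevels(data$pH) < 2 || nlevels(data$cell) < 2)
    stop("need >= 2 pH levels and >= 2 cells", call. = FALSE)
  tab <- table(data$cell, data$pH)
  complete <- rownames(tab)[apply(tab > 0, 1, all)]
  if (length(complete) < nlevels(data$cell)) {
    warning("cells with missing pH levels dropped listwise", call. = FALSE)
    data <- droplevels(data[data$cell %in% complete, ])
  }
  fit <- stats::aov(intensity ~ pH + cell, data = data)
  an <- summary(fit)[[1]]
  i <- grep("^pH", trimws(rownames(an)))[1]
  r <- grep("Residuals", rownames(an))
  Fv <- an[i, "F value"]; pv <- an[i, "Pr(>F)"]
  if (an[i, "Sum Sq"] <= 1e-25 * max(sum(an[, "Sum Sq"]), 1)) {
    Fv <- 0; pv <- 1  # no between-pH variation at all
  }
  list(F = Fv, df = an[i, "Df"], df_resid = an[r, "Df"], p = pv)
}

#' Read / write a two-column spectrum file
#'
#' Plain delimited text with columns `wavelength_nm`, `intensity` and an
#' optional `background` column.
#'
#' @param path File path.
#' @param spec A [spectrum_record()].
#' @return `read_spectrum` returns a [spectrum_record()].
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  spectrum_record(df$wavelength_nm, df$intensity,
                  background = df$background)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spec, path) {
  df <- data.frame(wavelength_nm = spec$wavelength_nm,
                   intensity = spec$intensity)
  if (!is.null(spec$background)) df$background <- spec$background
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
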