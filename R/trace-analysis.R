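#' A patch-clamp fluorometry recording
#'
#' Container for a family of sweeps recorded (or simulated) under one
#' condition. Each sweep holds the test voltage, an aligned current trace
#' and a fluorescence frame series with their own time bases.
#'
#' @param sweeps List of sweeps; each a list with `voltage_mV` (the test
#'   voltage), `current` (data frame `time_ms`, `current_pA`, optionally
#'   `voltage_mV`) and `fluor` (data frame `time_ms`, `fluor_au`).
#' @param construct Construct label (e.g. mutant name).
#' @param pHo,pHi External / internal pH.
#' @param v_rev_mV Measured reversal potential (mV).
#' @param pulse_window_ms Length-2 vector, start/end of the test pulse (ms);
#'   used by the end-of-pulse and fit-window logic.
#' @param meta Optional named list of extra metadata (seed, generator
#'   parameters, ...).
#' @return A `pcf_recording` object.
#' @export
pcf_recording <- function(sweeps, construct = "synthetic", pHo = 6.5,
                          pHi = 5.5, v_rev_mV = NULL,
                          pulse_window_ms = NULL, meta = list()) {
  for (sw in sweeps) {
    if (is.null(sw$voltage_mV) || is.null(sw$current))
      stop("each sweep needs voltage_mV and a current trace", call. = FALSE)
    if (is.unsorted(sw$current$time_ms, strictly = TRUE))
      stop("current time base must be strictly increasing", call. = FALSE)
    if (!is.null(sw$fluor) && nrow(sw$fluor) &&
        is.unsorted(sw$fluor$time_ms, strictly = TRUE))
      stop("fluorescence time base must be strictly increasing",
           call. = FALSE)
  }
  structure(
    list(sweeps = sweeps, construct = construct, pHo = pHo, pHi = pHi,
         dpH = pHo - pHi, v_rev_mV = v_rev_mV,
         pulse_window_ms = pulse_window_ms, meta = meta),
    class = "pcf_recording")
}

#' @export
print.pcf_recording <- function(x, ...) {
  cat(sprintf(
    "pcf_recording: %s, %d sweeps, pHo %.2g / pHi %.2g (dpH %.2g)\n",
    x$construct, length(x$sweeps), x$pHo, x$pHi, x$dpH))
  invisible(x)
}

end_of_pulse_window <- function(recording, fraction = 0.1) {
  pw <- recording$pulse_window_ms
  if (is.null(pw))
    stop("recording carries no pulse window metadata", call. = FALSE)
  c(pw[2] - fraction * (pw[2] - pw[1]), pw[2])
}

#' Conductance from a current-voltage family
#'
#' Chord conductance G = I / (V - Vrev), with I the mean current over an
#' end-of-pulse window of each sweep. Sweeps at the reversal potential are
#' excluded with a warning (zero driving force).
#'
#' @param recording A [pcf_recording()].
#' @param window Length-2 time window (ms) to average the current over;
#'   default the final 10% of the test pulse.
#' @param window_fraction Fraction of the pulse used when `window` is NULL.
#' @return Data frame with `voltage_mV`, `current_pA` (windowed mean) and
#'   `conductance_nS`.
#' @export
conductance_from_iv <- function(recording, window = NULL,
                                window_fraction = 0.1) {
  stopifnot(inherits(recording, "pcf_recording"))
  v_rev <- recording$v_rev_mV
  if (is.null(v_rev)) stop("recording has no v_rev_mV", call. = FALSE)
  if (is.null(window))
    window <- end_of_pulse_window(recording, window_fraction)
  rows <- lapply(recording$sweeps, function(sw) {
    sel <- sw$current$time_ms >= window[1] & sw$current$time_ms <= window[2]
    if (!any(sel)) stop("empty averaging window", call. = FALSE)
    i_end <- mean(sw$current$current_pA[sel])
    if (abs(sw$voltage_mV - v_rev) < 1e-9) {
      warning(sprintf("sweep at V = v_rev (%g mV) excluded", v_rev),
              call. = FALSE)
      return(NULL)
    }
    data.frame(voltage_mV = sw$voltage_mV, current_pA = i_end,
               conductance_nS = i_end / (sw$voltage_mV - v_rev) * 1)
  })
  do.call(rbind, rows[!vapply(rows, is.null, NA)])
}

#' Normalize a conductance (or fluorescence) - voltage relation
#'
#' @param points Data frame with `voltage_mV` and a value column (by
#'   default `conductance_nS`; the first non-voltage column otherwise).
#' @param mode `"max"` divides by the maximum point; `"amplitude"` divides
#'   by the fitted Boltzmann amplitude.
#' @param constants A [model_constants()] (used by amplitude mode).
#' @return Data frame `voltage_mV`, `norm` with maximum value 1 in max mode.
#' @export
normalize_gv <- function(points, mode = c("max", "amplitude"),
                         constants = model_constants()) {
  mode <- match.arg(mode)
  vcol <- setdiff(names(points), c("voltage_mV", "current_pA"))[1]
  y <- points[[vcol]]
  if (max(y) <= 0) stop("all-zero or negative relation", call. = FALSE)
  denom <- if (mode == "max") max(y) else {
    fit <- fit_boltzmann(data.frame(voltage_mV = points$voltage_mV,
                                    norm = y / max(y)),
                         constants = constants)
    fit$amplitude * max(y)
  }
  data.frame(voltage_mV = points$voltage_mV, norm = y / denom)
}

boltz <- function(v, amplitude, v_half, q, kT)
  amplitude / (1 + exp(-q * (v - v_half) / kT))

#' Fit a Boltzmann activation curve
#'
#' Least-squares fit of y(V) = A / (1 + exp(-q (V - V0.5) / kT)), the
#' activation form in which q > 0 describes curves that rise with
#' depolarization. Initialization uses the 0.5-crossing of the normalized
#' data for V0.5 and q = 1 e0, with five perturbed restarts before a fit
#' failure is declared.
#'
#' @param points Data frame with `voltage_mV` and a value column (`norm`,
#'   or the first non-voltage column).
#' @param constants A [model_constants()].
#' @param fix_amplitude Optional fixed amplitude (skips fitting A).
#' @return A `boltzmann_fit`: `v_half_mV`, `q_e0`, `amplitude`, standard
#'   errors, residual norm, and `fitted()`-style curve closure.
#' @export
fit_boltzmann <- function(points, constants = model_constants(),
                          fix_amplitude = NULL) {
  vcol <- setdiff(names(points), c("voltage_mV", "current_pA"))[1]
  v <- points$voltage_mV; y <- points[[vcol]]
  if (length(v) < 4) stop("need at least 4 points", call. = FALSE)
  rng <- diff(range(y))
  if (rng < 1e-3 * max(abs(y), 1))
    stop("ill-posed: points do not span a transition", call. = FALSE)
  kT <- kT_mV(constants)

  # init: linear interpolation of the half-maximum crossing
  yn <- (y - min(y)) / rng
  ord <- order(v)
  v_half0 <- tryCatch(
    stats::approx(yn[ord], v[ord], xout = 0.5, ties = mean)$y,
    error = function(e) stats::median(v))
  if (!is.finite(v_half0)) v_half0 <- stats::median(v)

  starts <- list(c(v_half = v_half0, q = 1))
  set_more <- expand.grid(dv = c(-20, 20, 0, 0), dq = c(0, 0, 0.8, -0.5))
  for (i in seq_len(5))
    starts[[i + 1]] <- c(v_half = v_half0 + set_more$dv[i],
                         q = 1 + set_more$dq[i])
  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      if (is.null(fix_amplitude)) {
        minpack.lm::nlsLM(
          y ~ amplitude / (1 + exp(-q * (v - v_half) / kT)),
          start = c(amplitude = max(y), as.list(st)),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        amplitude <- fix_amplitude
        minpack.lm::nlsLM(
          y ~ amplitude / (1 + exp(-q * (v - v_half) / kT)),
          start = as.list(st),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("Boltzmann fit failed to converge from all starts", call. = FALSE)
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  amplitude <- if (is.null(fix_amplitude)) cf[["amplitude"]] else fix_amplitude
  structure(
    list(v_half_mV = cf[["v_half"]], q_e0 = cf[["q"]],
         amplitude = amplitude,
         se = c(v_half_mV = unname(se["v_half"]), q_e0 = unname(se["q"]),
                amplitude = if (is.null(fix_amplitude))
                  unname(se["amplitude"]) else NA_real_),
         residual_norm = sqrt(best$rss), n = length(v), kT_mV = kT,
         data = data.frame(voltage_mV = v, value = y)),
    class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "boltzmann_fit: V0.5 = %.2f +- %.2f mV, q = %.2f +- %.2f e0, A = %.3g\n",
    x$v_half_mV, x$se["v_half_mV"], x$q_e0, x$se["q_e0"], x$amplitude))
  invisible(x)
}

#' Predicted Boltzmann curve from a fit
#' @param object A `boltzmann_fit`.
#' @param voltage_mV Voltages at which to evaluate.
#' @param ... Unused.
#' @export
predict.boltzmann_fit <- function(object, voltage_mV, ...)
  boltz(voltage_mV, object$amplitude, object$v_half_mV, object$q_e0,
        object$kT_mV)

#' Shift between two Boltzmann midpoints
#'
#' @param fitA,fitB `boltzmann_fit` objects.
#' @return List with `delta_mV` = V0.5(A) - V0.5(B) and `se_mV`, the
#'   root-sum-square of the two midpoint standard errors.
#' @export
delta_v_half <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "boltzmann_fit"), inherits(fitB, "boltzmann_fit"))
  list(delta_mV = fitA$v_half_mV - fitB$v_half_mV,
       se_mV = sqrt(sum(c(fitA$se["v_half_mV"], fitB$se["v_half_mV"])^2,
                        na.rm = TRUE)))
}

#' Normalize a fluorescence trace to its baseline (dF/F0, percent)
#'
#' dF/F0 = 100 * (F_i - F0) / F0, with F0 the first frame by default or the
#' mean over a pre-pulse baseline window.
#'
#' @param trace Data frame with `time_ms`, `fluor_au`.
#' @param baseline `"first"` (first frame) or a length-2 time window (ms)
#'   averaged for F0.
#' @return Data frame `time_ms`, `fluor_au`, `dF_F0_pct` with attribute
#'   `F0`.
#' @export
normalize_fluorescence <- function(trace, baseline = "first") {
  f <- trace$fluor_au
  F0 <- if (identical(baseline, "first")) f[1L] else {
    sel <- trace$time_ms >= baseline[1] & trace$time_ms <= baseline[2]
    if (!any(sel)) stop("empty baseline window", call. = FALSE)
    mean(f[sel])
  }
  if (!is.finite(F0) || F0 <= 0)
    stop("baseline F0 must be positive", call. = FALSE)
  out <- data.frame(time_ms = trace$time_ms, fluor_au = f,
                    dF_F0_pct = 100 * (f - F0) / F0)
  attr(out, "F0") <- F0
  out
}

#' Fit a single-exponential activation time course
#'
#' Fits y(t) = A_ss * (1 - exp(-(t - t0)/tau)) to the second half of a
#' rising trace (or, with `direction = "decay"`,
#' y(t) = A_ss + A * exp(-(t - t0)/tau) to a decaying one). The pulse start
#' t0 is fixed, not free.
#'
#' @param trace Data frame with `time_ms` and one signal column
#'   (`current_pA`, `fluor_au` or `dF_F0_pct`).
#' @param t0_ms Pulse start time (fixed).
#' @param window Length-2 fit window (ms); default the second half of
#'   `t0_ms`..end (fraction configurable).
#' @param fraction Fraction of the pulse excluded from the start when
#'   `window` is NULL (default 0.5: fit the second half).
#' @param direction `"rise"` or `"decay"`.
#' @return An `exponential_fit` with `tau_ms`, `a_ss`, standard errors, and
#'   a `degenerate` flag when tau is unidentifiable (flat trace).
#' @export
fit_exponential <- function(trace, t0_ms, window = NULL, fraction = 0.5,
                            direction = c("rise", "decay")) {
  direction <- match.arg(direction)
  ycol <- intersect(c("current_pA", "fluor_au", "dF_F0_pct", "value"),
                    names(trace))[1]
  if (is.na(ycol)) stop("no signal column found", call. = FALSE)
  tend <- max(trace$time_ms)
  if (is.null(window))
    window <- c(t0_ms + fraction * (tend - t0_ms), tend)
  sel <- trace$time_ms >= window[1] & trace$time_ms <= window[2]
  tt <- trace$time_ms[sel]; yy <- trace[[ycol]][sel]
  if (length(tt) < 10) stop("fit window has fewer than 10 samples",
                            call. = FALSE)
  if (diff(range(yy)) < 1e-10 * max(abs(yy), 1))
    return(structure(
      list(a_ss = mean(yy), tau_ms = NA_real_, t0_ms = t0_ms,
           se = c(a_ss = stats::sd(yy) / sqrt(length(yy)),
                  tau_ms = NA_real_),
           degenerate = TRUE, direction = direction),
      class = "exponential_fit"))
  tau0 <- max((tend - t0_ms) / 5, diff(range(tt)) / 5)
  fit <- tryCatch({
    if (direction == "rise")
      minpack.lm::nlsLM(
        yy ~ a_ss * (1 - exp(-(tt - t0_ms) / tau)),
        start = list(a_ss = yy[length(yy)], tau = tau0),
        lower = c(-Inf, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    else
      minpack.lm::nlsLM(
        yy ~ a_ss + a * exp(-(tt - t0_ms) / tau),
        start = list(a_ss = yy[length(yy)],
                     a = yy[1] - yy[length(yy)], tau = tau0),
        lower = c(-Inf, -Inf, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300))
  }, error = function(e)
    stop("exponential fit failed: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(
    list(a_ss = cf[["a_ss"]], tau_ms = cf[["tau"]], t0_ms = t0_ms,
         a = if (direction == "decay") cf[["a"]] else NA_real_,
         se = c(a_ss = unname(se["a_ss"]), tau_ms = unname(se["tau"])),
         degenerate = FALSE, direction = direction,
         residual_norm = sqrt(sum(stats::residuals(fit)^2))),
    class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (isTRUE(x$degenerate))
    cat(sprintf("exponential_fit: flat trace, A_ss = %.4g, tau unidentifiable\n",
                x$a_ss))
  else
    cat(sprintf("exponential_fit (%s): tau = %.4g ms, A_ss = %.4g\n",
                x$direction, x$tau_ms, x$a_ss))
  invisible(x)
}

#' Fit a bi-exponential off-relaxation
#'
#' Fits y(t) = c + a1 exp(-(t-t0)/tau1) + a2 exp(-(t-t0)/tau2) to an
#' off-response (e.g. fluorescence during repolarization). Components are
#' returned fast-first (tau1 < tau2). A single-exponential fit of the same
#' window is always computed and compared by AIC, so a genuinely
#' mono-exponential decay is reported as such.
#'
#' @param trace Data frame with `time_ms` and a signal column.
#' @param t0_ms Start of the off-epoch (fixed).
#' @param window Optional fit window; default `t0_ms`..end.
#' @param baseline Fit an additive constant `c` (default TRUE).
#' @return A `biexponential_fit`: `tau_fast_ms`, `tau_slow_ms`, `a_fast`,
#'   `a_slow`, `baseline`, `delta_aic` (mono minus bi; positive favors two
#'   components), `degenerate` flag when tau_slow/tau_fast < 3.
#' @export
fit_biexponential <- function(trace, t0_ms, window = NULL,
                              baseline = TRUE) {
  ycol <- intersect(c("dF_F0_pct", "fluor_au", "current_pA", "value"),
                    names(trace))[1]
  if (is.na(ycol)) stop("no signal column found", call. = FALSE)
  if (is.null(window)) window <- c(t0_ms, max(trace$time_ms))
  sel <- trace$time_ms >= window[1] & trace$time_ms <= window[2]
  tt <- trace$time_ms[sel] - t0_ms; yy <- trace[[ycol]][sel]
  if (length(tt) < 30)
    stop("off-trace has fewer than 30 samples", call. = FALSE)
  span <- max(tt)
  y_end <- mean(yy[tt > 0.9 * span])
  amp0 <- yy[1] - y_end

  fit_one <- function(l_tau1, l_tau2) tryCatch({
    if (baseline)
      minpack.lm::nlsLM(
        yy ~ c0 + a1 * exp(-tt / exp(lt1)) + a2 * exp(-tt / exp(lt2)),
        start = list(c0 = y_end, a1 = amp0 / 2, a2 = amp0 / 2,
                     lt1 = l_tau1, lt2 = l_tau2),
        control = minpack.lm::nls.lm.control(maxiter = 400))
    else
      minpack.lm::nlsLM(
        yy ~ a1 * exp(-tt / exp(lt1)) + a2 * exp(-tt / exp(lt2)),
        start = list(a1 = amp0 / 2, a2 = amp0 / 2,
                     lt1 = l_tau1, lt2 = l_tau2),
        control = minpack.lm::nls.lm.control(maxiter = 400))
  }, error = function(e) NULL)

  # grid of fast/slow starting guesses spread over the window's decades
  lt_fast <- log(span / c(500, 100, 20, 8))
  lt_slow <- log(span * c(1 / 8, 1 / 2, 1.5))
  grid <- expand.grid(lt1 = lt_fast, lt2 = lt_slow)
  grid <- grid[grid$lt1 < grid$lt2, ]
  lt_center <- log(span / 5)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    f <- fit_one(grid$lt1[i], grid$lt2[i])
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (is.null(best) || rss < best$rss * (1 - 1e-9))
        best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best))
    stop("bi-exponential fit failed from all starts", call. = FALSE)

  mono <- tryCatch({
    if (baseline)
      minpack.lm::nlsLM(yy ~ c0 + a1 * exp(-tt / exp(lt1)),
                        start = list(c0 = y_end, a1 = amp0, lt1 = lt_center),
                        control = minpack.lm::nls.lm.control(maxiter = 400))
    else
      minpack.lm::nlsLM(yy ~ a1 * exp(-tt / exp(lt1)),
                        start = list(a1 = amp0, lt1 = lt_center),
                        control = minpack.lm::nls.lm.control(maxiter = 400))
  }, error = function(e) NULL)
  delta_aic <- if (is.null(mono)) Inf else
    stats::AIC(mono) - stats::AIC(best$fit)

  cf <- stats::coef(best$fit)
  taus <- exp(c(cf[["lt1"]], cf[["lt2"]]))
  amps <- c(cf[["a1"]], cf[["a2"]])
  ord <- order(taus)
  taus <- taus[ord]; amps <- amps[ord]
  degen <- taus[2] / taus[1] < 3
  if (degen)
    warning("bi-exponential components within 3x of each other (degenerate)",
            call. = FALSE)
  structure(
    list(tau_fast_ms = taus[1], tau_slow_ms = taus[2],
         a_fast = amps[1], a_slow = amps[2],
         baseline = if (baseline) cf[["c0"]] else 0,
         t0_ms = t0_ms, delta_aic = delta_aic, degenerate = degen,
         residual_norm = sqrt(best$rss)),
    class = "biexponential_fit")
}

#' @export
print.biexponential_fit <- function(x, ...) {
  cat(sprintf(
    "biexponential_fit: tau_fast = %.4g ms (a = %.3g), tau_slow = %.4g ms (a = %.3g), dAIC(mono-bi) = %.3g%s\n",
    x$tau_fast_ms, x$a_fast, x$tau_slow_ms, x$a_slow, x$delta_aic,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fit the voltage dependence of a time constant
#'
#' Fits tau(V) = tau0 * exp(q V / kT) by log-linear least squares
#' (regression of ln tau on V).
#'
#' @param points Data frame with `voltage_mV` and `tau_ms` (> 0).
#' @param constants A [model_constants()].
#' @return List with `tau0_ms` (tau at 0 mV), `q_e0`, and standard errors.
#' @export
fit_tau_voltage <- function(points, constants = model_constants()) {
  v <- points$voltage_mV; tau <- points$tau_ms
  if (length(v) < 3) stop("need at least 3 voltages", call. = FALSE)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all tau must be positive", call. = FALSE)
  kT <- kT_mV(constants)
  fit <- stats::lm(log(tau) ~ v)
  cf <- stats::coef(fit)
  se <- suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  list(tau0_ms = exp(cf[[1]]), q_e0 = cf[[2]] * kT,
       se = c(tau0_ms = exp(cf[[1]]) * se[[1]], q_e0 = se[[2]] * kT))
}

#' F-V relation from a recording
#'
#' End-of-pulse dF/F0 per sweep, normalized and fit with the same Boltzmann
#' machinery as the G-V.
#'
#' @param recording A [pcf_recording()].
#' @param window End-of-pulse window (ms); default final 10% of the pulse.
#' @param baseline Passed to [normalize_fluorescence()].
#' @return List with `points` (voltage_mV, dF_F0_pct, norm) and `fit`
#'   (a `boltzmann_fit`).
#' @export
fv_curve <- function(recording, window = NULL, baseline = "first") {
  stopifnot(inherits(recording, "pcf_recording"))
  if (is.null(window)) window <- end_of_pulse_window(recording)
  rows <- lapply(recording$sweeps, function(sw) {
    if (is.null(sw$fluor) || !nrow(sw$fluor)) return(NULL)
    nf <- normalize_fluorescence(sw$fluor, baseline)
    sel <- nf$time_ms >= window[1] & nf$time_ms <= window[2]
    if (!any(sel)) sel <- which.max(nf$time_ms)  # nearest frame to pulse end
    data.frame(voltage_mV = sw$voltage_mV,
               dF_F0_pct = mean(nf$dF_F0_pct[sel]))
  })
  pts <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
  rng <- diff(range(pts$dF_F0_pct))
  if (rng < 1e-9)
    stop("ill-posed: end-of-pulse fluorescence is flat across sweeps",
         call. = FALSE)
  pts$norm <- pts$dF_F0_pct / max(pts$dF_F0_pct)
  fit <- fit_boltzmann(pts[, c("voltage_mV", "norm")])
  list(points = pts, fit = fit)
}

#' G-V relation from a recording
#'
#' Convenience composition: [conductance_from_iv()], [normalize_gv()],
#' [fit_boltzmann()].
#'
#' @inheritParams conductance_from_iv
#' @param mode Normalization mode, see [normalize_gv()].
#' @return List with `points` and `fit`.
#' @export
gv_curve <- function(recording, window = NULL, mode = "max") {
  g <- conductance_from_iv(recording, window)
  pts <- normalize_gv(g[, c("voltage_mV", "conductance_nS")], mode = mode)
  list(points = pts, fit = fit_boltzmann(pts))
}

#' Estimate the reversal potential from an I-V relation
#'
#' Linear interpolation of the zero crossing of end-of-pulse current versus
#' voltage; a helper for recordings without measured v_rev metadata.
#'
#' @param iv Data frame with `voltage_mV` and `current_pA`.
#' @return Estimated reversal potential (mV).
#' @export
estimate_vrev <- function(iv) {
  iv <- iv[order(iv$voltage_mV), ]
  s <- sign(iv$current_pA)
  cross <- which(diff(s) != 0 & s[-length(s)] != 0)
  if (!length(cross)) {
    z <- which(s == 0)
    if (length(z)) return(iv$voltage_mV[z[1]])
    stop("I-V relation does not cross zero", call. = FALSE)
  }
  i <- cross[1]
  x1 <- iv$voltage_mV[i]; x2 <- iv$voltage_mV[i + 1]
  y1 <- iv$current_pA[i]; y2 <- iv$current_pA[i + 1]
  x1 - y1 * (x2 - x1) / (y2 - y1)
}
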