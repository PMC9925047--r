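#' Noise model for synthetic recordings
#'
#' @param current_sd_pA Additive Gaussian SD per current sample (pA).
#' @param fluor_sd_au Additive Gaussian SD per fluorescence frame (a.u.),
#'   or, in shot mode, the photon count corresponding to 1 a.u.
#' @param mode `"gaussian"` (camera-read dominated, default) or `"shot"`
#'   (Poisson photon counting scaled by `fluor_sd_au` counts per a.u.).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A `noise_model`.
#' @export
noise_model <- function(current_sd_pA = 0, fluor_sd_au = 0,
                        mode = c("gaussian", "shot"), seed = 1L) {
  mode <- match.arg(mode)
  if (current_sd_pA < 0 || fluor_sd_au < 0)
    stop("noise scales must be non-negative", call. = FALSE)
  structure(list(current_sd_pA = current_sd_pA, fluor_sd_au = fluor_sd_au,
                 mode = mode, seed = as.integer(seed)),
            class = "noise_model")
}

#' Acquisition model
#'
#' The recording chain: current sampled at `sample_rate_kHz` after a 4-pole
#' low-pass Bessel anti-alias filter at `filter_corner_kHz`; fluorescence
#' frames at `camera_Hz` with `exposure_ms` integration.
#'
#' @param sample_rate_kHz Current sampling rate; default 20 kHz.
#' @param filter_corner_kHz Anti-alias corner; default 5 kHz; must be below
#'   Nyquist.
#' @param camera_Hz Frame rate, 10-25 Hz typical; default 10.
#' @param exposure_ms Exposure; must not exceed the frame interval; default
#'   the full frame interval.
#' @return An `acquisition_model`.
#' @export
acquisition_model <- function(sample_rate_kHz = 20, filter_corner_kHz = 5,
                              camera_Hz = 10, exposure_ms = NULL) {
  if (filter_corner_kHz >= sample_rate_kHz / 2)
    stop("filter corner must be below Nyquist", call. = FALSE)
  frame_ms <- 1000 / camera_Hz
  if (is.null(exposure_ms)) exposure_ms <- frame_ms
  if (exposure_ms > frame_ms + 1e-9)
    stop("exposure exceeds the frame interval", call. = FALSE)
  structure(list(sample_rate_kHz = sample_rate_kHz,
                 filter_corner_kHz = filter_corner_kHz,
                 camera_Hz = camera_Hz, exposure_ms = exposure_ms),
            class = "acquisition_model")
}

#' Nernst reversal potential for protons
#'
#' v_rev = ln(10) * (kB T / e0) * (pHi - pHo): an outward gradient
#' (pHo > pHi) gives a negative reversal potential.
#'
#' @param pHo,pHi External / internal pH, each within 3-10.
#' @param constants A [model_constants()].
#' @return Reversal potential (mV). -59.2 mV per unit of pHo - pHi at
#'   298.15 K.
#' @export
nernst_vrev <- function(pHo, pHi, constants = model_constants()) {
  if (any(c(pHo, pHi) < 3) || any(c(pHo, pHi) > 10))
    stop("pH outside the supported 3-10 range", call. = FALSE)
  log(10) * kT_mV(constants) * (pHi - pHo)
}

# 4th-order low-pass Bessel anti-alias filter applied forward (causal, as
# in an acquisition chain). Analog prototype poles for the -3 dB normalized
# 4th-order Bessel filter, discretized with the bilinear transform.
bessel4_filter <- function(x, corner_kHz, sample_rate_kHz) {
  # normalized (-3 dB at 1 rad/s) 4th-order Bessel poles
  p <- c(complex(real = -0.6572111716718830, imaginary = 0.8301614350048734),
         complex(real = -0.6572111716718830, imaginary = -0.8301614350048734),
         complex(real = -0.9047587967882448, imaginary = 0.2709187330038746),
         complex(real = -0.9047587967882448, imaginary = -0.2709187330038746))
  w0 <- 2 * pi * corner_kHz            # rad/ms
  fs <- sample_rate_kHz                # samples/ms
  # prewarp so the digital corner lands on the analog one
  warped <- 2 * fs * tan(w0 / (2 * fs))
  sp <- p * warped
  sg <- Re(prod(-sp))                  # unity DC gain
  zpk <- signal::bilinear(Sz = numeric(0), Sp = sp, Sg = sg, T = 1 / fs)
  arma <- signal::as.Arma(signal::Zpg(zero = zpk$zero, pole = zpk$pole,
                                      gain = zpk$gain))
  # pad with the initial value so the filter starts from steady state
  npad <- 8L * ceiling(fs / corner_kHz)
  xp <- c(rep(x[1L], npad), x)
  y <- Re(signal::filter(arma, xp))
  y[(npad + 1L):length(xp)]
}

#' Generate a synthetic patch-clamp fluorometry recording
#'
#' Runs the gating simulator over a protocol family and applies the
#' acquisition chain: the noiseless current is anti-alias filtered,
#' sampled, and Gaussian noise added; fluorescence frames are
#' exposure-averaged and noise added. Everything is a pure function of
#' (parameters, seed).
#'
#' @param scheme A [gating_scheme()].
#' @param protocols A list of [voltage_protocol()] as from
#'   [standard_protocol()], or a single protocol.
#' @param obs An [observation_model()]; if `v_rev_mV` is NULL it is filled
#'   from [nernst_vrev()] of the pH condition.
#' @param acq An [acquisition_model()].
#' @param noise A [noise_model()].
#' @param pHo,pHi pH condition recorded in metadata (and used for v_rev).
#' @param construct Construct label for metadata.
#' @param constants A [model_constants()].
#' @return A [pcf_recording()].
#' @export
generate_pcf_recording <- function(scheme, protocols, obs,
                                   acq = acquisition_model(),
                                   noise = noise_model(),
                                   pHo = 6.5, pHi = 5.5,
                                   construct = "synthetic",
                                   constants = model_constants()) {
  if (inherits(protocols, "voltage_protocol")) protocols <- list(protocols)
  if (is.null(obs$v_rev_mV))
    obs$v_rev_mV <- nernst_vrev(pHo, pHi, constants)
  set.seed(noise$seed)
  sweeps <- vector("list", length(protocols))
  pulse_window <- NULL
  for (s in seq_along(protocols)) {
    proto <- protocols[[s]]
    proto$sample_rate_kHz <- acq$sample_rate_kHz
    proto$camera_Hz <- acq$camera_Hz
    traj <- propagate(scheme, proto, constants = constants)
    cur <- simulate_current(traj, obs, scheme)
    cur$current_pA <- bessel4_filter(cur$current_pA,
                                     acq$filter_corner_kHz,
                                     acq$sample_rate_kHz)
    if (noise$current_sd_pA > 0)
      cur$current_pA <- cur$current_pA +
        stats::rnorm(nrow(cur), 0, noise$current_sd_pA)
    fl <- simulate_fluorescence(traj, scheme, camera_Hz = acq$camera_Hz,
                                exposure_ms = acq$exposure_ms)
    if (noise$fluor_sd_au > 0) {
      fl$fluor_au <- if (noise$mode == "gaussian")
        fl$fluor_au + stats::rnorm(nrow(fl), 0, noise$fluor_sd_au)
      else
        stats::rpois(nrow(fl),
                     pmax(fl$fluor_au, 0) * noise$fluor_sd_au) /
          noise$fluor_sd_au
    }
    # test pulse assumed to be the epoch with the largest |V - holding|
    ep <- proto$epochs
    test_idx <- which.max(abs(ep$voltage_mV - proto$holding_mV))
    edges <- cumsum(ep$duration_ms)
    pulse_window <- c(c(0, edges)[test_idx], edges[test_idx])
    sweeps[[s]] <- list(voltage_mV = ep$voltage_mV[test_idx],
                        current = cur, fluor = fl)
  }
  pcf_recording(
    sweeps, construct = construct, pHo = pHo, pHi = pHi,
    v_rev_mV = obs$v_rev_mV, pulse_window_ms = pulse_window,
    meta = list(seed = noise$seed,
                gamma_ch_pS = obs$gamma_ch_pS,
                n_channels = obs$n_channels,
                camera_Hz = acq$camera_Hz))
}

#' Generate a noisy normalized G-V dataset
#'
#' Boltzmann-shaped means with i.i.d. Gaussian noise; the standard fixture
#' for parameter-recovery studies.
#'
#' @param v_half_mV,q_e0,amplitude Generating Boltzmann parameters.
#' @param voltages_mV Test voltages; default -100..120 by 20.
#' @param sigma Noise SD on the normalized scale (>= 0).
#' @param n_replicates Number of replicate curves.
#' @param seed Integer seed.
#' @param constants A [model_constants()].
#' @return Data frame `replicate`, `voltage_mV`, `norm`, `truth`, with the
#'   generator parameters as attributes.
#' @export
generate_gv_dataset <- function(v_half_mV, q_e0, amplitude = 1,
                                voltages_mV = seq(-100, 120, by = 20),
                                sigma = 0, n_replicates = 1, seed = 1L,
                                constants = model_constants()) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  kT <- kT_mV(constants)
  truth <- boltz(voltages_mV, amplitude, v_half_mV, q_e0, kT)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
    data.frame(replicate = r, voltage_mV = voltages_mV,
               norm = truth + stats::rnorm(length(truth), 0, sigma),
               truth = truth)))
  attr(out, "params") <- list(v_half_mV = v_half_mV, q_e0 = q_e0,
                              amplitude = amplitude, sigma = sigma,
                              seed = seed)
  out
}

#' Generate a synthetic dual-band emission spectrum
#'
#' Sum of two Gaussian emission bands: the environment-sensitive probe
#' (default centered at `anap_peak_nm`, width 35 nm) and mCherry (610 nm,
#' width 20 nm), plus a fixed fractional direct-excitation bleed-through of
#' the mCherry band, additive Gaussian noise, on a 1 nm grid 420-680 nm.
#'
#' @param anap_peak_nm Probe band center (default 480).
#' @param anap_height,mcherry_height Band peak heights (>= 0).
#' @param bleed_fraction Fraction of the mCherry band added as bleed.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param background Optional constant (or vector) background added to the
#'   intensities and attached as the background channel.
#' @param anap_width_nm,mcherry_width_nm Gaussian SD widths (nm).
#' @return A [spectrum_record()].
#' @export
generate_spectrum <- function(anap_peak_nm = 480, anap_height = 1,
                              mcherry_height = 1, bleed_fraction = 0,
                              noise_sd = 0, seed = 1L, background = NULL,
                              anap_width_nm = 35, mcherry_width_nm = 20) {
  if (anap_height < 0 || mcherry_height < 0)
    stop("heights must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  wl <- seq(420, 680, by = 1)
  # bands are truncated at three widths so the default Anap and mCherry
  # search windows see one band each
  gauss_band <- function(center, width) {
    g <- exp(-0.5 * ((wl - center) / width)^2)
    g[abs(wl - center) > 3 * width] <- 0
    g
  }
  mch_band <- gauss_band(610, mcherry_width_nm)
  y <- anap_height * gauss_band(anap_peak_nm, anap_width_nm) +
    (mcherry_height + bleed_fraction * mcherry_height) * mch_band
  if (noise_sd > 0) y <- y + stats::rnorm(length(wl), 0, noise_sd)
  if (!is.null(background)) {
    bg <- rep_len(background, length(wl))
    spectrum_record(wl, y + bg, background = bg)
  } else {
    spectrum_record(wl, y)
  }
}
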