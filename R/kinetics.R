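#' Build the generator (Q-) matrix of a scheme at a voltage
#'
#' Off-diagonal entry (i, j) is the transition rate k_ij(V) for an existing
#' transition i -> j (ms^-1), zero otherwise; each diagonal entry is minus
#' its row sum, so probability is conserved by construction. State
#' occupancies then obey the master equation dP/dt = t(Q) %*% P.
#'
#' @param scheme A [gating_scheme()].
#' @param v Membrane potential (mV).
#' @param constants A [model_constants()].
#' @return An n x n numeric matrix with state labels as dimnames; every row
#'   sums to zero (within 1e-12).
#' @export
build_generator <- function(scheme, v, constants = model_constants()) {
  stopifnot(inherits(scheme, "gating_scheme"))
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (nm in names(scheme$transitions)) {
    pair <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    Q[pair[1L], pair[2L]] <-
      evaluate_rate(scheme$transitions[[nm]], v, constants)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary state occupancies at a voltage
#'
#' Solves t(Q) %*% p = 0 subject to sum(p) = 1; used to initialize the
#' occupancy distribution at the holding potential.
#'
#' @inheritParams build_generator
#' @return Named probability vector summing to 1.
#' @export
steady_state <- function(scheme, v, constants = model_constants()) {
  Q <- build_generator(scheme, v, constants)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("generator is singular or ill-conditioned at v = ", v, " mV: ",
         conditionMessage(e), call. = FALSE))
  resid <- max(abs(t(Q) %*% sol))
  if (!all(is.finite(sol)) || resid > 1e-8)
    stop(sprintf(
      "stationary solve failed at v = %g mV (residual %.3g)", v, resid),
      call. = FALSE)
  sol <- pmax(sol, 0)
  sol <- sol / sum(sol)
  stats::setNames(as.numeric(sol), rownames(Q))
}

# Occupancy evolution over a block of times from one start vector.
# Eigen-decomposition of t(Q) when it is well conditioned, otherwise a
# stepped matrix-exponential walk on the same grid.
propagate_block <- function(Q, p0, rel_times) {
  n <- nrow(Q)
  QT <- t(Q)
  eg <- eigen(QT)
  use_eigen <- FALSE
  if (all(is.finite(eg$values)) && all(is.finite(eg$vectors))) {
    rc <- tryCatch(rcond(eg$vectors), error = function(e) 0)
    use_eigen <- is.finite(rc) && rc > 1e-10
  }
  if (use_eigen) {
    coef <- solve(eg$vectors, p0)
    # occupancies(t) = V %*% (coef * exp(lambda * t))
    E <- exp(outer(eg$values, rel_times))      # n x T
    P <- Re(eg$vectors %*% (E * coef))         # n x T
    return(t(P))
  }
  # fallback: uniform-step matrix exponential walk hitting each rel_time
  out <- matrix(NA_real_, length(rel_times), n)
  ord <- order(rel_times)
  tcur <- 0; p <- p0
  dt_cache <- new.env(parent = emptyenv())
  for (i in ord) {
    dt <- rel_times[i] - tcur
    if (dt > 0) {
      key <- format(dt, digits = 15)
      M <- get0(key, envir = dt_cache)
      if (is.null(M)) {
        M <- as.matrix(Matrix::expm(QT * dt))
        assign(key, M, envir = dt_cache)
      }
      p <- as.numeric(M %*% p)
      tcur <- rel_times[i]
    }
    out[i, ] <- p
  }
  out
}

#' Propagate state occupancies through a voltage protocol
#'
#' Solves the master equation dP/dt = t(Q(V)) %*% P across the ordered
#' constant-voltage epochs of a protocol. Within each epoch the solution is
#' the exact matrix-exponential propagator applied to the epoch's entry
#' occupancy, evaluated on the current-sampling time grid.
#'
#' @param scheme A [gating_scheme()].
#' @param protocol A [voltage_protocol()].
#' @param p0 Initial occupancy vector (sums to 1); default is the
#'   stationary distribution at the protocol's holding potential.
#' @param constants A [model_constants()].
#' @return An `occupancy_trajectory`: list with `times_ms`, `occupancies`
#'   (time x state matrix), `voltage_mV` per time point and the protocol.
#' @export
propagate <- function(scheme, protocol, p0 = NULL,
                      constants = model_constants()) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(protocol, "voltage_protocol"))
  n <- length(scheme$states)
  if (is.null(p0))
    p0 <- steady_state(scheme, protocol$holding_mV, constants)
  if (length(p0) != n || any(p0 < -1e-12) ||
      abs(sum(p0) - 1) > 1e-6)
    stop("p0 must be a probability vector over the scheme's states",
         call. = FALSE)
  p0 <- as.numeric(p0) / sum(p0)

  dt <- 1 / protocol$sample_rate_kHz              # ms per sample
  total <- protocol_total_ms(protocol)
  times <- seq(0, total, by = dt)
  edges <- cumsum(protocol$epochs$duration_ms)
  starts <- c(0, edges[-length(edges)])

  occ <- matrix(NA_real_, length(times), n,
                dimnames = list(NULL, scheme$states))
  volt <- numeric(length(times))
  p_entry <- p0
  for (e in seq_len(nrow(protocol$epochs))) {
    v <- protocol$epochs$voltage_mV[e]
    Q <- build_generator(scheme, v, constants)
    lo <- starts[e]; hi <- edges[e]
    sel <- if (e == 1L) which(times <= hi) else
      which(times > lo & times <= hi)
    rel <- times[sel] - lo
    if (length(sel)) {
      occ[sel, ] <- propagate_block(Q, p_entry, rel)
      volt[sel] <- v
    }
    # exact entry state for the next epoch
    p_exit <- propagate_block(Q, p_entry, hi - lo)[1L, ]
    p_entry <- pmin(pmax(p_exit, 0), 1)
    p_entry <- p_entry / sum(p_entry)
  }
  # clamp round-off excursions only; conservation is by construction
  occ[occ < 0 & occ > -1e-12] <- 0
  structure(
    list(times_ms = times, occupancies = occ, voltage_mV = volt,
         protocol = protocol),
    class = "occupancy_trajectory")
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf(
    "occupancy_trajectory: %d time points, %d states, %.4g ms\n",
    length(x$times_ms), ncol(x$occupancies), max(x$times_ms)))
  invisible(x)
}

#' Whole-cell observation model
#'
#' Parameters mapping open-state occupancy to whole-cell current:
#' I(t) = gamma_ch * N * (V - v_rev) * Po(t) + gamma_leak * (V - v_rev_leak),
#' with the channel term in pS * mV (converted to pA) and the leak term in
#' nS * mV (already pA).
#'
#' @param gamma_ch_pS Single-channel conductance (pS, >= 0).
#' @param n_channels Number of channels (>= 0).
#' @param v_rev_mV Proton reversal potential (mV).
#' @param gamma_leak_nS Leak conductance (nS, >= 0); default 0.
#' @param v_rev_leak_mV Leak reversal potential (mV); default 0.
#' @return An `observation_model` object.
#' @export
observation_model <- function(gamma_ch_pS, n_channels, v_rev_mV,
                              gamma_leak_nS = 0, v_rev_leak_mV = 0) {
  if (gamma_ch_pS < 0 || n_channels < 0 || gamma_leak_nS < 0)
    stop("conductances and channel count must be non-negative",
         call. = FALSE)
  structure(
    list(gamma_ch_pS = gamma_ch_pS, n_channels = n_channels,
         v_rev_mV = v_rev_mV, gamma_leak_nS = gamma_leak_nS,
         v_rev_leak_mV = v_rev_leak_mV),
    class = "observation_model")
}

#' Current observable from an occupancy trajectory
#'
#' @param traj An [propagate()] result.
#' @param obs An [observation_model()].
#' @param scheme The [gating_scheme()] that produced `traj` (supplies the
#'   conducting flags).
#' @return Data frame with `time_ms`, `voltage_mV`, `current_pA`.
#' @export
simulate_current <- function(traj, obs, scheme) {
  stopifnot(inherits(traj, "occupancy_trajectory"),
            inherits(obs, "observation_model"),
            inherits(scheme, "gating_scheme"))
  if (!identical(colnames(traj$occupancies), scheme$states))
    stop("trajectory and scheme states do not align", call. = FALSE)
  po <- rowSums(traj$occupancies[, scheme$conducting, drop = FALSE])
  v <- traj$voltage_mV
  i_pA <- obs$gamma_ch_pS * obs$n_channels * (v - obs$v_rev_mV) * po / 1000 +
    obs$gamma_leak_nS * (v - obs$v_rev_leak_mV)
  data.frame(time_ms = traj$times_ms, voltage_mV = v, current_pA = i_pA)
}

#' Fluorescence observable from an occupancy trajectory
#'
#' The instantaneous fluorescence is F(t) = sum_i P_i(t) * f_i; each camera
#' frame reports the exposure-time average of F(t). Frame count is
#' `floor(total duration * frame rate)`.
#'
#' @param traj An [propagate()] result.
#' @param scheme The [gating_scheme()] (supplies the per-state weights f_i).
#' @param camera_Hz Frame rate (0, 1000] Hz.
#' @param exposure_ms Exposure per frame; must not exceed the frame
#'   interval. Default: full frame interval.
#' @return Data frame with `time_ms` (frame mid-exposure) and `fluor_au`.
#' @export
simulate_fluorescence <- function(traj, scheme,
                                  camera_Hz = traj$protocol$camera_Hz,
                                  exposure_ms = NULL) {
  stopifnot(inherits(traj, "occupancy_trajectory"),
            inherits(scheme, "gating_scheme"))
  if (camera_Hz <= 0 || camera_Hz > 1000)
    stop("camera_Hz must lie in (0, 1000]", call. = FALSE)
  frame_ms <- 1000 / camera_Hz
  if (is.null(exposure_ms)) exposure_ms <- frame_ms
  if (exposure_ms > frame_ms + 1e-9)
    stop("exposure_ms exceeds the frame interval", call. = FALSE)
  total <- max(traj$times_ms)
  n_frames <- floor(total / frame_ms)
  if (n_frames < 1) stop("protocol shorter than one frame", call. = FALSE)
  finst <- as.numeric(traj$occupancies %*% scheme$f)
  t_frame <- numeric(n_frames); fbar <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    t0 <- (k - 1) * frame_ms
    sel <- traj$times_ms >= t0 & traj$times_ms <= t0 + exposure_ms
    fbar[k] <- mean(finst[sel])
    t_frame[k] <- t0 + exposure_ms / 2
  }
  data.frame(time_ms = t_frame, fluor_au = fbar)
}
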