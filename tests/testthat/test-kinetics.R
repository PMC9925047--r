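test_that("rate law evaluates k0 * exp(-z V / kT) with the stated sign", {
  cc <- model_constants()
  expect_equal(cc$thermal_voltage_mV, 25.693, tolerance = 1e-3)

  k <- rate_law(k0 = 0.7, z = 0)
  expect_equal(evaluate_rate(k, 120, cc), 0.7)       # voltage-independent

  k1 <- rate_law(k0 = 2, z = 1)
  expect_equal(evaluate_rate(k1, -cc$thermal_voltage_mV, cc), 2 * exp(1),
               tolerance = 1e-12)

  # z = -0.5 at +2 kT: exponent -(-0.5)(2 kT)/kT = +1
  k2 <- rate_law(k0 = 3, z = -0.5)
  expect_equal(evaluate_rate(k2, 2 * cc$thermal_voltage_mV, cc), 3 * exp(1),
               tolerance = 1e-12)

  expect_error(evaluate_rate(k1, NA_real_, cc), "finite")
  expect_error(evaluate_rate(k1, 600, cc), "500")
  expect_error(rate_law(k0 = -1, z = 0), "positive")
})

test_that("generator rows sum to zero and have the two-state layout", {
  s <- two_state_scheme(k12 = 0.1, z12 = 0, k21 = 0.04, z21 = 0)
  Q <- build_generator(s, 0)
  expect_equal(Q, matrix(c(-0.1, 0.04, 0.1, -0.04), 2, 2,
                         dimnames = list(c("C", "O"), c("C", "O"))))
  set.seed(42)
  for (i in 1:10) {
    Q <- build_generator(random_scheme(5), stats::runif(1, -100, 100))
    expect_lt(max(abs(rowSums(Q))), 1e-12)
  }
})

test_that("largest eigenvalue of a connected reversible generator is zero", {
  set.seed(7)
  for (i in 1:10) {
    Q <- build_generator(random_scheme(), stats::runif(1, -80, 80))
    ev <- Re(eigen(Q, only.values = TRUE)$values)
    expect_lt(max(ev), 1e-10)
    expect_gt(max(ev), -1e-10)
    expect_true(all(ev[ev < -1e-10] < 0))
  }
})

test_that("two-state closed forms are reproduced to near machine precision", {
  cc <- model_constants()
  s <- two_state_scheme(k12 = 0.08, z12 = -0.6, k21 = 0.03, z21 = 0.4)
  for (v in c(-80, -20, 0, 35, 100)) {
    k12 <- evaluate_rate(s$transitions[["C->O"]], v, cc)
    k21 <- evaluate_rate(s$transitions[["O->C"]], v, cc)
    ss <- steady_state(s, v, cc)
    expect_equal(unname(ss["O"]), k12 / (k12 + k21), tolerance = 1e-10)
    expect_equal(sum(ss), 1, tolerance = 1e-12)
  }
  # symmetric rates: equal occupancy
  sym <- two_state_scheme(k12 = 0.05, z12 = 0, k21 = 0.05, z21 = 0)
  expect_equal(unname(steady_state(sym, 13)), c(0.5, 0.5),
               tolerance = 1e-12)

  # occupancy of the open state is a Boltzmann function of V with
  # effective charge -(z12 - z21)
  vs <- seq(-100, 100, by = 25)
  po <- vapply(vs, function(v) steady_state(s, v, cc)["O"], 0)
  k_ratio <- 0.03 / 0.08
  po_closed_form <-
    1 / (1 + k_ratio * exp(-(0.4 - (-0.6)) * vs / cc$thermal_voltage_mV))
  expect_equal(unname(po), po_closed_form, tolerance = 1e-10)
})

test_that("relaxation after a step is exponential with rate k12 + k21", {
  cc <- model_constants()
  s <- two_state_scheme(k12 = 0.06, z12 = -0.5, k21 = 0.02, z21 = 0.5)
  proto <- voltage_protocol(
    data.frame(voltage_mV = c(-60, 40), duration_ms = c(50, 400)),
    holding_mV = -60, sample_rate_kHz = 2)
  traj <- propagate(s, proto, constants = cc)
  k12 <- evaluate_rate(s$transitions[["C->O"]], 40, cc)
  k21 <- evaluate_rate(s$transitions[["O->C"]], 40, cc)
  p_inf <- k12 / (k12 + k21)
  p_00 <- steady_state(s, -60, cc)["O"]
  sel <- traj$times_ms > 50
  t_rel <- traj$times_ms[sel] - 50
  expected <- p_inf + (p_00 - p_inf) * exp(-(k12 + k21) * t_rel)
  expect_equal(unname(traj$occupancies[sel, "O"]), unname(expected),
               tolerance = 1e-10)
})

test_that("holding at the stationary state gives a constant trajectory", {
  s <- scheme_hv1_sequential()
  proto <- voltage_protocol(
    data.frame(voltage_mV = -60, duration_ms = 200), holding_mV = -60,
    sample_rate_kHz = 1)
  traj <- propagate(s, proto)
  ss <- steady_state(s, -60)
  drift <- sweep(traj$occupancies, 2, ss)
  expect_lt(max(abs(drift)), 1e-9)
})

test_that("propagation conserves probability and long runs stay normalized", {
  s <- scheme_hv1_sequential()
  proto <- voltage_protocol(
    data.frame(voltage_mV = c(-60, 100, -60), duration_ms = c(500, 2000, 3000)),
    holding_mV = -60, sample_rate_kHz = 20)  # > 1e5 time points
  traj <- propagate(s, proto)
  expect_gt(length(traj$times_ms), 1e5)
  expect_lt(max(abs(rowSums(traj$occupancies) - 1)), 1e-9)
  expect_true(all(traj$occupancies >= 0 & traj$occupancies <= 1))
})

test_that("splitting an epoch at an interior time leaves the end state unchanged", {
  set.seed(11)
  s <- random_scheme(4)
  whole <- voltage_protocol(
    data.frame(voltage_mV = c(-60, 30), duration_ms = c(20, 100)),
    holding_mV = -60, sample_rate_kHz = 1)
  split <- voltage_protocol(
    data.frame(voltage_mV = c(-60, 30, 30), duration_ms = c(20, 37.7, 62.3)),
    holding_mV = -60, sample_rate_kHz = 1)
  p0 <- steady_state(s, -60)
  t1 <- propagate(s, whole, p0)
  t2 <- propagate(s, split, p0)
  n1 <- nrow(t1$occupancies); n2 <- nrow(t2$occupancies)
  expect_equal(t1$occupancies[n1, ], t2$occupancies[n2, ],
               tolerance = 1e-10)
})

test_that("matrix-exponential propagation matches a brute-force RK4 oracle", {
  set.seed(99)
  for (i in 1:8) {
    s <- random_scheme()
    v_step <- stats::runif(1, -60, 60)
    proto <- voltage_protocol(
      data.frame(voltage_mV = v_step, duration_ms = 25),
      holding_mV = -60, sample_rate_kHz = 1)
    p0 <- steady_state(s, -60)
    traj <- propagate(s, proto, p0)
    Q <- build_generator(s, v_step)
    oracle <- rk4_occupancies(Q, unname(p0), traj$times_ms)
    expect_lt(max(abs(traj$occupancies - oracle)), 1e-6)
  }
})

test_that("long-time propagation converges to the stationary distribution", {
  set.seed(5)
  s <- random_scheme(4, rate_range = c(1e-2, 1))
  v <- 10
  ss <- steady_state(s, v)
  rates <- vapply(names(s$transitions), function(nm)
    evaluate_rate(s$transitions[[nm]], v), 0)
  t_long <- 100 / min(rates)
  proto <- voltage_protocol(
    data.frame(voltage_mV = v, duration_ms = t_long), holding_mV = v,
    sample_rate_kHz = max(2 / t_long, 1e-4))
  # arbitrary initial condition, all mass in state 1
  p0 <- c(1, rep(0, 3))
  traj <- propagate(s, proto, p0)
  expect_equal(unname(traj$occupancies[nrow(traj$occupancies), ]),
               unname(ss), tolerance = 1e-6)
})

test_that("stationary occupancies of reversible chains obey detailed balance", {
  set.seed(21)
  for (i in 1:10) {
    s <- random_chain_scheme(sample(3:5, 1))
    v <- stats::runif(1, -80, 80)
    p <- steady_state(s, v)
    for (nm in names(s$transitions)) {
      pair <- strsplit(nm, "->", fixed = TRUE)[[1]]
      flux_fwd <- p[pair[1]] * evaluate_rate(s$transitions[[nm]], v)
      rev_nm <- paste(rev(pair), collapse = "->")
      flux_rev <- p[pair[2]] * evaluate_rate(s$transitions[[rev_nm]], v)
      expect_equal(unname(flux_fwd), unname(flux_rev), tolerance = 1e-8)
    }
  }
})

test_that("current observable follows I = gch N (V - Vrev) Po + leak", {
  s <- two_state_scheme(f = c(0, 1))
  proto <- voltage_protocol(
    data.frame(voltage_mV = c(-60, 10), duration_ms = c(50, 200)),
    holding_mV = -60, sample_rate_kHz = 1)
  traj <- propagate(s, proto)

  # V = v_rev with no leak: identically zero in the test epoch
  obs0 <- observation_model(1.5, 1000, v_rev_mV = 10)
  cur <- simulate_current(traj, obs0, s)
  expect_equal(cur$current_pA[cur$voltage_mV == 10],
               rep(0, sum(cur$voltage_mV == 10)))

  # Po = 1 limit: slope gch * N (in pA/mV after pS conversion)
  always_open <- gating_scheme(
    states = "O", class = "open", f = 1, transitions = list())
  for (v in c(-40, 0, 60)) {
    protov <- voltage_protocol(
      data.frame(voltage_mV = v, duration_ms = 10), holding_mV = v,
      sample_rate_kHz = 1)
    trajv <- propagate(always_open, protov, p0 = 1)
    obsv <- observation_model(2, 500, v_rev_mV = -15)
    iv <- simulate_current(trajv, obsv, always_open)
    expect_equal(iv$current_pA[1], 2 * 500 * (v - (-15)) / 1000)
  }

  # leak term only
  closed <- two_state_scheme(k12 = 1e-6, z12 = 0, k21 = 1, z21 = 0)
  protoh <- voltage_protocol(
    data.frame(voltage_mV = -60, duration_ms = 10), holding_mV = -60,
    sample_rate_kHz = 1)
  trajh <- propagate(closed, protoh)
  obsl <- observation_model(0, 0, v_rev_mV = 0, gamma_leak_nS = 0.5,
                            v_rev_leak_mV = -10)
  il <- simulate_current(trajh, obsl, closed)
  expect_equal(il$current_pA[1], 0.5 * (-60 - (-10)), tolerance = 1e-9)
})

test_that("deactivation tail decays with the generator's fast eigenrate", {
  cc <- model_constants()
  s <- scheme_hv1_sequential()
  proto <- voltage_protocol(
    data.frame(voltage_mV = c(-60, 100, -60),
               duration_ms = c(200, 3000, 1500)),
    holding_mV = -60, sample_rate_kHz = 2)
  traj <- propagate(s, proto)
  obs <- observation_model(1.5, 2000, v_rev_mV = -59.2)
  cur <- simulate_current(traj, obs, s)
  tail <- cur[cur$time_ms > 3200 & cur$time_ms <= 4700, ]
  ef <- fit_exponential(tail, t0_ms = 3200, window = c(3200, 4700),
                        direction = "decay")
  ev <- eigen(build_generator(s, -60), only.values = TRUE)$values
  tau_fast <- 1 / max(-Re(ev[Re(ev) < -1e-9]))
  expect_equal(ef$tau_ms, tau_fast, tolerance = 0.1)
})

test_that("fluorescence observable averages Sum Pi fi over the exposure", {
  # equal weights: constant trace at the common value
  s_const <- two_state_scheme(f = c(0.7, 0.7))
  proto <- voltage_protocol(
    data.frame(voltage_mV = c(-60, 40), duration_ms = c(500, 1500)),
    holding_mV = -60, sample_rate_kHz = 1, camera_Hz = 10)
  traj <- propagate(s_const, proto)
  fl <- simulate_fluorescence(traj, s_const)
  expect_equal(fl$fluor_au, rep(0.7, nrow(fl)), tolerance = 1e-9)
  expect_equal(nrow(fl), floor(2000 / 100))

  # f = [0, 1]: trace equals open-state occupancy up to frame averaging
  s01 <- two_state_scheme(k12 = 0.002, z12 = -0.4, k21 = 0.001, z21 = 0.4)
  traj2 <- propagate(s01, proto)
  fl2 <- simulate_fluorescence(traj2, s01)
  po_at_frames <- stats::approx(traj2$times_ms,
                                traj2$occupancies[, "O"],
                                xout = fl2$time_ms)$y
  # slow kinetics relative to the 100 ms frame: averaging error is small
  expect_equal(fl2$fluor_au, po_at_frames, tolerance = 1e-3)

  expect_error(simulate_fluorescence(traj, s_const, camera_Hz = 10,
                                     exposure_ms = 150), "exposure")
})

test_that("scheme construction enforces its invariants", {
  expect_error(gating_scheme(
    states = c("A", "B"), class = c("closed", "closed"), f = c(0, 0),
    transitions = list("A->B" = rate_law(1), "B->A" = rate_law(1))),
    "open")
  expect_error(gating_scheme(
    states = c("A", "B"), class = c("closed", "open"), f = c(0, 1),
    transitions = list("A->B" = rate_law(1))), "reverse")
  # disconnected graph
  expect_error(gating_scheme(
    states = c("A", "B", "C", "D"), class = c("closed", "closed",
                                              "closed", "open"),
    f = c(0, 0, 0, 1),
    transitions = list("A->B" = rate_law(1), "B->A" = rate_law(1),
                       "C->D" = rate_law(1), "D->C" = rate_law(1))),
    "connected")
  # irreversible allowed when flagged
  s <- gating_scheme(
    states = c("A", "B"), class = c("closed", "open"), f = c(0, 1),
    transitions = list("A->B" = rate_law(1)), allow_irreversible = TRUE)
  expect_s3_class(s, "gating_scheme")
})

test_that("scheme files round-trip through YAML", {
  s <- scheme_hv1_sequential()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(s, path)
  s2 <- read_scheme(path)
  expect_equal(s2$states, s$states)
  expect_equal(s2$f, s$f)
  for (nm in names(s$transitions)) {
    expect_equal(s2$transitions[[nm]]$k0, s$transitions[[nm]]$k0)
    expect_equal(s2$transitions[[nm]]$z, s$transitions[[nm]]$z)
  }
})
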