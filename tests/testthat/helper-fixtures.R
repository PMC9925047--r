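# Shared fixtures: schemes built in code, no stored data.

# Two-state C <-> O scheme with explicit rates
two_state_scheme <- function(k12 = 0.1, z12 = -0.5, k21 = 0.05, z21 = 0.5,
                             f = c(0, 1)) {
  gating_scheme(
    states = c("C", "O"), class = c("closed", "open"), f = f,
    transitions = list("C->O" = rate_law(k12, z12),
                       "O->C" = rate_law(k21, z21)))
}

# Random connected reversible scheme: spanning tree plus optional extra
# edges; rates log-uniform, charges uniform in [-1, 1].
random_scheme <- function(n_states = sample(3:6, 1),
                          rate_range = c(1e-4, 1), extra_edges = 1) {
  states <- paste0("S", seq_len(n_states))
  edges <- cbind(2:n_states, vapply(2:n_states,
                                    function(i) sample(i - 1, 1), 0L))
  if (extra_edges > 0) {
    all_pairs <- t(combn(n_states, 2))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    avail <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% key, ,
                       drop = FALSE]
    if (nrow(avail))
      edges <- rbind(edges, avail[sample(nrow(avail),
                                         min(extra_edges, nrow(avail))), ,
                                  drop = FALSE])
  }
  rlu <- function() exp(stats::runif(1, log(rate_range[1]),
                                     log(rate_range[2])))
  trans <- list()
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    trans[[paste0(states[i], "->", states[j])]] <-
      rate_law(rlu(), stats::runif(1, -1, 1))
    trans[[paste0(states[j], "->", states[i])]] <-
      rate_law(rlu(), stats::runif(1, -1, 1))
  }
  cls <- c(rep("closed", n_states - 1), "open")
  gating_scheme(states = states, class = cls,
                f = stats::runif(n_states), transitions = trans)
}

# Random reversible linear chain (for detailed-balance checks)
random_chain_scheme <- function(n_states = 4) {
  states <- paste0("S", seq_len(n_states))
  trans <- list()
  for (i in seq_len(n_states - 1)) {
    trans[[paste0(states[i], "->", states[i + 1])]] <-
      rate_law(exp(stats::runif(1, log(1e-3), log(1))),
               stats::runif(1, -1, 1))
    trans[[paste0(states[i + 1], "->", states[i])]] <-
      rate_law(exp(stats::runif(1, log(1e-3), log(1))),
               stats::runif(1, -1, 1))
  }
  gating_scheme(states = states,
                class = c(rep("closed", n_states - 1), "open"),
                f = seq(0, 1, length.out = n_states), transitions = trans)
}

# Brute-force fixed-step 4th-order Runge-Kutta master-equation integrator
# (independent of the package's propagator).
rk4_occupancies <- function(Q, p0, times) {
  QT <- t(Q)
  maxrate <- max(abs(diag(Q)))
  dt <- min(0.02 / max(maxrate, 1e-12), diff(range(times)) / 50)
  deriv <- function(p) as.numeric(QT %*% p)
  out <- matrix(NA_real_, length(times), length(p0))
  p <- p0; tcur <- times[1]
  out[1, ] <- p
  for (k in 2:length(times)) {
    target <- times[k]
    while (tcur < target - 1e-12) {
      h <- min(dt, target - tcur)
      k1 <- deriv(p)
      k2 <- deriv(p + h / 2 * k1)
      k3 <- deriv(p + h / 2 * k2)
      k4 <- deriv(p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tcur <- tcur + h
    }
    out[k, ] <- p
  }
  out
}
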