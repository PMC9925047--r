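#' Voltage-dependent transition rate law
#'
#' A transition rate follows k(V) = k0 * exp(-z * V / (kB*T/e0)): `k0` is the
#' rate at 0 mV and `z` the partial charge moved during the transition, in
#' elementary charges. Transitions that speed up with depolarization carry
#' negative `z` under this sign convention.
#'
#' @param k0 Rate at 0 mV in ms^-1; strictly positive.
#' @param z Partial charge in e0; any sign.
#' @return A `rate_law` object.
#' @export
rate_law <- function(k0, z = 0) {
  if (!is.numeric(k0) || length(k0) != 1L || !is.finite(k0) || k0 <= 0)
    stop("k0 must be a single strictly positive finite number (ms^-1)",
         call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("z must be a single finite number (e0)", call. = FALSE)
  structure(list(k0 = k0, z = z), class = "rate_law")
}

#' Evaluate a rate law at a membrane potential
#'
#' @param law A [rate_law()].
#' @param v Membrane potential in mV; |v| must not exceed 500 mV.
#' @param constants A [model_constants()] object.
#' @return The rate in ms^-1 (strictly positive).
#' @examples
#' k <- rate_law(k0 = 1, z = 1)
#' evaluate_rate(k, -25.693, model_constants())  # exp(1) = 2.71828...
#' @export
evaluate_rate <- function(law, v, constants = model_constants()) {
  stopifnot(inherits(law, "rate_law"))
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("v must be finite (mV)", call. = FALSE)
  if (any(abs(v) > 500))
    stop("|v| > 500 mV is outside the supported range", call. = FALSE)
  law$k0 * exp(-law$z * v / kT_mV(constants))
}

#' Markov gating scheme
#'
#' A gating scheme is a connected graph of channel states. Each state has a
#' class tag (`closed` or `open`), a fluorescence weight `f` (arbitrary
#' units, the per-state brightness the reporter fluorophore would emit) and a
#' conducting flag used by the current observable. Each directed transition
#' (i -> j) carries its own [rate_law()].
#'
#' @param states Character vector of unique state labels, in order.
#' @param class Character vector, one of `"closed"`/`"open"` per state.
#' @param f Numeric vector of per-state fluorescence weights (>= 0).
#' @param conducting Logical vector; defaults to `class == "open"`.
#' @param transitions Named list of [rate_law()] objects; names of the form
#'   `"from->to"` using state labels, e.g. `"C1->C2"`.
#' @param allow_irreversible If `FALSE` (default) every transition must have
#'   its reverse; set `TRUE` to permit one-way transitions.
#' @return A `gating_scheme` object.
#' @examples
#' two_state <- gating_scheme(
#'   states = c("C", "O"), class = c("closed", "open"), f = c(0, 1),
#'   transitions = list("C->O" = rate_law(0.1, -0.5),
#'                      "O->C" = rate_law(0.05, 0.5)))
#' @export
gating_scheme <- function(states, class, f = rep(0, length(states)),
                          conducting = NULL, transitions,
                          allow_irreversible = FALSE) {
  if (anyDuplicated(states)) stop("state labels must be unique", call. = FALSE)
  n <- length(states)
  if (length(class) != n || !all(class %in% c("closed", "open")))
    stop("class must be 'closed' or 'open' for each state", call. = FALSE)
  if (!any(class == "open"))
    stop("scheme must contain at least one open state", call. = FALSE)
  if (length(f) != n || any(!is.finite(f)) || any(f < 0))
    stop("f must be a non-negative finite weight per state", call. = FALSE)
  if (is.null(conducting)) conducting <- class == "open"
  if (length(conducting) != n || !is.logical(conducting))
    stop("conducting must be one logical per state", call. = FALSE)
  if (length(transitions) == 0 && n > 1)
    stop("a multi-state scheme needs transitions", call. = FALSE)

  parsed <- lapply(names(transitions), function(nm) {
    pair <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    if (length(pair) != 2L || !all(pair %in% states))
      stop(sprintf("transition '%s' does not name two known states", nm),
           call. = FALSE)
    if (pair[1L] == pair[2L])
      stop("self-transitions are not allowed", call. = FALSE)
    pair
  })
  for (tr in transitions)
    if (!inherits(tr, "rate_law"))
      stop("every transition must be a rate_law", call. = FALSE)
  keys <- vapply(parsed, paste, "", collapse = "->")
  if (anyDuplicated(keys)) stop("duplicate transitions", call. = FALSE)
  if (!allow_irreversible) {
    rev_keys <- vapply(parsed, function(p) paste(rev(p), collapse = "->"), "")
    missing_rev <- setdiff(rev_keys, keys)
    if (length(missing_rev))
      stop("missing reverse transitions (set allow_irreversible = TRUE to ",
           "permit): ", paste(missing_rev, collapse = ", "), call. = FALSE)
  }

  scheme <- structure(
    list(states = states, class = class, f = as.numeric(f),
         conducting = conducting, transitions = transitions,
         allow_irreversible = allow_irreversible),
    class = "gating_scheme")
  if (!scheme_is_connected(scheme))
    stop("transition graph is not connected", call. = FALSE)
  scheme
}

scheme_is_connected <- function(scheme) {
  n <- length(scheme$states)
  if (n == 1L) return(TRUE)
  adj <- matrix(FALSE, n, n, dimnames = list(scheme$states, scheme$states))
  for (nm in names(scheme$transitions)) {
    pair <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    adj[pair[1L], pair[2L]] <- TRUE
    adj[pair[2L], pair[1L]] <- TRUE  # undirected reachability
  }
  seen <- logical(n); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat(sprintf("gating_scheme: %d states (%s)\n", length(x$states),
              paste(x$states, collapse = ", ")))
  for (nm in names(x$transitions)) {
    tr <- x$transitions[[nm]]
    cat(sprintf("  %-10s k0 = %.4g ms^-1, z = %+.3g e0\n", nm, tr$k0, tr$z))
  }
  invisible(x)
}

#' Built-in three-state sequential activation scheme
#'
#' Ships the package's default gating model for the proton channel voltage
#' sensor: a linear chain C1 <-> C2 <-> O3 with a single conducting open
#' state. The defining kinetic feature is that the backward step between the
#' closed states (C2 -> C1) is much slower than channel closing (O3 -> C2),
#' so that on repolarization the current tail decays mono-exponentially
#' while the fluorescence off-response is bi-exponential with a slow
#' component in the seconds range. Fluorescence weights report voltage-sensor
#' position: the resting state C1 is quenched (f = 0) and both activated
#' states (C2, O3) are bright (f = 1).
#'
#' Numeric rate parameters are package defaults chosen to reproduce the
#' qualitative kinetics above at the reference gradient `dpH = 1`
#' (activation midpoint near +20 mV, tail time constant ~140 ms at -60 mV,
#' slow off-component of several seconds); they are not fitted values.
#'
#' @param dpH Transmembrane pH gradient (pHo - pHi). Activation shifts
#'   -`dv_per_dpH` mV per unit increase relative to the reference dpH = 1,
#'   implemented by shifting every voltage-dependent rate along V.
#' @param dv_per_dpH Shift magnitude in mV per pH unit (default 40).
#' @param rate_overrides Named list of [rate_law()] objects replacing the
#'   defaults after the dpH shift, e.g. `list("C2->C1" = rate_law(...))`; use
#'   to weaken the slow backward step under particular pH conditions.
#' @param constants A [model_constants()] object (used by the shift).
#' @return A [gating_scheme()].
#' @export
scheme_hv1_sequential <- function(dpH = 1, dv_per_dpH = 40,
                                  rate_overrides = NULL,
                                  constants = model_constants()) {
  base <- list(
    "C1->C2" = rate_law(k0 = 1.390e-4, z = -0.9),
    "C2->C1" = rate_law(k0 = 9.866e-5, z = 0.2),
    "C2->O3" = rate_law(k0 = 1.177e-3, z = -0.55),
    "O3->C2" = rate_law(k0 = 2.371e-3, z = 0.45)
  )
  dv <- dv_per_dpH * (dpH - 1)
  kT <- kT_mV(constants)
  shifted <- lapply(base, function(tr)
    rate_law(k0 = tr$k0 * exp(-tr$z * dv / kT), z = tr$z))
  if (!is.null(rate_overrides)) {
    if (!all(names(rate_overrides) %in% names(shifted)))
      stop("rate_overrides names unknown transitions", call. = FALSE)
    shifted[names(rate_overrides)] <- rate_overrides
  }
  gating_scheme(
    states = c("C1", "C2", "O3"),
    class = c("closed", "closed", "open"),
    f = c(0, 1, 1),
    transitions = shifted)
}

#' Allosteric ladder gating scheme
#'
#' A 2x2 ladder of closed and open states in which opening is allowed from a
#' partially activated closed state: C1 <-> C2 (sensor activation),
#' C1 <-> O1 and C2 <-> O2 (pore opening), O1 <-> O2. This topology is a
#' configurable approximation of an allosteric gating variant; it is not a
#' fitted model.
#'
#' @param rates Named list of [rate_law()] objects overriding any of the six
#'   default transitions `C1->C2`, `C2->C1`, `C1->O1`, `O1->C1`, `C2->O2`,
#'   `O2->C2`, `O1->O2`, `O2->O1`.
#' @return A [gating_scheme()].
#' @export
scheme_allosteric <- function(rates = NULL) {
  base <- list(
    "C1->C2" = rate_law(0.02, -1.0), "C2->C1" = rate_law(5e-4, 0.3),
    "C1->O1" = rate_law(1e-4, -0.2), "O1->C1" = rate_law(0.05, 0.2),
    "C2->O2" = rate_law(0.03, -0.4), "O2->C2" = rate_law(0.01, 0.4),
    "O1->O2" = rate_law(0.02, -1.0), "O2->O1" = rate_law(5e-4, 0.3)
  )
  if (!is.null(rates)) {
    if (!all(names(rates) %in% names(base)))
      stop("rates names unknown transitions", call. = FALSE)
    base[names(rates)] <- rates
  }
  gating_scheme(
    states = c("C1", "C2", "O1", "O2"),
    class = c("closed", "closed", "open", "open"),
    f = c(0, 1, 0, 1),
    transitions = base)
}

#' Read / write a gating scheme as a YAML file
#'
#' The on-disk format lists `states` (label, class, f, conducting) and
#' `transitions` (from, to, k0 in ms^-1, z in e0).
#'
#' @param path File path.
#' @param scheme A [gating_scheme()] (for writing).
#' @return `read_scheme` returns a [gating_scheme()]; `write_scheme`
#'   invisibly returns `path`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path))
    stop("scheme file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$states) || is.null(doc$transitions))
    stop("scheme file must contain 'states' and 'transitions'", call. = FALSE)
  st <- doc$states
  trs <- stats::setNames(
    lapply(doc$transitions, function(tr) rate_law(tr$k0, tr$z)),
    vapply(doc$transitions, function(tr) paste0(tr$from, "->", tr$to), ""))
  gating_scheme(
    states = vapply(st, `[[`, "", "label"),
    class = vapply(st, `[[`, "", "class"),
    f = vapply(st, function(s) as.numeric(s$f %||% 0), 0),
    conducting = vapply(st, function(s)
      isTRUE(s$conducting %||% (s$class == "open")), NA),
    transitions = trs,
    allow_irreversible = isTRUE(doc$allow_irreversible))
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "gating_scheme"))
  doc <- list(
    states = lapply(seq_along(scheme$states), function(i) list(
      label = scheme$states[i], class = scheme$class[i],
      f = scheme$f[i], conducting = scheme$conducting[i])),
    transitions = lapply(names(scheme$transitions), function(nm) {
      pair <- strsplit(nm, "->", fixed = TRUE)[[1L]]
      tr <- scheme$transitions[[nm]]
      list(from = pair[1L], to = pair[2L], k0 = tr$k0, z = tr$z)
    }),
    allow_irreversible = scheme$allow_irreversible)
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
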