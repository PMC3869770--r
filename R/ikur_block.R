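# Voltage- and time-dependent IKur inhibition.  The non-blocked fraction
# y_Kur relaxes toward a Boltzmann steady state (half-maximum block at
# -40 mV, slope 5 mV, 90% maximal block) with a voltage-dependent time
# constant interpolating between tau_onset (depolarized) and tau_recovery
# (hyperpolarized).  Five model compounds span the kinetic space; compound #5
# is a state-independent (tonic) 50% block.

#' Block kinetics of one IKur inhibitor
#'
#' Dynamic compounds are described by an onset time constant (block
#' development at depolarized voltages) and a recovery time constant (unblock
#' at hyperpolarized voltages).  A tonic compound instead fixes the
#' non-blocked fraction at a constant level at every voltage.
#'
#' @param name compound label.
#' @param tau_onset,tau_recovery time constants (ms), both positive; omit for
#'   a tonic compound.
#' @param tonic_level fixed non-blocked fraction in (0, 1); omit for a
#'   dynamic compound.
#' @return a `compound_kinetics` object.
#' @export
#' @examples
#' compound_kinetics("#1", tau_onset = 5, tau_recovery = 1000)
#' compound_kinetics("#5", tonic_level = 0.5)
compound_kinetics <- function(name, tau_onset = NULL, tau_recovery = NULL,
                              tonic_level = NULL) {
  dyn <- !is.null(tau_onset) || !is.null(tau_recovery)
  if (dyn) {
    if (!is.null(tonic_level))
      stop("a dynamic compound cannot also have a tonic level")
    if (is.null(tau_onset) || is.null(tau_recovery) ||
        tau_onset <= 0 || tau_recovery <= 0)
      stop("dynamic compounds need tau_onset > 0 and tau_recovery > 0")
  } else {
    if (is.null(tonic_level) || tonic_level <= 0 || tonic_level >= 1)
      stop("a tonic compound needs tonic_level in (0, 1)")
  }
  structure(list(name = name, tau_onset = tau_onset,
                 tau_recovery = tau_recovery, tonic_level = tonic_level),
            class = "compound_kinetics")
}

#' @rdname compound_kinetics
#' @param x object to test.
#' @export
is_tonic <- function(x) {
  inherits(x, "compound_kinetics") && !is.null(x$tonic_level)
}

#' The five model compounds
#'
#' The compound library: #1 fast onset / slow recovery (5 / 1000 ms),
#' #2 fast onset / fast recovery (16 / 238 ms), #3 slow onset / slow recovery
#' (100 / 16000 ms), #4 slow onset / fast recovery (200 / 250 ms), and #5 a
#' tonic 50% block (the heterozygous loss-of-function situation).  Shipped as
#' a plain-text config in `inst/extdata/compounds.yaml`.
#'
#' @param id optional compound id (1-5 or "#1".."#5"); if missing, the whole
#'   library is returned.
#' @return a named list of [compound_kinetics()] objects, or a single one.
#' @export
#' @examples
#' compound_library("#1")$tau_recovery
compound_library <- function(id = NULL) {
  path <- system.file("extdata", "compounds.yaml", package = "atriawave")
  raw <- yaml::read_yaml(path)
  lib <- lapply(raw, function(r)
    compound_kinetics(r$name, tau_onset = r$tau_onset,
                      tau_recovery = r$tau_recovery,
                      tonic_level = r$tonic_level))
  names(lib) <- vapply(lib, `[[`, "", "name")
  if (is.null(id)) return(lib)
  if (is.numeric(id)) id <- paste0("#", id)
  if (!id %in% names(lib)) stop("unknown compound: ", id)
  lib[[id]]
}

#' Voltage dependence of IKur block
#'
#' Steady-state non-blocked fraction: a Boltzmann function
#' `y_inf = 1 - max_block / (1 + exp(-(Vm - v_half)/slope))`.  At strongly
#' hyperpolarized voltages the channel is not inhibited (`y_inf -> 1`); at
#' strongly depolarized voltages up to `max_block` of the channels are
#' blocked.
#'
#' @param v_half half-maximum block voltage (mV).
#' @param slope slope factor (mV), positive.
#' @param max_block maximal blocked fraction in \[0, 1\].
#' @return a `block_params` list.
#' @export
block_params <- function(v_half = -40, slope = 5, max_block = 0.9) {
  stopifnot(slope > 0, max_block >= 0, max_block <= 1)
  structure(list(v_half = v_half, slope = slope, max_block = max_block),
            class = "block_params")
}

#' @rdname block_params
#' @param vm membrane voltage (mV), vectorized.
#' @param bp a `block_params` object.
#' @export
#' @examples
#' block_steady_state(-40)   # half-maximum point: 1 - 0.9/2
block_steady_state <- function(vm, bp = block_params()) {
  1 - bp$max_block / (1 + exp(-(vm - bp$v_half) / bp$slope))
}

#' Voltage-dependent time constant of block
#'
#' Sigmoidal interpolation between `tau_recovery` (hyperpolarized limit) and
#' `tau_onset` (depolarized limit), sharing the midpoint and slope of the
#' steady-state Boltzmann so that block develops with `tau_onset` wherever it
#' develops at all.  The interpolation is exposed here so alternative shapes
#' (e.g. a hard switch) can be compared.
#'
#' @param vm membrane voltage (mV), vectorized.
#' @param compound a dynamic [compound_kinetics()].
#' @param bp a [block_params()] object supplying midpoint and slope.
#' @return time constant(s) in ms.
#' @export
#' @examples
#' block_time_constant(30, compound_library("#1"))    # ~5 ms
#' block_time_constant(-80, compound_library("#1"))   # ~1000 ms
block_time_constant <- function(vm, compound, bp = block_params()) {
  stopifnot(inherits(compound, "compound_kinetics"))
  if (is_tonic(compound))
    stop("a tonic compound has no block dynamics")
  s <- 1 / (1 + exp(-(vm - bp$v_half) / bp$slope))
  compound$tau_recovery + (compound$tau_onset - compound$tau_recovery) * s
}

#' Advance the non-blocked IKur fraction
#'
#' Exact exponential (Rush-Larsen) relaxation of `y` toward
#' [block_steady_state()] with time constant [block_time_constant()].  For a
#' tonic compound the level is returned unconditionally.
#'
#' @param y current non-blocked fraction in \[0, 1\].
#' @param vm membrane voltage (mV).
#' @param dt time step (ms), non-negative.
#' @param compound a [compound_kinetics()].
#' @param bp a [block_params()] object.
#' @return the updated non-blocked fraction.
#' @export
update_block <- function(y, vm, dt, compound, bp = block_params()) {
  stopifnot(dt >= 0, all(y >= 0 & y <= 1))
  if (is_tonic(compound)) return(rep_len(compound$tonic_level, length(y)))
  yinf <- block_steady_state(vm, bp)
  tau <- block_time_constant(vm, compound, bp)
  yinf + (y - yinf) * exp(-dt / tau)
}

#' IKur under block
#'
#' The CRN IKur current density multiplied by the non-blocked fraction
#' carried in the state (`ykur`).
#'
#' @param state a `crn_state` vector.
#' @param params a `crn_params` object.
#' @return current density (pA/pF).
#' @export
blocked_ikur <- function(state, params = crn_params()) {
  ionic_currents(state, params)$i_kur
}

#' Repeated voltage-step assay of IKur block
#'
#' Reproduces the voltage-clamp characterization of the compounds: a
#' rectangular step from the holding potential to a depolarized level,
#' repeated at a fixed rate, with the activation/inactivation gates and the
#' block variable evolving across pulses.  Under piecewise-constant voltage
#' all three variables relax exponentially, so the trace is evaluated in
#' closed form (this also makes the assay an independent oracle for the
#' stepping kernel).
#'
#' @param compound a [compound_kinetics()] or `NULL` for the drug-free trace.
#' @param bp a [block_params()] object.
#' @param n_pulses number of pulses.
#' @param v_hold,v_step holding and step voltage (mV).
#' @param step_ms step duration (ms).
#' @param bcl pulse period (ms); 1000 for 1 Hz.
#' @param sample_dt output sampling (ms).
#' @param params a `crn_params` object (for the K reversal).
#' @return list with the trace data.frame (`t`, `vm`, `ua`, `ui`, `y`,
#'   `ikur`) and `pulse_block`: per-pulse blocked fraction `1 - y` at the end
#'   of each step.
#' @export
voltage_step_assay <- function(compound = NULL, bp = block_params(),
                               n_pulses = 10, v_hold = -80, v_step = 30,
                               step_ms = 500, bcl = 1000, sample_dt = 1,
                               params = crn_params()) {
  stopifnot(step_ms < bcl, n_pulses >= 1)
  ek <- .crn_const$RTF * log(params$k_o / 139)
  gkur <- function(v) params$g_kur_scale *
    (0.005 + 0.05 / (1 + exp(-(v - 15) / 13)))
  # gate rates at a constant voltage
  gr <- function(v) {
    a_ua <- 0.65 / (exp(-(v + 10) / 8.5) + exp(-(v - 30) / 59))
    b_ua <- 0.65 / (2.5 + exp((v + 82) / 17))
    a_ui <- 1 / (21 + exp(-(v - 185) / 28))
    b_ui <- exp((v - 158) / 16)
    list(ua_inf = 1 / (1 + exp(-(v + 30.3) / 9.6)),
         tau_ua = 1 / (3 * (a_ua + b_ua)),
         ui_inf = 1 / (1 + exp((v - 99.45) / 27.48)),
         tau_ui = 1 / (3 * (a_ui + b_ui)))
  }
  relax <- function(x0, xinf, tau, t) xinf + (x0 - xinf) * exp(-t / tau)
  y_pars <- function(v) {
    if (is.null(compound)) list(yinf = 1, tau = Inf, tonic = NULL)
    else if (is_tonic(compound))
      list(yinf = compound$tonic_level, tau = 0, tonic = compound$tonic_level)
    else list(yinf = block_steady_state(v, bp),
              tau = block_time_constant(v, compound, bp), tonic = NULL)
  }
  ua <- gr(v_hold)$ua_inf; ui <- gr(v_hold)$ui_inf; y <- 1
  rows <- vector("list", 2 * n_pulses)
  pulse_block <- numeric(n_pulses)
  seg <- function(t0, v, dur, ua0, ui0, y0) {
    tt <- seq(0, dur, by = sample_dt)
    r <- gr(v); yp <- y_pars(v)
    ua <- relax(ua0, r$ua_inf, r$tau_ua, tt)
    ui <- relax(ui0, r$ui_inf, r$tau_ui, tt)
    y <- if (!is.null(yp$tonic)) rep(yp$tonic, length(tt))
         else if (is.infinite(yp$tau)) rep(1, length(tt))
         else relax(y0, yp$yinf, yp$tau, tt)
    data.frame(t = t0 + tt, vm = v, ua = ua, ui = ui, y = y,
               ikur = gkur(v) * ua^3 * ui * (v - ek) * y)
  }
  for (p in seq_len(n_pulses)) {
    t0 <- (p - 1) * bcl
    up <- seg(t0, v_step, step_ms, ua, ui, y)
    n <- nrow(up)
    pulse_block[p] <- 1 - up$y[n]
    dn <- seg(t0 + step_ms, v_hold, bcl - step_ms, up$ua[n], up$ui[n], up$y[n])
    ua <- dn$ua[nrow(dn)]; ui <- dn$ui[nrow(dn)]; y <- dn$y[nrow(dn)]
    rows[[2 * p - 1]] <- up; rows[[2 * p]] <- dn
  }
  list(trace = do.call(rbind, rows), pulse_block = pulse_block)
}
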