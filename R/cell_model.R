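# Courtemanche-Ramirez-Nattel (CRN) human atrial myocyte model:
# parameter sets, initial conditions, chronic-AF remodeling, pacing and
# action-potential metrics.  The stiff inner loop lives in src/engine.cpp;
# ionic_currents() is an independent pure-R evaluation of the same current
# set used for validation.

#' CRN model parameters
#'
#' Maximal conductances (nS/pF) and pump/exchanger scaling factors of the
#' Courtemanche-Ramirez-Nattel human atrial myocyte model, plus a flag
#' recording whether chronic-AF electrical remodeling has been applied.
#'
#' @param remodeled logical; if `TRUE`, [apply_remodeling()] is applied to the
#'   baseline parameter set before returning.
#' @return an object of class `crn_params` (named list).
#' @seealso [apply_remodeling()], [crn_initial_state()]
#' @export
#' @examples
#' p <- crn_params()
#' p$g_k1
crn_params <- function(remodeled = FALSE) {
  p <- structure(list(
    g_na = 7.8, g_k1 = 0.09, g_to = 0.1652, g_kur_scale = 1,
    g_kr = 0.029411765, g_ks = 0.12941176, g_cal = 0.12375,
    g_bca = 0.001131, g_bna = 0.0006744375,
    i_nak_max = 0.59933874, i_naca_max = 1600, i_pca_max = 0.275,
    cm = 100, na_o = 140, k_o = 5.4, ca_o = 1.8,
    remodeled = FALSE
  ), class = "crn_params")
  if (remodeled) p <- apply_remodeling(p)
  p
}

#' Apply chronic-AF electrical remodeling
#'
#' Scales the maximal conductances by the chronic-AF remodeling factors:
#' IK1 increased by 110% (x2.1), ICa,L and Ito each decreased by 65% (x0.35).
#' The accompanying 30% reduction of tissue conductivity is applied at the
#' tissue level (see [init_strand()]), not here.  Applying remodeling twice
#' is an error.
#'
#' @param params a `crn_params` object.
#' @return the remodeled `crn_params` object with `remodeled = TRUE`.
#' @export
apply_remodeling <- function(params) {
  stopifnot(inherits(params, "crn_params"))
  if (isTRUE(params$remodeled))
    stop("remodeling has already been applied to this parameter set")
  params$g_k1 <- params$g_k1 * 2.1
  params$g_cal <- params$g_cal * 0.35
  params$g_to <- params$g_to * 0.35
  params$remodeled <- TRUE
  params
}

#' State variable names of the CRN model
#' @keywords internal
crn_state_names <- function() {
  c("vm", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
    "d", "f", "fca", "u", "vg", "w", "nai", "cai", "ki", "carel", "caup",
    "ykur")
}

#' CRN resting initial state
#'
#' The published resting state of the CRN model (quiescent, 1 Hz-adapted),
#' extended with the non-blocked IKur fraction `ykur = 1` (drug free).
#' `vm` is in mV, concentrations in mM, gates dimensionless.
#'
#' @return a named numeric vector of class `crn_state`.
#' @export
crn_initial_state <- function() {
  s <- c(
    vm = -81.18, m = 2.908e-3, h = 9.649e-1, j = 9.775e-1,
    oa = 3.043e-2, oi = 9.992e-1, ua = 4.966e-3, ui = 9.986e-1,
    xr = 3.296e-5, xs = 1.869e-2, d = 1.367e-4, f = 9.996e-1,
    fca = 7.755e-1, u = 0, vg = 1, w = 9.992e-1,
    nai = 11.17, cai = 1.013e-4, ki = 139.0, carel = 1.488, caup = 1.488,
    ykur = 1
  )
  class(s) <- "crn_state"
  s
}

#' Validate a CRN state vector
#' @keywords internal
check_state <- function(state) {
  nm <- crn_state_names()
  if (length(state) != length(nm))
    stop("state must have ", length(nm), " elements")
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite state variable: ", paste(nm[bad], collapse = ", "))
  invisible(state)
}

# physical constants shared by the R-side current evaluation
.crn_const <- list(RTF = 8.3143 * 310 / 96.4867, Far = 96.4867)

#' Evaluate all CRN membrane currents at a given state
#'
#' Pure-R evaluation of the instantaneous CRN current set (pA/pF), including
#' IKur with its non-blocked fraction `ykur`.  Used as an independent check
#' of the compiled stepping engine and for current-level diagnostics.
#'
#' @param state a `crn_state` vector (see [crn_initial_state()]).
#' @param params a `crn_params` object.
#' @return named list of current densities (pA/pF) including `i_total`, plus
#'   the Nernst potentials.
#' @export
#' @examples
#' cur <- ionic_currents(crn_initial_state(), crn_params())
#' abs(cur$i_total) < 0.05
ionic_currents <- function(state, params = crn_params()) {
  check_state(state)
  s <- as.list(state)
  names(s) <- crn_state_names()
  RTF <- .crn_const$RTF
  ena <- RTF * log(params$na_o / s$nai)
  ek <- RTF * log(params$k_o / s$ki)
  eca <- RTF / 2 * log(params$ca_o / s$cai)
  v <- s$vm

  i_na <- params$g_na * s$m^3 * s$h * s$j * (v - ena)
  i_k1 <- params$g_k1 * (v - ek) / (1 + exp(0.07 * (v + 80)))
  i_to <- params$g_to * s$oa^3 * s$oi * (v - ek)
  g_kur <- params$g_kur_scale * (0.005 + 0.05 / (1 + exp(-(v - 15) / 13)))
  i_kur <- g_kur * s$ua^3 * s$ui * (v - ek) * s$ykur
  i_kr <- params$g_kr * s$xr * (v - ek) / (1 + exp((v + 15) / 22.4))
  i_ks <- params$g_ks * s$xs^2 * (v - ek)
  i_cal <- params$g_cal * s$d * s$f * s$fca * (v - 65)
  sig <- (exp(params$na_o / 67.3) - 1) / 7
  f_nak <- 1 / (1 + 0.1245 * exp(-0.1 * v / RTF) + 0.0365 * sig * exp(-v / RTF))
  i_nak <- params$i_nak_max * f_nak * (1 / (1 + (10 / s$nai)^1.5)) *
    params$k_o / (params$k_o + 1.5)
  e1 <- exp(0.35 * v / RTF)
  e2 <- exp(-0.65 * v / RTF)
  den <- (87.5^3 + params$na_o^3) * (1.38 + params$ca_o) * (1 + 0.1 * e2)
  i_naca <- params$i_naca_max *
    (e1 * s$nai^3 * params$ca_o - e2 * params$na_o^3 * s$cai) / den
  i_bna <- params$g_bna * (v - ena)
  i_bca <- params$g_bca * (v - eca)
  i_pca <- params$i_pca_max * s$cai / (0.0005 + s$cai)

  i_total <- i_na + i_k1 + i_to + i_kur + i_kr + i_ks + i_cal +
    i_nak + i_naca + i_bna + i_bca + i_pca
  list(i_na = i_na, i_k1 = i_k1, i_to = i_to, i_kur = i_kur, i_kr = i_kr,
       i_ks = i_ks, i_cal = i_cal, i_nak = i_nak, i_naca = i_naca,
       i_bna = i_bna, i_bca = i_bca, i_pca = i_pca, i_total = i_total,
       e_na = ena, e_k = ek, e_ca = eca)
}

#' Advance a single cell by one time step
#'
#' One Rush-Larsen / forward-Euler step of the CRN model (the same compiled
#' kernel used by the tissue solver, on a 1-node grid).
#'
#' @param state a `crn_state` vector.
#' @param dt time step (ms), must be positive.
#' @param i_stim stimulus current density (pA/pF, depolarizing positive).
#' @param params a `crn_params` object.
#' @param compound optional [compound_kinetics()]; block dynamics active from
#'   time 0.
#' @return the updated `crn_state`.
#' @export
step_cell <- function(state, dt, i_stim = 0, params = crn_params(),
                      compound = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  check_state(state)
  res <- sim_run(matrix(unclass(state), ncol = 1), params, compound,
                 drug_on = 0, D = 0, dx = 1, nx = 1, ny = 1, dt = dt,
                 t0 = 0, duration = dt,
                 stims = list(stim_event(0, dt, i_stim, nodes = 1)),
                 probes = 1, sample_dt = dt)
  out <- res$state[, 1]
  names(out) <- crn_state_names()
  class(out) <- "crn_state"
  out
}

#' Pace a single cell to steady state
#'
#' Paces one CRN cell with rectangular stimuli (default 2 ms, 20 pA/pF,
#' roughly twice diastolic threshold) at a fixed basic cycle length and
#' returns the full voltage trace together with per-beat AP metrics.
#'
#' @param params a `crn_params` object.
#' @param compound optional [compound_kinetics()] for IKur block; the drug is
#'   present from `drug_on` (ms, default 0 = whole run).
#' @param bcl basic cycle length (ms).
#' @param n_beats number of beats; the last beat is taken as the converged
#'   beat (APD drift is < 1 ms/beat well before 20 beats at 1 Hz).
#' @param dt integrator step (ms); the reference value is 0.01.
#' @param sample_dt trace sampling interval (ms).
#' @param stim_amp,stim_dur stimulus amplitude (pA/pF) and duration (ms).
#' @param drug_on time at which block dynamics switch on (ms).
#' @param block block voltage-dependence parameters, see [block_params()].
#' @param state optional starting `crn_state` (default: resting state).
#' @return an object of class `paced_cell`: a list with the trace
#'   (`t`, `vm`), per-beat metrics (`beats`, a data.frame with
#'   apd30/apd70/apd90/amplitude), the last-beat trace, and the final state.
#' @export
#' @examples
#' \donttest{
#' pc <- pace_cell(crn_params(remodeled = TRUE), n_beats = 5)
#' tail(pc$beats$apd90, 1)
#' }
pace_cell <- function(params = crn_params(), compound = NULL, bcl = 1000,
                      n_beats = 20, dt = 0.01, sample_dt = 0.05,
                      stim_amp = 20, stim_dur = 2, drug_on = 0,
                      block = block_params(), state = crn_initial_state()) {
  stopifnot(bcl > 0, n_beats >= 1, dt > 0)
  stim_times <- (seq_len(n_beats) - 1) * bcl
  stims <- lapply(stim_times, function(tt)
    stim_event(tt, stim_dur, stim_amp, nodes = 1))
  res <- sim_run(matrix(unclass(state), ncol = 1), params, compound,
                 drug_on = drug_on, D = 0, dx = 1, nx = 1, ny = 1, dt = dt,
                 t0 = 0, duration = n_beats * bcl, stims = stims,
                 probes = 1, sample_dt = sample_dt, block = block)
  t <- res$sample_t
  vm <- res$probe_vm[, 1]
  beats <- do.call(rbind, lapply(seq_len(n_beats), function(b) {
    sel <- t >= stim_times[b] & t < stim_times[b] + bcl
    m <- tryCatch(ap_metrics(t[sel], vm[sel]), error = function(e) NULL)
    if (is.null(m)) return(data.frame(beat = b, apd30 = NA_real_,
      apd70 = NA_real_, apd90 = NA_real_, amplitude = NA_real_,
      v_rest = NA_real_, v_peak = NA_real_))
    data.frame(beat = b, apd30 = m$apd30, apd70 = m$apd70, apd90 = m$apd90,
               amplitude = m$amplitude, v_rest = m$v_rest, v_peak = m$v_peak)
  }))
  last <- t >= stim_times[n_beats]
  fin <- res$state[, 1]
  names(fin) <- crn_state_names()
  class(fin) <- "crn_state"
  structure(list(t = t, vm = vm, beats = beats,
                 last_beat = list(t = t[last] - stim_times[n_beats],
                                  vm = vm[last]),
                 state = fin, bcl = bcl, params = params,
                 compound = compound),
            class = "paced_cell")
}

#' Action potential duration at a repolarization fraction
#'
#' APD measured from the time of maximum upstroke velocity to the crossing of
#' `v_rest + (1 - fraction/100) * amplitude` on the repolarizing limb, with
#' linear interpolation between samples.  Amplitude is peak-to-resting of the
#' same beat.
#'
#' @param t,vm time (ms) and membrane voltage (mV) samples of one beat.
#' @param fraction repolarization percentage (e.g. 90 for APD90).
#' @return duration in ms.
#' @export
#' @examples
#' t <- seq(0, 400, by = 0.5)
#' vm <- ifelse(t < 2, -80 + 50 * t, pmax(-80, 20 - (t - 2) * 0.35))
#' measure_apd(t, vm, 90)
measure_apd <- function(t, vm, fraction = 90) {
  stopifnot(length(t) == length(vm), fraction > 0, fraction <= 100)
  dv <- diff(vm) / diff(t)
  iup <- which.max(dv)
  if (dv[iup] < 5) stop("no upstroke found (max dV/dt < 5 mV/ms)")
  t_up <- t[iup]
  post <- t > t_up
  v_peak <- max(vm[post])
  ipk <- which(post)[which.max(vm[post])]
  v_rest <- if (iup > 1) min(vm[seq_len(iup)]) else vm[1]
  amp <- v_peak - v_rest
  thr <- v_rest + (1 - fraction / 100) * amp
  idx <- which(vm[-1] <= thr & vm[-length(vm)] > thr)
  idx <- idx[idx >= ipk]
  if (!length(idx))
    stop(sprintf("repolarization to %g%% never reached", fraction))
  i <- idx[1]
  t_cross <- t[i] + (thr - vm[i]) / (vm[i + 1] - vm[i]) * (t[i + 1] - t[i])
  t_cross - t_up
}

#' AP metrics of one beat
#'
#' @param t,vm time (ms) and voltage (mV) samples of one beat.
#' @return list with `apd30`, `apd70`, `apd90` (ms), `amplitude`, `v_rest`,
#'   `v_peak`, `v_plateau` (mV; mean voltage between 20% and 50% of APD90
#'   after the upstroke).
#' @export
ap_metrics <- function(t, vm) {
  apd30 <- measure_apd(t, vm, 30)
  apd70 <- measure_apd(t, vm, 70)
  apd90 <- measure_apd(t, vm, 90)
  dv <- diff(vm) / diff(t)
  iup <- which.max(dv)
  t_up <- t[iup]
  v_peak <- max(vm[t > t_up])
  v_rest <- if (iup > 1) min(vm[seq_len(iup)]) else vm[1]
  sel <- t >= t_up + 0.2 * apd90 & t <= t_up + 0.5 * apd90
  list(apd30 = apd30, apd70 = apd70, apd90 = apd90,
       amplitude = v_peak - v_rest, v_rest = v_rest, v_peak = v_peak,
       v_plateau = mean(vm[sel]))
}
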