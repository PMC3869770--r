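# Restitution protocols: APD, ERP, CV and wavelength as functions of the
# diastolic interval (DI), plus minimum DI and alternans detection.
#
# All protocols are S1-S2: a priming S1 train at fixed cycle length, one
# premature S2, DI defined as the S2 coupling interval (stimulus-to-stimulus)
# minus the APD90 of the last S1 beat.  The state at the onset of the last
# S1 is cached so that every S2 trial only re-simulates the final beat pair.

restitution_curve <- function(df, quantity, condition, compound) {
  structure(df, class = c("restitution_curve", "data.frame"),
            quantity = quantity, condition = condition,
            compound = if (is.null(compound)) "none" else compound$name)
}

cond_params <- function(condition) {
  condition <- match.arg(condition, c("normal", "caf"))
  crn_params(remodeled = condition == "caf")
}

# ---- single-cell S1 context ------------------------------------------------

# Pace n_s1 beats; cache the state at the onset of the last S1 and measure
# the last S1's APD90.  With a compound present the train is long enough to
# reach the pharmacological steady state (slow-recovery compounds accumulate
# block over tens of beats).
cell_s1_context <- function(condition = "caf", compound = NULL, bcl = 1000,
                            n_s1 = NULL, dt = 0.01, stim_amp = 20,
                            stim_dur = 2, block = block_params()) {
  params <- cond_params(condition)
  if (is.null(n_s1)) n_s1 <- if (is.null(compound)) 10 else 40
  t_last <- (n_s1 - 1) * bcl
  st0 <- matrix(unclass(crn_initial_state()), ncol = 1)
  pre <- if (n_s1 > 1) {
    stims <- lapply((seq_len(n_s1 - 1) - 1) * bcl, function(tt)
      stim_event(tt, stim_dur, stim_amp, nodes = 1))
    sim_run(st0, params, compound, drug_on = 0, D = 0, dx = 1, nx = 1, ny = 1,
            dt = dt, t0 = 0, duration = t_last, stims = stims,
            probes = 1, sample_dt = 5, block = block)
  } else list(state = st0, t_end = 0)
  # reference continuation: the last S1 alone
  ref <- sim_run(pre$state, params, compound, drug_on = 0, D = 0, dx = 1,
                 ny = 1, nx = 1, dt = dt, t0 = t_last, duration = bcl,
                 stims = list(stim_event(t_last, stim_dur, stim_amp, nodes = 1)),
                 probes = 1, sample_dt = 0.05, block = block)
  apd90_s1 <- measure_apd(ref$sample_t, ref$probe_vm[, 1], 90)
  list(kind = "cell", params = params, compound = compound, block = block,
       state = pre$state, t_last = t_last, bcl = bcl, dt = dt,
       stim_amp = stim_amp, stim_dur = stim_dur, apd90_s1 = apd90_s1)
}

# One S2 trial at stimulus coupling interval `ci` (ms after the last S1
# stimulus).  Returns the S2 segment trace and capture information.
cell_s2_trial <- function(ctx, ci, tail_ms = 500) {
  t_s2 <- ctx$t_last + ci
  res <- sim_run(ctx$state, ctx$params, ctx$compound, drug_on = 0, D = 0,
                 dx = 1, nx = 1, ny = 1, dt = ctx$dt, t0 = ctx$t_last,
                 duration = ci + tail_ms,
                 stims = list(
                   stim_event(ctx$t_last, ctx$stim_dur, ctx$stim_amp, nodes = 1),
                   stim_event(t_s2, ctx$stim_dur, ctx$stim_amp, nodes = 1)),
                 probes = 1, sample_dt = 0.05, block = ctx$block)
  t <- res$sample_t; vm <- res$probe_vm[, 1]
  seg <- t >= t_s2 + ctx$stim_dur          # post-stimulus S2 segment
  dv <- diff(vm[seg]) / diff(t[seg])
  captured <- length(dv) > 0 && max(dv) >= 10    # regenerative upstroke, mV/ms
  apd90 <- NA_real_
  if (captured) {
    apd90 <- tryCatch(measure_apd(t[seg], vm[seg], 90), error = function(e) NA_real_)
    if (is.na(apd90)) captured <- FALSE
  }
  list(t = t[seg], vm = vm[seg], captured = captured, apd90 = apd90,
       t_s2 = t_s2)
}

#' APD restitution by S1-S2 pacing
#'
#' For each target diastolic interval, a single cell is paced with an S1
#' train and one premature S2 at coupling interval `APD90(S1) + DI`; the APD
#' of the S2 beat is recorded.  S2 beats that fail to elicit a regenerative
#' upstroke (max dV/dt < 10 mV/ms after the stimulus) are marked
#' non-captured.
#'
#' @param condition `"normal"` or `"caf"`.
#' @param compound optional [compound_kinetics()]; the S1 train is then long
#'   enough (40 beats) to reach the pharmacological steady state.
#' @param di_grid diastolic intervals (ms), positive and decreasing.
#' @param fraction repolarization percentage for the reported APD.
#' @param bcl S1 cycle length (ms).
#' @param dt integrator step (ms).
#' @param n_s1 S1 beats (default 10, or 40 with a compound).
#' @return a `restitution_curve` data.frame: `di`, `value` (ms), `captured`.
#' @export
apd_restitution <- function(condition = "caf", compound = NULL,
                            di_grid = c(500, 400, 300, 250, 200, 150, 100,
                                        80, 60, 50, 40, 30),
                            fraction = 90, bcl = 1000, dt = 0.01,
                            n_s1 = NULL) {
  stopifnot(all(di_grid > 0), all(diff(di_grid) < 0))
  ctx <- cell_s1_context(condition, compound, bcl = bcl, dt = dt, n_s1 = n_s1)
  rows <- lapply(di_grid, function(di) {
    tr <- cell_s2_trial(ctx, ctx$apd90_s1 + di)
    val <- if (tr$captured) {
      if (fraction == 90) tr$apd90
      else tryCatch(measure_apd(tr$t, tr$vm, fraction), error = function(e) NA_real_)
    } else NA_real_
    data.frame(di = di, value = val, captured = tr$captured)
  })
  restitution_curve(do.call(rbind, rows), paste0("APD", fraction),
                    condition, compound)
}

#' Minimum diastolic interval with 1:1 capture
#'
#' Sweeps the pacing cycle length downward (dynamic restitution protocol,
#' carrying the cell state between stages) until 1:1 capture is lost, i.e.
#' a stimulus fails to elicit a regenerative action potential.  The reported
#' minimum DI is the smallest diastolic interval actually traversed while
#' every beat still captured, measured per beat as the time from 90%
#' repolarization of one AP to the upstroke of the next (so with alternans
#' the short-DI phase of the alternating pair counts).
#'
#' @inheritParams apd_restitution
#' @param medium `"strand"` (reference: capture limited by propagation on a
#'   20 mm paced strand, DIs read at the strand midpoint) or `"cell"`
#'   (space-clamped; captures to much shorter DIs since no wavefront must be
#'   sustained).
#' @param bcl_start starting cycle length (ms) of the downward sweep.
#' @param resolution cycle-length resolution near capture loss (ms).
#' @param n_beats beats per stage; beats after the rate-change transient
#'   must all capture.
#' @param length_mm,dx strand geometry (mm) for `medium = "strand"`.
#' @param D normal-tissue conductivity (mm^2/ms); default calibrated value.
#' @return minimum DI (ms), with attributes `bcl_min` (shortest fully
#'   captured BCL) and `apd90` (mean APD90 at that BCL).
#' @export
minimum_di <- function(condition = "caf", compound = NULL,
                       medium = c("strand", "cell"), bcl_start = 260,
                       resolution = 1, n_beats = 6, dt = NULL,
                       length_mm = 20, dx = 0.1, D = NULL) {
  medium <- match.arg(medium)
  params <- cond_params(condition)
  if (is.null(dt)) dt <- if (medium == "strand") 0.02 else 0.01
  n_pre <- if (is.null(compound)) 10 else 40

  # pharmacological pre-equilibration is always space-clamped (cheap); the
  # diastolic state (including the block variable) seeds every strand node
  pre <- sim_run(matrix(unclass(crn_initial_state()), ncol = 1), params,
                 compound, drug_on = 0, D = 0, dx = 1, nx = 1, ny = 1,
                 dt = 0.01, t0 = 0, duration = n_pre * 1000,
                 stims = lapply((seq_len(n_pre) - 1) * 1000, function(tt)
                   stim_event(tt, 2, 20, nodes = 1)),
                 probes = 1, sample_dt = 5)

  if (medium == "strand") {
    grid <- init_strand(length_mm, condition, dx = dx, D = D)
    grid$states <- matrix(pre$state[, 1], nrow = nrow(pre$state),
                          ncol = grid$nx)
    stim_nodes <- seq_len(max(2, round(0.5 / dx)))
    p_mid <- round(grid$nx / 2); p_far <- max(1, round(0.95 * grid$nx))
    sim_stage <- function(state_mat, t0, bcl) {
      g <- grid; g$states <- state_mat; g$t <- t0
      run <- run_tissue(g, duration = n_beats * bcl, dt = dt,
                        stimuli = lapply(t0 + (seq_len(n_beats) - 1) * bcl,
                                         function(tt) stim_event(tt, 2, 60,
                                                                 nodes = stim_nodes)),
                        compound = compound, drug_on = 0,
                        probes = c(p_mid, p_far), sample_dt = 0.1)
      list(t = run$t, vm = run$probe_vm[, 1], far = run$probe_vm[, 2],
           state = run$grid$states, t_end = run$grid$t)
    }
  } else {
    sim_stage <- function(state_mat, t0, bcl) {
      res <- sim_run(state_mat, params, compound, drug_on = 0, D = 0,
                     dx = 1, nx = 1, ny = 1, dt = dt, t0 = t0,
                     duration = n_beats * bcl,
                     stims = lapply(t0 + (seq_len(n_beats) - 1) * bcl,
                                    function(tt) stim_event(tt, 2, 20, nodes = 1)),
                     probes = 1, sample_dt = 0.1)
      list(t = res$sample_t, vm = res$probe_vm[, 1], far = NULL,
           state = res$state, t_end = res$t_end)
    }
  }

  # One fixed-BCL stage: capture requires a measurable AP per assessed beat
  # at the (mid)probe and, on the strand, per-beat activation at the distal
  # 10% of the strand (1:1 propagation).
  stage <- function(state_mat, t0, bcl) {
    st <- sim_stage(state_mat, t0, bcl)
    t <- st$t; vm <- st$vm
    ups <- reps <- apds <- rep(NA_real_, n_beats)
    for (b in seq_len(n_beats)) {
      sel <- t >= t0 + (b - 1) * bcl & t < t0 + b * bcl
      m <- tryCatch({
        a <- measure_apd(t[sel], vm[sel], 90)
        dv <- diff(vm[sel]) / diff(t[sel])
        # a regenerative AP overshoots well above any stimulus artifact and
        # has far larger amplitude than plateau remnants or graded responses
        if (max(vm[sel]) < -20 ||
            max(vm[sel]) - min(vm[sel]) < 40) NULL
        else list(apd = a, up = t[sel][which.max(dv)])
      }, error = function(e) NULL)
      if (!is.null(m)) { apds[b] <- m$apd; ups[b] <- m$up; reps[b] <- m$up + m$apd }
    }
    assess <- seq(3, n_beats)            # skip the rate-change transient
    ok <- !anyNA(apds[assess])
    if (ok && !is.null(st$far)) {
      nact <- sum(diff(st$far >= -40) == 1 &
                  t[-1] >= t0 + 2 * bcl)   # distal activations, assessed span
      ok <- nact >= length(assess)
    }
    dis <- ups[assess][-1] - reps[assess][-length(assess)]
    list(ok = ok, dis = dis, apd = mean(apds[assess]),
         state = st$state, t_end = st$t_end)
  }

  state <- if (medium == "strand") {
    matrix(pre$state[, 1], nrow = nrow(pre$state), ncol = round(length_mm / dx))
  } else pre$state
  t0 <- pre$t_end
  bcl <- bcl_start
  best <- NULL
  for (stp in c(8, resolution)) {
    repeat {
      st <- stage(state, t0, bcl)
      if (!st$ok) break
      best <- list(bcl = bcl, di = min(st$dis, na.rm = TRUE), apd = st$apd)
      state <- st$state; t0 <- st$t_end
      bcl <- bcl - stp
      if (bcl <= 0) break
    }
    bcl <- bcl + stp - resolution   # refine from the last captured BCL
    if (bcl <= 0) break
  }
  if (is.null(best)) stop("no capture even at the starting cycle length")
  structure(round(best$di), bcl_min = best$bcl, apd90 = best$apd)
}

# ---- strand S1 context -----------------------------------------------------

strand_s1_context <- function(condition = "caf", compound = NULL, di = 500,
                              length_mm = 20, dx = 0.1, dt = 0.02,
                              n_s1 = 4, stim_amp = 60, stim_dur = 2,
                              D = NULL, block = block_params(),
                              apd_ref = NULL) {
  grid <- init_strand(length_mm, condition, dx = dx, D = D)
  # S1 cycle length targeting the requested diastolic interval
  if (is.null(apd_ref))
    apd_ref <- if (condition == "caf") 129 else 300    # 1 Hz single-cell APD90
  bcl <- round(apd_ref + di)
  stim_nodes <- seq_len(max(2, round(0.5 / dx)))
  t_last <- (n_s1 - 1) * bcl
  if (n_s1 > 1) {
    stims <- lapply((seq_len(n_s1 - 1) - 1) * bcl, function(tt)
      stim_event(tt, stim_dur, stim_amp, nodes = stim_nodes))
    pre <- run_tissue(grid, duration = t_last, dt = dt, stimuli = stims,
                      compound = compound, drug_on = 0, probes = 1,
                      sample_dt = 5, block = block)
    grid <- pre$grid
  }
  p_mid <- round(grid$nx / 2)
  p_far <- max(1, round(0.95 * grid$nx))
  p_cv <- c(round(0.25 * grid$nx), round(0.75 * grid$nx))
  probes <- c(p_mid, p_far, p_cv)
  ref <- run_tissue(grid, duration = bcl, dt = dt,
                    stimuli = list(stim_event(t_last, stim_dur, stim_amp,
                                              nodes = stim_nodes)),
                    compound = compound, drug_on = 0, probes = probes,
                    sample_dt = 0.05, block = block)
  apd90_s1 <- measure_apd(ref$t, ref$probe_vm[, 1], 90)
  list(kind = "strand", grid = grid, compound = compound, block = block,
       t_last = t_last, bcl = bcl, dt = dt, di = di,
       stim_amp = stim_amp, stim_dur = stim_dur, stim_nodes = stim_nodes,
       probes = probes, probe_x = (probes - 1) * dx,
       apd90_s1 = apd90_s1, di_actual = bcl - apd90_s1)
}

strand_s2_trial <- function(ctx, ci, tail_ms = 260) {
  t_s2 <- ctx$t_last + ci
  run <- run_tissue(ctx$grid, duration = ci + tail_ms, dt = ctx$dt,
                    stimuli = list(
                      stim_event(ctx$t_last, ctx$stim_dur, ctx$stim_amp,
                                 nodes = ctx$stim_nodes),
                      stim_event(t_s2, ctx$stim_dur, ctx$stim_amp,
                                 nodes = ctx$stim_nodes)),
                    compound = ctx$compound, drug_on = 0,
                    probes = ctx$probes, sample_dt = 0.05, block = ctx$block)
  run$t_s2 <- t_s2
  run
}

# S2 wave reaches the distal 10% of the strand with a regenerative upstroke
s2_propagates <- function(ctx, run) {
  t_act <- activation_time(run$t, run$probe_vm[, 2], after = run$t_s2)
  if (is.na(t_act)) return(FALSE)
  sel <- run$t >= t_act - 2 & run$t <= t_act + 5
  max(diff(run$probe_vm[sel, 2]) / diff(run$t[sel])) >= 10
}

#' ERP restitution on a 1D strand
#'
#' For each diastolic interval, a 20 mm strand is primed with an S1 train
#' whose cycle length targets that DI; the effective refractory period is
#' the shortest S1-S2 stimulus interval whose S2 wave propagates to the
#' distal 10% of the strand (binary search, 1 ms resolution).
#'
#' @inheritParams apd_restitution
#' @param length_mm,dx strand geometry (mm).
#' @param resolution ERP resolution (ms).
#' @param D normal-tissue conductivity (mm^2/ms); default calibrated value.
#' @return a `restitution_curve`: `di` (nominal), `di_actual`, `value` = ERP
#'   (ms), `captured`.
#' @export
erp_restitution <- function(condition = "caf", compound = NULL,
                            di_grid = 500, length_mm = 20, dx = 0.1,
                            dt = 0.02, resolution = 1, D = NULL) {
  rows <- lapply(di_grid, function(di) {
    ctx <- strand_s1_context(condition, compound, di = di,
                             length_mm = length_mm, dx = dx, dt = dt, D = D)
    lo <- 40; hi <- ctx$bcl
    if (!s2_propagates(ctx, strand_s2_trial(ctx, hi)))
      return(data.frame(di = di, di_actual = ctx$di_actual,
                        value = NA_real_, captured = FALSE))
    while (hi - lo > resolution) {
      mid <- round((lo + hi) / 2)
      if (s2_propagates(ctx, strand_s2_trial(ctx, mid))) hi <- mid else lo <- mid
    }
    data.frame(di = di, di_actual = ctx$di_actual, value = hi, captured = TRUE)
  })
  restitution_curve(do.call(rbind, rows), "ERP", condition, compound)
}

#' CV restitution on a 1D strand
#'
#' Conduction velocity of the premature S2 wave at each diastolic interval,
#' from the activation-time difference between interior probes at 25% and
#' 75% of the strand.
#'
#' @inheritParams erp_restitution
#' @return a `restitution_curve`: `di`, `di_actual`, `value` = CV (mm/s),
#'   `captured`.
#' @export
cv_restitution <- function(condition = "caf", compound = NULL, di_grid = 500,
                           length_mm = 20, dx = 0.1, dt = 0.02, D = NULL) {
  rows <- lapply(di_grid, function(di) {
    ctx <- strand_s1_context(condition, compound, di = di,
                             length_mm = length_mm, dx = dx, dt = dt, D = D)
    run <- strand_s2_trial(ctx, round(ctx$apd90_s1 + di), tail_ms = 160)
    cv <- conduction_velocity(run, ctx$probe_x[3], ctx$probe_x[4],
                              after = run$t_s2, cols = c(3, 4))
    data.frame(di = di, di_actual = ctx$di_actual, value = cv,
               captured = !is.na(cv))
  })
  restitution_curve(do.call(rbind, rows), "CV", condition, compound)
}

#' Wavelength restitution
#'
#' WL(DI) = ERP(DI) x CV(DI), the spatial extent of refractory tissue behind
#' a wavefront (mm).  Both curves must share the same DI grid.
#'
#' @param erp,cv `restitution_curve`s of quantity ERP (ms) and CV (mm/s).
#' @return a `restitution_curve` of quantity WL (mm).
#' @export
wavelength_curve <- function(erp, cv) {
  stopifnot(attr(erp, "quantity") == "ERP", attr(cv, "quantity") == "CV")
  if (!isTRUE(all.equal(erp$di, cv$di)))
    stop("ERP and CV curves have mismatched DI grids")
  df <- data.frame(di = erp$di, value = erp$value * cv$value / 1000,
                   captured = erp$captured & cv$captured)
  restitution_curve(df, "WL", attr(erp, "condition"), NULL)
}

#' Detect APD alternans in a beat sequence
#'
#' Electrical alternans: the APDs of even and odd beats separate into two
#' distinct values.  Detected when the absolute difference between the even-
#' and odd-beat mean APD exceeds `threshold` (2 ms by default, above the
#' numerical jitter of the protocol).
#'
#' @param apds numeric vector of per-beat APDs (ms), at least 8 beats.
#' @param threshold detection threshold (ms).
#' @return list with `alternans` (logical) and `amplitude` (ms).
#' @export
#' @examples
#' detect_alternans(rep(c(100, 140), 4))  # amplitude 40
detect_alternans <- function(apds, threshold = 2) {
  if (length(apds) < 8) stop("need at least 8 beats to assess alternans")
  if (anyNA(apds)) stop("APD sequence contains failed beats")
  even <- apds[seq_along(apds) %% 2 == 0]
  odd <- apds[seq_along(apds) %% 2 == 1]
  amp <- abs(mean(even) - mean(odd))
  list(alternans = amp > threshold, amplitude = amp)
}

#' Alternans onset under dynamic pacing
#'
#' Paces a single cell at successively shorter cycle lengths (carrying the
#' state over between stages, as in dynamic restitution protocols) and
#' reports the largest BCL at which APD alternans appears.
#'
#' @inheritParams apd_restitution
#' @param bcls cycle lengths (ms), decreasing.
#' @param n_beats beats per stage; the last 8 are analyzed.
#' @param threshold alternans threshold (ms), see [detect_alternans()].
#' @return list with `onset_bcl` (ms or `NA`), `amplitude` at onset (ms), and
#'   the per-BCL table.
#' @export
alternans_onset <- function(condition = "caf", compound = NULL,
                            bcls = seq(400, 130, by = -10), n_beats = 16,
                            threshold = 2, dt = 0.01) {
  stopifnot(all(diff(bcls) < 0))
  params <- cond_params(condition)
  state <- matrix(unclass(crn_initial_state()), ncol = 1)
  # pharmacological pre-equilibration at 1 Hz
  n_pre <- if (is.null(compound)) 10 else 40
  pre <- sim_run(state, params, compound, drug_on = 0, D = 0, dx = 1,
                 nx = 1, ny = 1, dt = dt, t0 = 0, duration = n_pre * 1000,
                 stims = lapply((seq_len(n_pre) - 1) * 1000, function(tt)
                   stim_event(tt, 2, 20, nodes = 1)),
                 probes = 1, sample_dt = 5)
  state <- pre$state
  t0 <- pre$t_end
  tab <- data.frame(bcl = numeric(0), amplitude = numeric(0),
                    alternans = logical(0))
  onset <- NA_real_; onset_amp <- NA_real_
  for (bcl in bcls) {
    res <- sim_run(state, params, compound, drug_on = 0, D = 0, dx = 1,
                   nx = 1, ny = 1, dt = dt, t0 = t0,
                   duration = n_beats * bcl,
                   stims = lapply(t0 + (seq_len(n_beats) - 1) * bcl,
                                  function(tt) stim_event(tt, 2, 20, nodes = 1)),
                   probes = 1, sample_dt = 0.1)
    t <- res$sample_t; vm <- res$probe_vm[, 1]
    apds <- vapply(seq_len(n_beats), function(b) {
      sel <- t >= t0 + (b - 1) * bcl & t < t0 + b * bcl
      tryCatch(measure_apd(t[sel], vm[sel], 90), error = function(e) NA_real_)
    }, 0)
    last8 <- tail(apds, 8)
    if (anyNA(last8)) break                     # loss of 1:1 capture: stop sweep
    det <- detect_alternans(last8, threshold)
    tab <- rbind(tab, data.frame(bcl = bcl, amplitude = det$amplitude,
                                 alternans = det$alternans))
    if (det$alternans && is.na(onset)) { onset <- bcl; onset_amp <- det$amplitude }
    state <- res$state
    t0 <- res$t_end
  }
  list(onset_bcl = onset, amplitude = onset_amp, table = tab)
}
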