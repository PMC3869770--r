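# Thin R wrapper around the compiled monodomain/cell stepping kernel.

#' Stimulus event
#'
#' A rectangular stimulus applied to a set of grid nodes.
#'
#' @param t_on onset time (ms).
#' @param duration duration (ms), must be positive.
#' @param amplitude current density (pA/pF, depolarizing positive).
#' @param nodes integer vector of 1-based node indices (column-major for 2D
#'   grids); must be non-empty.
#' @return a `stim_event` list.
#' @export
stim_event <- function(t_on, duration = 2, amplitude = 20, nodes) {
  stopifnot(duration > 0, length(nodes) > 0)
  structure(list(t_on = t_on, duration = duration, amplitude = amplitude,
                 nodes = as.integer(nodes)), class = "stim_event")
}

# Assemble arguments and call the compiled kernel.  `state` is a
# NSTATE x n matrix; stims a list of stim_event; probes 1-based.
sim_run <- function(state, params, compound = NULL, drug_on = 0,
                    D = 0, dx = 0.1, nx, ny, dt, t0 = 0, duration,
                    stims = list(), probes = integer(0), sample_dt = 1,
                    frame_dt = 0, record_h = FALSE, ecg_w = numeric(0),
                    record_refr = FALSE, block = block_params()) {
  stopifnot(inherits(params, "crn_params"))
  cp <- compound_engine_pars(compound, block, drug_on)
  pars <- c(params[c("g_na", "g_k1", "g_to", "g_kur_scale", "g_kr", "g_ks",
                     "g_cal", "g_bca", "g_bna", "i_nak_max", "i_naca_max",
                     "i_pca_max")],
            list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, D = D),
            cp)
  if (length(stims)) {
    st <- list(t_on = vapply(stims, `[[`, 0, "t_on"),
               duration = vapply(stims, `[[`, 0, "duration"),
               amplitude = vapply(stims, `[[`, 0, "amplitude"),
               nodes = lapply(stims, function(s) s$nodes - 1L))
  } else {
    st <- list(t_on = numeric(0), duration = numeric(0),
               amplitude = numeric(0), nodes = list())
  }
  rec <- list(probes = as.integer(probes) - 1L, sample_dt = sample_dt,
              frame_dt = frame_dt, record_h = record_h,
              ecg_w = ecg_w, record_refr = record_refr)
  sim_run_cpp(state, pars, dt, t0, duration, st, rec)
}

# Map a compound (or NULL) onto the kernel's parameter fields.
compound_engine_pars <- function(compound, block, drug_on) {
  if (is.null(compound)) {
    return(list(compound_mode = 0L, tau_onset = 1, tau_recovery = 1,
                v_half = block$v_half, slope = block$slope,
                max_block = block$max_block, tonic_level = 1,
                drug_on = drug_on))
  }
  stopifnot(inherits(compound, "compound_kinetics"))
  if (is_tonic(compound)) {
    list(compound_mode = 2L, tau_onset = 1, tau_recovery = 1,
         v_half = block$v_half, slope = block$slope,
         max_block = block$max_block,
         tonic_level = compound$tonic_level, drug_on = drug_on)
  } else {
    list(compound_mode = 1L, tau_onset = compound$tau_onset,
         tau_recovery = compound$tau_recovery,
         v_half = block$v_half, slope = block$slope,
         max_block = block$max_block, tonic_level = 1, drug_on = drug_on)
  }
}
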