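# Shared lazily-computed simulation results.  Expensive runs (steady-state
# pacing for the Table-2 surface, strand calibration, desk-scale patch runs)
# are computed once per test session and reused across test files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# 1 Hz steady-state AP metrics: control + five compounds, remodeled cells
table2_metrics <- function() {
  cached("table2", {
    conds <- c(list(NULL), lapply(1:5, compound_library))
    names(conds) <- c("control", paste0("#", 1:5))
    p <- crn_params(remodeled = TRUE)
    out <- lapply(conds, function(cmp) {
      pc <- pace_cell(p, cmp, n_beats = if (is.null(cmp)) 20 else 60)
      tail(pc$beats, 1)
    })
    do.call(rbind, out)
  })
}

normal_metrics <- function() {
  cached("normal_metrics", tail(pace_cell(crn_params(), n_beats = 20)$beats, 1))
}

# desk-scale patch runs for the rotor pharmacology properties
patch_run <- function(label, compound = NULL, condition = "caf",
                      duration = 2200) {
  cached(paste0("patch_", label), {
    cross_field_induction(condition, compound, drug_on = 1000,
                          duration = duration)
  })
}

# Dominant frequency and refractory fraction are assessed after the drug-on
# transient.  DF is computed over the interval in which the tissue is
# actually active (refractory fraction above 1%): when a compound
# extinguishes the rotor, tapering a mostly-quiescent window would bury the
# real activity under the window edges.  Short windows use zero-padded peak
# interpolation.
patch_analysis <- function(label, run, df_from = 1000, refr_from = 1200,
                           detect = TRUE) {
  cached(paste0("patchan_", label), {
    mv <- run$movie
    det <- trajs <- NULL
    if (detect) {
      det <- detect_phase_singularities(mv)
      trajs <- track_tips(det)
    }
    active_end <- max(run$t[run$refractory_pct > 1])
    seldf <- run$t >= df_from & run$t <= active_end
    df <- tryCatch(as.numeric(dominant_frequency(
      run$ecg[seldf], fs = 1000 / mean(diff(run$t)),
      fmin = 2, min_s = 0.4, pad = 8)), error = function(e) NA_real_)
    list(detections = det, trajectories = trajs,
         refr_mean = mean(run$refractory_pct[run$t >= refr_from]),
         df = df, active_end = active_end,
         ps_end = if (!is.null(det) && nrow(det))
                    sum(det$t == max(mv$t)) else 0L)
  })
}
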