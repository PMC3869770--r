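# Fibrillation analysis: percent refractory area, pseudo-ECG, dominant
# frequency, phase-singularity detection and spiral-tip trajectory tracking.
# All operations consume a wave_movie, whether produced by the monodomain
# solver or by a synthetic fixture.

#' Percent area of refractory tissue
#'
#' A node counts as refractory when the INa inactivation gate h is below a
#' cutoff (0.5 by reference); the refractory fraction is the percentage of
#' such nodes.  For a movie with h frames the whole series is returned.
#'
#' @param x a numeric h-field (vector/matrix) or a [wave_movie()] carrying
#'   h frames (or a precomputed solver series).
#' @param threshold h cutoff (reference 0.5); the fraction is monotone
#'   non-increasing in this threshold.
#' @param ... unused.
#' @return percentage in \[0, 100\]; for movies a data.frame `t`, `pct`.
#' @export
#' @examples
#' refractory_fraction(c(0.2, 0.6, 0.4, 0.9))  # 50
refractory_fraction <- function(x, threshold = 0.5, ...) {
  UseMethod("refractory_fraction")
}

#' @export
refractory_fraction.default <- function(x, threshold = 0.5, ...) {
  if (!is.numeric(x)) stop("h field must be numeric")
  if (anyNA(x)) stop("h field contains missing values")
  100 * mean(x < threshold)
}

#' @export
refractory_fraction.wave_movie <- function(x, threshold = 0.5, ...) {
  if (is.null(x$h)) {
    if (threshold == 0.5 && !is.null(x$series$refractory_pct))
      return(data.frame(t = x$series$t, pct = x$series$refractory_pct))
    stop("movie carries no h frames")
  }
  pct <- apply(x$h, 3, function(h) 100 * mean(h < threshold))
  data.frame(t = x$t, pct = pct)
}

#' Pseudo-ECG from a voltage movie
#'
#' Far-field potential at an electrode P in an infinite homogeneous volume
#' conductor: `Phi_e(P) = 1/(4*pi*sigma) * sum_i Im_i / r_i`, with the
#' distributed source current Im taken as the diffusive (net axial) current
#' per node, `D * lap(Vm)`.  The pseudo-ECG is the difference between two
#' electrodes; by reference both sit over the patch center, 10 mm apart,
#' 5 mm off the tissue plane.
#'
#' @param movie a [wave_movie()] with conductivity `D` set.
#' @param p1,p2 electrode positions, numeric length-3 (mm; z is the off-plane
#'   distance).  Default: horizontal pair straddling the center at z = 5.
#' @param sigma volume-conductor conductivity (arbitrary positive scale).
#' @return data.frame `t`, `ecg` (class `pseudo_ecg`, attribute `fs` in Hz).
#' @export
pseudo_ecg <- function(movie, p1 = NULL, p2 = NULL, sigma = 1) {
  stopifnot(inherits(movie, "wave_movie"))
  d <- dim(movie$vm)
  cx <- (d[1] - 1) * movie$dx / 2
  cy <- (d[2] - 1) * movie$dx / 2
  if (is.null(p1)) p1 <- c(cx - 5, cy, 5)
  if (is.null(p2)) p2 <- c(cx + 5, cy, 5)
  stopifnot(length(p1) == 3, length(p2) == 3, sigma > 0)
  D <- if (is.null(movie$D)) 1 else movie$D
  x <- ((seq_len(d[1]) - 1) * movie$dx)[row(matrix(0, d[1], d[2]))]
  y <- ((seq_len(d[2]) - 1) * movie$dx)[col(matrix(0, d[1], d[2]))]
  r1 <- sqrt((x - p1[1])^2 + (y - p1[2])^2 + p1[3]^2)
  r2 <- sqrt((x - p2[1])^2 + (y - p2[2])^2 + p2[3]^2)
  if (min(r1, r2) < movie$dx / 2)
    stop("electrode lies inside the tissue plane (r -> 0)")
  w <- matrix(1 / (4 * pi * sigma) * (1 / r1 - 1 / r2), d[1], d[2])
  ecg <- vapply(seq_len(d[3]), function(k) {
    im <- D * laplacian5(movie$vm[, , k, drop = TRUE], movie$dx)
    sum(w * im)
  }, 0)
  fs <- 1000 / mean(diff(movie$t))
  structure(data.frame(t = movie$t, ecg = ecg),
            class = c("pseudo_ecg", "data.frame"), fs = fs)
}

# 5-point Laplacian with no-flux boundaries (zero-gradient ghost nodes),
# matching the solver; conservative: the summed Laplacian telescopes to zero
laplacian5 <- function(v, dx) {
  v <- as.matrix(v)
  nx <- nrow(v); ny <- ncol(v)
  up <- v[c(1, seq_len(nx - 1)), , drop = FALSE]
  dn <- v[c(seq_len(nx)[-1], nx), , drop = FALSE]
  if (ny > 1) {
    lf <- v[, c(1, seq_len(ny - 1)), drop = FALSE]
    rt <- v[, c(seq_len(ny)[-1], ny), drop = FALSE]
    (up + dn + lf + rt - 4 * v) / dx^2
  } else {
    (up + dn - 2 * v) / dx^2
  }
}

#' Dominant frequency of a fibrillation signal
#'
#' Peak of the power spectral density (mean removed, Hann taper, FFT) above
#' a drift-exclusion floor.
#'
#' @param trace a `pseudo_ecg`, or a numeric vector with `fs` given.
#' @param fs sampling rate (Hz); taken from the trace attribute if present.
#' @param fmin exclude frequencies below this floor (Hz).
#' @param min_s minimum trace length (s); the default demands 0.5 Hz
#'   intrinsic resolution.
#' @param pad zero-padding factor (integer >= 1); padding interpolates the
#'   PSD peak on a finer frequency grid without adding true resolution,
#'   useful when comparing peak shifts between short traces.
#' @return dominant frequency (Hz), with attributes `resolution` (Hz,
#'   intrinsic, before padding) and `psd` (data.frame `f`, `power`).
#' @export
#' @examples
#' t <- seq(0, 9999, by = 2)
#' dominant_frequency(sin(2 * pi * 7 * t / 1000), fs = 500)  # 7 Hz
dominant_frequency <- function(trace, fs = NULL, fmin = 1, min_s = 2,
                               pad = 1) {
  if (inherits(trace, "pseudo_ecg")) {
    if (is.null(fs)) fs <- attr(trace, "fs")
    x <- trace$ecg
  } else x <- as.numeric(trace)
  if (is.null(fs)) stop("sampling rate fs is required")
  n <- length(x)
  if (n / fs < min_s)
    stop(sprintf("trace too short for dominant-frequency analysis (need >= %g s)",
                 min_s))
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))   # Hann
  xp <- c(x * w, numeric((max(1L, as.integer(pad)) - 1L) * n))
  np <- length(xp)
  sp <- Mod(fft(xp))^2
  f <- (seq_len(np) - 1) * fs / np
  keep <- f >= fmin & f <= fs / 2
  pk <- which.max(sp[keep])
  structure(f[keep][pk], resolution = fs / n,
            psd = data.frame(f = f[keep], power = sp[keep] / max(sp[keep])))
}

#' Phase singularities of a voltage movie
#'
#' Activation phase is defined per node by time-delay embedding,
#' `phi = atan2(Vm(t - tau) - V*, Vm(t) - V*)`, and a phase singularity is a
#' 2x2 plaquette around which the wrapped phase differences wind by +-2*pi.
#' Sub-grid position is the plaquette center; chirality is the winding sign.
#'
#' @param movie a [wave_movie()] (2D).
#' @param tau embedding delay (ms, default 4); rounded to frames.
#' @param v_star embedding origin (mV), default -40.
#' @param frames frame indices to analyze (default: all with a delayed
#'   partner).
#' @return data.frame `frame`, `t`, `x`, `y`, `chirality` (class
#'   `ps_detections`, attribute `times`).
#' @export
detect_phase_singularities <- function(movie, tau = 4, v_star = -40,
                                       frames = NULL) {
  stopifnot(inherits(movie, "wave_movie"))
  d <- dim(movie$vm)
  if (d[2] < 2) stop("phase mapping needs a 2D movie")
  fdt <- mean(diff(movie$t))
  lag <- max(1L, round(tau / fdt))
  if (is.null(frames)) frames <- seq(lag + 1, d[3])
  frames <- frames[frames > lag & frames <= d[3]]
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[k]
    now <- movie$vm[, , fr] - v_star
    del <- movie$vm[, , fr - lag] - v_star
    if (any(!is.finite(now)) || any(!is.finite(del)))
      stop("non-finite voltage in frame ", fr)
    phi <- atan2(del, now)
    ps <- plaquette_winding(phi)
    if (nrow(ps)) {
      out[[k]] <- data.frame(frame = fr, t = movie$t[fr],
                             x = (ps$i - 0.5) * movie$dx,
                             y = (ps$j - 0.5) * movie$dx,
                             chirality = ps$w)
    }
  }
  det <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(det))
    det <- data.frame(frame = integer(0), t = numeric(0), x = numeric(0),
                      y = numeric(0), chirality = numeric(0))
  structure(det, class = c("ps_detections", "data.frame"),
            times = movie$t[frames], dx = movie$dx)
}

# wrapped phase differences summed around each 2x2 plaquette
plaquette_winding <- function(phi) {
  wrap <- function(a) a - 2 * pi * round(a / (2 * pi))
  nx <- nrow(phi); ny <- ncol(phi)
  a <- phi[-nx, -ny]; b <- phi[-1, -ny]; c <- phi[-1, -1]; d <- phi[-nx, -1]
  s <- wrap(b - a) + wrap(c - b) + wrap(d - c) + wrap(a - d)
  idx <- which(abs(s) > pi, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(i = numeric(0), j = numeric(0), w = numeric(0)))
  data.frame(i = idx[, 1], j = idx[, 2], w = sign(s[idx]))
}

#' Track spiral tips across frames
#'
#' Greedy nearest-neighbour frame-to-frame linking of phase-singularity
#' detections of equal chirality within a maximum displacement radius,
#' tolerating a configurable number of missed frames; birth and death events
#' are implicit in each trajectory's first and last sample.
#'
#' @param detections a `ps_detections` data.frame
#'   (see [detect_phase_singularities()]).
#' @param max_disp maximum displacement (mm) between consecutive analyzed
#'   frames.
#' @param max_gap tolerated missed frames before a trajectory is closed.
#' @return list of class `tip_trajectories`; each element is a data.frame
#'   `t`, `x`, `y` with attributes `chirality` and `id`.
#' @export
track_tips <- function(detections, max_disp = 3, max_gap = 5) {
  times <- attr(detections, "times")
  if (is.null(times)) times <- sort(unique(detections$t))
  active <- list()   # each: list(id, chir, x, y, last_k, rows)
  done <- list()
  next_id <- 1L
  for (k in seq_along(times)) {
    tk <- times[k]
    det <- detections[detections$t == tk, , drop = FALSE]
    used <- rep(FALSE, nrow(det))
    # match active tracks in order of age (older first)
    for (a in seq_along(active)) {
      tr <- active[[a]]
      if (is.null(tr)) next
      cand <- which(!used & det$chirality == tr$chir)
      if (length(cand)) {
        dd <- sqrt((det$x[cand] - tr$x)^2 + (det$y[cand] - tr$y)^2)
        allow <- max_disp * (k - tr$last_k)
        if (min(dd) <= allow) {
          j <- cand[which.min(dd)]
          used[j] <- TRUE
          tr$rows[[length(tr$rows) + 1]] <- c(tk, det$x[j], det$y[j])
          tr$x <- det$x[j]; tr$y <- det$y[j]; tr$last_k <- k
          active[[a]] <- tr
          next
        }
      }
      if (k - tr$last_k > max_gap) {       # close the track
        done[[length(done) + 1]] <- tr
        active[a] <- list(NULL)
      }
    }
    active <- active[!vapply(active, is.null, TRUE)]
    for (j in which(!used)) {              # births
      active[[length(active) + 1]] <-
        list(id = next_id, chir = det$chirality[j], x = det$x[j],
             y = det$y[j], last_k = k,
             rows = list(c(times[k], det$x[j], det$y[j])))
      next_id <- next_id + 1L
    }
  }
  done <- c(done, active)
  trajs <- lapply(done, function(tr) {
    m <- do.call(rbind, tr$rows)
    df <- data.frame(t = m[, 1], x = m[, 2], y = m[, 3])
    attr(df, "chirality") <- tr$chir
    attr(df, "id") <- tr$id
    df
  })
  ord <- order(vapply(trajs, function(d) d$t[1], 0))
  structure(trajs[ord], class = "tip_trajectories")
}

#' @export
print.tip_trajectories <- function(x, ...) {
  cat(sprintf("<tip_trajectories> %d trajectories\n", length(x)))
  for (tr in head(x, 10))
    cat(sprintf("  id %d: chirality %+d, t = %.0f..%.0f ms, %d samples\n",
                attr(tr, "id"), attr(tr, "chirality"),
                tr$t[1], tr$t[nrow(tr)], nrow(tr)))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Rotor count over time
#'
#' Step function of the number of live trajectories (a trajectory is live
#' between its first and last detection, bridging tolerated gaps).
#'
#' @param trajectories a `tip_trajectories` list.
#' @param times evaluation times (ms).
#' @param min_life only count trajectories living at least this long (ms);
#'   filters single-frame spurious detections.
#' @return data.frame `t`, `n`.
#' @export
rotor_count_series <- function(trajectories, times, min_life = 0) {
  n <- vapply(times, function(tt) {
    sum(vapply(trajectories, function(tr) {
      life <- tr$t[nrow(tr)] - tr$t[1]
      life >= min_life && tt >= tr$t[1] && tt <= tr$t[nrow(tr)]
    }, TRUE))
  }, 0L)
  data.frame(t = times, n = n)
}
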