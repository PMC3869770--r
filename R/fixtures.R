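# Analytic fixtures emulating the geometric/spectral structure the analysis
# stages consume: rotating spiral phase fields, counter-rotating pairs, and
# multi-tone traces.  Each fixture carries machine-readable ground truth in
# its metadata so recovery tests close the loop without tissue simulation.

#' Analytic spiral-wave movie
#'
#' An Archimedean spiral voltage field
#' `Vm(x, y, t) = v_center + A * cos(theta - k*r + omega*t)` rotating about a
#' (possibly drifting) core, with a synthetic INa-inactivation field
#' `h = 1` where `Vm < v_star`, else 0, Gaussian-smoothed over ~2 mm, so the
#' refractory fraction has an analytic expectation.  The movie's metadata
#' records the exact core path.
#'
#' @param size_mm square edge length (mm).
#' @param dx node spacing (mm).
#' @param duration,frame_dt movie length and frame interval (ms).
#' @param freq_hz rotation frequency (Hz); must be non-zero.
#' @param core core position (mm, length 2), default center.
#' @param drift core drift velocity (mm/ms, length 2).
#' @param k radial wavenumber (rad/mm).
#' @param amplitude,v_center voltage scale and offset (mV).
#' @param v_star threshold for the synthetic h field (mV).
#' @param chirality +1 (counter-clockwise) or -1.
#' @param noise_sd white voltage noise (mV).
#' @param seed RNG seed for the noise; same spec + seed gives identical
#'   movies.
#' @param with_h store the synthetic h field.
#' @return a [wave_movie()] with ground truth in `meta` (`core`: data.frame
#'   of per-frame core positions; `freq_hz`; `chirality`).
#' @export
make_spiral_movie <- function(size_mm = 20, dx = 0.5, duration = 1000,
                              frame_dt = 5, freq_hz = 7, core = NULL,
                              drift = c(0, 0), k = 0.5, amplitude = 40,
                              v_center = -40, v_star = -40, chirality = 1,
                              noise_sd = 0, seed = 1, with_h = TRUE) {
  if (freq_hz == 0) stop("rotation frequency must be non-zero")
  stopifnot(chirality %in% c(-1, 1))
  n <- round(size_mm / dx) + 1
  xs <- (seq_len(n) - 1) * dx
  if (is.null(core)) core <- c(mean(xs), mean(xs))
  t <- seq(0, duration, by = frame_dt)
  omega <- 2 * pi * freq_hz / 1000          # rad/ms
  X <- matrix(xs, n, n); Y <- t(X)
  set.seed(seed)
  vm <- array(0, dim = c(n, n, length(t)))
  cx <- core[1] + drift[1] * t
  cy <- core[2] + drift[2] * t
  for (i in seq_along(t)) {
    th <- atan2(Y - cy[i], X - cx[i])
    r <- sqrt((X - cx[i])^2 + (Y - cy[i])^2)
    vm[, , i] <- v_center +
      amplitude * cos(chirality * th - k * r + omega * t[i])
    if (noise_sd > 0)
      vm[, , i] <- vm[, , i] + rnorm(n * n, sd = noise_sd)
  }
  h <- if (with_h) synth_h(vm, v_star, dx) else NULL
  wave_movie(vm, t, dx, h = h, D = 1,
             meta = list(kind = "spiral", freq_hz = freq_hz,
                         chirality = chirality, k = k,
                         amplitude = amplitude, v_center = v_center,
                         v_star = v_star, noise_sd = noise_sd, seed = seed,
                         core = data.frame(t = t, x = cx, y = cy)))
}

#' Figure-of-eight movie: a counter-rotating spiral pair
#'
#' Two phase singularities of opposite chirality: the phase field is
#' `arg(z - c1) - arg(z - c2) - k * min(r1, r2) + omega*t`, which winds +2*pi
#' around the first core and -2*pi around the second (total topological
#' charge zero).
#'
#' @inheritParams make_spiral_movie
#' @param core1,core2 the two core positions (mm); must differ.
#' @return a [wave_movie()] with both cores in `meta$cores`.
#' @export
make_figure_of_eight <- function(size_mm = 20, dx = 0.5, duration = 1000,
                                 frame_dt = 5, freq_hz = 7,
                                 core1 = NULL, core2 = NULL, k = 0.5,
                                 amplitude = 40, v_center = -40,
                                 v_star = -40, noise_sd = 0, seed = 1,
                                 with_h = FALSE) {
  if (freq_hz == 0) stop("rotation frequency must be non-zero")
  n <- round(size_mm / dx) + 1
  xs <- (seq_len(n) - 1) * dx
  c0 <- mean(xs)
  if (is.null(core1)) core1 <- c(c0 - size_mm / 5, c0)
  if (is.null(core2)) core2 <- c(c0 + size_mm / 5, c0)
  if (all(abs(core1 - core2) < 1e-9)) stop("the two cores must not coincide")
  t <- seq(0, duration, by = frame_dt)
  omega <- 2 * pi * freq_hz / 1000
  X <- matrix(xs, n, n); Y <- t(X)
  th1 <- atan2(Y - core1[2], X - core1[1])
  th2 <- atan2(Y - core2[2], X - core2[1])
  r1 <- sqrt((X - core1[1])^2 + (Y - core1[2])^2)
  r2 <- sqrt((X - core2[1])^2 + (Y - core2[2])^2)
  psi <- th1 - th2 - k * pmin(r1, r2)
  set.seed(seed)
  vm <- array(0, dim = c(n, n, length(t)))
  for (i in seq_along(t)) {
    vm[, , i] <- v_center + amplitude * cos(psi + omega * t[i])
    if (noise_sd > 0)
      vm[, , i] <- vm[, , i] + rnorm(n * n, sd = noise_sd)
  }
  h <- if (with_h) synth_h(vm, v_star, dx) else NULL
  wave_movie(vm, t, dx, h = h, D = 1,
             meta = list(kind = "figure_of_eight", freq_hz = freq_hz,
                         cores = rbind(c(core1, +1), c(core2, -1)),
                         k = k, noise_sd = noise_sd, seed = seed))
}

# synthetic h field: indicator(Vm < v_star) blurred over ~2 mm
synth_h <- function(vm, v_star, dx) {
  sigma_mm <- 1
  half <- max(1L, round(2 * sigma_mm / dx))
  g <- exp(-((-half:half) * dx)^2 / (2 * sigma_mm^2))
  g <- g / sum(g)
  h <- array(0, dim = dim(vm))
  for (i in seq_len(dim(vm)[3])) {
    m <- (vm[, , i] < v_star) * 1
    m <- apply(m, 2, function(col) pad_conv(col, g, half))
    m <- t(apply(m, 1, function(row) pad_conv(row, g, half)))
    h[, , i] <- m
  }
  h
}

pad_conv <- function(x, g, half) {
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, g, sides = 2))[(half + 1):(half + n)]
}

#' Multi-tone synthetic trace
#'
#' Sum of sinusoids with optional white noise; the canonical two-tone
#' fixture for dominant-frequency analysis.
#'
#' @param freqs tone frequencies (Hz), each below `fs/2`.
#' @param amps amplitudes (same length).
#' @param duration length (ms).
#' @param fs sampling rate (Hz).
#' @param noise_sd white-noise standard deviation.
#' @param seed RNG seed.
#' @return data.frame `t` (ms), `ecg` (class `pseudo_ecg`, attribute `fs`),
#'   with the tone table as attribute `tones`.
#' @export
#' @examples
#' tr <- make_two_tone_ecg(c(5, 9), c(1, 0.3))
#' dominant_frequency(tr)   # 5 Hz
make_two_tone_ecg <- function(freqs = c(5, 9), amps = c(1, 0.3),
                              duration = 10000, fs = 500, noise_sd = 0,
                              seed = 1) {
  stopifnot(length(freqs) == length(amps))
  if (any(freqs >= fs / 2))
    stop("tone at or above the Nyquist frequency (aliasing)")
  t <- seq(0, duration - 1000 / fs, by = 1000 / fs)
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t / 1000),
                      numeric(length(t))))
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(length(t), sd = noise_sd)
  }
  structure(data.frame(t = t, ecg = x),
            class = c("pseudo_ecg", "data.frame"), fs = fs,
            tones = data.frame(freq = freqs, amp = amps))
}
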