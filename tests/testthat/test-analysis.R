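# Fibrillation analysis on analytic fixtures: refractory area, pseudo-ECG,
# dominant frequency, phase singularities and tip tracking.

test_that("refractory fraction counts h below the cutoff", {
  expect_equal(refractory_fraction(rep(0.99, 10)), 0)     # all at rest
  expect_equal(refractory_fraction(rep(0.01, 10)), 100)   # all depolarized
  expect_equal(refractory_fraction(c(0.2, 0.6, 0.4, 0.9)), 50)
  expect_error(refractory_fraction(c(0.2, NA)), "missing")
  # monotone non-increasing in the threshold
  set.seed(7)
  h <- runif(500)
  thr <- seq(0.1, 0.9, by = 0.1)
  fr <- vapply(thr, function(k) refractory_fraction(h, k), 0)
  expect_true(all(diff(fr) >= 0))   # larger cutoff marks more nodes refractory
  mv <- make_spiral_movie(size_mm = 10, dx = 0.5, duration = 100, frame_dt = 10)
  expect_error(refractory_fraction(wave_movie(mv$vm, mv$t, mv$dx)), "no h")
})

test_that("pseudo-ECG matches a hand-evaluated 1/r sum on a toy grid", {
  # 3x1 strand, one frame, dx = 1 mm; voltage chosen so the central node is
  # a positive diffusive source
  vm <- array(c(-80, -60, -80), dim = c(3, 1, 1))
  dx <- 1; D <- 0.5
  mv <- wave_movie(vm, t = 0, dx = dx, D = D)
  p1 <- c(0, 0, 5); p2 <- c(2, 0, 5)
  sigma <- 2
  # zero-gradient-ghost Laplacian by hand:
  # node1: v2 - v1; node2: v1 + v3 - 2*v2; node3: v2 - v3
  im <- D * c((-60) - (-80), (-80) + (-80) - 2 * (-60), (-60) - (-80)) / dx^2
  r1 <- sqrt((c(0, 1, 2) - p1[1])^2 + p1[3]^2)
  r2 <- sqrt((c(0, 1, 2) - p2[1])^2 + p2[3]^2)
  expected <- sum(1 / (4 * pi * sigma) * (1 / r1 - 1 / r2) * im)
  got <- pseudo_ecg(mv, p1, p2, sigma = sigma)$ecg
  expect_lt(abs(got - expected), 1e-10)
})

test_that("pseudo-ECG symmetry and polarity", {
  # quiescent movie -> identically zero
  vq <- array(-80, dim = c(11, 11, 3))
  mq <- wave_movie(vq, t = c(0, 5, 10), dx = 1, D = 1)
  expect_equal(max(abs(pseudo_ecg(mq)$ecg)), 0)
  # point inhomogeneity equidistant from both electrodes -> zero difference
  v <- array(-80, dim = c(11, 11, 1)); v[6, 6, 1] <- -100
  ms <- wave_movie(v, t = 0, dx = 1, D = 1)   # center node: Im = +D*80
  sym <- pseudo_ecg(ms, c(5 - 3, 5, 5), c(5 + 3, 5, 5))$ecg
  expect_lt(abs(sym), 1e-12)
  # dominant positive source strictly nearer P1 -> positive deflection
  near <- pseudo_ecg(ms, c(5, 5, 2), c(5, 5, 8))$ecg
  expect_gt(near, 0)
  # electrode in the tissue plane is rejected
  expect_error(pseudo_ecg(ms, c(5, 5, 0), c(5, 5, 8)), "inside")
})

test_that("dominant frequency resolves tones to the spectral resolution", {
  t <- seq(0, 10000 - 2, by = 2)
  pure <- sin(2 * pi * 7 * t / 1000)
  df <- dominant_frequency(pure, fs = 500)
  expect_lt(abs(df - 7), attr(df, "resolution"))
  two <- make_two_tone_ecg(c(5, 9), c(1, 0.3))
  expect_lt(abs(dominant_frequency(two) - 5),
            attr(dominant_frequency(two), "resolution"))
  swapped <- make_two_tone_ecg(c(5, 9), c(0.3, 1))
  expect_lt(abs(dominant_frequency(swapped) - 9), 0.2)
  expect_error(dominant_frequency(pure[1:400], fs = 500), "short")
})

test_that("phase singularity detector recovers the spiral core", {
  mv <- make_spiral_movie(size_mm = 15, dx = 0.25, duration = 300,
                          frame_dt = 5, freq_hz = 7)
  det <- detect_phase_singularities(mv)
  expect_gt(nrow(det), 0)
  err <- sqrt((det$x - 7.5)^2 + (det$y - 7.5)^2)
  expect_lt(max(err), 0.2)
  expect_true(all(det$chirality == 1))
  # opposite handedness flips the detected winding
  mv2 <- make_spiral_movie(size_mm = 15, dx = 0.25, duration = 100,
                           frame_dt = 5, chirality = -1)
  expect_true(all(detect_phase_singularities(mv2)$chirality == -1))
})

test_that("uniform oscillation has no phase singularities", {
  nt <- 40
  vm <- array(rep(-40 + 30 * sin(2 * pi * (1:nt) / 20),
                  each = 21 * 21), dim = c(21, 21, nt))
  mv <- wave_movie(vm, t = (1:nt) * 5, dx = 0.5)
  expect_equal(nrow(detect_phase_singularities(mv)), 0)
})

test_that("figure-of-eight yields two singularities of opposite chirality", {
  m8 <- make_figure_of_eight(size_mm = 20, dx = 0.25, duration = 150,
                             frame_dt = 5)
  det <- detect_phase_singularities(m8)
  per_frame <- split(det, det$frame)
  for (fr in per_frame) {
    expect_equal(nrow(fr), 2)
    expect_equal(sum(fr$chirality), 0)   # total topological charge conserved
  }
  # detected cores sit near the ground-truth cores
  gt <- m8$meta$cores
  last <- per_frame[[length(per_frame)]]
  for (i in 1:2) {
    d <- min(sqrt((last$x - gt[i, 1])^2 + (last$y - gt[i, 2])^2))
    expect_lt(d, 1)
  }
})

test_that("tracker links a stationary tip into one full-length trajectory", {
  det <- data.frame(frame = 1:100, t = (1:100) * 5, x = 10, y = 10,
                    chirality = 1)
  attr(det, "times") <- (1:100) * 5
  tt <- track_tips(det, max_disp = 2)
  expect_length(tt, 1)
  expect_equal(nrow(tt[[1]]), 100)
  expect_equal(attr(tt[[1]], "chirality"), 1)
})

test_that("tracker recovers a drifting core within 0.2 mm RMS", {
  mv <- make_spiral_movie(size_mm = 15, dx = 0.25, duration = 400,
                          frame_dt = 5, drift = c(0.004, 0.002))
  det <- detect_phase_singularities(mv)
  tt <- track_tips(det, max_disp = 1)
  expect_length(tt, 1)
  m <- merge(tt[[1]], mv$meta$core, by = "t")
  rms <- sqrt(mean((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2))
  expect_lt(rms, 0.2)
})

test_that("tracker keeps distinct ids for a close counter-rotating pair", {
  m8 <- make_figure_of_eight(size_mm = 20, dx = 0.25, duration = 200,
                             frame_dt = 5, core1 = c(9, 10), core2 = c(11, 10))
  det <- detect_phase_singularities(m8)
  tt <- track_tips(det, max_disp = 1.5)
  lives <- vapply(tt, nrow, 0)
  keep <- tt[lives > 10]
  expect_length(keep, 2)
  expect_setequal(vapply(keep, attr, 0, "chirality"), c(-1, 1))
})

test_that("tracker tolerates detection gaps up to max_gap", {
  keepfr <- setdiff(1:60, c(20, 21, 22))    # 3 missed frames
  det <- data.frame(frame = keepfr, t = keepfr * 5, x = 5, y = 5,
                    chirality = 1)
  attr(det, "times") <- (1:60) * 5
  tt <- track_tips(det, max_disp = 2, max_gap = 5)
  expect_length(tt, 1)
  tt2 <- track_tips(det, max_disp = 2, max_gap = 2)
  expect_length(tt2, 2)                     # gap too long: track splits
})

test_that("rotor counts follow trajectory lifetimes", {
  trajs <- structure(list(
    structure(data.frame(t = c(0, 50, 100), x = 1, y = 1),
              chirality = 1, id = 1L),
    structure(data.frame(t = c(60, 200), x = 5, y = 5),
              chirality = -1, id = 2L)), class = "tip_trajectories")
  counts <- rotor_count_series(trajs, c(0, 80, 150, 250))
  expect_equal(counts$n, c(1, 2, 1, 0))
  expect_equal(rotor_count_series(structure(list(), class = "tip_trajectories"),
                                  c(0, 10))$n, c(0, 0))
  # min_life filters one-frame flickers
  counts2 <- rotor_count_series(trajs, c(80), min_life = 120)
  expect_equal(counts2$n, 1)
})

test_that("spiral movie dominant frequency equals the rotation frequency", {
  mv <- make_spiral_movie(size_mm = 12, dx = 0.5, duration = 2500,
                          frame_dt = 5, freq_hz = 7)
  ecg <- pseudo_ecg(mv)
  df <- dominant_frequency(ecg)
  expect_lt(abs(df - 7), 2 * attr(df, "resolution"))
})
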