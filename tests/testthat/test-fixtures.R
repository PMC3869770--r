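# Synthetic fixture generators: determinism, ground truth, error handling.

test_that("fixtures are reproducible: same spec and seed, identical output", {
  a <- make_spiral_movie(size_mm = 8, dx = 0.5, duration = 50, frame_dt = 10,
                         noise_sd = 1, seed = 11)
  b <- make_spiral_movie(size_mm = 8, dx = 0.5, duration = 50, frame_dt = 10,
                         noise_sd = 1, seed = 11)
  expect_identical(a$vm, b$vm)
  c <- make_spiral_movie(size_mm = 8, dx = 0.5, duration = 50, frame_dt = 10,
                         noise_sd = 1, seed = 12)
  expect_false(identical(a$vm, c$vm))
})

test_that("fixture constructors reject degenerate specs", {
  expect_error(make_spiral_movie(freq_hz = 0), "non-zero")
  expect_error(make_figure_of_eight(core1 = c(5, 5), core2 = c(5, 5)),
               "coincide")
  expect_error(make_two_tone_ecg(freqs = c(5, 300), amps = c(1, 1), fs = 500),
               "alias")
})

test_that("fixtures carry machine-readable ground truth", {
  mv <- make_spiral_movie(size_mm = 8, dx = 0.5, duration = 50, frame_dt = 10,
                          drift = c(0.01, 0))
  expect_s3_class(mv, "wave_movie")
  expect_equal(mv$meta$freq_hz, 7)
  expect_equal(nrow(mv$meta$core), length(mv$t))
  expect_equal(diff(range(mv$meta$core$x)), 0.01 * 50)
  tt <- make_two_tone_ecg(c(4, 11), c(1, 2), duration = 3000)
  expect_equal(attr(tt, "tones")$freq, c(4, 11))
})

test_that("synthetic h field gives the analytic refractory expectation", {
  # v_star at the oscillation center: half the area is below threshold
  mv <- make_spiral_movie(size_mm = 16, dx = 0.5, duration = 200,
                          frame_dt = 10)
  rf <- refractory_fraction(mv)
  expect_lt(abs(mean(rf$pct) - 50), 2)
})

test_that("movie container round-trips through write/read", {
  mv <- make_spiral_movie(size_mm = 6, dx = 0.5, duration = 30, frame_dt = 10)
  f <- tempfile(fileext = ".rds")
  write_movie(mv, f)
  back <- read_movie(f)
  expect_identical(back$vm, mv$vm)
  expect_identical(back$meta$core, mv$meta$core)
  unlink(f)
  saveRDS(1:3, f)
  expect_error(read_movie(f), "not a wave_movie")
  unlink(f)
})
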