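# Monodomain solver: geometry, uniformity, conservation, stability guard,
# conduction properties.

test_that("strand and patch geometry validate their inputs", {
  expect_equal(init_strand(20, "caf")$nx, 200)
  expect_equal(init_strand(60, "normal")$nx, 600)
  expect_error(init_strand(0), "positive")
  expect_error(init_strand(-5), "positive")
  expect_error(init_strand(20.05), "multiple")
  g <- init_patch(36, "caf", dx = 0.3)
  expect_equal(c(g$nx, g$ny), c(120, 120))
  expect_error(init_patch(0), "positive")
})

test_that("remodeled tissue gets the 30% conductivity reduction", {
  gn <- init_strand(20, "normal")
  gc <- init_strand(20, "caf")
  expect_equal(gc$D / gn$D, 0.7)
  expect_true(gc$params$remodeled)
  expect_false(gn$params$remodeled)
})

test_that("a uniform resting grid stays uniform under diffusion", {
  g <- init_strand(5, "caf", dx = 0.5)
  g2 <- step_tissue(g, dt = 0.02)
  vm <- g2$states[1, ]
  expect_lt(diff(range(vm)), 1e-12)
  # all state variables remain spatially uniform
  expect_lt(max(apply(g2$states, 1, function(r) diff(range(r)))), 1e-12)
})

test_that("no-flux diffusion is conservative (summed Laplacian is zero)", {
  # the analysis-side operator mirrors the solver's boundary handling
  set.seed(3)
  v <- matrix(cumsum(rnorm(30 * 20, sd = 0.3)), 30, 20)
  lap <- atriawave:::laplacian5(v, dx = 0.5)
  expect_lt(abs(sum(lap)) / sum(abs(lap)), 1e-8)
  v1 <- matrix(cumsum(rnorm(50)), ncol = 1)
  expect_lt(abs(sum(atriawave:::laplacian5(v1, 0.1))) /
            sum(abs(atriawave:::laplacian5(v1, 0.1))), 1e-8)
})

test_that("the stability guard warns when dt exceeds the explicit bound", {
  g <- init_strand(5, "normal", dx = 0.1, D = 0.3)
  expect_warning(run_tissue(g, duration = 0.1, dt = 0.05, sample_dt = 0.05),
                 "unstable")
  g2 <- init_strand(5, "normal", dx = 0.1, D = 0.1)
  expect_no_warning(run_tissue(g2, duration = 0.1, dt = 0.02,
                               sample_dt = 0.02))
})

test_that("stimuli outside the grid are rejected", {
  g <- init_patch(6, "caf", dx = 0.3)
  expect_error(grid_region(g, x_mm = c(10, 12)), "no nodes")
  expect_error(stim_event(0, 2, 20, nodes = integer(0)))
})

test_that("CV increases monotonically with conductivity", {
  cvs <- vapply(c(0.08, 0.16, 0.24), function(D)
    atriawave:::measure_strand_cv(D, dx = 0.1, dt = 0.01, n_beats = 1), 0)
  expect_true(all(diff(cvs) > 0))
  # rough sqrt scaling: tripling D scales CV by about sqrt(3)
  expect_equal(cvs[3] / cvs[1], sqrt(3), tolerance = 0.15)
})

test_that("waveback speed equals wavefront speed on a long strand", {
  g <- init_strand(60, "caf", dx = 0.1)
  p <- c(round(20 / 0.1), round(40 / 0.1)) + 1
  run <- run_tissue(g, duration = 320, dt = 0.02,
                    stimuli = list(stim_event(0, 2, 60, nodes = 1:5)),
                    probes = p, sample_dt = 0.1)
  front <- vapply(1:2, function(i)
    atriawave:::activation_time(run$t, run$probe_vm[, i]), 0)
  # waveback: downward crossing of -70 mV (repolarization tail)
  tail_t <- vapply(1:2, function(i) {
    vm <- run$probe_vm[, i]
    j <- which(vm[-1] <= -70 & vm[-length(vm)] > -70)[1]
    run$t[j]
  }, 0)
  cv_front <- 20 / diff(front)
  cv_back <- 20 / diff(tail_t)
  expect_equal(cv_back, cv_front, tolerance = 0.02)
})

test_that("plane-wave CV on a 2D sheet matches the strand (isotropy)", {
  D <- default_conductivity("normal", 0.3)
  cv1 <- atriawave:::measure_strand_cv(D, dx = 0.3, dt = 0.025, n_beats = 1,
                                       length_mm = 21)
  g <- init_patch(21, "normal", dx = 0.3)
  left <- grid_region(g, x_mm = c(0, 0.9))
  p <- c(round(0.25 * 70), round(0.75 * 70)) + 1   # along-row probes
  run <- run_tissue(g, duration = 60, dt = 0.025,
                    stimuli = list(stim_event(0, 2, 60, nodes = left)),
                    probes = (35 - 1) * g$nx + p, sample_dt = 0.05)
  cv2 <- conduction_velocity(run, (p[1] - 1) * 0.3, (p[2] - 1) * 0.3)
  expect_equal(cv2, cv1, tolerance = 0.01)
})
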