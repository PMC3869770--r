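# Voltage- and time-dependent IKur block: Boltzmann steady state, the
# onset/recovery time-constant interpolation, exact relaxation updates and
# the repeated voltage-step assay.

test_that("compound constructors enforce the kinetic invariants", {
  expect_error(compound_kinetics("x", tau_onset = 5), "tau_recovery")
  expect_error(compound_kinetics("x", tau_onset = -1, tau_recovery = 10))
  expect_error(compound_kinetics("x", tau_onset = 5, tau_recovery = 10,
                                 tonic_level = 0.5), "tonic")
  expect_error(compound_kinetics("x", tonic_level = 1.2), "tonic_level")
  expect_error(compound_kinetics("x"), "tonic_level")
  lib <- compound_library()
  expect_length(lib, 5)
  expect_equal(lib[["#1"]]$tau_onset, 5)
  expect_equal(lib[["#1"]]$tau_recovery, 1000)
  expect_equal(lib[["#3"]]$tau_recovery, 16000)
  expect_true(is_tonic(lib[["#5"]]))
  expect_equal(lib[["#5"]]$tonic_level, 0.5)
  expect_error(compound_library("#9"), "unknown")
})

test_that("block steady state is the stated Boltzmann", {
  expect_equal(block_steady_state(-40), 1 - 0.9 / 2)        # half-max point
  expect_lt(abs(block_steady_state(100) - 0.10), 0.01)      # deep block
  expect_lt(abs(block_steady_state(-90) - 1), 1e-4)         # no block at rest
  # bounded in [1 - max_block, 1]
  v <- seq(-150, 150, by = 1)
  y <- block_steady_state(v)
  expect_true(all(y >= 0.1 - 1e-12 & y <= 1 + 1e-12))
})

test_that("block time constant interpolates tau_recovery -> tau_onset", {
  c1 <- compound_library(1); c3 <- compound_library(3)
  expect_equal(block_time_constant(30, c1), 5, tolerance = 1e-3)
  expect_equal(block_time_constant(-80, c1), 1000, tolerance = 1e-3)
  expect_equal(block_time_constant(-80, c3), 16000, tolerance = 1e-3)
  expect_equal(block_time_constant(-40, c1), (5 + 1000) / 2)  # midpoint
  expect_error(block_time_constant(0, compound_library(5)), "tonic")
})

test_that("update_block matches the closed-form relaxation to 1e-9", {
  c2 <- compound_library(2)
  bp <- block_params()
  vm <- -20; dt <- 0.5
  yinf <- block_steady_state(vm, bp)
  tau <- block_time_constant(vm, c2, bp)
  y <- 1
  for (k in 1:100) y <- update_block(y, vm, dt, c2, bp)
  y_exact <- yinf + (1 - yinf) * exp(-100 * dt / tau)
  expect_lt(abs(y - y_exact), 1e-9)
  # dt = 0 leaves y unchanged
  expect_equal(update_block(0.73, vm, 0, c2, bp), 0.73)
  # tonic compound pins y at its level everywhere
  c5 <- compound_library(5)
  for (v in c(-90, -40, 30)) expect_equal(update_block(0.9, v, 1, c5), 0.5)
})

test_that("update_block is consistent under step splitting", {
  c1 <- compound_library(1)
  y1 <- update_block(1, 10, 2, c1)
  y2 <- update_block(update_block(1, 10, 1, c1), 10, 1, c1)
  expect_lt(abs(y1 - y2), 1e-12)
})

test_that("y respects the comparison-principle bound on any trajectory", {
  set.seed(42)
  c4 <- compound_library(4)
  y <- 0.95
  lo <- min(y, 1 - block_params()$max_block); hi <- max(y, 1)
  for (k in 1:500) {
    y <- update_block(y, runif(1, -100, 50), runif(1, 0, 5), c4)
    expect_gte(y, lo - 1e-12); expect_lte(y, hi + 1e-12)
  }
})

test_that("engine block dynamics agree with the R-side relaxation", {
  # integrate update_block along the engine's own voltage trace and compare
  # with the engine's final ykur state
  c2 <- compound_library(2)
  pc <- pace_cell(crn_params(remodeled = TRUE), c2, n_beats = 2,
                  dt = 0.02, sample_dt = 0.02)
  y <- 1
  for (i in seq_along(pc$t)[-1])
    y <- update_block(y, pc$vm[i - 1], pc$t[i] - pc$t[i - 1], c2)
  expect_lt(abs(y - pc$state[["ykur"]]), 5e-3)
})

test_that("tonic compound #5 halves IKur in the engine at every time", {
  pc <- pace_cell(crn_params(remodeled = TRUE), compound_library(5),
                  n_beats = 2, dt = 0.02)
  expect_equal(pc$state[["ykur"]], 0.5)
})

test_that("voltage-step assay: fast-recovery compounds dissociate, slow ones accumulate", {
  res <- lapply(1:4, function(i)
    voltage_step_assay(compound_library(i), n_pulses = 5))
  start_block <- function(r) {   # blocked fraction at each pulse onset
    tr <- r$trace
    vapply(0:4 * 1000, function(t0) 1 - tr$y[which.min(abs(tr$t - t0))], 0)
  }
  sb <- lapply(res, start_block)
  # slow recovery (#1, #3): block accumulates across pulses (drug-free at
  # pulse 1, substantially pre-blocked from pulse 2 on)
  expect_gt(sb[[1]][2], sb[[1]][1] + 0.3)
  expect_gt(sb[[3]][2], sb[[3]][1] + 0.5)
  # fast recovery (#2, #4): near-complete dissociation in diastole
  expect_lt(sb[[2]][5], 0.15); expect_lt(sb[[4]][5], 0.15)
  # end-of-step block converges pulse-to-pulse for fast-recovery compounds
  expect_lt(abs(res[[2]]$pulse_block[5] - res[[2]]$pulse_block[4]), 1e-3)
  # no compound: non-blocked fraction is identically 1
  drugfree <- voltage_step_assay(NULL, n_pulses = 2)
  expect_true(all(drugfree$trace$y == 1))
})
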