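# Single-cell CRN model: currents, stepping, remodeling, AP metrics.

test_that("resting state is consistent: near-zero net current and stable Vm", {
  s <- crn_initial_state()
  cur <- ionic_currents(s, crn_params())
  expect_lt(abs(cur$i_total), 0.05)

  # 1 s unstimulated: membrane stays at rest
  res <- atriawave:::sim_run(matrix(unclass(s), ncol = 1), crn_params(),
                             D = 0, dx = 1, nx = 1, ny = 1, dt = 0.02,
                             t0 = 0, duration = 1000, probes = 1,
                             sample_dt = 1)
  expect_lt(max(abs(res$probe_vm[, 1] - s[["vm"]])), 0.1)
})

test_that("IKur vanishes at the K reversal potential and with closed gates", {
  s <- crn_initial_state()
  p <- crn_params()
  ek <- ionic_currents(s, p)$e_k
  s_ek <- s; s_ek[["vm"]] <- ek
  expect_equal(ionic_currents(s_ek, p)$i_kur, 0)
  s_ua0 <- s; s_ua0[["vm"]] <- 20; s_ua0[["ua"]] <- 0
  expect_equal(ionic_currents(s_ua0, p)$i_kur, 0)
  # ykur factor scales the current linearly
  s_y <- s_ek
  s_y[["vm"]] <- 20; s_y[["ua"]] <- 0.5
  full <- ionic_currents(s_y, p)$i_kur
  s_y[["ykur"]] <- 0.4
  expect_equal(ionic_currents(s_y, p)$i_kur, 0.4 * full)
  s_y[["ykur"]] <- 0
  expect_equal(ionic_currents(s_y, p)$i_kur, 0)
})

test_that("non-finite state is rejected with the offending variable named", {
  s <- crn_initial_state()
  s[["cai"]] <- NaN
  expect_error(ionic_currents(s, crn_params()), "cai")
  expect_error(step_cell(s, dt = 0.01), "cai")
})

test_that("step_cell validates dt and advances the state", {
  s <- crn_initial_state()
  expect_error(step_cell(s, dt = 0), "dt")
  expect_error(step_cell(s, dt = -1), "dt")
  s2 <- step_cell(s, dt = 0.01, i_stim = 20)
  expect_gt(s2[["vm"]], s[["vm"]])   # depolarizing stimulus raises Vm
})

test_that("remodeling scales IK1/ICaL/Ito by 2.1/0.35/0.35 exactly once", {
  p <- crn_params()
  r <- apply_remodeling(p)
  expect_equal(r$g_k1 / p$g_k1, 2.1)
  expect_equal(r$g_cal / p$g_cal, 0.35)
  expect_equal(r$g_to / p$g_to, 0.35)
  expect_true(r$remodeled)
  expect_error(apply_remodeling(r), "already")
  # with all factors at 1 the parameter set is bit-identical to baseline
  r1 <- r
  r1$g_k1 <- r1$g_k1 / 2.1; r1$g_cal <- r1$g_cal / 0.35
  r1$g_to <- r1$g_to / 0.35; r1$remodeled <- FALSE
  expect_identical(unlist(r1), unlist(p))
})

test_that("measure_apd recovers analytic crossings of a triangular pulse", {
  # piecewise-linear AP: rest -80, upstroke to +20 over 1 ms, linear
  # repolarization over 200 ms
  dt <- 0.5
  t <- seq(0, 300, by = dt)
  vm <- ifelse(t < 10, -80,
        ifelse(t < 11, -80 + 100 * (t - 10),
        pmax(-80, 20 - 0.5 * (t - 11))))
  for (f in c(30, 70, 90)) {
    # analytic: threshold crossing at 11 + (20 - thr)/0.5; dV/dt is maximal
    # over the whole linear upstroke, so the upstroke time is its start (10)
    thr <- -80 + (1 - f / 100) * 100
    apd_true <- (11 + (20 - thr) / 0.5) - 10
    expect_lt(abs(measure_apd(t, vm, f) - apd_true), dt)
  }
  expect_error(measure_apd(t, rep(-80, length(t)), 90), "upstroke")
  vm_cut <- ifelse(t < 11, vm, pmax(0, vm))   # never repolarizes below 0 mV
  expect_error(measure_apd(t, vm_cut, 90), "never")
})

test_that("APD fractions are ordered on a simulated beat", {
  b <- normal_metrics()
  expect_lt(b$apd30, b$apd70)
  expect_lt(b$apd70, b$apd90)
  expect_gt(b$apd90, 0)
})

test_that("gating variables and ykur stay in [0, 1] during pacing", {
  pc <- pace_cell(crn_params(remodeled = TRUE), compound_library(1),
                  n_beats = 3, dt = 0.02)
  gates <- pc$state[c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                      "d", "f", "fca", "u", "vg", "w", "ykur")]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(pc$state[c("nai", "cai", "ki", "carel", "caup")] > 0))
})

test_that("halving dt changes APD90 by less than 1 ms", {
  p <- crn_params(remodeled = TRUE)
  a1 <- tail(pace_cell(p, n_beats = 5, dt = 0.02)$beats$apd90, 1)
  a2 <- tail(pace_cell(p, n_beats = 5, dt = 0.01)$beats$apd90, 1)
  expect_lt(abs(a1 - a2), 1)
})

test_that("remodeling triangulates and shortens the AP (APD90 < 0.5x normal)", {
  expect_lt(tail(table2_metrics()["control", "apd90"], 1),
            0.5 * normal_metrics()$apd90)
})
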