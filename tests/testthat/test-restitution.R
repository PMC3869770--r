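# Restitution protocols: alternans detection, curve algebra, protocol
# oracles on small instances.

test_that("alternans detection on constructed sequences", {
  expect_false(detect_alternans(rep(120, 8))$alternans)
  det <- detect_alternans(rep(c(100, 140), 4))
  expect_true(det$alternans)
  expect_equal(det$amplitude, 40)
  expect_error(detect_alternans(c(100, 140)), "8 beats")
  expect_error(detect_alternans(c(rep(100, 7), NA)), "failed")
  # threshold is respected
  expect_false(detect_alternans(rep(c(100, 101.5), 4))$alternans)
  expect_true(detect_alternans(rep(c(100, 101.5), 4), threshold = 1)$alternans)
})

test_that("wavelength is ERP x CV with consistent units", {
  erp <- atriawave:::restitution_curve(
    data.frame(di = c(500, 300), value = c(137, 130),
               captured = TRUE), "ERP", "caf", NULL)
  cv <- atriawave:::restitution_curve(
    data.frame(di = c(500, 300), value = c(598, 580),
               captured = TRUE), "CV", "caf", NULL)
  wl <- wavelength_curve(erp, cv)
  expect_equal(wl$value, c(137 * 598, 130 * 580) / 1000)
  # unit refactoring invariance: ms * mm/s / 1000 == ms * mm/ms
  expect_equal(wl$value, erp$value * (cv$value / 1000), tolerance = 1e-12)
  # zero ERP -> zero WL
  erp0 <- erp; erp0$value[1] <- 0
  expect_equal(wavelength_curve(erp0, cv)$value[1], 0)
  # mismatched grids are rejected
  cv2 <- cv; cv2$di <- c(500, 250)
  expect_error(wavelength_curve(erp, cv2), "mismatch")
})

test_that("APD restitution is monotone in DI and validates its grid", {
  expect_error(apd_restitution(di_grid = c(100, 200)))   # must decrease
  curve <- cached("apd_rest_small",
                  apd_restitution("caf", di_grid = c(300, 100, 50)))
  expect_true(all(curve$captured))
  expect_true(all(diff(curve$value) < 0))   # APD shrinks with DI
  expect_s3_class(curve, "restitution_curve")
})

test_that("ERP binary search agrees with a linear scan on a small strand", {
  ctx <- cached("erp_ctx_small",
                atriawave:::strand_s1_context("caf", di = 300, length_mm = 10,
                                              dx = 0.2, dt = 0.02, n_s1 = 3,
                                              D = 0.21875))
  res <- 4
  # binary search
  lo <- 40; hi <- ctx$bcl
  while (hi - lo > res) {
    mid <- round((lo + hi) / 2)
    ok <- atriawave:::s2_propagates(ctx, atriawave:::strand_s2_trial(ctx, mid))
    if (ok) hi <- mid else lo <- mid
  }
  # linear scan downward at the same resolution
  ci <- hi
  lin <- hi
  repeat {
    ci <- ci - res
    if (ci <= 40) break
    if (!atriawave:::s2_propagates(ctx, atriawave:::strand_s2_trial(ctx, ci)))
      break
    lin <- ci
  }
  expect_equal(hi, lin)
})

test_that("alternans appears earlier for steep-restitution (slow-recovery) compounds", {
  ao <- cached("alternans_onsets", {
    conds <- list(control = NULL, "#1" = compound_library(1),
                  "#3" = compound_library(3), "#4" = compound_library(4))
    vapply(conds, function(cmp)
      alternans_onset("caf", cmp, bcls = seq(320, 150, by = -10))$onset_bcl, 0)
  })
  onset <- function(x) if (is.na(x)) -Inf else x   # never alternating: -Inf
  expect_gte(onset(ao["#1"]), onset(ao["#4"]))
  expect_gte(onset(ao["#3"]), onset(ao["#4"]))
  expect_gte(onset(ao["#1"]), onset(ao["control"]))
  expect_gte(onset(ao["#3"]), onset(ao["control"]))
})

test_that("minimum DI rejects configurations without capture", {
  # a 50 ms cycle cannot conduct 1:1 on the strand (APD alone is ~130 ms)
  expect_error(minimum_di("caf", bcl_start = 50, n_beats = 4), "capture")
})
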