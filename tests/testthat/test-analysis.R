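# Feature extraction on analytic fixtures and simulated beats.

test_that("triangular AP fixture yields its geometric APDs", {
  fx <- fixtures("triangle_ap")
  ap <- ap_features_window(fx$t, fx$V, stim_t = 0)
  expect_equal(ap[["RMP"]], -80)
  expect_equal(ap[["OS"]], 20)
  expect_equal(ap[["APA"]], 100)
  # linear 1 mV/ms repolarization from the peak: APD_x = x ms (up to the
  # 1-ms upstroke offset of the reference instant)
  expect_equal(ap[["APD50"]], 50, tolerance = 0.03)
  expect_equal(ap[["APD90"]], 90, tolerance = 0.03)
  expect_true(ap[["APD20"]] <= ap[["APD30"]] &&
              ap[["APD30"]] <= ap[["APD50"]] &&
              ap[["APD50"]] <= ap[["APD90"]])
})

test_that("a constant trace is flagged with no detected beat", {
  t <- seq(0, 500, 0.5)
  ap <- ap_features_window(t, rep(-80, length(t)))
  expect_true(all(is.na(ap[grep("^APD", names(ap))])))
})

test_that("exponential transient fixture recovers its generator time constant", {
  fx <- fixtures("exp_cat")
  ct <- cat_features_window(fx$t, fx$ca, stim_t = 0)
  expect_equal(unname(ct[["tau_decay"]]), fx$tau, tolerance = 0.01)
  expect_equal(unname(ct[["ca_dia"]]), 0.1, tolerance = 0.01)  # baseline (uM)
})

test_that("removal partition sums to 100 and collapses to SERCA when others are blocked", {
  p <- default_parameters()
  y <- snapshot_05hz()
  r <- measure_beat(y, p, cl = 2000, grid = 0.5)
  part <- ca_removal_partition(r)
  expect_equal(sum(part), 100, tolerance = 1e-6)
  pb <- default_parameters(b_ncx = 1, b_pmca = 1)
  rb <- measure_beat(y, pb, cl = 2000, grid = 0.5)
  pb_part <- ca_removal_partition(rb)
  expect_equal(unname(pb_part[["SERCA"]]), 100, tolerance = 1e-6)
})

test_that("I-V summaries normalize correctly and reject out-of-family voltages", {
  p <- default_parameters()
  fam <- run_voltage_clamp("Ito", standard_clamp_protocol("Ito"), p, dt = 1)
  nrm <- iv_summary(fam, "peak", normalize_at = 30)
  expect_equal(nrm$I[nrm$V == 30], 1)
  expect_error(iv_summary(fam, "peak", normalize_at = 35), "not in the step family")
})

test_that("overshoot falls and Na+ rises as the cycle length shortens", {
  p <- default_parameters()
  y4 <- pace_beats(snapshot_2hz(), p, cl = 250, n = 60, grid = 2)
  r4 <- measure_beat(y4, p, cl = 250, grid = 0.1)
  y10 <- pace_beats(y4, p, cl = 100, n = 120, grid = 2)
  r10 <- measure_beat(y10, p, cl = 100, grid = 0.1)
  expect_gt(ap_features(r4)[["OS"]], ap_features(r10)[["OS"]])
  expect_gt(y10[["Na_i"]], snapshot_2hz()[["Na_i"]])
})

test_that("AP features are stable against the APD reference convention switch", {
  p <- default_parameters()
  r <- measure_beat(snapshot_2hz(), p, cl = 500)
  up <- ap_features(r, reference = "upstroke")
  st <- ap_features(r, reference = "stimulus")
  # stimulus onset precedes the upstroke, so stimulus-referenced APDs are longer
  expect_gt(st[["APD90"]], up[["APD90"]])
  expect_lt(st[["APD90"]] - up[["APD90"]], 6)
})

test_that("rate sweep emits one converged feature row per cycle length", {
  p <- default_parameters()
  tab <- rate_sweep(p, cl_list = c(500, 250), state0 = snapshot_2hz(),
                    max_beats = 25, tol = 5e-3)
  expect_equal(tab$cl, c(500, 250))
  expect_true(all(c("APD90", "ca_dia", "Na_i", "K_i", "Cl_i") %in% names(tab)))
  expect_true(all(is.finite(tab$APD90)))
  expect_true(all(tab$Na_i > 10 & tab$Na_i < 17))
})
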