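# Protocol engine: drug registry, clamps, S1S2, caffeine, determinism.

test_that("drug registry returns the literature block fractions exactly", {
  expect_equal(drug_to_block("4-AP", "50uM"), c(b_to = 0.16, b_kur = 0.70))
  expect_equal(drug_to_block("4-AP", "100uM"), c(b_to = 0.30, b_kur = 1.00))
  expect_equal(drug_to_block("E-4031", "5uM"), c(b_kr = 1.00))
  expect_equal(drug_to_block("TEA", "5mM"), c(b_ss = 0.55, b_kur = 0.00))
  expect_error(drug_to_block("4-AP", "10uM"), "supported")
  expect_error(drug_to_block("dofetilide", "1uM"), "supported")
  p <- apply_block(default_parameters(), drug_to_block("4-AP", "100uM"))
  expect_equal(p[["b_kur"]], 1)
  expect_error(apply_block(default_parameters(), c(b_to = 1.2)))
})

test_that("identical protocol, state and tolerances reproduce identical traces", {
  p <- default_parameters()
  y <- snapshot_2hz()
  r1 <- integrate_model(y, p, pacing_protocol(cl = 400), t_span = 400, grid = 0.2)
  r2 <- integrate_model(y, p, pacing_protocol(cl = 400), t_span = 400, grid = 0.2)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$t, r2$t)
})

test_that("clamping an ion at its free-running value leaves one beat unchanged", {
  p <- default_parameters()
  y <- snapshot_2hz()
  free <- measure_beat(y, p, cl = 500, grid = 0.2)
  cl <- apply_ion_clamp(clamp_ion("K_i", y[["K_i"]]), p, y)
  clamped <- integrate_model(cl$state, cl$params, pacing_protocol(cl = 500),
                             t_span = 500, grid = 0.2)
  expect_lt(max(abs(free$states[, "V"] - clamped$states[, "V"])), 0.05)
  expect_equal(unname(clamped$states[nrow(clamped$states), "K_i"]), y[["K_i"]])
  expect_error(clamp_ion("Mg_i", 1))
})

test_that("caffeine dumps the store: non-increasing SR, peak above twitch, fractional release in (0,1)", {
  p <- default_parameters()
  y <- snapshot_05hz()
  tw <- measure_beat(y, p, cl = 2000, grid = 0.5)
  caf <- caffeine_transient(y, p, duration = 8000, grid = 1)
  expect_true(all(diff(caf$states[, "Ca_sr"]) <= 1e-12))
  expect_gte(max(caf$states[, "Ca_i"]), max(tw$states[, "Ca_i"]))
  frac <- (max(tw$states[, "Ca_i"]) - tw$states[1, "Ca_i"]) /
    (max(caf$states[, "Ca_i"]) - caf$states[1, "Ca_i"])
  expect_gt(frac, 0); expect_lt(frac, 1)
})

test_that("S1S2 restitution shortens the premature APD30 and plateaus at long intervals", {
  p <- default_parameters()
  tab <- s1s2_restitution(p, s1_cl = 130, s2_list = c(90, 130, 250, 1000, 2000),
                          n_s1 = 20, state0 = snapshot_2hz())
  expect_true(all(tab$captured))
  expect_true(all(diff(tab$apd30[1:4]) > 0))          # shorter interval, shorter APD30
  expect_lt(abs(tab$apd30[5] - tab$apd30[4]) / tab$apd30[4], 0.05)  # plateau
  # S2 = S1 cycle length reproduces the steady APD30 at that rate (continuity)
  y <- pace_beats(snapshot_2hz(), p, cl = 130, n = 20, grid = 0.5)
  ap <- ap_features(measure_beat(y, p, cl = 130))
  expect_equal(tab$apd30[tab$s2 == 130], ap[["APD30"]], tolerance = 0.02)
})

test_that("the standard stimulus sits about 1.5x above the excitation threshold", {
  thr <- stimulus_threshold(default_parameters())
  expect_gt(thr, 5); expect_lt(thr, 8.5)
})
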