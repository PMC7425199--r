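# RHS assembly, compiled/reference consistency, integration, pacing.

test_that("Markov occupancy derivative blocks each sum to zero", {
  p <- default_parameters()
  set.seed(11)
  for (k in 1:4) {
    s <- unclass(default_state())
    s["V"] <- runif(1, -100, 40)
    for (b in markov_blocks()) { x <- runif(length(b)); s[b] <- x / sum(x) }
    class(s) <- "mamyo_state"
    d <- derivatives(s, p)
    for (b in markov_blocks()) expect_lt(abs(sum(d[b])), 1e-14)
  }
})

test_that("stimulus charges the membrane at 10 mV/ms when every pathway is silenced", {
  p <- default_parameters(
    g_na = 0, g_nal_parent = 0, g_nab = 0, g_cal_parent = 0, g_to = 0,
    g_kur = 0, g_kr = 0, g_ss = 0, g_k1 = 0, g_kb = 0, g_kach = 0, g_kca = 0,
    g_clca = 0, g_clb = 0, g_cab = 0, ibar_nak_parent = 0, ibar_ncx = 0,
    ibar_pmca = 0)
  d <- derivatives(default_state(), p, stim = -10)
  expect_equal(d[["V"]], 10, tolerance = 1e-12)
})

test_that("compiled and reference right-hand sides agree to solver precision", {
  p <- default_parameters()
  set.seed(42)
  for (k in 1:6) {
    s <- unclass(default_state())
    s["V"] <- runif(1, -120, 50)
    s[c("Na_i", "K_i", "Cl_i")] <- s[c("Na_i", "K_i", "Cl_i")] * runif(3, 0.7, 1.3)
    s[c("Ca_i", "Ca_sl", "Ca_j", "Ca_sr")] <-
      s[c("Ca_i", "Ca_sl", "Ca_j", "Ca_sr")] * runif(4, 0.5, 5)
    for (b in markov_blocks()) { x <- runif(length(b)); s[b] <- x / sum(x) }
    s[c("m", "h", "j", "mL", "hL", "x_ss")] <- runif(6)
    class(s) <- "mamyo_state"
    dR <- derivatives(s, p)
    dC <- deSolve::DLLfunc(func = "mamyo_derivs", dllname = "mamyo",
                           initfunc = "mamyo_initmod", times = 0,
                           y = unclass(s), parms = unclass(p), nout = 4)$dy
    expect_lt(max(abs(dR - dC) / pmax(abs(dR), 1e-6)), 1e-10)
  }
})

test_that("a frozen system stays constant and non-finite stimuli are rejected", {
  p <- default_parameters(
    g_na = 0, g_nal_parent = 0, g_nab = 0, g_cal_parent = 0, g_to = 0,
    g_kur = 0, g_kr = 0, g_ss = 0, g_k1 = 0, g_kb = 0, g_kach = 0, g_kca = 0,
    g_clca = 0, g_clb = 0, g_cab = 0, ibar_nak_parent = 0, ibar_ncx = 0,
    ibar_pmca = 0, vmax_serca_parent = 0, ks_rel = 0, kleak = 0,
    d_j_sl = 0, d_sl_myo = 0)
  s0 <- default_state()
  # freeze buffers and gates at their fixed points by zeroing gradients:
  # concentrations cannot move, so V and ion states must stay put
  res <- integrate_model(s0, p, NULL, t_span = 100, grid = 1)
  fin <- res$states[nrow(res$states), ]
  expect_lt(max(abs(fin[c("V", "Na_i", "K_i", "Cl_i")] -
                    s0[c("V", "Na_i", "K_i", "Cl_i")])), 1e-8)
  expect_lt(abs(fin[["Ca_sr"]] - s0[["Ca_sr"]]), 1e-5)
  expect_error(derivatives(s0, default_parameters(), stim = NaN), "finite")
})

test_that("halving solver tolerances changes the paced APD90 by less than 0.1 ms", {
  p <- default_parameters()
  y <- snapshot_2hz()
  a1 <- ap_features(integrate_model(y, p, pacing_protocol(cl = 500),
                                    t_span = 500, grid = 0.05, rtol = 1e-6))
  a2 <- ap_features(integrate_model(y, p, pacing_protocol(cl = 500),
                                    t_span = 500, grid = 0.05, rtol = 5e-7,
                                    atol = mamyo:::.default_atol() / 2))
  expect_lt(abs(a1[["APD90"]] - a2[["APD90"]]), 0.1)
})

test_that("doubling the output-grid resolution leaves AP features unchanged", {
  p <- default_parameters()
  y <- snapshot_2hz()
  a1 <- ap_features(integrate_model(y, p, pacing_protocol(cl = 500),
                                    t_span = 500, grid = 0.05))
  a2 <- ap_features(integrate_model(y, p, pacing_protocol(cl = 500),
                                    t_span = 500, grid = 0.025))
  expect_lt(abs(a1[["APD90"]] - a2[["APD90"]]), 0.05)
  expect_lt(abs(a1[["RMP"]] - a2[["RMP"]]), 0.1)
  expect_lt(abs(a1[["OS"]] - a2[["OS"]]), 0.1)
})

test_that("at 1-Hz pacing the membrane returns within 1 mV of its pre-stimulus potential", {
  p <- default_parameters()
  y <- pace_beats(snapshot_2hz(), p, cl = 1000, n = 20, grid = 2)
  r <- measure_beat(y, p, cl = 1000, grid = 0.5)
  v0 <- r$states[1, "V"]
  v_end <- r$states[nrow(r$states), "V"]
  expect_lt(abs(v_end - v0), 1)
})

test_that("pacing to steady state converges and flags its beat count", {
  p <- default_parameters()
  ss <- pace_to_steady_state(p, cl = 500, max_beats = 60, tol = 5e-3,
                             state0 = snapshot_2hz(), grid = 0.5)
  expect_true(ss$converged)
  expect_true(ss$n_beats < 60)
  expect_s3_class(ss$state, "mamyo_state")
  validate_state(normalize_occupancies(ss$state, tol = 0))
  expect_error(pace_to_steady_state(p, cl = 50), "12.5")
})
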