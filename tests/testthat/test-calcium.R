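# Calcium handling: SERCA scaling, fluxes, CaMKII, conservation.

test_that("CaMKII-SERCA factor has its midpoint, zero limit and derived values", {
  expect_equal(k_serca(0.0167), 0.5, tolerance = 1e-12)
  expect_equal(k_serca(0), 0, tolerance = 1e-10)
  # direct evaluation at twice the midpoint: 1 / ((1/2)^12 + 1)
  expect_equal(k_serca(0.0334), 1 / (0.5^12 + 1), tolerance = 1e-9)
  expect_equal(k_serca(0.0334), 0.999756, tolerance = 1e-5)
  ph <- seq(0, 0.2, by = 0.004)
  kk <- k_serca(ph)
  expect_true(all(kk >= 0 & kk < 1))
  expect_true(all(diff(kk) >= 0))
})

test_that("SERCA flux is forward-only with an empty SR and increases with the CaMKII factor", {
  p <- default_parameters()
  expect_gt(serca_flux(1.5e-4, 1e-9, p, k = 0), 0)
  j0 <- serca_flux(2e-4, 0.6, p, k = 0.2)
  j1 <- serca_flux(2e-4, 0.6, p, k = 0.4)
  expect_gt(j1, j0)
  ks <- seq(0, 0.99, by = 0.09)
  js <- vapply(ks, function(k) serca_flux(2e-4, 0.6, p, k), numeric(1))
  expect_true(all(diff(js) > 0))
})

test_that("CaMKII activity decays toward basal under clamped diastolic Ca2+", {
  p <- default_parameters()
  ca <- list(ca_j = 1e-4, ca_sl = 1e-4, ca_i = 1e-4)
  st <- c(ck_j = 0.2, ck_sl = 0.2, ck_cyt = 0.2, Ph_PLB = 0.02)
  out <- camkii_activation(ca, st, dt = 10000, params = p)
  expect_lt(out[["ck_j"]], st[["ck_j"]])
  expect_lt(out[["ck_cyt"]], st[["ck_cyt"]])
  # the drift function agrees in sign
  dr <- camkii_rates(ca, st[c("ck_j", "ck_sl", "ck_cyt")], p)
  expect_true(all(dr < 0))
})

test_that("total Ca2+ is conserved for 10 s with a closed sarcolemma", {
  p <- default_parameters(b_cal = 1, b_cab = 1, b_pmca = 1, b_ncx = 1)
  total_ca <- function(st) {
    v <- compartment_volumes(p)
    (st[["Ca_i"]] * v[["myo"]] + st[["Ca_sl"]] * v[["sl"]] +
       st[["Ca_j"]] * v[["junc"]] + st[["Ca_sr"]] * v[["sr"]] +
       (st[["TnCL"]] + st[["CaM"]] + st[["SRB"]]) * v[["myo"]] +
       (st[["SLLsl"]] + st[["SLHsl"]]) * v[["sl"]] +
       (st[["SLLj"]] + st[["SLHj"]]) * v[["junc"]] +
       st[["Csqn"]] * v[["sr"]]) / p[["vcell"]]
  }
  s0 <- default_state()
  res <- integrate_model(s0, p, NULL, t_span = 10000, grid = 10)
  expect_lt(abs(total_ca(res$final_state) - total_ca(s0)), 1e-9)
})

test_that("SR- and cytosol-referenced release fluxes differ exactly by the volume ratio", {
  p <- default_parameters()
  vol <- compartment_volumes(p)
  occ <- c(0.6, 0.2, 0.1, 0.1)
  fl <- ryr_flux(occ, 0.6, 1e-3, 0, p)
  j_cyt <- fl$j_rel * vol[["sr"]] / vol[["myo"]]
  expect_equal(j_cyt * vol[["myo"]] / vol[["sr"]], fl$j_rel, tolerance = 1e-15)
})

test_that("mean CaMKII activity and PLB phosphorylation rise with pacing rate", {
  p <- default_parameters()
  y <- snapshot_2hz()
  # 4-Hz pacing from the 2-Hz steady state
  y4 <- pace_beats(y, p, cl = 250, n = 80, grid = 2)
  r4 <- measure_beat(y4, p, cl = 250, grid = 0.5)
  r2 <- measure_beat(y, p, cl = 2000, grid = 0.5)
  expect_gt(mean(r4$states[, "ck_cyt"]), mean(r2$states[, "ck_cyt"]))
  # Ph_PLB rises monotonically over tens of seconds at fast pacing
  ph <- numeric(4); yy <- y
  for (k in 1:4) {
    yy <- pace_beats(yy, p, cl = 250, n = 40, grid = 2)
    ph[k] <- yy[["Ph_PLB"]]
  }
  expect_true(all(diff(ph) > 0))
})
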