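# The five Markov channel models under their published clamp protocols.

test_that("L-type current is zero with the open state empty and rejects bad Ca", {
  p <- default_parameters()
  occ <- c(1, 0, 0, 0, 0, 0, 0)
  expect_identical(ical_current(occ, 0, 1e-4, p), 0)
  expect_error(ical_current(occ, 0, -1, p), "positive")
})

test_that("L-type clamp family reproduces the calibrated peak density and I-V shape", {
  p <- default_parameters()
  fam <- run_voltage_clamp("ICaL", standard_clamp_protocol("ICaL"), p, dt = 0.1)
  iv <- iv_summary(fam, "peak")
  pk <- max(abs(iv$I))
  expect_equal(pk, 4.76, tolerance = 0.05)
  v_pk <- iv$V[which.max(abs(iv$I))]
  expect_true(abs(v_pk) <= 10)        # maximal inward current near 0 mV
  below <- iv$I[iv$V < v_pk]; above <- iv$I[iv$V > v_pk]
  expect_true(all(diff(abs(below)) > 0))   # rising limb
  expect_true(all(diff(abs(above)) < 0))   # falling limb
})

test_that("transient-outward and ultra-rapid currents hit their +30 mV densities", {
  p <- default_parameters()
  f2 <- run_voltage_clamp("Ito", standard_clamp_protocol("Ito"), p, dt = 0.2)
  iv2 <- iv_summary(f2, "peak")
  expect_equal(iv2$I[iv2$V == 30], 11.6, tolerance = 0.05)
  f3 <- run_voltage_clamp("IKur", standard_clamp_protocol("IKur"), p, dt = 0.5)
  iv3 <- iv_summary(f3, "peak")
  expect_equal(iv3$I[iv3$V == 30], 5.1, tolerance = 0.05)
  # normalized I-V equals 1 at the normalization voltage
  nrm <- iv_summary(f2, "peak", normalize_at = 30)
  expect_equal(nrm$I[nrm$V == 30], 1)
})

test_that("K+ Markov currents vanish at the K+ reversal potential", {
  p <- default_parameters()
  e_k <- nernst(1, 140, p[["ko"]], p[["temp"]])
  occ7 <- c(0, 0, 0, 1, 0, 0, 0)  # all open
  expect_equal(ito_current(occ7, e_k, p, k_i = 140), 0, tolerance = 1e-12)
  occ6 <- c(0, 0, 0, 0, 1, 0)
  expect_equal(ikur_current(occ6, e_k, p, k_i = 140), 0, tolerance = 1e-12)
  occ5 <- c(0, 0, 0, 1, 0)
  expect_equal(ikr_current(occ5, e_k, p, k_i = 140), 0, tolerance = 1e-12)
})

test_that("transient-outward inactivation is sigmoidal and recovery is monotone", {
  p <- default_parameters()
  spec <- channel_spec("Ito", p)
  # steady-state availability from holding potentials (two-pulse logic):
  # occupancy at the hold determines the current evoked by a +40 mV test
  holds <- seq(-90, -10, by = 10)
  avail <- vapply(holds, function(h) {
    p0 <- steady_state_distribution(spec, h, params = p)
    fam <- markov_clamp_trace(spec, p, list(list(V = 40, dur = 60, label = "step")),
                              p0, dt = 0.2)
    max(fam$O)
  }, numeric(1))
  avail <- avail / max(avail)
  expect_true(all(diff(avail) < 1e-6))          # monotone falling with depolarized holds
  expect_lt(avail[length(avail)], 0.30)         # inactivated at -10 mV hold
  expect_gt(avail[1], 0.97)                     # available at -90 mV hold
  # recovery from inactivation: monotone in interval, complete at long intervals
  p_inact <- steady_state_distribution(spec, -10, params = p)
  ints <- c(5, 15, 40, 100, 300, 1000)
  rec <- vapply(ints, function(dt_rec) {
    tr <- markov_clamp_trace(spec, p,
      list(list(V = -75, dur = dt_rec, label = "rest"),
           list(V = 40, dur = 60, label = "step")), p_inact, dt = 0.2)
    max(tr$O[tr$phase == "step"])
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  expect_gt(rec[length(rec)] / max(rec), 0.999)
})

test_that("steady-state K+ current activates slowly without inactivating and hits 3.32 pA/pF", {
  p <- default_parameters()
  fam <- run_voltage_clamp("x_ss", standard_clamp_protocol("x_ss"), p, dt = 1)
  iv <- iv_summary(fam, "peak")
  expect_equal(iv$I[iv$V == 30], 3.32, tolerance = 0.05)
  rec <- fam$records[[which(vapply(fam$records, `[[`, numeric(1), "V_step") == 30)]]
  step <- rec$trace[rec$trace$phase == "step", ]
  expect_true(all(diff(step$current) >= -1e-9))   # monotone rise, no decay
  expect_equal(rec$peak, rec$ss, tolerance = 1e-6)
})

test_that("rapid delayed-rectifier tail currents are nonnegative and saturate", {
  p <- default_parameters()
  fam <- run_voltage_clamp("IKr", standard_clamp_protocol("IKr"), p, dt = 1)
  tails <- iv_summary(fam, "tail")
  expect_true(all(tails$I >= -1e-9))
  # saturating with depolarized prepulses: top step within 15% of the max
  expect_gt(tails$I[nrow(tails)], 0.85 * max(tails$I))
  expect_true(all(diff(tails$I) > -1e-6))
})

test_that("RyR flux is zero with the open state empty and leak disabled", {
  p <- default_parameters(kleak = 0)
  fl <- ryr_flux(c(1, 0, 0, 0), 0.6, 1e-4, 0, p)
  expect_identical(fl$j_rel, 0)
  expect_identical(fl$j_leak, 0)
})

test_that("zero-conductance channel yields an all-zero clamp family", {
  p <- default_parameters(g_to = 0)
  fam <- run_voltage_clamp("Ito", standard_clamp_protocol("Ito"), p, dt = 1)
  iv <- iv_summary(fam, "peak")
  expect_true(all(abs(iv$I) < 1e-12))
  expect_error(iv_summary(fam, "peak", normalize_at = 30), "zero current")
})
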