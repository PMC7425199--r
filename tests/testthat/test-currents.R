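# Algebraic/HH sarcolemmal currents, pumps and exchangers.

test_that("Nernst potentials match hand-evaluated values and reject bad input", {
  expect_equal(nernst(1, 10, 10, 37), 0)
  expect_equal(nernst(1, 140, 5.4, 37), -87.0, tolerance = 0.01)
  # raising internal Cl- at fixed external Cl- makes E_Cl less negative
  expect_gt(nernst(-1, 14, 150, 37), nernst(-1, 8, 150, 37))
  expect_error(nernst(0, 1, 1), "valence")
  expect_error(nernst(1, -1, 1), "positive")
})

test_that("inward rectifier reverses at E_K, rectifies, and normalizes at -100 mV", {
  p <- default_parameters()
  e_k <- nernst(1, 140, p[["ko"]], p[["temp"]])
  expect_equal(ik1_current(e_k, 140, p), 0, tolerance = 1e-12)
  expect_gt(abs(ik1_current(-150, 140, p)), abs(ik1_current(-40, 140, p)))
  # normalization convention: value at -100 mV maps to 1
  v <- seq(-150, -40, 10)
  i <- vapply(v, ik1_current, numeric(1), k_i = 140, params = p)
  nrm <- i / abs(i[v == -100])
  expect_equal(abs(nrm[v == -100]), 1)
})

test_that("background K+ current is zero at E_K with a saturating monotone I-V", {
  p <- default_parameters()
  e_k <- -87
  expect_equal(ikb_current(e_k, e_k, p), 0)
  v <- seq(-120, 60, 5)
  i <- vapply(v, ikb_current, numeric(1), e_k = e_k, params = p)
  # strictly monotone above the K+ reversal; essentially closed below it
  expect_true(all(diff(i[v >= -90]) > 0))
  expect_true(all(abs(i[v < -90]) < 2e-3))
  # conductance saturates far above the half-activation voltage
  g_hi <- ikb_current(60, e_k, p) / (60 - e_k)
  g_vhi <- ikb_current(120, e_k, p) / (120 - e_k)
  expect_equal(g_hi, g_vhi, tolerance = 0.01)
})

test_that("Na+/K+ pump vanishes without internal Na+ and rises monotonically with it", {
  p <- default_parameters()
  expect_lt(inak_current(1e-6, -80, p), 1e-10)
  na <- c(4, 8, 12, 16, 20)
  i <- vapply(na, inak_current, numeric(1), V = -80, params = p)
  expect_true(all(diff(i) > 0))
})

test_that("exchanger current reverses sign across its reversal potential", {
  p <- default_parameters()
  v <- seq(-100, 60, 2)
  i <- vapply(v, incx_current, numeric(1), na_i = 10, ca_sl = 2e-4, params = p)
  expect_lt(min(i), 0); expect_gt(max(i), 0)
  expect_equal(sum(diff(sign(i)) != 0), 1)  # single crossing
})

test_that("late Na+ conductance carries the 68% increase as an exact factor", {
  p <- default_parameters()
  i1 <- inal_current(0.5, 0.5, -20, 70, p)
  p2 <- p; p2[["f_nal"]] <- 1
  expect_equal(i1 / inal_current(0.5, 0.5, -20, 70, p2), 1.68, tolerance = 1e-12)
})

test_that("each current is zero at its reversal potential", {
  p <- default_parameters()
  expect_equal(ina_current(0.5, 0.9, 0.9, 70, 70, p), 0)
  expect_equal(inab_current(70, 70, p), 0)
  expect_equal(icab_current(120, 120, p), 0)
  expect_equal(iclb_current(-78, -78, p), 0)
  expect_equal(iclca_current(3e-4, -78, -78, p), 0)
  expect_equal(ikca_current(3e-4, -87, -87, p), 0)
  expect_equal(iss_current(0, 0, -87, p), 0)  # closed gate
})

test_that("species-resolved currents add up exactly to the total ionic current", {
  p <- default_parameters()
  set.seed(7)
  for (k in 1:5) {
    s <- unclass(default_state())
    s["V"] <- runif(1, -90, 40)
    s[c("Ca_i", "Ca_sl", "Ca_j")] <- s[c("Ca_i", "Ca_sl", "Ca_j")] * runif(3, 0.5, 5)
    class(s) <- "mamyo_state"
    cur <- model_currents(s, p)
    total <- sum(cur[c("i_na", "i_nal", "i_nab", "i_cal", "i_to", "i_kur",
                       "i_kr", "i_ss", "i_k1", "i_kb", "i_kach", "i_kca",
                       "i_clca", "i_clb", "i_nak", "i_ncx", "i_pmca", "i_cab")])
    expect_equal(total, unname(cur[["i_ion"]]), tolerance = 1e-12)
  }
})
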