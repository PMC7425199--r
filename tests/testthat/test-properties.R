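# Cross-cutting physiological invariants of the assembled model.

test_that("occupancy conservation holds along a paced trajectory", {
  p <- default_parameters()
  r <- integrate_model(snapshot_2hz(), p, pacing_protocol(cl = 500, n_beats = 2),
                       t_span = 1000, grid = 0.5)
  for (idx in markov_blocks()) {
    sums <- rowSums(r$states[, idx, drop = FALSE])
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
  validate_state(normalize_occupancies(r$final_state, tol = 0))
})

test_that("APD ordering holds on every beat of a paced train", {
  p <- default_parameters()
  y <- snapshot_2hz()
  for (b in 1:5) {
    r <- measure_beat(y, p, cl = 500, grid = 0.1)
    ap <- ap_features(r)
    expect_true(ap[["APD20"]] <= ap[["APD30"]])
    expect_true(ap[["APD30"]] <= ap[["APD50"]])
    expect_true(ap[["APD50"]] <= ap[["APD90"]])
    expect_equal(ap[["APA"]], ap[["OS"]] - ap[["RMP"]], tolerance = 1e-9)
    y <- normalize_occupancies(r$final_state, tol = 1e-9)
  }
})

test_that("net transmembrane flux of Na+ and Ca2+ vanishes over a steady cycle", {
  p <- default_parameters()
  r <- measure_beat(snapshot_2hz(), p, cl = 500, grid = 0.1)
  cur <- result_currents(r)
  dt <- diff(r$t); mid <- function(x) (x[-1] + x[-length(x)]) / 2
  flux <- list(
    Na = cur[, "i_na"] + cur[, "i_nal"] + cur[, "i_nab"] +
      3 * cur[, "i_ncx"] + 3 * cur[, "i_nak"],
    K = cur[, "i_to"] + cur[, "i_kur"] + cur[, "i_kr"] + cur[, "i_ss"] +
      cur[, "i_k1"] + cur[, "i_kb"] + cur[, "i_kach"] + cur[, "i_kca"] -
      2 * cur[, "i_nak"] + r$i_stim,
    Ca = cur[, "i_cal"] + cur[, "i_cab"] + cur[, "i_pmca"] - 2 * cur[, "i_ncx"])
  ratio <- vapply(flux, function(f)
    abs(sum(mid(f) * dt)) / sum(abs(mid(f)) * dt), numeric(1))
  expect_lt(ratio[["Na"]], 1e-3)
  expect_lt(ratio[["Ca"]], 1e-3)
  # K+ carries the residual equilibration of the slow Cl-/K+ pair and sits
  # within 1%; Cl- itself turns over too little per cycle for a meaningful
  # net/gross ratio (its absolute drift is bounded instead)
  expect_lt(ratio[["K"]], 1e-2)
  expect_lt(abs(r$final_state[["Cl_i"]] - r$states[1, "Cl_i"]), 1e-4)
})

test_that("Ca2+-transient decay accelerates from 0.5-Hz to 4-Hz pacing", {
  p <- default_parameters()
  y5 <- snapshot_05hz()
  tau5 <- cat_features(measure_beat(y5, p, cl = 2000, grid = 0.5))[["tau_decay"]]
  y4 <- pace_beats(snapshot_2hz(), p, cl = 250, n = 100, grid = 2)
  tau4 <- cat_features(measure_beat(y4, p, cl = 250, grid = 0.2))[["tau_decay"]]
  expect_lt(tau4, tau5)
})

test_that("bulk Na+ stays within 10-17 mM across the paced rate range", {
  p <- default_parameters()
  y <- snapshot_2hz()
  nai <- c(at_2hz = y[["Na_i"]])
  y1 <- pace_beats(y, p, cl = 1000, n = 60, grid = 2)
  nai["at_1hz"] <- y1[["Na_i"]]
  y4 <- pace_beats(y, p, cl = 250, n = 120, grid = 2)
  nai["at_4hz"] <- y4[["Na_i"]]
  expect_true(all(nai > 10 & nai < 17))
})

test_that("intracellular Cl- rises when pacing accelerates from 1 to 10 Hz", {
  p <- default_parameters()
  y1 <- pace_beats(snapshot_2hz(), p, cl = 1000, n = 30, grid = 2)
  y10 <- pace_beats(y1, p, cl = 100, n = 300, grid = 2)
  expect_gt(y10[["Cl_i"]], y1[["Cl_i"]])
})

test_that("potassium depletion at 10-Hz pacing elevates the resting potential", {
  p <- default_parameters()
  y10 <- pace_beats(snapshot_2hz(), p, cl = 100, n = 300, grid = 2)
  expect_lt(y10[["K_i"]], snapshot_2hz()[["K_i"]])
  r10 <- measure_beat(y10, p, cl = 100, grid = 0.1)
  r2 <- measure_beat(snapshot_2hz(), p, cl = 500, grid = 0.1)
  expect_gt(min(r10$states[, "V"]), min(r2$states[, "V"]))
})
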