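# Markov gating engine: generator structure, stationary distributions,
# temperature rescaling.

test_that("generators have zero column sums for every channel over a voltage grid", {
  p <- default_parameters()
  lig <- list(ca_j = 2e-4, ca_sr = 0.6, camkii = 0.01)
  for (ch in c("ICaL", "Ito", "IKur", "IKr", "RyR")) {
    spec <- channel_spec(ch, p)
    for (V in seq(-150, 80, by = 23)) {
      Q <- transition_matrix(spec, V, lig, params = p)
      expect_lt(max(abs(colSums(Q))), 1e-12)
      offdiag <- Q - diag(diag(Q))
      expect_true(all(offdiag >= 0))
    }
  }
})

test_that("two-state fixture yields the analytic generator and open fraction", {
  fx <- fixtures("two_state_channel")
  Q <- transition_matrix(fx, 0)
  expect_equal(unname(Q), matrix(c(-2, 2, 1, -1), 2, 2))
  ss <- steady_state_distribution(fx, 0)
  expect_equal(unname(ss[["O"]]), 2 / 3, tolerance = 1e-12)
})

test_that("detailed-balance ring reaches its Boltzmann weights", {
  fx <- fixtures("detailed_balance_ring")
  ss <- steady_state_distribution(fx$spec, 0)
  expect_equal(unname(ss), unname(fx$weights), tolerance = 1e-10)
  # brute-force long-time integration agrees
  brute <- relax_markov(fx$spec, 0)
  expect_equal(unname(brute), unname(fx$weights), tolerance = 1e-7)
})

test_that("stationary distributions match brute-force relaxation for all channels", {
  p <- default_parameters()
  lig <- list(ca_j = 5e-4, ca_sr = 0.6, camkii = 0)
  for (ch in c("ICaL", "Ito", "IKur", "IKr", "RyR")) {
    spec <- channel_spec(ch, p)
    for (V in c(-80, -40, 0, 30)) {
      ss <- steady_state_distribution(spec, V, lig, params = p)
      brute <- relax_markov(spec, V, lig, p)
      expect_lt(max(abs(ss - brute)), 1e-6)
      expect_equal(sum(ss), 1, tolerance = 1e-12)
      expect_true(all(ss >= 0))
    }
  }
})

test_that("kinetic Q10 scaling multiplies every rate by the expected factor", {
  expect_equal(q10_factor(1.8, 22, 32), 1.8)
  expect_equal(q10_factor(2.4, 22, 22), 1)
  p <- default_parameters()
  spec <- channel_spec("Ito", p)
  Q22 <- transition_matrix(spec, 10, temp = p[["texp_ito"]], params = p)
  Q32 <- transition_matrix(spec, 10, temp = p[["texp_ito"]] + 10, params = p)
  off <- Q22 != 0 & row(Q22) != col(Q22)
  expect_equal(Q32[off] / Q22[off], rep(1.8, sum(off)), tolerance = 1e-12)
})

test_that("temperature neutrality: all Q10 factors are exactly 1 at the reference", {
  p <- default_parameters()
  expect_identical(q10_factor(p[["q10_ito_kin"]], p[["texp_ito"]], p[["texp_ito"]]), 1)
  expect_identical(q10_factor(p[["q10_kur_cond"]], p[["texp_kur"]], p[["texp_kur"]]), 1)
  expect_identical(q10_factor(p[["q10_ss"]], p[["texp_ss"]], p[["texp_ss"]]), 1)
})

test_that("negative rates and unknown channels are rejected with informative errors", {
  bad <- markov_spec("bad", c("A", "B"),
                     function(V, ligands, temp, params)
                       matrix(c(0, -1, 1, 0), 2, 2), c(B = 1),
                     function(params, temp) 1, 0)
  expect_error(transition_matrix(bad, 0), "negative transition rate")
  expect_error(channel_spec("INa"), "registry")
  expect_error(transition_matrix(channel_spec("Ito"), NaN), "finite")
})
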