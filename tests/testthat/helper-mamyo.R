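# Shared helpers: short pacing loops and stored steady-state snapshots.

# Pace n beats at a cycle length, returning the end-diastolic state.
pace_beats <- function(state, params, cl, n, grid = 1) {
  y <- state
  proto <- pacing_protocol(cl = cl, n_beats = 1)
  for (b in seq_len(n)) {
    r <- integrate_model(y, params, proto, t_span = cl, grid = grid)
    y <- normalize_occupancies(r$final_state, tol = 1e-9)
  }
  y
}

# One finely sampled beat from a given state.
measure_beat <- function(state, params, cl, grid = 0.05) {
  integrate_model(state, params, pacing_protocol(cl = cl), t_span = cl,
                  grid = grid)
}

snapshot_2hz <- function() {
  read_state(system.file("extdata", "steady_2hz_ra.json", package = "mamyo"))
}

snapshot_05hz <- function() {
  read_state(system.file("extdata", "steady_05hz_ra.json", package = "mamyo"))
}

# Long-time ODE relaxation of a Markov chain: brute-force stationary
# distribution, independent of the null-space solver.
relax_markov <- function(spec, V, ligands = list(), params = default_parameters(),
                         p0 = NULL, t_end = 2e5) {
  Q <- transition_matrix(spec, V, ligands, params[["temp"]], params)
  n <- nrow(Q)
  if (is.null(p0)) p0 <- rep(1 / n, n)
  out <- deSolve::lsoda(p0, c(0, t_end / 2, t_end),
                        function(t, y, parms) list(as.numeric(Q %*% y)),
                        rtol = 1e-10, atol = 1e-12)
  stats::setNames(pmax(out[nrow(out), -1], 0), spec$states)
}
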