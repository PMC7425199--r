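# Analytic test fixtures with closed-form answers. No external data: every
# test object is built in code.

#' Analytic fixtures for testing
#'
#' * `two_state_channel`: 2-state Markov spec with constant rates alpha = 2,
#'   beta = 1 ms^-1; stationary open fraction 2/3, generator
#'   `[[-2, 1], [2, -1]]`.
#' * `triangle_ap`: triangular action potential from -80 mV to +20 mV with
#'   an instantaneous upstroke and a linear 100-ms repolarization, so
#'   APD_x = x ms by construction.
#' * `exp_cat`: synthetic Ca2+ transient -- 0.1 uM baseline with an abrupt
#'   0.2 uM rise at t = 10 ms decaying as exp(-t/200), so the decay constant
#'   is 200 ms by construction.
#' * `detailed_balance_ring`: 3-state ring whose rates satisfy detailed
#'   balance with Boltzmann weights proportional to (1, 2, 4).
#'
#' @param kind fixture name
#' @return the fixture object (spec, data.frame, or list)
#' @export
#' @examples
#' fx <- fixtures("two_state_channel")
fixtures <- function(kind) {
  switch(kind,
    two_state_channel = markov_spec(
      "two_state", c("C", "O"),
      rate_fn = function(V, ligands, temp, params) {
        matrix(c(0, 2, 1, 0), 2, 2,
               dimnames = list(c("C", "O"), c("C", "O")))
      },
      conducting = c(O = 1),
      g_fn = function(params, temp) 1,
      erev = 0),
    triangle_ap = {
      t_up <- seq(0, 1, by = 0.05)
      t_down <- seq(1, 101, by = 0.05)
      data.frame(
        t = c(t_up, t_down[-1]),
        V = c(-80 + 100 * t_up, 20 - (t_down[-1] - 1)))
    },
    exp_cat = {
      t <- seq(0, 1500, by = 1)
      ca <- ifelse(t < 10, 0.1, 0.1 + 0.2 * exp(-(t - 10) / 200)) * 1e-3
      list(t = t, ca = ca, tau = 200)
    },
    detailed_balance_ring = {
      w <- c(A = 1, B = 2, C = 4)
      base <- 0.5
      R <- matrix(0, 3, 3, dimnames = list(names(w), names(w)))
      for (pair in list(c("A", "B"), c("B", "C"), c("C", "A"))) {
        i <- pair[1]; j <- pair[2]
        R[j, i] <- base * w[[j]]   # i -> j
        R[i, j] <- base * w[[i]]   # j -> i
      }
      spec <- markov_spec(
        "ring", names(w),
        rate_fn = function(V, ligands, temp, params) R,
        conducting = c(C = 1), g_fn = function(params, temp) 1, erev = 0)
      list(spec = spec, weights = w / sum(w))
    },
    stop("unknown fixture '", kind, "'; known: two_state_channel, ",
         "triangle_ap, exp_cat, detailed_balance_ring")
  )
}
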