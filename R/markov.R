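# Generic Markov-chain gating engine and the channel registry.
#
# Occupancy dynamics follow dp/dt = Q(V, ligands, T) p, where Q is a
# generator matrix: off-diagonal entry Q[i, j] is the transition rate from
# state j to state i (ms^-1), and each diagonal entry is minus its column
# sum, so column sums vanish and total occupancy is conserved.

#' Construct a Markov chain specification
#'
#' @param name channel name (label only)
#' @param states ordered character vector of state labels
#' @param rate_fn function `(V, ligands, temp, params)` returning a
#'   states-x-states matrix of nonnegative off-diagonal transition rates
#'   (ms^-1), entry `[i, j]` being the rate from state j to state i
#' @param conducting named numeric vector of per-state conductance weights;
#'   names must be a subset of `states`
#' @param g_fn function `(params, temp)` returning the effective maximal
#'   conductance (nS/pF) at the simulation temperature, including Q10 and
#'   printed scaling factors but excluding drug block
#' @param erev one of `"K"` (Nernst on potassium), `"GHK_Ca"` (Goldman flux
#'   on calcium), or a fixed numeric reversal potential (mV)
#' @return object of class `mamyo_markov_spec`
#' @export
markov_spec <- function(name, states, rate_fn, conducting, g_fn, erev) {
  stopifnot(is.character(states), length(states) >= 2,
            all(names(conducting) %in% states))
  structure(list(name = name, states = states, rate_fn = rate_fn,
                 conducting = conducting, g_fn = g_fn, erev = erev),
            class = "mamyo_markov_spec")
}

#' Generator (transition-rate) matrix of a Markov channel
#'
#' Evaluates the channel's transition rates at a membrane potential, ligand
#' set and temperature (kinetic Q10 scaling is applied inside the channel's
#' rate function) and assembles the generator matrix.
#'
#' @param spec a `mamyo_markov_spec`
#' @param V membrane potential (mV)
#' @param ligands named list of ligand concentrations (mM), e.g.
#'   `list(ca_j = 1e-4)`; channels ignore ligands they do not bind
#' @param temp simulation temperature (degC)
#' @param params model parameters
#' @return generator matrix (ms^-1) with zero column sums
#' @export
transition_matrix <- function(spec, V, ligands = list(),
                              temp = NULL, params = default_parameters()) {
  if (!is.finite(V)) stop("V must be finite")
  if (is.null(temp)) temp <- params[["temp"]]
  R <- spec$rate_fn(V, ligands, temp, params)
  if (any(R < 0)) {
    bad <- which(R < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative transition rate %s -> %s in %s",
                 spec$states[bad[2]], spec$states[bad[1]], spec$name))
  }
  diag(R) <- 0
  diag(R) <- -colSums(R)
  dimnames(R) <- list(spec$states, spec$states)
  R
}

#' Stationary occupancy distribution of a Markov channel
#'
#' Solves the null space of the generator at fixed conditions, the
#' distribution a voltage-clamped channel relaxes to. Used for protocol
#' initialization and steady-state activation/inactivation curves.
#'
#' @inheritParams transition_matrix
#' @return occupancy vector: entries nonnegative, summing to 1
#' @export
steady_state_distribution <- function(spec, V, ligands = list(),
                                      temp = NULL, params = default_parameters()) {
  Q <- transition_matrix(spec, V, ligands, temp, params)
  n <- nrow(Q)
  A <- rbind(Q, rep(1, n))
  b <- c(rep(0, n), 1)
  p <- tryCatch(qr.solve(A, b), error = function(e)
    stop("generator is singular beyond its conservation null space"))
  if (any(p < -1e-8))
    stop("generator admits no nonnegative stationary distribution")
  p <- pmax(p, 0)
  stats::setNames(p / sum(p), spec$states)
}

## ---------------------------------------------------------------------------
## Per-channel transition-rate definitions. Rates are authored at each
## channel's reference temperature and multiplied by the kinetic Q10 factor.

.rates_ical <- function(V, ligands, temp, p) {
  ca <- ligands$ca_j
  if (is.null(ca)) ca <- 1e-4
  if (ca <= 0) stop("Ca_cleft must be positive")
  ck <- if (is.null(ligands$camkii)) 0 else ligands$camkii
  Vs <- V + p[["cal_shift"]]
  a  <- p[["cal_r0"]] * exp((Vs - p[["cal_vh"]]) / (2 * p[["cal_k"]]))
  b  <- p[["cal_r0"]] * exp(-(Vs - p[["cal_vh"]]) / (2 * p[["cal_k"]]))
  phi <- ca^2 / (ca^2 + p[["cal_kd_cdi"]]^2)
  kcdi <- p[["cal_kcdi"]] * phi / (1 + p[["ck_fltcc"]] * ck)
  kvdi <- p[["cal_kvdi"]] / (1 + exp(-(V - p[["cal_vdi_vh"]]) / p[["cal_vdi_k"]]))
  s <- c("C2", "C1", "O", "I1Ca", "I2Ca", "I1V", "I2V")
  R <- matrix(0, 7, 7, dimnames = list(s, s))
  R["C1", "C2"] <- a;                 R["C2", "C1"] <- b
  R["O", "C1"]  <- p[["cal_k1"]];     R["C1", "O"]  <- p[["cal_k2"]]
  R["I1Ca", "O"] <- kcdi;             R["O", "I1Ca"] <- p[["cal_rcdi"]]
  R["I2Ca", "I1Ca"] <- p[["cal_kif"]]; R["I1Ca", "I2Ca"] <- p[["cal_kir"]]
  R["C2", "I2Ca"] <- p[["cal_rec2"]]
  R["I1V", "O"] <- kvdi;              R["O", "I1V"] <- p[["cal_rvdi"]]
  R["I2V", "I1V"] <- p[["cal_kvf"]];  R["I1V", "I2V"] <- p[["cal_kvr"]]
  R["C2", "I2V"] <- p[["cal_rec2v"]]
  R
}

.rates_ito <- function(V, ligands, temp, p) {
  f <- q10_factor(p[["q10_ito_kin"]], p[["texp_ito"]], temp)
  a <- p[["ito_a"]] * exp(V / p[["ito_sa"]])
  b <- p[["ito_b"]] * exp(-V / p[["ito_sb"]])
  ro <- p[["ito_r0"]] * exp(-V / p[["ito_sr"]])
  s <- c("C3", "C2", "C1", "O", "I", "IS1", "IS2")
  R <- matrix(0, 7, 7, dimnames = list(s, s))
  R["C2", "C3"] <- 3 * a; R["C3", "C2"] <- b
  R["C1", "C2"] <- 2 * a; R["C2", "C1"] <- 2 * b
  R["O", "C1"]  <- a;     R["C1", "O"]  <- 3 * b
  R["I", "O"]   <- p[["ito_ki"]];     R["O", "I"] <- ro
  R["IS1", "I"] <- p[["ito_kis1f"]];  R["I", "IS1"] <- p[["ito_kis1r"]]
  R["IS2", "IS1"] <- p[["ito_kis2f"]]; R["IS1", "IS2"] <- p[["ito_kis2r"]]
  R * f
}

.rates_ikur <- function(V, ligands, temp, p) {
  f <- q10_factor(p[["q10_kur_kin"]], p[["texp_kur"]], temp)
  a <- p[["kur_scale"]] * p[["kur_a"]] * exp(V / p[["kur_sa"]])
  b <- p[["kur_scale"]] * p[["kur_b"]] * exp(-V / p[["kur_sb"]])
  s <- c("C4", "C3", "C2", "C1", "O", "I")
  R <- matrix(0, 6, 6, dimnames = list(s, s))
  R["C3", "C4"] <- 4 * a; R["C4", "C3"] <- b
  R["C2", "C3"] <- 3 * a; R["C3", "C2"] <- 2 * b
  R["C1", "C2"] <- 2 * a; R["C2", "C1"] <- 3 * b
  R["O", "C1"]  <- a;     R["C1", "O"]  <- 4 * b
  R["I", "O"]   <- p[["kur_ki"]]; R["O", "I"] <- p[["kur_ri"]]
  R * f
}

.rates_ikr <- function(V, ligands, temp, p) {
  # fitted directly at body temperature; no Q10 rescaling
  s <- c("C3", "C2", "C1", "O", "I")
  R <- matrix(0, 5, 5, dimnames = list(s, s))
  R["C2", "C3"] <- p[["kr_a3"]] * exp(V / p[["kr_s3"]])
  R["C3", "C2"] <- p[["kr_b3"]] * exp(-V / p[["kr_sb3"]])
  R["C1", "C2"] <- p[["kr_a2"]] * exp(V / p[["kr_s2"]])
  R["C2", "C1"] <- p[["kr_b2"]] * exp(-V / p[["kr_sb2"]])
  R["O", "C1"]  <- p[["kr_ao"]] * exp(V / p[["kr_so"]])
  R["C1", "O"]  <- p[["kr_bo"]] * exp(-V / p[["kr_sbo"]])
  R["I", "O"]   <- p[["kr_ki"]] * exp(V / p[["kr_ski"]])
  R["O", "I"]   <- p[["kr_ri"]] * exp(-V / p[["kr_sri"]])
  R
}

.rates_ryr <- function(V, ligands, temp, p) {
  ca_j  <- if (is.null(ligands$ca_j)) 1e-4 else ligands$ca_j
  ca_sr <- if (is.null(ligands$ca_sr)) 0.55 else ligands$ca_sr
  ck    <- if (is.null(ligands$camkii)) 0 else ligands$camkii
  ec50 <- p[["ec50sr_parent"]] * p[["f_ec50"]]
  kcasr <- p[["maxsr"]] - (p[["maxsr"]] - p[["minsr"]]) /
    (1 + (ec50 / ca_sr)^2.5)
  ko_sr <- (1 + p[["ck_fryr"]] * ck) *
    (1 + 0.5 * p[["pka_ryr"]]) * p[["ko_ca"]] / kcasr
  ki_sr <- p[["ki_ca"]] * kcasr
  # caffeine raises the opening probability by sensitizing the channel to
  # cleft Ca2+ (the multiplier acts on the Ca2+ seen by the activation gate)
  ca_act <- ca_j * p[["caff_ryr"]]
  s <- c("R", "O", "I", "RI")
  R <- matrix(0, 4, 4, dimnames = list(s, s))
  hh <- p[["ryr_hill"]]
  act <- ca_act^hh / (ca_act^hh + p[["ryr_kd"]]^hh)
  R["O", "R"]  <- ko_sr * act;    R["R", "O"]  <- p[["kom"]]
  R["I", "O"]  <- ki_sr * ca_j;   R["O", "I"]  <- p[["kim"]]
  R["RI", "I"] <- p[["kom"]];     R["I", "RI"] <- ko_sr * act
  R["R", "RI"] <- p[["kim"]];     R["RI", "R"] <- ki_sr * ca_j
  R
}

## ---------------------------------------------------------------------------

#' Channel registry
#'
#' Returns the Markov specification of a named channel: `"ICaL"` (7-state
#' L-type Ca2+ channel with the stated C2-C1 voltage shift), `"Ito"`
#' (7-state transient outward K+), `"IKur"` (6-state ultra-rapid K+ with
#' activation rates at 1/8 of the parent values), `"IKr"` (5-state rapid
#' delayed rectifier), `"RyR"` (4-state SR release channel).
#'
#' @param name channel name
#' @param params model parameters (conductance factors are read from here)
#' @return a `mamyo_markov_spec`
#' @export
channel_spec <- function(name, params = default_parameters()) {
  switch(name,
    ICaL = markov_spec("ICaL",
      c("C2", "C1", "O", "I1Ca", "I2Ca", "I1V", "I2V"), .rates_ical,
      c(O = 1),
      function(p, temp) p[["g_cal_parent"]] * p[["f_cal"]] * (1 - p[["b_cal"]]),
      "GHK_Ca"),
    Ito = markov_spec("Ito",
      c("C3", "C2", "C1", "O", "I", "IS1", "IS2"), .rates_ito,
      c(O = 1),
      function(p, temp) p[["g_to"]] *
        q10_factor(p[["q10_ito_cond"]], p[["texp_ito"]], temp) *
        (1 - p[["b_to"]]),
      "K"),
    IKur = markov_spec("IKur",
      c("C4", "C3", "C2", "C1", "O", "I"), .rates_ikur,
      c(O = 1),
      function(p, temp) p[["g_kur"]] * p[["vm_kur"]] *
        q10_factor(p[["q10_kur_cond"]], p[["texp_kur"]], temp) *
        (1 - p[["b_kur"]]),
      "K"),
    IKr = markov_spec("IKr",
      c("C3", "C2", "C1", "O", "I"), .rates_ikr,
      c(O = 1),
      function(p, temp) p[["g_kr"]] * (1 - p[["b_kr"]]),
      "K"),
    RyR = markov_spec("RyR",
      c("R", "O", "I", "RI"), .rates_ryr,
      c(O = 1),
      function(p, temp) p[["ks_rel"]],
      0),
    stop("unknown channel '", name,
         "'; registry: ICaL, Ito, IKur, IKr, RyR")
  )
}
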