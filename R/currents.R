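# Sarcolemmal currents: Markov-channel current equations, HH/algebraic
# currents, pumps and exchangers. Sign convention: inward current negative.
# All densities in pA/pF.

#' Nernst equilibrium potential
#'
#' @param z ionic valence (nonzero)
#' @param c_in intracellular concentration (mM, > 0)
#' @param c_out extracellular concentration (mM, > 0)
#' @param temp temperature (degC)
#' @return potential (mV)
#' @export
#' @examples
#' nernst(1, 140, 5.4, 37)   # ~ -87 mV
nernst <- function(z, c_in, c_out, temp = 37) {
  if (z == 0) stop("valence must be nonzero")
  if (any(c_in <= 0) || any(c_out <= 0)) stop("concentrations must be positive")
  rtf_mv(temp) / z * log(c_out / c_in)
}

#' Reversal potentials from live concentrations
#' @param state model state
#' @param params model parameters
#' @return named vector E_Na, E_K, E_Cl, E_Ca (mV)
#' @export
reversal_set <- function(state, params) {
  tc <- params[["temp"]]
  c(E_Na = nernst(1, state[["Na_i"]], params[["nao"]], tc),
    E_K  = nernst(1, state[["K_i"]], params[["ko"]], tc),
    E_Cl = nernst(-1, state[["Cl_i"]], params[["clo"]], tc),
    E_Ca = nernst(2, state[["Ca_sl"]], params[["cao"]], tc))
}

# Goldman-Hodgkin-Katz driving term for Ca2+ (mM * mV scale); the channel
# permeability parameter absorbs the remaining constants.
.ghk_ca <- function(V, ca_in, ca_out, temp) {
  gam <- 0.341
  u <- 2 * V / rtf_mv(temp)
  small <- abs(u) < 1e-6
  num <- gam * (ca_in * exp(u) - ca_out)
  out <- ifelse(small,
                rtf_mv(temp) / 2 * gam * (ca_in - ca_out),
                V * num / (exp(u) - 1))
  out
}

#' L-type Ca2+ current from Markov occupancy
#'
#' Goldman flux through the open state; conductance is the parent value
#' times the printed 1/4 scaling and the drug-block multiplier.
#'
#' @param occ occupancy vector in registry order (C2, C1, O, I1Ca, I2Ca,
#'   I1V, I2V)
#' @param V membrane potential (mV)
#' @param ca_j dyadic-cleft Ca2+ (mM, > 0)
#' @param params model parameters
#' @param temp simulation temperature (degC; default from `params`)
#' @return current density (pA/pF), negative inward
#' @export
ical_current <- function(occ, V, ca_j, params, temp = NULL) {
  if (ca_j <= 0) stop("Ca_cleft must be positive")
  if (is.null(temp)) temp <- params[["temp"]]
  g <- params[["g_cal_parent"]] * params[["f_cal"]] *
    (1 + 0.5 * params[["pka_ltcc"]]) * (1 - params[["b_cal"]])
  g * occ[[3]] * .ghk_ca(V, ca_j, params[["cao"]], temp)
}

.k_markov_current <- function(spec_name, occ, V, params, k_i, temp) {
  if (is.null(temp)) temp <- params[["temp"]]
  spec <- channel_spec(spec_name, params)
  g <- spec$g_fn(params, temp)
  e_k <- nernst(1, k_i, params[["ko"]], temp)
  o <- occ[[match(names(spec$conducting), spec$states)]]
  g * o * (V - e_k)
}

#' Transient outward K+ current from Markov occupancy
#' @param occ occupancy vector in registry order
#' @param V membrane potential (mV)
#' @param params model parameters
#' @param k_i cytosolic K+ (mM) for the Nernst reversal
#' @param temp simulation temperature (degC)
#' @return current density (pA/pF)
#' @export
ito_current <- function(occ, V, params, k_i = 140, temp = NULL)
  .k_markov_current("Ito", occ, V, params, k_i, temp)

#' Ultra-rapid delayed-rectifier K+ current from Markov occupancy
#' @inheritParams ito_current
#' @return current density (pA/pF)
#' @export
ikur_current <- function(occ, V, params, k_i = 140, temp = NULL)
  .k_markov_current("IKur", occ, V, params, k_i, temp)

#' Rapid delayed-rectifier K+ current from Markov occupancy
#' @inheritParams ito_current
#' @return current density (pA/pF)
#' @export
ikr_current <- function(occ, V, params, k_i = 140, temp = NULL)
  .k_markov_current("IKr", occ, V, params, k_i, temp)

## -- HH-type and algebraic currents -----------------------------------------

#' Steady-state K+ current activation curve and time constant
#' @param V membrane potential (mV)
#' @param params model parameters
#' @param temp simulation temperature (degC)
#' @return list with `inf` and `tau` (ms, Q10-rescaled from the 22 degC data)
#' @export
xss_gate <- function(V, params, temp = NULL) {
  if (is.null(temp)) temp <- params[["temp"]]
  inf <- 1 / (1 + exp(-(V - params[["ss_vh"]]) / params[["ss_k"]]))
  tau22 <- params[["ss_tau0"]] /
    (1 + exp((V - params[["ss_tvh"]]) / params[["ss_tk"]])) + params[["ss_tau1"]]
  tau <- tau22 / q10_factor(params[["q10_ss"]], params[["texp_ss"]], temp)
  list(inf = inf, tau = tau)
}

#' Steady-state (non-inactivating) K+ current
#'
#' Single-activation-gate HH current with conductance 0.049 nS/pF; the
#' conductance Q10 of 2.4 rescales it away from its body-temperature
#' reference when the model is run at other temperatures.
#'
#' @param x_ss activation gate value in [0, 1]
#' @param V membrane potential (mV)
#' @param e_k potassium reversal potential (mV)
#' @param params model parameters
#' @param temp simulation temperature (degC)
#' @return current density (pA/pF)
#' @export
iss_current <- function(x_ss, V, e_k, params, temp = NULL) {
  stopifnot(x_ss >= 0, x_ss <= 1)
  if (is.null(temp)) temp <- params[["temp"]]
  g <- params[["g_ss"]] *
    q10_factor(params[["q10_ss"]], params[["tref_cond_ss"]], temp)
  g * (1 - params[["b_ss"]]) * x_ss * (V - e_k)
}

#' Inward-rectifier K+ current
#'
#' Algebraic inward rectifier; reverses at the K+ Nernst potential computed
#' from the live concentrations, so K+ depletion shifts (and can invert) the
#' current.
#'
#' @param V membrane potential (mV)
#' @param k_i cytosolic K+ (mM)
#' @param params model parameters
#' @param temp temperature (degC)
#' @return current density (pA/pF)
#' @export
ik1_current <- function(V, k_i, params, temp = NULL) {
  if (is.null(temp)) temp <- params[["temp"]]
  e_k <- nernst(1, k_i, params[["ko"]], temp)
  dv <- V - e_k
  a <- 1.02 / (1 + exp(0.2385 * (dv - 59.215)))
  b <- params[["k1_rect"]] *
    (0.49124 * exp(0.08032 * (dv + 5.476)) + exp(0.06175 * (dv - 594.31))) /
    (1 + exp(-0.5143 * (dv + 4.753)))
  g <- params[["g_k1"]] * params[["vm_k1"]] * sqrt(params[["ko"]] / 5.4)
  g * (1 - params[["b_k1"]]) * a / (a + b) * dv
}

#' Background K+ current (instantaneous Boltzmann conductance)
#' @param V membrane potential (mV)
#' @param e_k potassium reversal (mV)
#' @param params model parameters
#' @return current density (pA/pF)
#' @export
ikb_current <- function(V, e_k, params) {
  g <- params[["g_kb"]] / (1 + exp(-(V - params[["kb_vh"]]) / params[["kb_k"]]))
  g * (1 - params[["b_kb"]]) * (V - e_k)
}

#' Na+/K+-ATPase current
#'
#' Parent pump formulation with the maximal rate decreased by 40%. The PKA
#' phosphorylation input lowers the pump's Na+ half-saturation.
#'
#' @param na_i cytosolic Na+ (mM, > 0)
#' @param V membrane potential (mV)
#' @param params model parameters
#' @param temp temperature (degC)
#' @return current density (pA/pF), positive (outward)
#' @export
inak_current <- function(na_i, V, params, temp = NULL) {
  stopifnot(na_i > 0)
  if (is.null(temp)) temp <- params[["temp"]]
  rtf <- rtf_mv(temp)
  sigma <- (exp(params[["nao"]] / 67.3) - 1) / 7
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * V / rtf) +
                 0.0365 * sigma * exp(-V / rtf))
  km_na <- params[["km_naip"]] * (1 - 0.3 * params[["pka_nak"]])
  ibar <- params[["ibar_nak_parent"]] * params[["f_nak"]] *
    (1 - params[["b_nak"]])
  ibar * fnak * params[["ko"]] / (params[["ko"]] + params[["km_ko"]]) /
    (1 + (km_na / na_i)^4)
}

#' Na+/Ca2+ exchanger current
#'
#' Reversible electrogenic exchanger (3 Na+ : 1 Ca2+) sensing
#' sub-sarcolemmal Ca2+, with allosteric Ca2+ activation. Positive current =
#' reverse mode (Ca2+ entry, Na+ efflux).
#'
#' @param V membrane potential (mV)
#' @param na_i cytosolic Na+ (mM)
#' @param ca_sl sub-sarcolemmal Ca2+ (mM)
#' @param params model parameters
#' @param temp temperature (degC)
#' @return current density (pA/pF)
#' @export
incx_current <- function(V, na_i, ca_sl, params, temp = NULL) {
  if (is.null(temp)) temp <- params[["temp"]]
  rtf <- rtf_mv(temp)
  eta <- params[["ncx_eta"]]
  ef <- exp(eta * V / rtf); er <- exp((eta - 1) * V / rtf)
  nao <- params[["nao"]]; cao <- params[["cao"]]
  ka <- 1 / (1 + (params[["ncx_kdact"]] / ca_sl)^3)
  num <- ef * na_i^3 * cao - er * nao^3 * ca_sl
  den <- (params[["km_cao"]] * na_i^3 + params[["km_nao"]]^3 * ca_sl +
          params[["km_nai"]]^3 * cao * (1 + ca_sl / params[["km_cai"]]) +
          params[["km_cai"]] * nao^3 * (1 + (na_i / params[["km_nai"]])^3) +
          na_i^3 * cao + nao^3 * ca_sl) *
    (1 + params[["ncx_ksat"]] * er)
  params[["ibar_ncx"]] * (1 - params[["b_ncx"]]) * ka * num / den
}

#' Plasma-membrane Ca2+ pump current
#' @param ca_sl sub-sarcolemmal Ca2+ (mM)
#' @param params model parameters
#' @return current density (pA/pF), positive (outward)
#' @export
ipmca_current <- function(ca_sl, params) {
  h <- 1.6
  params[["ibar_pmca"]] * (1 - params[["b_pmca"]]) *
    ca_sl^h / (ca_sl^h + params[["km_pca"]]^h)
}

#' Fast Na+ current (HH m3hj formulation, kinetics from the parent lineage)
#' @param m,h,j gate values
#' @param V membrane potential (mV)
#' @param e_na Na+ reversal (mV)
#' @param params model parameters
#' @return current density (pA/pF)
#' @export
ina_current <- function(m, h, j, V, e_na, params) {
  params[["g_na"]] * (1 - params[["b_na"]]) * m^3 * h * j * (V - e_na)
}

#' Late Na+ current; conductance is the parent value increased by 68%
#' @param mL,hL gate values
#' @param V membrane potential (mV)
#' @param e_na Na+ reversal (mV)
#' @param params model parameters
#' @return current density (pA/pF)
#' @export
inal_current <- function(mL, hL, V, e_na, params) {
  params[["g_nal_parent"]] * params[["f_nal"]] * (1 - params[["b_nal"]]) *
    mL^3 * hL * (V - e_na)
}

#' Acetylcholine-activated K+ current (closed at the baseline ACh = 0)
#' @param V membrane potential (mV)
#' @param e_k potassium reversal (mV)
#' @param params model parameters
#' @return current density (pA/pF)
#' @export
ikach_current <- function(V, e_k, params) {
  act <- params[["ach"]] / (params[["ach"]] + params[["kach_k05"]])
  rect <- 1 / (1 + exp((V - e_k - 140) / 25)) * 0.1 +
    1 / (1 + exp((V - e_k + 10) / 12)) * 0.9
  params[["g_kach"]] * (1 - params[["b_kach"]]) * act * rect * (V - e_k)
}

#' Small-conductance Ca2+-activated K+ current
#' @param ca_sl sub-sarcolemmal Ca2+ (mM)
#' @param V membrane potential (mV)
#' @param e_k potassium reversal (mV)
#' @param params model parameters
#' @return current density (pA/pF)
#' @export
ikca_current <- function(ca_sl, V, e_k, params) {
  h <- params[["kca_h"]]
  act <- ca_sl^h / (ca_sl^h + params[["kca_kd"]]^h)
  params[["g_kca"]] * (1 - params[["b_kca"]]) * act * (V - e_k)
}

#' Ca2+-activated Cl- current
#' @param ca_sl sub-sarcolemmal Ca2+ (mM)
#' @param V membrane potential (mV)
#' @param e_cl chloride reversal (mV)
#' @param params model parameters
#' @return current density (pA/pF)
#' @export
iclca_current <- function(ca_sl, V, e_cl, params) {
  act <- ca_sl / (ca_sl + params[["clca_kd"]])
  params[["g_clca"]] * (1 - params[["b_clca"]]) * act * (V - e_cl)
}

#' Background (leak) currents
#' @param V membrane potential (mV)
#' @param e reversal potential of the carried ion (mV)
#' @param params model parameters
#' @return current density (pA/pF)
#' @name backgrounds
NULL

#' @rdname backgrounds
#' @export
inab_current <- function(V, e, params) params[["g_nab"]] * (V - e)

#' @rdname backgrounds
#' @export
icab_current <- function(V, e, params)
  params[["g_cab"]] * (1 - params[["b_cab"]]) * (V - e)

#' @rdname backgrounds
#' @export
iclb_current <- function(V, e, params) params[["g_clb"]] * (V - e)

## -- HH gate kinetics for the fast/late Na+ current --------------------------

#' @keywords internal
na_gate_rates <- function(V, mshift = 0) {
  vm <- V + mshift
  dv <- vm + 47.13
  am <- if (abs(dv) < 1e-6) 3.2 else 0.32 * dv / (1 - exp(-0.1 * dv))
  bm <- 0.08 * exp(-vm / 11)
  if (V >= -40) {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp((V + 10.66) / -11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    ah <- 0.135 * exp((80 + V) / -6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  c(am = am, bm = bm, ah = ah, bh = bh, aj = aj, bj = bj)
}

#' @keywords internal
hl_gate <- function(V, params) {
  list(inf = 1 / (1 + exp((V + 91) / 6.1)), tau = params[["tau_hl"]])
}
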