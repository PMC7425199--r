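# Intracellular Ca2+ handling: SERCA with CaMKII-dependent scaling, RyR
# release/leak fluxes, buffering, inter-compartment diffusion, and the
# reduced CaMKII/phospholamban module.

#' CaMKII-dependent SERCA scaling factor
#'
#' Hill-type function of the phospholamban phosphorylation fraction:
#' `K_SERCA = 1 / ((0.0167 / Ph_PLB)^12 + 1)`. The factor lies in [0, 1);
#' `Ph_PLB` is clamped below at 1e-6 so the limit at zero phosphorylation is
#' exactly 0.
#'
#' @param ph_plb phospholamban phosphorylation fraction (>= 0)
#' @param params model parameters (midpoint and Hill exponent)
#' @return dimensionless factor in [0, 1)
#' @export
#' @examples
#' k_serca(0.0167)   # 0.5
k_serca <- function(ph_plb, params = default_parameters()) {
  ph <- pmax(ph_plb, 1e-6)
  1 / ((params[["kserca_mid"]] / ph)^params[["kserca_hill"]] + 1)
}

#' SERCA Ca2+ uptake flux
#'
#' Reversible pump with the parent form; the maximal rate carries the
#' printed 50% reduction and is scaled upward by the CaMKII factor
#' (`Vmax_eff = Vmax * (1 + k)`), so the flux is strictly increasing in `k`
#' at fixed concentrations. Cytosol-referenced.
#'
#' @param ca_i bulk cytosolic Ca2+ (mM, > 0)
#' @param ca_sr SR Ca2+ (mM, > 0)
#' @param params model parameters
#' @param k CaMKII scaling factor from [k_serca()]
#' @return J_up (mM/ms, cytosol-referenced); positive = uptake into SR
#' @export
serca_flux <- function(ca_i, ca_sr, params, k = 0) {
  stopifnot(ca_i > 0, ca_sr >= 0)
  h <- params[["hill_serca"]]
  kmf <- params[["kmf_parent"]] * params[["f_kmf"]] *
    (1 - 0.45 * params[["pka_plb"]])
  fwd <- (ca_i / kmf)^h
  rev <- (ca_sr / params[["kmr"]])^h
  vmax <- params[["vmax_serca_parent"]] * params[["f_vmax"]] * (1 + k) *
    (1 - params[["b_serca"]])
  vmax * (fwd - rev) / (1 + fwd + rev)
}

#' RyR release and leak fluxes
#'
#' Four-state release channel gated by cleft Ca2+ with luminal-Ca-dependent
#' sensitivity (EC50 = parent value x 0.9). Release is SR-referenced; the
#' leak (a parallel closed-state pathway) is cytosol-referenced, both driven
#' by the SR-to-cleft gradient. CaMKII enhances opening and leak; the
#' caffeine hook multiplies the opening rate.
#'
#' @param occ RyR occupancy (R, O, I, RI)
#' @param ca_sr SR Ca2+ (mM)
#' @param ca_j cleft Ca2+ (mM)
#' @param camkii active CaMKII fraction in the cleft
#' @param params model parameters
#' @return list with `j_rel` (mM/ms, SR-referenced) and `j_leak` (mM/ms,
#'   cytosol-referenced)
#' @export
ryr_flux <- function(occ, ca_sr, ca_j, camkii = 0, params = default_parameters()) {
  grad <- ca_sr - ca_j
  j_rel <- params[["ks_rel"]] * occ[[2]] * grad
  j_leak <- params[["kleak"]] * (1 + params[["ck_fleak"]] * camkii) * grad
  list(j_rel = j_rel, j_leak = j_leak)
}

#' CaMKII activation drift
#'
#' Reduced Ca2+-calmodulin activation cascade: in each compartment the
#' active fraction rises with a Hill function of local Ca2+ and decays at a
#' constant rate. Faster pacing raises time-averaged Ca2+ and hence the mean
#' active fraction, which drives phospholamban phosphorylation and the
#' frequency-dependent acceleration of Ca2+-transient decay.
#'
#' @param ca named vector/list of compartment Ca2+ (`ca_j`, `ca_sl`, `ca_i`, mM)
#' @param ck named vector of active fractions (`ck_j`, `ck_sl`, `ck_cyt`)
#' @param params model parameters
#' @return named vector of d(active fraction)/dt (ms^-1)
#' @export
camkii_rates <- function(ca, ck, params) {
  hill <- params[["ck_hill"]]
  act <- function(c_x, kd) c_x^hill / (c_x^hill + kd^hill)
  ka <- params[["ck_kact"]]; kd <- params[["ck_kdeact"]]
  c(ck_j   = ka * act(ca[["ca_j"]],  params[["ck_kdj"]])  * (1 - ck[["ck_j"]])  - kd * ck[["ck_j"]],
    ck_sl  = ka * act(ca[["ca_sl"]], params[["ck_kdsl"]]) * (1 - ck[["ck_sl"]]) - kd * ck[["ck_sl"]],
    ck_cyt = ka * act(ca[["ca_i"]],  params[["ck_kdcyt"]]) * (1 - ck[["ck_cyt"]]) - kd * ck[["ck_cyt"]])
}

#' Advance CaMKII activation states over a small interval
#'
#' Explicit exponential-relaxation update of the per-compartment active
#' fractions and the phospholamban phosphorylation fraction, useful for
#' stand-alone signalling experiments; inside full simulations the same
#' drift is integrated with the rest of the system.
#'
#' @param ca named compartment Ca2+ (mM), held constant over `dt`
#' @param state named vector with `ck_j`, `ck_sl`, `ck_cyt`, `Ph_PLB`
#' @param dt interval (ms)
#' @param params model parameters
#' @return updated named vector
#' @export
camkii_activation <- function(ca, state, dt, params = default_parameters()) {
  hill <- params[["ck_hill"]]
  act <- function(c_x, kd) c_x^hill / (c_x^hill + kd^hill)
  upd <- function(x, kon, koff) {
    rate <- kon + koff
    xinf <- kon / rate
    xinf + (x - xinf) * exp(-rate * dt)
  }
  ka <- params[["ck_kact"]]; kd <- params[["ck_kdeact"]]
  out <- state
  out[["ck_j"]]   <- upd(state[["ck_j"]],  ka * act(ca[["ca_j"]],  params[["ck_kdj"]]),  kd)
  out[["ck_sl"]]  <- upd(state[["ck_sl"]], ka * act(ca[["ca_sl"]], params[["ck_kdsl"]]), kd)
  out[["ck_cyt"]] <- upd(state[["ck_cyt"]], ka * act(ca[["ca_i"]], params[["ck_kdcyt"]]), kd)
  out[["Ph_PLB"]] <- upd(state[["Ph_PLB"]],
                         params[["plb_kp"]] * out[["ck_cyt"]], params[["plb_kdp"]])
  out
}

#' @keywords internal
buffer_rate <- function(ca_free, bound, bmax, kon, koff) {
  kon * ca_free * (bmax - bound) - koff * bound
}
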