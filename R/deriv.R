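# Right-hand side assembly (reference implementation).
#
# `model_currents()` evaluates every membrane current, transport flux and
# reversal potential at a state; `derivatives()` assembles the full
# d(state)/dt. The compiled RHS in src/model.c implements exactly the same
# equations for production integration; the two are held together by a
# consistency test.

#' All membrane currents and Ca2+ fluxes at a model state
#'
#' @param state model state vector
#' @param params model parameters
#' @param stim applied stimulus current (pA/pF, negative = inward), booked
#'   as a K+ current
#' @return named numeric vector: currents (pA/pF), Ca fluxes (`j_up`,
#'   `j_leak` cytosol-referenced mM/ms; `j_rel_sr` SR-referenced), reversal
#'   potentials (mV)
#' @export
model_currents <- function(state, params, stim = 0) {
  s <- unclass(state); p <- params
  tc <- p[["temp"]]
  e_na <- nernst(1, s[["Na_i"]], p[["nao"]], tc)
  e_k  <- nernst(1, s[["K_i"]], p[["ko"]], tc)
  e_cl <- nernst(-1, s[["Cl_i"]], p[["clo"]], tc)
  e_ca <- nernst(2, s[["Ca_sl"]], p[["cao"]], tc)

  i_na  <- ina_current(s[["m"]], s[["h"]], s[["j"]], s[["V"]], e_na, p)
  i_nal <- inal_current(s[["mL"]], s[["hL"]], s[["V"]], e_na, p)
  i_nab <- inab_current(s[["V"]], e_na, p)

  occ_cal <- s[c("cal_C2", "cal_C1", "cal_O", "cal_I1Ca", "cal_I2Ca",
                 "cal_I1V", "cal_I2V")]
  i_cal <- ical_current(occ_cal, s[["V"]], s[["Ca_j"]], p, tc)

  g_to <- p[["g_to"]] * q10_factor(p[["q10_ito_cond"]], p[["texp_ito"]], tc) *
    (1 - p[["b_to"]])
  i_to <- g_to * s[["ito_O"]] * (s[["V"]] - e_k)
  g_kur <- p[["g_kur"]] * p[["vm_kur"]] *
    q10_factor(p[["q10_kur_cond"]], p[["texp_kur"]], tc) * (1 - p[["b_kur"]])
  i_kur <- g_kur * s[["kur_O"]] * (s[["V"]] - e_k)
  i_kr  <- p[["g_kr"]] * (1 - p[["b_kr"]]) * s[["kr_O"]] * (s[["V"]] - e_k)
  i_ss  <- iss_current(s[["x_ss"]], s[["V"]], e_k, p, tc)
  i_k1  <- ik1_current(s[["V"]], s[["K_i"]], p, tc)
  i_kb  <- ikb_current(s[["V"]], e_k, p)
  i_kach <- ikach_current(s[["V"]], e_k, p)
  i_kca <- ikca_current(s[["Ca_sl"]], s[["V"]], e_k, p)

  i_clca <- iclca_current(s[["Ca_sl"]], s[["V"]], e_cl, p)
  i_clb  <- iclb_current(s[["V"]], e_cl, p)

  i_nak <- inak_current(s[["Na_i"]], s[["V"]], p, tc)
  i_ncx <- incx_current(s[["V"]], s[["Na_i"]], s[["Ca_sl"]], p, tc)
  i_pmca <- ipmca_current(s[["Ca_sl"]], p)
  i_cab <- icab_current(s[["V"]], e_ca, p)

  ks <- k_serca(s[["Ph_PLB"]], p)
  j_up <- serca_flux(s[["Ca_i"]], s[["Ca_sr"]], p, ks)
  ry <- ryr_flux(s[c("ryr_R", "ryr_O", "ryr_I", "ryr_RI")],
                 s[["Ca_sr"]], s[["Ca_j"]], s[["ck_j"]], p)

  i_ion <- i_na + i_nal + i_nab + i_cal + i_to + i_kur + i_kr + i_ss +
    i_k1 + i_kb + i_kach + i_kca + i_clca + i_clb + i_nak + i_ncx +
    i_pmca + i_cab

  c(i_na = i_na, i_nal = i_nal, i_nab = i_nab, i_cal = i_cal, i_to = i_to,
    i_kur = i_kur, i_kr = i_kr, i_ss = i_ss, i_k1 = i_k1, i_kb = i_kb,
    i_kach = i_kach, i_kca = i_kca, i_clca = i_clca, i_clb = i_clb,
    i_nak = i_nak, i_ncx = i_ncx, i_pmca = i_pmca, i_cab = i_cab,
    i_stim = stim, i_ion = i_ion,
    j_up = j_up, j_rel_sr = ry$j_rel, j_leak = ry$j_leak,
    k_serca = ks,
    e_na = e_na, e_k = e_k, e_cl = e_cl, e_ca = e_ca)
}

#' Time derivative of the full model state
#'
#' Assembles d(state)/dt from the channel, transporter and Ca2+-handling
#' submodules. The stimulus current is booked as a K+ flux so that paced
#' steady states conserve every ion species over a cycle.
#'
#' @param state model state vector
#' @param params model parameters
#' @param t time (ms; the autonomous system ignores it)
#' @param stim applied stimulus (pA/pF, negative = inward)
#' @return named derivative vector (same layout as the state)
#' @export
derivatives <- function(state, params, t = 0, stim = params[["stim_amp"]]) {
  if (!is.finite(stim)) stop("stimulus must be finite")
  s <- unclass(state); p <- params
  tc <- p[["temp"]]
  cur <- model_currents(state, p, stim)
  d <- stats::setNames(numeric(length(s)), names(s))

  ## Markov occupancy derivatives: dp/dt = Q p
  lig <- list(ca_j = s[["Ca_j"]], ca_sr = s[["Ca_sr"]], camkii = s[["ck_j"]])
  for (ch in names(.MARKOV_BLOCKS)) {
    idx <- match(.MARKOV_BLOCKS[[ch]], names(s))
    Q <- transition_matrix(channel_spec(ch, p), s[["V"]], lig, tc, p)
    d[idx] <- as.numeric(Q %*% s[idx])
  }

  ## HH gates
  g <- na_gate_rates(s[["V"]], p[["na_mshift"]])
  d[["m"]] <- g[["am"]] * (1 - s[["m"]]) - g[["bm"]] * s[["m"]]
  d[["h"]] <- g[["ah"]] * (1 - s[["h"]]) - g[["bh"]] * s[["h"]]
  d[["j"]] <- g[["aj"]] * (1 - s[["j"]]) - g[["bj"]] * s[["j"]]
  d[["mL"]] <- g[["am"]] * (1 - s[["mL"]]) - g[["bm"]] * s[["mL"]]
  hl <- hl_gate(s[["V"]], p)
  d[["hL"]] <- (hl$inf - s[["hL"]]) / hl$tau
  xg <- xss_gate(s[["V"]], p, tc)
  d[["x_ss"]] <- (xg$inf - s[["x_ss"]]) / xg$tau

  ## membrane potential (C normalized: pA/pF = mV/ms)
  d[["V"]] <- if (p[["vclamp_on"]] > 0) 0 else -(cur[["i_ion"]] + stim)

  ## ion bookkeeping
  vol <- compartment_volumes(p)
  cmyo  <- current_to_flux(p[["cm"]], vol[["myo"]])
  csl   <- current_to_flux(p[["cm"]], vol[["sl"]])
  cjunc <- current_to_flux(p[["cm"]], vol[["junc"]])

  d[["Na_i"]] <- -(cur[["i_na"]] + cur[["i_nal"]] + cur[["i_nab"]] +
                     3 * cur[["i_ncx"]] + 3 * cur[["i_nak"]]) * cmyo
  d[["K_i"]] <- -(cur[["i_to"]] + cur[["i_kur"]] + cur[["i_kr"]] +
                    cur[["i_ss"]] + cur[["i_k1"]] + cur[["i_kb"]] +
                    cur[["i_kach"]] + cur[["i_kca"]] - 2 * cur[["i_nak"]] +
                    stim) * cmyo
  d[["Cl_i"]] <- (cur[["i_clca"]] + cur[["i_clb"]]) * cmyo

  ## Ca2+ compartments
  jd_jsl  <- p[["d_j_sl"]] * (s[["Ca_j"]] - s[["Ca_sl"]])    # mmol/ms
  jd_slmy <- p[["d_sl_myo"]] * (s[["Ca_sl"]] - s[["Ca_i"]])  # mmol/ms

  db <- c(
    TnCL  = buffer_rate(s[["Ca_i"]], s[["TnCL"]], p[["tnc_bmax"]], p[["tnc_kon"]], p[["tnc_koff"]]),
    CaM   = buffer_rate(s[["Ca_i"]], s[["CaM"]], p[["cam_bmax"]], p[["cam_kon"]], p[["cam_koff"]]),
    SRB   = buffer_rate(s[["Ca_i"]], s[["SRB"]], p[["srb_bmax"]], p[["srb_kon"]], p[["srb_koff"]]),
    SLLsl = buffer_rate(s[["Ca_sl"]], s[["SLLsl"]], p[["sllsl_bmax"]], p[["sllsl_kon"]], p[["sllsl_koff"]]),
    SLHsl = buffer_rate(s[["Ca_sl"]], s[["SLHsl"]], p[["slhsl_bmax"]], p[["slhsl_kon"]], p[["slhsl_koff"]]),
    SLLj  = buffer_rate(s[["Ca_j"]], s[["SLLj"]], p[["sllj_bmax"]], p[["sllj_kon"]], p[["sllj_koff"]]),
    SLHj  = buffer_rate(s[["Ca_j"]], s[["SLHj"]], p[["slhj_bmax"]], p[["slhj_kon"]], p[["slhj_koff"]]),
    Csqn  = buffer_rate(s[["Ca_sr"]], s[["Csqn"]], p[["csqn_bmax"]], p[["csqn_kon"]], p[["csqn_koff"]])
  )
  d[names(db)] <- db

  j_up <- cur[["j_up"]]; j_rel <- cur[["j_rel_sr"]]; j_leak <- cur[["j_leak"]]
  r_myo_sr <- vol[["myo"]] / vol[["sr"]]
  d[["Ca_sr"]] <- j_up * r_myo_sr - j_rel - j_leak * r_myo_sr - db[["Csqn"]]
  d[["Ca_j"]] <- -cur[["i_cal"]] * cjunc / 2 +
    j_rel * vol[["sr"]] / vol[["junc"]] +
    j_leak * vol[["myo"]] / vol[["junc"]] -
    jd_jsl / vol[["junc"]] - db[["SLLj"]] - db[["SLHj"]]
  d[["Ca_sl"]] <- (cur[["i_ncx"]] - (cur[["i_cab"]] + cur[["i_pmca"]]) / 2) * csl +
    jd_jsl / vol[["sl"]] - jd_slmy / vol[["sl"]] -
    db[["SLLsl"]] - db[["SLHsl"]]
  d[["Ca_i"]] <- jd_slmy / vol[["myo"]] - j_up -
    db[["TnCL"]] - db[["CaM"]] - db[["SRB"]]

  ## CaMKII / phospholamban
  ck <- camkii_rates(list(ca_j = s[["Ca_j"]], ca_sl = s[["Ca_sl"]], ca_i = s[["Ca_i"]]),
                     list(ck_j = s[["ck_j"]], ck_sl = s[["ck_sl"]], ck_cyt = s[["ck_cyt"]]), p)
  d[["ck_j"]] <- ck[["ck_j"]]; d[["ck_sl"]] <- ck[["ck_sl"]]
  d[["ck_cyt"]] <- ck[["ck_cyt"]]
  d[["Ph_PLB"]] <- p[["plb_kp"]] * s[["ck_cyt"]] * (1 - s[["Ph_PLB"]]) -
    p[["plb_kdp"]] * s[["Ph_PLB"]]

  ## ion clamps force the species derivative to zero
  if (p[["clamp_nai"]] > 0) d[["Na_i"]] <- 0
  if (p[["clamp_ki"]]  > 0) d[["K_i"]]  <- 0
  if (p[["clamp_cli"]] > 0) d[["Cl_i"]] <- 0
  if (p[["clamp_cai"]] > 0) d[["Ca_i"]] <- 0

  bad <- !is.finite(d)
  if (any(bad))
    stop("non-finite derivative for state component(s): ",
         paste(names(d)[bad], collapse = ", "))
  d
}
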