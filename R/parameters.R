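# Model parameter catalogue.
#
# This is the single annotated parameter file for the model. Every constant
# the right-hand side uses is listed here once, with units and a provenance
# tag:
#   [published]    published value for this cell type
#   [parent-model] value carried over from the published ventricular
#                  modelling framework this model descends from
#   [fitted-here]  value calibrated in this package against the printed
#                  channel densities, action-potential and calcium-transient
#                  characteristics (see the methods vignette)
# Printed multipliers are stored as explicit factors next to the baseline
# value they scale, so recalibration is a parameter edit, not a code change.
#
# The parameter object is a flat named numeric vector (class "mamyo_params");
# the same vector, in the same order, is handed to the compiled right-hand
# side, so the order of .PARAM_DEFAULTS must match the index macros in
# src/model.c.

.PARAM_DEFAULTS <- c(
  ## -- geometry & bath ------------------------------------------------------
  temp      = 37,        # degC, simulation temperature [published]
  cm        = 50,        # pF, whole-cell capacitance [fitted-here]
  vcell     = 1.2e-11,   # L, cell volume [fitted-here]
  f_myo     = 0.70,      # bulk cytosol volume fraction [fitted-here: atrial
                         # cells carry a larger cytosolic share than the
                         # ventricular parent]
  f_sr      = 0.030,     # SR volume fraction [fitted-here]
  f_sl      = 0.015,     # sub-sarcolemmal shell fraction [fitted-here]
  f_junc    = 5.0e-4,    # dyadic cleft fraction [fitted-here]
  nao       = 140,       # mM [parent-model]
  ko        = 5.4,       # mM [parent-model]
  clo       = 150,       # mM [parent-model]
  cao       = 1.8,       # mM [parent-model]
  d_j_sl    = 7.0e-14,   # L/ms, cleft<->SL Ca diffusion [parent-model]
  d_sl_myo  = 1.0e-12,   # L/ms, SL<->cytosol Ca diffusion [parent-model]

  ## -- fast and late Na+ current -------------------------------------------
  g_na      = 6,         # nS/pF [fitted-here: upstroke ~210 V/s]
  g_nal_parent = 0.0066, # nS/pF [parent-model]
  f_nal     = 1.68,      # conductance increased by 68% [published]
  tau_hl    = 600,       # ms, late-Na inactivation [parent-model]
  na_mshift = 11,         # mV leftward shift of Na-channel activation
                         # (m gate); sets the excitation threshold near
                         # 7 pA/pF with the standard 4-ms pulse [fitted-here]
  g_nab     = 0.005,     # nS/pF background Na+ [fitted-here]

  ## -- L-type Ca2+ current, 7-state Markov chain ----------------------------
  g_cal_parent = 5.06,    # GHK permeability scale [fitted-here: peak density]
  f_cal     = 0.25,      # conductance reduced to 1/4 of parent [published]
  cal_shift = 4.4,       # mV added inside the C2<->C1 rates [published]
  cal_vh    = 0,         # mV, C2<->C1 steady-state half voltage [fitted-here]
  cal_k     = 6.5,       # mV, C2<->C1 slope [fitted-here]
  cal_r0    = 0.9,       # /ms, C2<->C1 speed [fitted-here]
  cal_k1    = 0.36,      # /ms, C1->O (voltage-independent) [fitted-here]
  cal_k2    = 0.16,      # /ms, O->C1 [fitted-here]
  cal_kcdi  = 0.5,       # /ms, max O->ICa (Ca-dependent inactivation)
  cal_kd_cdi = 0.002,    # mM, cleft-Ca half saturation of CDI [fitted-here]
  cal_rcdi  = 0.004,     # /ms, ICa->O recovery [fitted-here]
  cal_kif   = 0.010,     # /ms, I1Ca->I2Ca [fitted-here]
  cal_kir   = 0.004,     # /ms, I2Ca->I1Ca [fitted-here]
  cal_rec2  = 0.006,     # /ms, I2Ca->C2 recovery [fitted-here]
  cal_kvdi  = 0.08,      # /ms, max O->I1V (voltage-dependent inact.)
  cal_vdi_vh = -5,       # mV [fitted-here]
  cal_vdi_k = 8,         # mV [fitted-here]
  cal_rvdi  = 0.002,     # /ms, I1V->O [fitted-here]
  cal_kvf   = 0.005,     # /ms, I1V->I2V [fitted-here]
  cal_kvr   = 0.002,     # /ms, I2V->I1V [fitted-here]
  cal_rec2v = 0.004,     # /ms, I2V->C2 recovery [fitted-here]

  ## -- transient outward K+, 7-state Markov chain (rates at texp_ito) -------
  g_to      = 0.098,      # nS/pF at texp_ito [fitted-here: 11.6 pA/pF @ +30]
  ito_a     = 0.20,      # /ms, activation alpha prefactor [fitted-here]
  ito_sa    = 16,        # mV, alpha voltage slope [fitted-here]
  ito_b     = 0.08,      # /ms, beta prefactor [fitted-here]
  ito_sb    = 24,        # mV, beta slope [fitted-here]
  ito_ki    = 0.025,     # /ms, O->I [fitted-here]
  ito_r0    = 0.004,     # /ms, I->O recovery prefactor [fitted-here]
  ito_sr    = 40,        # mV, recovery slope [fitted-here]
  ito_kis1f = 0.006,     # /ms, I->IS1 [fitted-here]
  ito_kis1r = 0.003,     # /ms [fitted-here]
  ito_kis2f = 0.001,     # /ms, IS1->IS2 [fitted-here]
  ito_kis2r = 0.0008,    # /ms [fitted-here]
  q10_ito_kin  = 1.8,    # kinetics Q10 [published]
  q10_ito_cond = 1.1,    # conductance Q10 [published]
  texp_ito  = 22,        # degC, reference temperature of the rate set [published]

  ## -- ultra-rapid delayed rectifier K+, 6-state Markov chain ---------------
  g_kur     = 0.0285,      # nS/pF at texp_kur [fitted-here: 5.1 pA/pF @ +30]
  kur_a     = 0.36,       # /ms, parent activation alpha prefactor
  kur_sa    = 25,        # mV [fitted-here]
  kur_b     = 0.02,      # /ms, parent beta prefactor [fitted-here]
  kur_sb    = 40,        # mV [fitted-here]
  kur_scale = 0.125,     # alpha,beta decreased to 1/8 of parent [published]
  kur_ki    = 4e-4,      # /ms, O->I slow inactivation [fitted-here]
  kur_ri    = 2e-4,      # /ms, I->O [fitted-here]
  q10_kur_kin  = 1.9,    # [published]
  q10_kur_cond = 1.37,   # [published]
  texp_kur  = 22,        # degC [published]

  ## -- rapid delayed rectifier K+, 5-state Markov chain (37 degC) -----------
  g_kr      = 0.55,      # nS/pF [fitted-here: APD90 prolongation on block]
  kr_a3     = 0.02,      # /ms, C3->C2 [fitted-here]
  kr_s3     = 30,        # mV
  kr_b3     = 0.002,     # /ms, C2->C3
  kr_sb3    = 40,
  kr_a2     = 0.08,      # /ms, C2->C1
  kr_s2     = 25,
  kr_b2     = 0.005,     # /ms, C1->C2
  kr_sb2    = 40,
  kr_ao     = 0.08,      # /ms, C1->O
  kr_so     = 30,
  kr_bo     = 0.002,     # /ms, O->C1
  kr_sbo    = 25,
  kr_ki     = 0.3,       # /ms, O->I fast inactivation [fitted-here]
  kr_ski    = 25,
  kr_ri     = 0.06,      # /ms, I->O recovery
  kr_sri    = 30,

  ## -- steady-state K+ current (single HH activation gate) ------------------
  g_ss      = 0.049,     # nS/pF [published]
  ss_vh     = 24.3,        # mV, activation half voltage [fitted-here]
  ss_k      = 18,        # mV, slope [fitted-here]
  ss_tau0   = 450,       # ms at texp_ss [fitted-here]
  ss_tau1   = 150,       # ms floor at texp_ss [fitted-here]
  ss_tvh    = -40,       # mV [fitted-here]
  ss_tk     = 25,        # mV [fitted-here]
  q10_ss    = 2.4,       # applied to tau and conductance [published]
  texp_ss   = 22,        # degC, kinetics reference [published]
  tref_cond_ss = 37,     # degC, the stated conductance is the body-
                         # temperature value [fitted-here interpretation]

  ## -- inward rectifier and background K+ currents --------------------------
  g_k1      = 0.33,      # nS/pF [fitted-here: resting potential]
  g_kb      = 0.035,     # nS/pF [fitted-here]
  kb_vh     = -45,       # mV, Boltzmann half voltage [fitted-here]
  kb_k      = 8,         # mV [fitted-here]
  g_kach    = 0.10,      # nS/pF [parent-model]
  ach       = 0,         # uM acetylcholine; baseline 0 [fitted-here choice]
  kach_k05  = 0.125,     # uM half activation [parent-model]
  g_kca     = 0.003,     # nS/pF small-conductance Ca2+-activated K+
  kca_kd    = 3e-4,      # mM [parent-model]
  kca_h     = 2,         # Hill coefficient [parent-model]

  ## -- Cl- currents ----------------------------------------------------------
  g_clca    = 0.03,      # nS/pF Ca2+-activated Cl- [fitted-here]
  clca_kd   = 0.10,      # mM [parent-model]
  g_clb     = 0.0006,    # nS/pF background Cl- [fitted-here]
  g_cab     = 5e-5,      # nS/pF background Ca2+ [fitted-here]

  ## -- Na+/K+ ATPase ---------------------------------------------------------
  ibar_nak_parent = 3.0, # pA/pF maximal rate [parent-model]
  f_nak     = 0.6,       # maximum rate decreased by 40% [published]
  km_naip   = 15,        # mM [parent-model]
  km_ko     = 1.5,       # mM [parent-model]

  ## -- Na+/Ca2+ exchanger ----------------------------------------------------
  ibar_ncx  = 1.2,       # pA/pF [fitted-here]
  ncx_eta   = 0.35,      # [parent-model]
  ncx_ksat  = 0.32,      # [parent-model]
  km_cai    = 0.00359,   # mM [parent-model]
  km_cao    = 1.3,       # mM [parent-model]
  km_nai    = 12.29,     # mM [parent-model]
  km_nao    = 87.5,      # mM [parent-model]
  ncx_kdact = 2.56e-4,   # mM allosteric Ca activation [parent-model]

  ## -- sarcolemmal Ca2+ pump -------------------------------------------------
  ibar_pmca = 0.13,      # pA/pF [fitted-here]
  km_pca    = 5e-4,      # mM [parent-model]

  ## -- SERCA -----------------------------------------------------------------
  vmax_serca_parent = 8.0e-4,    # mM/ms cytosol-referenced [parent-model]
  f_vmax    = 0.5,       # Vmax reduced by 50% [published]
  kmf_parent = 2.46e-4,  # mM forward affinity [parent-model]
  f_kmf     = 1.13,      # Kmf increased by 13% [published]
  kmr       = 1.7,       # mM reverse affinity [parent-model]
  hill_serca = 1.787,    # [parent-model]

  ## -- ryanodine receptor, 4-state Markov chain ------------------------------
  ko_ca     = 0.5,       # /ms maximal opening rate [fitted-here]
  kom       = 0.06,      # /ms [parent-model]
  ki_ca     = 0.5,       # /mM/ms [parent-model]
  kim       = 0.001,     # /ms [parent-model]
  ec50sr_parent = 0.45,  # mM luminal half activation [parent-model]
  f_ec50    = 0.9,       # EC50 reduced by 10% [published]
  maxsr     = 15,        # [parent-model]
  minsr     = 1,         # [parent-model]
  ks_rel    = 0.4,        # /ms release rate scale (SR-referenced) [fitted-here]
  kleak     = 7.0e-7,    # /ms cytosol-referenced leak [fitted-here]

  ## -- Ca2+ buffers (Bmax mM in their own compartment, kon /mM/ms, koff /ms) -
  tnc_bmax  = 0.070,  tnc_kon  = 32.7, tnc_koff  = 0.0196, # troponin C low [parent-model]
  cam_bmax  = 0.024,  cam_kon  = 34,   cam_koff  = 0.238,  # calmodulin [parent-model]
  srb_bmax  = 0.0171, srb_kon  = 100,  srb_koff  = 0.060,  # SR membrane [parent-model]
  sllsl_bmax = 0.0374, sllsl_kon = 100, sllsl_koff = 1.3,  # SL low-affinity [parent-model]
  slhsl_bmax = 0.0134, slhsl_kon = 100, slhsl_koff = 0.03, # SL high-affinity [parent-model]
  sllj_bmax = 0.55,   sllj_kon = 100,  sllj_koff = 1.3,    # cleft low-affinity [parent-model]
  slhj_bmax = 0.20,   slhj_kon = 100,  slhj_koff = 0.03,   # cleft high-affinity [parent-model]
  csqn_bmax = 3.3,    csqn_kon = 100,  csqn_koff = 65,     # calsequestrin, SR-referenced [parent-model]

  ## -- CaMKII activation and phospholamban phosphorylation -------------------
  ck_kact   = 1e-4,      # /ms activation rate scale [fitted-here]
  ck_kdeact = 5e-4,      # /ms deactivation [fitted-here]
  ck_kdj    = 0.020,     # mM half-activation, cleft [fitted-here]
  ck_kdsl   = 0.0015,    # mM, SL [fitted-here]
  ck_kdcyt  = 6e-4,      # mM, cytosol [fitted-here]
  ck_hill   = 2,         # Hill coefficient of Ca-CaM activation
  plb_kp    = 6e-6,      # /ms phospholamban phosphorylation [fitted-here:
                         # slow kinetics, tens of seconds]
  plb_kdp   = 3e-6,      # /ms dephosphorylation [fitted-here]
  ck_fltcc  = 0.3,       # CDI relief per active-CaMKII unit [fitted-here]
  ck_fryr   = 1.0,       # RyR opening enhancement [fitted-here]
  ck_fleak  = 3.0,       # SR leak enhancement [fitted-here]
  kserca_mid  = 0.0167,  # PLB-phosphorylation midpoint of K_SERCA [published]
  kserca_hill = 12,      # Hill exponent of K_SERCA [published]

  ## -- static PKA phosphorylation fractions (reduced beta-adrenergic input) --
  pka_ltcc  = 0,
  pka_plb   = 0,
  pka_nak   = 0,
  pka_ryr   = 0,

  ## -- atrial variant conductance multipliers --------------------------------
  vm_kur    = 1,         # x2.10 in the left-atrial variant [published]
  vm_k1     = 1,         # x1.70 in the left-atrial variant [published]

  ## -- fractional drug block per current (0 = none, 1 = full) ----------------
  b_na = 0, b_nal = 0, b_cal = 0, b_to = 0, b_kur = 0, b_kr = 0, b_ss = 0,
  b_k1 = 0, b_kb = 0, b_kca = 0, b_kach = 0, b_clca = 0, b_ncx = 0,
  b_nak = 0, b_pmca = 0, b_serca = 0, b_cab = 0,

  ## -- protocol/runtime switches (set by the protocol engine, not by hand) ---
  stim_amp  = 0,         # pA/pF applied current (negative = inward)
  vclamp_on = 0,         # 1: membrane potential is an exogenous input
  clamp_nai = 0, clamp_ki = 0, clamp_cli = 0, clamp_cai = 0, # ion clamps
  caff_ryr  = 1,         # RyR opening-rate multiplier (7.5 under caffeine)
  ryr_hill  = 4,         # cooperativity of cleft-Ca activation of RyR
                         # (tetramer-like steepness) [fitted-here]
  ryr_kd    = 0.015,     # mM, half-saturation of cleft-Ca activation of
                         # RyR opening [fitted-here]
  k1_rect   = 0.2          # inward-rectification strength of I_K1 (scales the
                         # blocking-particle rate; < 1 weakens
                         # rectification at depolarized potentials) [fitted-here]
)

#' Default model parameters (right-atrial baseline)
#'
#' Returns the full parameter vector of the model: conductances, maximal
#' transport rates, compartment geometry, Q10 factors, buffer constants,
#' CaMKII/PLB kinetics, variant multipliers and per-current block fractions.
#' Units are noted in the package source next to each value together with a
#' provenance tag (published / parent-model / fitted-here).
#'
#' @param ... named overrides, e.g. `default_parameters(temp = 32)`
#' @return a named numeric vector of class `mamyo_params`
#' @export
#' @examples
#' p <- default_parameters()
#' p[["g_ss"]]
default_parameters <- function(...) {
  p <- .PARAM_DEFAULTS
  dots <- list(...)
  if (length(dots)) {
    nm <- names(dots)
    if (is.null(nm) || any(nm == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(nm, names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[nm] <- unlist(dots)
  }
  validate_parameters(p)
  class(p) <- "mamyo_params"
  p
}

#' Validate a parameter vector
#'
#' Checks structural invariants: completeness and ordering of the vector,
#' positive volume fractions, block fractions in [0, 1], positive Q10
#' factors, and the stated steady-state K+ conductance of 0.049 nS/pF at its
#' reference temperature unless deliberately overridden.
#'
#' @param p parameter vector
#' @return `p`, invisibly; errors describe the offending entry
#' @export
validate_parameters <- function(p) {
  if (!identical(names(p), names(.PARAM_DEFAULTS)))
    stop("parameter vector does not match the model's parameter catalogue")
  fr <- p[c("f_myo", "f_sr", "f_sl", "f_junc")]
  if (any(fr <= 0)) stop("compartment volume fractions must be positive")
  if (p[["f_myo"]] <= max(p[c("f_sr", "f_sl", "f_junc")]))
    stop("the bulk cytosol must be the largest compartment")
  blocks <- p[grep("^b_", names(p))]
  if (any(blocks < 0 | blocks > 1))
    stop("block fractions must lie in [0, 1]: ",
         paste(names(blocks)[blocks < 0 | blocks > 1], collapse = ", "))
  q10 <- p[grep("^q10_", names(p))]
  if (any(q10 <= 0)) stop("Q10 factors must be positive")
  if (any(p[c("vm_kur", "vm_k1")] <= 0))
    stop("variant multipliers must be positive")
  invisible(p)
}

#' Compartment volumes in litres
#' @param p parameter vector
#' @return named vector (myo, sr, sl, junc) in L
#' @export
compartment_volumes <- function(p) {
  v <- p[["vcell"]]
  c(myo = v * p[["f_myo"]], sr = v * p[["f_sr"]],
    sl = v * p[["f_sl"]], junc = v * p[["f_junc"]])
}

#' Temperature scaling factor
#'
#' Standard Q10 rescaling `q10 ^ ((t_sim - t_exp) / 10)`. Identity when the
#' simulation runs at the reference temperature.
#'
#' @param q10 fold change per 10 degC (> 0)
#' @param t_exp reference temperature (degC)
#' @param t_sim simulation temperature (degC)
#' @return dimensionless scaling factor
#' @export
#' @examples
#' q10_factor(1.8, 22, 32)  # 1.8
q10_factor <- function(q10, t_exp, t_sim) {
  stopifnot(q10 > 0)
  q10^((t_sim - t_exp) / 10)
}
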