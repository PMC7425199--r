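# Model state vector: layout, defaults, validation.
#
# The state is a flat named numeric vector; the order below is shared with
# the compiled right-hand side (src/model.c) and must not change.

.MARKOV_BLOCKS <- list(
  ICaL = c("cal_C2", "cal_C1", "cal_O", "cal_I1Ca", "cal_I2Ca", "cal_I1V", "cal_I2V"),
  Ito  = c("ito_C3", "ito_C2", "ito_C1", "ito_O", "ito_I", "ito_IS1", "ito_IS2"),
  IKur = c("kur_C4", "kur_C3", "kur_C2", "kur_C1", "kur_O", "kur_I"),
  IKr  = c("kr_C3", "kr_C2", "kr_C1", "kr_O", "kr_I"),
  RyR  = c("ryr_R", "ryr_O", "ryr_I", "ryr_RI")
)

.STATE_NAMES <- c(
  "V",
  unlist(.MARKOV_BLOCKS, use.names = FALSE),
  "m", "h", "j", "mL", "hL", "x_ss",
  "Na_i", "K_i", "Cl_i", "Ca_i", "Ca_sl", "Ca_j", "Ca_sr",
  "TnCL", "CaM", "SRB", "SLLsl", "SLHsl", "SLLj", "SLHj", "Csqn",
  "ck_j", "ck_sl", "ck_cyt", "Ph_PLB"
)

#' Names and order of the model state vector
#' @return character vector of state names
#' @export
state_names <- function() .STATE_NAMES

#' Indices of each Markov occupancy block within the state vector
#' @return named list of integer index vectors
#' @export
markov_blocks <- function() {
  lapply(.MARKOV_BLOCKS, function(nms) match(nms, .STATE_NAMES))
}

# Resting-state values: the calibrated right-atrial model relaxed without
# pacing for 200 s; the standard warm start for every protocol.
.STATE_DEFAULTS <- c(
  V = -84.7960843,
  cal_C2 = 0.99998025,
  cal_C1 = 4.25e-06,
  cal_O = 9.448e-06,
  cal_I1Ca = 3.02e-06,
  cal_I2Ca = 3.02e-06,
  cal_I1V = 7e-09,
  cal_I2V = 6e-09,
  ito_C3 = 0.998906915,
  ito_C2 = 0.001092686,
  ito_C1 = 3.98e-07,
  ito_O = 0,
  ito_I = 0,
  ito_IS1 = 0,
  ito_IS2 = 0,
  kur_C4 = 0.755203215,
  kur_C3 = 0.219621901,
  kur_C2 = 0.023950729,
  kur_C1 = 0.001160859,
  kur_O = 2.1099e-05,
  kur_I = 4.2198e-05,
  kr_C3 = 0.929324356,
  kr_C2 = 0.066062708,
  kr_C1 = 0.00426929,
  kr_O = 0.000340257,
  kr_I = 3.39e-06,
  ryr_R = 0.731778993,
  ryr_O = 1.7e-08,
  ryr_I = 6e-09,
  ryr_RI = 0.268220983,
  m = 0.009625792,
  h = 0.984201988,
  j = 0.990066233,
  mL = 0.009625792,
  hL = 0.265606593,
  x_ss = 0.002326888,
  Na_i = 13.1217321,
  K_i = 137.576063,
  Cl_i = 7.91583216,
  Ca_i = 0.000102193,
  Ca_sl = 0.000105865,
  Ca_j = 0.000160424,
  Ca_sr = 0.621919111,
  TnCL = 0.010196247,
  CaM = 0.000345334,
  SRB = 0.00248863,
  SLLsl = 0.000302106,
  SLHsl = 0.003495235,
  SLLj = 0.006704437,
  SLHj = 0.069685328,
  Csqn = 1.613572,
  ck_j = 1.2866e-05,
  ck_sl = 0.000990215,
  ck_cyt = 0.005606173,
  Ph_PLB = 0.009638936
)

#' Default model state
#'
#' Resting (quiescent end-diastolic) state of the right-atrial model:
#' membrane potential, Markov occupancies for the five gating schemes, HH
#' gates, bulk ion concentrations, compartmental Ca2+, bound buffers, and
#' CaMKII/phospholamban signalling states.
#'
#' @param ... named overrides
#' @return named numeric vector of class `mamyo_state`
#' @export
default_state <- function(...) {
  s <- .STATE_DEFAULTS[.STATE_NAMES]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .STATE_NAMES)
    if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
    s[names(dots)] <- unlist(dots)
  }
  s <- normalize_occupancies(s)
  class(s) <- "mamyo_state"
  s
}

#' Renormalize Markov occupancy blocks
#'
#' All states of every Markov chain are integrated explicitly, so occupancy
#' sums can drift at the solver tolerance. This clips entries to [0, 1] and
#' rescales each block to sum to exactly 1; the correction applied is tiny in
#' a healthy run and the conservation invariant remains directly testable.
#'
#' @param state state vector
#' @param tol drift above which renormalization is applied
#' @return state vector with occupancies renormalized
#' @export
normalize_occupancies <- function(state, tol = 0) {
  for (idx in markov_blocks()) {
    blk <- pmin(pmax(unclass(state)[idx], 0), 1)
    s <- sum(blk)
    if (s > 0 && abs(s - 1) > tol) state[idx] <- blk / s
  }
  state
}

#' Validate a model state
#'
#' Enforces the state invariants: each Markov occupancy block sums to 1
#' within `occ_tol` with entries in [-1e-12, 1 + 1e-12]; concentrations are
#' positive; gates and fractions lie in [0, 1].
#'
#' @param state state vector
#' @param occ_tol tolerance on occupancy sums (default 1e-9)
#' @return `state`, invisibly; errors name the violated component
#' @export
validate_state <- function(state, occ_tol = 1e-9) {
  if (!identical(names(state), .STATE_NAMES))
    stop("state vector does not match the model's state catalogue")
  for (ch in names(.MARKOV_BLOCKS)) {
    idx <- match(.MARKOV_BLOCKS[[ch]], .STATE_NAMES)
    blk <- unclass(state)[idx]
    if (any(blk < -1e-12 | blk > 1 + 1e-12))
      stop(ch, " occupancy out of [0, 1]")
    if (abs(sum(blk) - 1) > occ_tol)
      stop(ch, " occupancies do not sum to 1 (sum = ", format(sum(blk)), ")")
  }
  conc <- unclass(state)[c("Na_i", "K_i", "Cl_i", "Ca_i", "Ca_sl", "Ca_j", "Ca_sr")]
  if (any(conc <= 0))
    stop("non-positive concentration: ",
         paste(names(conc)[conc <= 0], collapse = ", "))
  gates <- unclass(state)[c("m", "h", "j", "mL", "hL", "x_ss",
                            "ck_j", "ck_sl", "ck_cyt", "Ph_PLB")]
  if (any(gates < 0 | gates > 1))
    stop("gate/fraction out of [0, 1]: ",
         paste(names(gates)[gates < 0 | gates > 1], collapse = ", "))
  invisible(state)
}
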