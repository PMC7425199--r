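# Feature extraction: action-potential metrics, Ca2+-transient metrics,
# I-V summaries, Ca2+-removal partitioning, rate-dependence sweeps.

#' Action-potential features from a voltage trace
#'
#' The window must contain exactly one stimulated beat starting at
#' `stim_t`. Resting membrane potential (RMP) is the voltage immediately
#' before the stimulus; overshoot (OS) is the maximum; amplitude
#' APA = OS - RMP; the maximal upstroke velocity comes from finite
#' differences; APD at x% repolarization runs from the reference instant
#' (time of maximal upstroke by default, stimulus onset optionally) to the
#' linearly interpolated crossing of RMP + (1 - x/100) APA.
#'
#' @param t time grid (ms)
#' @param V voltage trace (mV)
#' @param stim_t stimulus onset time (ms)
#' @param levels repolarization percentages
#' @param reference `"upstroke"` or `"stimulus"` APD reference point
#' @return named vector: RMP, OS, APA, dVdt_max (V/s), APD<levels>,
#'   APD50/APD90 ratio; failed repolarization yields `NA` for that level
#' @export
ap_features_window <- function(t, V, stim_t = t[1],
                               levels = c(20, 30, 50, 90),
                               reference = c("upstroke", "stimulus")) {
  reference <- match.arg(reference)
  stopifnot(length(t) == length(V), length(t) > 5)
  pre <- which(t <= stim_t)
  rmp <- if (length(pre)) V[max(pre)] else V[1]
  os <- max(V)
  apa <- os - rmp
  dv <- diff(V) / diff(t)
  i_up <- which.max(dv)
  dvdt_max <- dv[i_up]            # mV/ms = V/s
  if (apa < 10 || dvdt_max < 1) {
    out <- c(RMP = rmp, OS = os, APA = apa, dVdt_max = dvdt_max,
             stats::setNames(rep(NA_real_, length(levels)),
                             paste0("APD", levels)),
             APD50_APD90 = NA_real_)
    return(out)
  }
  t_ref <- if (reference == "upstroke") t[i_up] else stim_t
  i_peak <- which.max(V)
  apd <- vapply(levels, function(lv) {
    v_target <- rmp + (1 - lv / 100) * apa
    idx <- seq(i_peak, length(V))
    below <- which(V[idx] <= v_target)
    if (!length(below)) return(NA_real_)
    k <- idx[below[1]]
    if (k == 1) return(NA_real_)
    # linear interpolation across the crossing
    t_cross <- t[k - 1] + (v_target - V[k - 1]) *
      (t[k] - t[k - 1]) / (V[k] - V[k - 1])
    t_cross - t_ref
  }, numeric(1))
  names(apd) <- paste0("APD", levels)
  ratio <- if (all(c("APD50", "APD90") %in% names(apd)))
    apd[["APD50"]] / apd[["APD90"]] else NA_real_
  c(RMP = rmp, OS = os, APA = apa, dVdt_max = dvdt_max, apd,
    APD50_APD90 = ratio)
}

#' Action-potential features of a simulation result
#'
#' @param result a `mamyo_result` holding one stimulated beat (the stimulus
#'   is located from the recorded stimulus trace)
#' @param levels repolarization percentages
#' @param reference APD reference point, see [ap_features_window()]
#' @return named feature vector
#' @export
ap_features <- function(result, levels = c(20, 30, 50, 90),
                        reference = "upstroke") {
  stim_on <- which(result$i_stim != 0)
  stim_t <- if (length(stim_on)) result$t[stim_on[1]] else result$t[1]
  ap_features_window(result$t, result$states[, "V"], stim_t, levels, reference)
}

#' Ca2+-transient features
#'
#' @param t time grid (ms)
#' @param ca cytosolic Ca2+ trace (mM)
#' @param stim_t stimulus onset (ms)
#' @return named vector: `ca_dia` (uM), `ca_peak` (uM), `amp_ratio`
#'   (peak/diastolic), `ttp` (ms, stimulus to peak), `tau_decay` (ms,
#'   monoexponential fit from the peak to 10% above diastole); fit failure
#'   flags `tau_decay` as `NA`
#' @export
cat_features_window <- function(t, ca, stim_t = t[1]) {
  pre <- which(t <= stim_t)
  ca_dia <- if (length(pre)) ca[max(pre)] else ca[1]
  i_peak <- which.max(ca)
  ca_peak <- ca[i_peak]
  ttp <- t[i_peak] - stim_t
  floor_ca <- ca_dia + 0.1 * (ca_peak - ca_dia)
  idx <- seq(i_peak, length(ca))
  stop_i <- which(ca[idx] <= floor_ca)
  idx <- if (length(stop_i)) idx[seq_len(stop_i[1])] else idx
  tau <- NA_real_
  if (length(idx) > 5 && ca_peak > ca_dia * 1.05) {
    df <- data.frame(tt = t[idx] - t[idx[1]], y = ca[idx])
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ a * exp(-tt / tau) + c0, data = df,
                   start = list(a = ca_peak - ca_dia, tau = 100, c0 = ca_dia),
                   control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est <- stats::coef(fit)[["tau"]]
      if (is.finite(est) && est > 0) tau <- est
    }
  }
  c(ca_dia = ca_dia * 1e3, ca_peak = ca_peak * 1e3,
    amp_ratio = ca_peak / ca_dia, ttp = ttp, tau_decay = tau)
}

#' Ca2+-transient features of a simulation result
#' @param result a `mamyo_result` holding one beat
#' @return named feature vector, see [cat_features_window()]
#' @export
cat_features <- function(result) {
  stim_on <- which(result$i_stim != 0)
  stim_t <- if (length(stim_on)) result$t[stim_on[1]] else result$t[1]
  cat_features_window(result$t, result$states[, "Ca_i"], stim_t)
}

#' Recompute every membrane current along a trace
#'
#' @param result a `mamyo_result`
#' @param params model parameters (defaults to those stored in the result)
#' @return matrix (rows = time samples) of currents, fluxes and reversal
#'   potentials as returned by [model_currents()]
#' @export
result_currents <- function(result, params = result$params) {
  n <- nrow(result$states)
  first <- model_currents(result$states[1, ], params, result$i_stim[1])
  out <- matrix(NA_real_, n, length(first),
                dimnames = list(NULL, names(first)))
  out[1, ] <- first
  if (n > 1) for (i in 2:n)
    out[i, ] <- model_currents(result$states[i, ], params, result$i_stim[i])
  out
}

#' Partition of cytosolic Ca2+ removal among SERCA, NCX and PMCA
#'
#' Integrates each cytosol-referenced removal flux over the decay phase of
#' one steady beat (Ca2+-transient peak to the end of the window) and
#' reports each pathway's share of the summed removal. Shares add to 100.
#'
#' @param result a `mamyo_result` holding one steady beat
#' @param params model parameters
#' @return named vector (percent): SERCA, NCX, PMCA
#' @export
ca_removal_partition <- function(result, params = result$params) {
  cur <- result_currents(result, params)
  i_peak <- which.max(result$states[, "Ca_i"])
  idx <- seq(i_peak, length(result$t))
  vol <- compartment_volumes(params)
  conv <- current_to_flux(params[["cm"]], vol[["myo"]])
  dt <- diff(result$t[idx])
  mid <- function(x) (x[-1] + x[-length(x)]) / 2
  f_serca <- pmax(cur[idx, "j_up"], 0)
  f_ncx <- pmax(-cur[idx, "i_ncx"] * conv, 0)        # forward mode extrudes
  f_pmca <- pmax(cur[idx, "i_pmca"] * conv / 2, 0)
  tot <- c(SERCA = sum(mid(f_serca) * dt),
           NCX = sum(mid(f_ncx) * dt),
           PMCA = sum(mid(f_pmca) * dt))
  100 * tot / sum(tot)
}

#' Steady-state rate dependence sweep
#'
#' Paces independently to steady state at each cycle length and extracts
#' action-potential features, Ca2+-transient features and bulk ion
#' concentrations from a final finely sampled beat.
#'
#' @param params model parameters
#' @param cl_list cycle lengths (ms, each >= 80)
#' @param state0 starting state (reused across cycle lengths)
#' @param max_beats per-CL pacing budget
#' @param tol steady-state tolerance, see [pace_to_steady_state()]
#' @return data.frame, one row per cycle length; non-converged rows are
#'   flagged in the `converged` column
#' @export
rate_sweep <- function(params = default_parameters(), cl_list,
                       state0 = default_state(), max_beats = 150,
                       tol = 1e-4) {
  rows <- lapply(cl_list, function(cl) {
    ss <- pace_to_steady_state(params, cl = cl, max_beats = max_beats,
                               tol = tol, state0 = state0)
    res <- integrate_model(ss$state, params, pacing_protocol(cl = cl),
                           t_span = cl, grid = 0.05)
    ap <- ap_features(res)
    ct <- cat_features(res)
    data.frame(cl = cl, converged = ss$converged, n_beats = ss$n_beats,
               t(ap), t(ct),
               Na_i = ss$state[["Na_i"]], K_i = ss$state[["K_i"]],
               Cl_i = ss$state[["Cl_i"]])
  })
  do.call(rbind, rows)
}

#' I-V summary of a voltage-clamp family
#'
#' @param family a `mamyo_clamp_family` from [run_voltage_clamp()]
#' @param mode scalar per step: `"peak"`, `"ss"` (end of step) or `"tail"`
#' @param normalize_at test potential (mV) whose value maps to 1, or `NA`
#'   for raw currents; normalization by a zero current is rejected
#' @return data.frame with `V` (mV) and `I` (pA/pF or normalized)
#' @export
iv_summary <- function(family, mode = c("peak", "ss", "tail"),
                       normalize_at = NA) {
  mode <- match.arg(mode)
  stopifnot(length(family$records) >= 1)
  v <- vapply(family$records, function(r) r$V_step, numeric(1))
  i <- vapply(family$records, function(r)
    switch(mode, peak = r$peak, ss = r$ss, tail = r$tail_peak), numeric(1))
  if (!is.na(normalize_at)) {
    k <- match(normalize_at, v)
    if (is.na(k)) stop("normalize_at = ", normalize_at,
                       " mV is not in the step family")
    if (abs(i[k]) < 1e-12) stop("cannot normalize by a zero current")
    i <- i / abs(i[k])
  }
  data.frame(V = v, I = i)
}
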