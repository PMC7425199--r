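# Declarative experiment engine: pacing trains, voltage-clamp families,
# S1S2 restitution, caffeine dump, ion clamp, drug block.

#' Pacing protocol (stimulus train)
#'
#' Standard stimulus: square pulse of 10 pA/pF (inward) lasting 4 ms,
#' roughly 1.5x the excitation threshold of the model (7 pA/pF diagnostic
#' threshold, see [stimulus_threshold()]).
#'
#' @param cl cycle length (ms)
#' @param n_beats number of stimuli
#' @param stim_amp stimulus amplitude (pA/pF, magnitude)
#' @param stim_dur stimulus duration (ms)
#' @return a `mamyo_protocol`
#' @export
pacing_protocol <- function(cl = 1000, n_beats = 1, stim_amp = 10, stim_dur = 4) {
  stopifnot(cl > stim_dur, n_beats >= 1, stim_amp >= 0, stim_dur > 0)
  structure(list(kind = "pacing", cl = cl, n_beats = n_beats,
                 stim_amp = stim_amp, stim_dur = stim_dur),
            class = "mamyo_protocol")
}

#' Voltage-clamp step-family protocol
#'
#' @param holding holding potential (mV)
#' @param steps test potentials (mV, non-empty)
#' @param step_dur step duration (ms)
#' @param tail tail potential (mV) or `NA` for none
#' @param tail_dur tail duration (ms)
#' @param pre_dur time spent at holding before the step (ms)
#' @return a `mamyo_protocol`
#' @export
vclamp_protocol <- function(holding, steps, step_dur, tail = NA,
                            tail_dur = 500, pre_dur = 50) {
  stopifnot(length(steps) >= 1, step_dur > 0)
  structure(list(kind = "vclamp", holding = holding, steps = steps,
                 step_dur = step_dur, tail = tail, tail_dur = tail_dur,
                 pre_dur = pre_dur),
            class = "mamyo_protocol")
}

#' Caffeine-dump protocol
#'
#' Emulates rapid caffeine application: RyR opening probability is raised
#' 7.5-fold while SERCA and the background Ca2+ current are fully blocked.
#'
#' @param duration exposure duration (ms)
#' @return a `mamyo_protocol`
#' @export
caffeine_protocol <- function(duration = 10000) {
  structure(list(kind = "caffeine", duration = duration),
            class = "mamyo_protocol")
}

#' Ion-clamp protocol modifier
#'
#' Freezes one bulk species at a fixed value: its derivative is forced to
#' zero while every current keeps reading the clamped concentration.
#'
#' @param species one of `"Na_i"`, `"K_i"`, `"Cl_i"`, `"Ca_i"`
#' @param value clamped concentration (mM)
#' @return a modifier usable via [apply_ion_clamp()]
#' @export
clamp_ion <- function(species, value) {
  species <- match.arg(species, c("Na_i", "K_i", "Cl_i", "Ca_i"))
  stopifnot(value > 0)
  structure(list(species = species, value = value), class = "mamyo_ion_clamp")
}

#' Apply an ion clamp to a parameter/state pair
#' @param clamp a `mamyo_ion_clamp`
#' @param params model parameters
#' @param state model state
#' @return list with modified `params` and `state`
#' @export
apply_ion_clamp <- function(clamp, params, state) {
  flag <- c(Na_i = "clamp_nai", K_i = "clamp_ki",
            Cl_i = "clamp_cli", Ca_i = "clamp_cai")[[clamp$species]]
  params[[flag]] <- 1
  state[[clamp$species]] <- clamp$value
  list(params = params, state = state)
}

# Compile a protocol into constant-input integration segments.
#' @keywords internal
protocol_segments <- function(protocol, t_span, params) {
  if (is.null(protocol))
    return(list(list(t0 = 0, t1 = t_span, set = c(stim_amp = 0))))
  switch(protocol$kind,
    pacing = {
      segs <- list()
      t0 <- 0
      for (b in seq_len(protocol$n_beats)) {
        if (t0 >= t_span) break
        t_on <- min(t0 + protocol$stim_dur, t_span)
        segs[[length(segs) + 1]] <-
          list(t0 = t0, t1 = t_on, set = c(stim_amp = -abs(protocol$stim_amp)))
        t_end <- min(t0 + protocol$cl, t_span)
        if (t_end > t_on)
          segs[[length(segs) + 1]] <-
            list(t0 = t_on, t1 = t_end, set = c(stim_amp = 0))
        t0 <- t0 + protocol$cl
      }
      segs
    },
    caffeine = list(list(
      t0 = 0, t1 = t_span,
      set = c(stim_amp = 0, caff_ryr = 7.5, b_serca = 1, b_cab = 1))),
    vclamp = stop("voltage-clamp families are run with run_voltage_clamp()"),
    stop("unknown protocol kind: ", protocol$kind)
  )
}

## ---------------------------------------------------------------------------
## Drug-block registry

.DRUG_REGISTRY <- list(
  "4-AP" = list(
    "50uM"  = c(b_to = 0.16, b_kur = 0.70),
    "100uM" = c(b_to = 0.30, b_kur = 1.00)),
  "E-4031" = list(
    "5uM" = c(b_kr = 1.00)),
  "TEA" = list(
    "5mM" = c(b_ss = 0.55, b_kur = 0.00))
)

#' Map a drug and dose to fractional channel block
#'
#' Closed registry of the literature-derived block percentages: 4-AP at 50
#' uM (16% transient-outward, 70% ultra-rapid block) or 100 uM (30%/100%),
#' E-4031 at 5 uM (full rapid-delayed-rectifier block), TEA at 5 mM (55%
#' steady-state current, no ultra-rapid block). Unknown drug/dose pairs are
#' rejected rather than interpolated.
#'
#' @param drug drug name
#' @param dose dose string, e.g. `"100uM"`, `"5mM"`
#' @return named vector of block fractions (parameter names `b_*`)
#' @export
#' @examples
#' drug_to_block("4-AP", "100uM")
drug_to_block <- function(drug, dose) {
  entry <- .DRUG_REGISTRY[[drug]]
  if (is.null(entry) || is.null(entry[[dose]])) {
    supported <- unlist(lapply(names(.DRUG_REGISTRY), function(d)
      paste0(d, " @ ", names(.DRUG_REGISTRY[[d]]))))
    stop("unregistered drug/dose '", drug, " @ ", dose,
         "'; supported: ", paste(supported, collapse = "; "))
  }
  entry[[dose]]
}

#' Apply a drug block to a parameter vector
#' @param params model parameters
#' @param block named block fractions from [drug_to_block()] or hand-built
#' @return modified parameters
#' @export
apply_block <- function(params, block) {
  stopifnot(all(names(block) %in% names(params)),
            all(startsWith(names(block), "b_")),
            all(block >= 0 & block <= 1))
  params[names(block)] <- block
  params
}

## ---------------------------------------------------------------------------
## Channel-level voltage clamp via matrix-exponential propagation (exact for
## piecewise-constant voltage).

#' Propagate a Markov channel through piecewise-constant voltage phases
#'
#' Exact matrix-exponential propagation of channel occupancy through a
#' sequence of constant-voltage phases, the primitive under every
#' channel-level clamp protocol (including two-pulse availability and
#' recovery experiments).
#'
#' @param spec a `mamyo_markov_spec`
#' @param params model parameters
#' @param phases list of phases, each `list(V = mV, dur = ms, label = chr)`
#' @param p0 starting occupancy (e.g. from [steady_state_distribution()])
#' @param dt output resolution (ms)
#' @param ligands fixed ligand concentrations (mM)
#' @param temp simulation temperature (degC)
#' @return data.frame with `t`, `V`, `phase` and one occupancy column per state
#' @export
markov_clamp_trace <- function(spec, params, phases, p0, dt = 0.25,
                               ligands = list(), temp = NULL) {
  if (is.null(temp)) temp <- params[["temp"]]
  t_acc <- 0
  out <- list()
  occ <- p0
  for (ph in phases) {
    Q <- transition_matrix(spec, ph$V, ligands, temp, params)
    n_sub <- max(1L, ceiling(ph$dur / dt))
    h <- ph$dur / n_sub
    E <- as.matrix(Matrix::expm(Q * h))
    occs <- matrix(NA_real_, n_sub + 1, length(occ))
    occs[1, ] <- occ
    for (i in seq_len(n_sub)) occs[i + 1, ] <- E %*% occs[i, ]
    occ <- occs[n_sub + 1, ]
    out[[length(out) + 1]] <- data.frame(
      t = t_acc + h * (0:n_sub), V = ph$V, phase = ph$label,
      occs, check.names = FALSE)
    t_acc <- t_acc + ph$dur
  }
  df <- do.call(rbind, out)
  names(df)[-(1:3)] <- spec$states
  df
}

#' @keywords internal
markov_clamp_current <- function(spec, df, params, k_i = 140, temp = NULL) {
  if (is.null(temp)) temp <- params[["temp"]]
  o <- df[[names(spec$conducting)[1]]]
  if (identical(spec$erev, "GHK_Ca")) {
    ca <- attr(df, "ca_j")
    if (is.null(ca)) ca <- 1e-4
    g <- spec$g_fn(params, temp)
    g * o * .ghk_ca(df$V, ca, params[["cao"]], temp)
  } else if (identical(spec$erev, "K")) {
    e_k <- nernst(1, k_i, params[["ko"]], temp)
    spec$g_fn(params, temp) * o * (df$V - e_k)
  } else {
    spec$g_fn(params, temp) * o * (df$V - spec$erev)
  }
}

#' Run a voltage-clamp step family
#'
#' For a registered Markov channel the occupancy is propagated exactly
#' (matrix exponential on each constant-voltage phase) from the stationary
#' distribution at the holding potential; for `channel = "x_ss"` the single
#' HH gate is relaxed analytically; for `channel = "cell"` the whole model
#' is integrated with the membrane potential as an exogenous input. Per-step
#' peak, end-of-step and tail-current summaries are extracted.
#'
#' @param channel `"ICaL"`, `"Ito"`, `"IKur"`, `"IKr"`, `"x_ss"`, or `"cell"`
#' @param protocol a [vclamp_protocol()]
#' @param params model parameters
#' @param k_i assumed pipette/cytosolic K+ (mM) for K+-current reversal
#' @param ca_j fixed cleft Ca2+ (mM) seen by the L-type channel under clamp
#' @param dt trace resolution (ms)
#' @param state0 starting state for whole-cell clamp
#' @return a `mamyo_clamp_family`: list of per-step records with `V_step`,
#'   `trace` (t, V, current), `peak`, `ss`, `tail_peak`
#' @export
run_voltage_clamp <- function(channel, protocol, params = default_parameters(),
                              k_i = 140, ca_j = 1e-4, dt = 0.25,
                              state0 = default_state()) {
  stopifnot(inherits(protocol, "mamyo_protocol"), protocol$kind == "vclamp")
  steps <- protocol$steps
  fam <- vector("list", length(steps))
  if (channel == "cell") {
    for (i in seq_along(steps)) {
      fam[[i]] <- .whole_cell_step(protocol, steps[i], params, state0, dt)
    }
  } else if (channel == "x_ss") {
    for (i in seq_along(steps)) {
      fam[[i]] <- .xss_step(protocol, steps[i], params, k_i, dt)
    }
  } else {
    spec <- channel_spec(channel, params)
    ligands <- list(ca_j = ca_j)
    p0 <- steady_state_distribution(spec, protocol$holding, ligands,
                                    params[["temp"]], params)
    for (i in seq_along(steps)) {
      phases <- list(
        list(V = protocol$holding, dur = protocol$pre_dur, label = "hold"),
        list(V = steps[i], dur = protocol$step_dur, label = "step"))
      if (!is.na(protocol$tail))
        phases <- c(phases, list(list(V = protocol$tail,
                                      dur = protocol$tail_dur, label = "tail")))
      df <- markov_clamp_trace(spec, params, phases, p0, dt, ligands)
      attr(df, "ca_j") <- ca_j
      i_tr <- markov_clamp_current(spec, df, params, k_i)
      fam[[i]] <- .clamp_record(steps[i], df$t, df$phase, df$V, i_tr)
    }
  }
  structure(list(channel = channel, protocol = protocol, records = fam),
            class = "mamyo_clamp_family")
}

#' @keywords internal
.clamp_record <- function(v_step, t, phase, V, current) {
  in_step <- phase == "step"
  in_tail <- phase == "tail"
  pk <- if (any(in_step)) current[in_step][which.max(abs(current[in_step]))] else NA
  ss <- if (any(in_step)) current[in_step][sum(in_step)] else NA
  tp <- if (any(in_tail)) current[in_tail][which.max(abs(current[in_tail]))] else NA
  list(V_step = v_step,
       trace = data.frame(t = t, V = V, phase = phase, current = current),
       peak = pk, ss = ss, tail_peak = tp)
}

#' @keywords internal
.xss_step <- function(protocol, v_step, params, k_i, dt) {
  gate <- function(V) xss_gate(V, params)
  e_k <- nernst(1, k_i, params[["ko"]], params[["temp"]])
  relax <- function(x0, V, dur) {
    g <- gate(V)
    tt <- seq(0, dur, by = dt)
    list(t = tt, x = g$inf + (x0 - g$inf) * exp(-tt / g$tau))
  }
  hold <- relax(gate(protocol$holding)$inf, protocol$holding, protocol$pre_dur)
  step <- relax(hold$x[length(hold$x)], v_step, protocol$step_dur)
  t <- c(hold$t, protocol$pre_dur + step$t)
  x <- c(hold$x, step$x)
  V <- c(rep(protocol$holding, length(hold$t)), rep(v_step, length(step$t)))
  phase <- c(rep("hold", length(hold$t)), rep("step", length(step$t)))
  current <- vapply(seq_along(t), function(i)
    iss_current(x[i], V[i], e_k, params), numeric(1))
  .clamp_record(v_step, t, phase, V, current)
}

#' @keywords internal
.whole_cell_step <- function(protocol, v_step, params, state0, dt) {
  p <- params
  p[["vclamp_on"]] <- 1
  y <- state0
  run_phase <- function(y, V, dur) {
    y[["V"]] <- V
    res <- integrate_model(y, p, NULL, t_span = dur, grid = dt)
    res
  }
  r1 <- run_phase(state0, protocol$holding, protocol$pre_dur)
  r2 <- run_phase(r1$final_state, v_step, protocol$step_dur)
  segs <- list(hold = r1, step = r2)
  if (!is.na(protocol$tail))
    segs$tail <- run_phase(r2$final_state, protocol$tail, protocol$tail_dur)
  t <- c(); V <- c(); phase <- c(); current <- c()
  off <- 0
  for (nm in names(segs)) {
    r <- segs[[nm]]
    t <- c(t, off + r$t); off <- off + max(r$t)
    V <- c(V, r$states[, "V"]); phase <- c(phase, rep(nm, length(r$t)))
    current <- c(current, r$i_ion)
  }
  .clamp_record(v_step, t, phase, V, current)
}

## ---------------------------------------------------------------------------

#' Caffeine-induced Ca2+ transient
#'
#' From a steady paced state, applies the caffeine emulation (RyR opening
#' x7.5, SERCA and background Ca2+ current fully blocked) and records the
#' resulting cytosolic Ca2+ transient for fractional-release computation.
#'
#' @param state0 starting state (end-diastolic, from steady 0.5-Hz pacing)
#' @param params model parameters
#' @param duration exposure (ms)
#' @param grid output grid (ms)
#' @return a `mamyo_result`
#' @export
caffeine_transient <- function(state0, params = default_parameters(),
                               duration = 10000, grid = 0.5) {
  integrate_model(state0, params, caffeine_protocol(duration),
                  t_span = duration, grid = grid)
}

#' S1S2 restitution of APD30
#'
#' Paces an S1 train at the basic cycle length, then delivers a single
#' premature S2 stimulus and measures the APD at 30% repolarization of the
#' S2 beat. An S2 that fails the capture criterion (maximal upstroke
#' velocity >= 10 V/s) is flagged with `NA`.
#'
#' @param params model parameters
#' @param s1_cl S1 basic cycle length (ms)
#' @param s2_list S1S2 intervals (ms)
#' @param n_s1 number of S1 beats before each S2 (default 20)
#' @param state0 starting state
#' @return data.frame with `s2` (ms), `apd30` (ms), `captured`
#' @export
s1s2_restitution <- function(params = default_parameters(), s1_cl = 130,
                             s2_list, n_s1 = 20, state0 = default_state()) {
  train <- integrate_model(state0, params,
                           pacing_protocol(cl = s1_cl, n_beats = n_s1),
                           t_span = n_s1 * s1_cl, grid = 0.5)
  base <- train$final_state
  out <- data.frame(s2 = s2_list, apd30 = NA_real_, captured = FALSE)
  for (i in seq_along(s2_list)) {
    s2 <- s2_list[i]
    # last S1 ends the train at a beat boundary; wait the S2 interval then
    # deliver a single stimulus
    res <- integrate_model(base, params, pacing_protocol(cl = s2, n_beats = 2),
                           t_span = s2 + 150, grid = 0.05)
    win <- res$t >= s2
    ap <- tryCatch(
      ap_features_window(res$t[win], res$states[win, "V"], stim_t = s2),
      error = function(e) NULL)
    if (!is.null(ap) && is.finite(ap[["dVdt_max"]]) &&
        ap[["dVdt_max"]] >= 10 && is.finite(ap[["APD30"]])) {
      out$apd30[i] <- ap[["APD30"]]
      out$captured[i] <- TRUE
    }
  }
  out
}

#' Diagnostic: minimal capturing stimulus amplitude
#'
#' Bisects the stimulus amplitude that still evokes an action potential
#' (upstroke >= 10 V/s) with the standard 4-ms pulse.
#'
#' @param params model parameters
#' @param state0 starting state
#' @param lo,hi bracket (pA/pF)
#' @param tol bisection tolerance (pA/pF)
#' @return threshold amplitude (pA/pF)
#' @export
stimulus_threshold <- function(params = default_parameters(),
                               state0 = default_state(), lo = 2, hi = 20,
                               tol = 0.25) {
  fires <- function(a) {
    res <- integrate_model(state0, params,
                           pacing_protocol(cl = 100, n_beats = 1, stim_amp = a),
                           t_span = 60, grid = 0.05)
    max(diff(res$states[, "V"]) / diff(res$t)) >= 10
  }
  if (!fires(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}
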