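# Configuration, serialization and trace export.
#
# Formats: JSON for configuration, state snapshots and trace metadata
# sidecars; CSV for traces. All round-trips are identities.

.CONFIG_KEYS <- c("variant", "temperature", "protocol", "drug", "dose",
                  "block", "solver", "record", "grid", "pka")

#' Read and validate a run configuration
#'
#' JSON keys: `variant` ("RA"/"LA"), `temperature` (degC), `protocol`
#' (object with `kind` and its fields), `drug` + `dose` or explicit `block`
#' (map of `b_*` fractions), `solver` (`rtol`, `atol`), `grid` (ms),
#' `record` (current names), `pka` (map of static phosphorylation
#' fractions). Unknown keys are rejected.
#'
#' @param path JSON file
#' @return validated config list
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.CONFIG_KEYS, collapse = ", "))
  if (!is.null(cfg$variant) &&
      !cfg$variant %in% names(.VARIANT_SCALING))
    stop("config.variant must be RA or LA")
  if (!is.null(cfg$block)) {
    if (!all(startsWith(names(cfg$block), "b_")))
      stop("config.block entries must be named b_<current>")
  }
  cfg
}

#' Build parameters from a configuration
#' @param cfg config list from [read_config()]
#' @return parameter vector
#' @export
config_to_params <- function(cfg) {
  p <- default_parameters()
  if (!is.null(cfg$variant)) p <- make_variant(p, cfg$variant)
  if (!is.null(cfg$temperature)) p[["temp"]] <- cfg$temperature
  if (!is.null(cfg$drug)) {
    if (is.null(cfg$dose)) stop("config.drug requires config.dose")
    p <- apply_block(p, drug_to_block(cfg$drug, cfg$dose))
  }
  if (!is.null(cfg$block)) p <- apply_block(p, unlist(cfg$block))
  if (!is.null(cfg$pka)) p[names(cfg$pka)] <- unlist(cfg$pka)
  p
}

#' Save / load a model-state snapshot (versioned JSON name-value map)
#' @param state model state
#' @param path file path
#' @return (load) a `mamyo_state`
#' @export
write_state <- function(state, path) {
  jsonlite::write_json(
    list(model = "mamyo", revision = as.character(utils::packageVersion("mamyo")),
         state = as.list(unclass(state))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$state)) stop("not a mamyo state snapshot: ", path)
  s <- unlist(obj$state)
  missing <- setdiff(.STATE_NAMES, names(s))
  if (length(missing))
    stop("snapshot lacks state(s): ", paste(missing, collapse = ", "))
  out <- s[.STATE_NAMES]
  class(out) <- "mamyo_state"
  out
}

#' Export a simulation result to CSV with a JSON metadata sidecar
#'
#' Column header: `t_ms,V_mV,<name>_pA_per_pF,...` plus concentration
#' columns in mM; the sidecar (`<path>.json`) records the protocol and
#' solver statistics.
#'
#' @param result a `mamyo_result`
#' @param path CSV path
#' @param record additional current names to recompute and include (e.g.
#'   `c("i_na", "i_k1")`), or `"all"`
#' @return `path`, invisibly
#' @export
write_traces <- function(result, path, record = NULL) {
  df <- data.frame(t_ms = result$t,
                   V_mV = result$states[, "V"],
                   i_CaL_pA_per_pF = result$i_cal,
                   i_ion_pA_per_pF = result$i_ion,
                   i_stim_pA_per_pF = result$i_stim,
                   J_up_mM_per_ms_per_L_cytosol = result$j_up,
                   J_rel_mM_per_ms_per_L_SR = result$j_rel_sr,
                   Na_i_mM = result$states[, "Na_i"],
                   K_i_mM = result$states[, "K_i"],
                   Cl_i_mM = result$states[, "Cl_i"],
                   Ca_i_mM = result$states[, "Ca_i"],
                   Ca_sr_mM = result$states[, "Ca_sr"])
  if (!is.null(record)) {
    cur <- result_currents(result)
    nm <- if (identical(record, "all"))
      grep("^i_", colnames(cur), value = TRUE) else record
    for (x in nm) df[[paste0(sub("^i_", "I", x), "_pA_per_pF")]] <- cur[, x]
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(protocol = if (is.null(result$protocol)) NULL else unclass(result$protocol),
               stats = as.list(result$stats),
               n_samples = length(result$t))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
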