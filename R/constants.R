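# Physical constants and unit conventions.
#
# Units used throughout: V in mV, t in ms, membrane currents in pA/pF,
# concentrations in mM, Ca fluxes cytosol-referenced mM/ms unless a function
# documents SR- or cleft-referencing. All conversions live here.

#' @keywords internal
.FARADAY <- 96485          # C/mol

#' @keywords internal
.RGAS <- 8.314             # J/(mol K)

#' Thermal voltage RT/F in millivolts
#' @param temp_c temperature in degrees Celsius
#' @return RT/F (mV)
#' @keywords internal
rtf_mv <- function(temp_c) 1000 * .RGAS * (temp_c + 273.15) / .FARADAY

#' Current-to-concentration conversion factor
#'
#' Converts a membrane current density (pA/pF) carried by an ion of unit
#' charge into a rate of concentration change (mM/ms) in a compartment.
#' Multiply by current and divide by the carried valence.
#'
#' @param cm_pf membrane capacitance (pF)
#' @param vol_l compartment volume (L)
#' @return factor such that dC/dt (mM/ms) = factor * I (pA/pF) / z
#' @keywords internal
current_to_flux <- function(cm_pf, vol_l) cm_pf * 1e-12 / (.FARADAY * vol_l)
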