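# Left/right atrial variants.
#
# The left-atrial myocyte differs from the right-atrial baseline only in
# two conductances: the ultra-rapid delayed rectifier is 110% larger and the
# inward rectifier 70% larger; all kinetics are shared. Further measured
# left/right density ratios exist for the L-type Ca2+, transient-outward and
# rapid delayed-rectifier currents, but only the two dominant differences
# are applied; the optional multipliers are listed here for reference:
#   # vm_cal = 0.95; vm_to = 0.90; vm_kr = 1.10   (not applied)

.VARIANT_SCALING <- list(
  RA = c(vm_kur = 1.00, vm_k1 = 1.00),
  LA = c(vm_kur = 2.10, vm_k1 = 1.70)
)

#' Build a named atrial variant from the right-atrial baseline
#'
#' @param base right-atrial baseline parameters
#' @param name `"RA"` (identity) or `"LA"` (ultra-rapid K+ conductance
#'   x2.10, inward-rectifier conductance x1.70)
#' @return parameter vector of the variant
#' @export
#' @examples
#' la <- make_variant(default_parameters(), "LA")
#' la[["vm_kur"]]  # 2.10
make_variant <- function(base = default_parameters(), name) {
  sc <- .VARIANT_SCALING[[name]]
  if (is.null(sc))
    stop("unknown variant '", name, "'; known: ",
         paste(names(.VARIANT_SCALING), collapse = ", "))
  base[names(sc)] <- sc
  base
}
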