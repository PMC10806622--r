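#' Construct a point-charge model
#'
#' @param name Model name.
#' @param types data.frame with columns `type`, `charge` (e) and
#'   `multiplicity` (atoms of that type per molecule).
#' @return A [ChargeModel-class].
#' @export
chargeModel <- function(name, types) {
  new("ChargeModel", name = name, types = types)
}

#' @noRd
.tmaTypes <- function(qN, qC, qH) {
  data.frame(type = c("N", "C", "H"), charge = c(qN, qC, qH),
             multiplicity = c(1, 4, 12))
}

#' Charge models of tetramethylammonium and neopentane
#'
#' The force-field charge variants compared in the analysis: full-charge
#' CHARMM (+1), the electronic-continuum-corrected prosECCo scaling (+0.75),
#' three redistributions of the +0.75 charge (low CH dipole, center-N,
#' surface-H), a single-bead +0.75 sphere, and neutral neopentane. All
#' tetrahedral models share the N(CH3)4 stoichiometry (1 central atom, 4 C,
#' 12 H).
#'
#' @return Named list of [ChargeModel-class] objects.
#' @examples
#' sapply(tmaChargeModels(), netCharge)
#' @export
tmaChargeModels <- function() {
  list(
    CHARMM      = chargeModel("CHARMM",        .tmaTypes(-0.60, -0.35, 0.25)),
    prosECCo    = chargeModel("prosECCo",      .tmaTypes(-0.61, -0.35, 0.23)),
    lowCHdipole = chargeModel("low CH dipole", .tmaTypes(-0.05, -0.10, 0.10)),
    centerN     = chargeModel("center-N",      .tmaTypes(0.75, 0.00, 0.00)),
    surfaceH    = chargeModel("surface-H",     .tmaTypes(0.00, 0.00, 0.0625)),
    centerBead  = chargeModel("center-bead",
                              data.frame(type = "bead", charge = 0.75,
                                         multiplicity = 1)),
    neopentane  = chargeModel("neopentane",
                              data.frame(type = c("C_central", "C", "H"),
                                         charge = c(0.00, -0.30, 0.10),
                                         multiplicity = c(1, 4, 12))))
}

#' Net molecular charge (e)
#'
#' Sum over atom types of multiplicity times partial charge.
#'
#' @param model A [ChargeModel-class].
#' @return Net charge in elementary charge units.
#' @examples
#' netCharge(tmaChargeModels()$CHARMM)  # +1
#' @export
netCharge <- function(model) {
  stopifnot(is(model, "ChargeModel"))
  sum(model@types$charge * model@types$multiplicity)
}
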