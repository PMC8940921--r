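## Centralised unit conventions and conversion constants.
##
## Internal convention (all public interfaces use these units):
##   time                 days (d)
##   concentration        micromolar (uM); 1 uM = 1e-3 mol m^-3
##   phycosphere radius   micrometres (um)
##   plate geometry       millimetres (mm)
##   well volume          microlitres (ul)
##   cell density         cells ml^-1
##   diffusivity          m^2 s^-1 (as tabulated in the literature)
##   per-cell rates       fmol cell^-1 d^-1
##   yields               cells per umol of substrate

#' Unit conversion constants
#'
#' Named vector of the conversion constants used throughout the package.
#' All unit handling is funnelled through these values so that the
#' geometry/transport arithmetic is inspectable in one place.
#'
#' @return Named numeric vector.
#' @examples
#' unitConstants()["seconds_per_day"]
#' @export
unitConstants <- function() {
  c(
    seconds_per_day = 86400,
    # mol m^-3 per uM
    mol_m3_per_uM = 1e-3,
    # uM per (fmol ml^-1): 1 fmol/ml = 1e-15 mol / 1e-3 L = 1e-12 M
    uM_per_fmol_per_ml = 1e-6,
    # uM per (umol ml^-1): 1 umol/ml = 1e-3 mol/L
    uM_per_umol_per_ml = 1e3,
    m_per_um = 1e-6,
    m_per_mm = 1e-3,
    m2_per_mm2 = 1e-6,
    m3_per_ul = 1e-9,
    nmol_per_mol = 1e9
  )
}

## Excess concentration (uM) at distance r (um) from a continuous point
## source of strength q (fmol d^-1) in a medium of diffusivity d (m^2 s^-1):
## the 1/(4 pi D r) kernel with unit bookkeeping folded in.
.pointSourceExcess <- function(q_fmol_d, d_m2_s, r_um) {
  u <- unitConstants()
  q_mol_s <- q_fmol_d * 1e-15 / u[["seconds_per_day"]]
  conc_mol_m3 <- q_mol_s / (4 * pi * d_m2_s * r_um * u[["m_per_um"]])
  conc_mol_m3 / u[["mol_m3_per_uM"]]
}

## Wall conductance in nmol d^-1 uM^-1 for a porous wall of effective
## diffusivity d_eff (m^2 s^-1), cross-section area (mm^2), thickness (mm).
.wallConductance <- function(d_eff_m2_s, area_mm2, thickness_mm) {
  u <- unitConstants()
  # J (mol/d per (mol m^-3)) = D * A / L ; convert to nmol/d per uM
  d_eff_m2_s * u[["seconds_per_day"]] *
    area_mm2 * u[["m2_per_mm2"]] / (thickness_mm * u[["m_per_mm"]]) *
    u[["mol_m3_per_uM"]] * u[["nmol_per_mol"]]
}
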