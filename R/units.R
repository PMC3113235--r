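#' Unit conversions for concentrations and rate constants
#'
#' Internally all interstitial concentrations are molecules/um^3 (of available
#' interstitial fluid) and all surface densities molecules/um^2. These helpers
#' convert between those units and the molar units used in the literature
#' tables. 1 M = 6.022e23 molecules/L = 6.022e8 molecules/um^3, so
#' 1 pM = 6.022e-4 molecules/um^3.
#'
#' @name units
NULL

# Avogadro scalings
.AVOGADRO <- 6.022e23
.MOLAR_PER_UM3 <- 6.022e8     # molecules/um^3 in a 1 M solution
.PM_TO_UM3 <- 6.022e-4        # molecules/um^3 per pM

#' @describeIn units picomolar to molecules/um^3.
#' @param pM,nM,x numeric values (vectorised).
#' @export
pM_to_molec_um3 <- function(pM) {
  stopifnot(all(pM >= 0 | is.na(pM)))
  pM * .PM_TO_UM3
}

#' @describeIn units molecules/um^3 to picomolar.
#' @export
molec_um3_to_pM <- function(x) x / .PM_TO_UM3

#' @describeIn units nanomolar to molecules/um^3.
#' @export
nM_to_molec_um3 <- function(nM) pM_to_molec_um3(nM * 1e3)

#' @describeIn units volumetric association rate, M^-1 s^-1 to
#'   (molecules/um^3)^-1 s^-1.
#' @export
kon_molar_to_um3 <- function(x) x / .MOLAR_PER_UM3

#' @describeIn units surface coupling rate, printed units of
#'   1e15 um^2/(mol s), to (molecules/um^2)^-1 s^-1. The scaling is the same
#'   Avogadro factor as for volumetric rates: x * 1e15 / 6.022e23.
#' @export
kc_surface_to_um2 <- function(x) x / .MOLAR_PER_UM3

#' Association rate from dissociation constant
#'
#' Returns `koff / Kd` in M^-1 s^-1, the convention used to set the
#' VEGF-HSPG on-rates from measured equilibrium constants (e.g. koff = 0.01
#' s^-1 and Kd = 165 nM give 6.06e4 M^-1 s^-1). An infinite Kd encodes a
#' non-binding isoform and yields 0.
#'
#' @param koff dissociation rate, s^-1 (>= 0).
#' @param Kd dissociation constant in nM; may be `Inf` for a non-binder.
#' @return on-rate in M^-1 s^-1.
#' @export
#' @examples
#' kon_from_kd(0.01, 165)  # 6.06e4
#' kon_from_kd(0.01, 8.5)  # 1.18e6
kon_from_kd <- function(koff, Kd) {
  if (any(koff < 0)) stop("`koff` must be non-negative", call. = FALSE)
  if (any(Kd <= 0)) stop("`Kd` must be positive (or Inf)", call. = FALSE)
  ifelse(is.infinite(Kd), 0, koff / (Kd * 1e-9))
}

#' Convert a concentration to molecules per cubic micron
#'
#' @param value concentration value.
#' @param unit one of "pM", "nM".
#' @return molecules/um^3.
#' @export
concentration_units <- function(value, unit = c("pM", "nM")) {
  unit <- match.arg(unit)
  if (any(value < 0)) stop("concentrations must be non-negative", call. = FALSE)
  switch(unit, pM = pM_to_molec_um3(value), nM = nM_to_molec_um3(value))
}
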