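#' VEGF isoform kinetic specifications
#'
#' An `isoform_spec` collects every rate constant and binding capability of a
#' (real or hypothetical) VEGF-A splice isoform: HSPG matrix binding, direct
#' receptor binding to VEGFR1/VEGFR2/NRP1, the surface coupling reactions that
#' bridge VEGF-VEGFR2 with NRP1, and binding of short isoforms to the
#' preformed VEGFR1-NRP1 complex. Rates are stored in literature units
#' (volumetric on-rates in M^-1 s^-1, surface coupling rates in
#' 1e15 um^2/(mol s)); they are converted to molecules/um^3 and /um^2 when a
#' scenario is compiled.
#'
#' Canonical isoforms:
#' * `VEGF165`: binds HSPG (Kd 165 nM), VEGFR1, VEGFR2, NRP1; bridges
#'   VEGFR2-NRP1; does not touch the VEGFR1-NRP1 complex.
#' * `VEGF121`: no HSPG or NRP1 binding; binds VEGFR1, VEGFR2 and the
#'   preformed VEGFR1-NRP1 complex.
#' * `VEGF189`: HSPG Kd 8.5 nM; NRP1 on-rate scaled up by the HSPG affinity
#'   ratio (165/8.5); VEGFR2 binding controlled by `allow_V189_R2`.
#' * `VEGF114`: the MMP cleavage product; identical receptor kinetics to
#'   VEGF121, no HSPG binding, not cleavable further.
#'
#' @param name label for the isoform.
#' @param Kd_H HSPG dissociation constant, nM (`Inf` = non-binding).
#' @param koff_H HSPG off-rate, s^-1.
#' @param kon_R1,koff_R1 VEGFR1 binding, M^-1 s^-1 and s^-1.
#' @param kon_R2,koff_R2 VEGFR2 binding (kon_R2 may be 0).
#' @param kon_N1,koff_N1 NRP1 binding (kon_N1 may be 0).
#' @param kc_VR2_N1,kuc_VR2_N1 coupling of the VEGF-VEGFR2 complex to NRP1
#'   (surface rate, 1e15 um^2/(mol s); s^-1).
#' @param kc_VN1_R2,kuc_VN1_R2 coupling of the VEGF-NRP1 complex to VEGFR2.
#' @param kon_R1N1,koff_R1N1 binding of soluble ligand to the preformed
#'   VEGFR1-NRP1 complex (volumetric; 0 for isoforms with HSPG affinity at or
#'   above that of VEGF165).
#' @param kc_VR1_N1,kuc_VR1_N1 coupling of NRP1 to the VEGF-VEGFR1 complex
#'   (surface; same capability gate as `kon_R1N1`).
#' @param cleavable logical; proteolysis converts this isoform to VEGF114.
#' @return an object of class `isoform_spec` (a named list).
#' @export
isoform_spec <- function(name,
                         Kd_H = Inf, koff_H = 0.01,
                         kon_R1 = 3e7, koff_R1 = 1e-3,
                         kon_R2 = 1e7, koff_R2 = 1e-3,
                         kon_N1 = 0, koff_N1 = 1e-3,
                         kc_VR2_N1 = 0, kuc_VR2_N1 = 1e-3,
                         kc_VN1_R2 = 0, kuc_VN1_R2 = 1e-3,
                         kon_R1N1 = 0, koff_R1N1 = 0.01,
                         kc_VR1_N1 = 0, kuc_VR1_N1 = 0.01,
                         cleavable = TRUE) {
  rates <- c(koff_H = koff_H, kon_R1 = kon_R1, koff_R1 = koff_R1,
             kon_R2 = kon_R2, koff_R2 = koff_R2, kon_N1 = kon_N1,
             koff_N1 = koff_N1, kc_VR2_N1 = kc_VR2_N1,
             kc_VN1_R2 = kc_VN1_R2, kon_R1N1 = kon_R1N1,
             kc_VR1_N1 = kc_VR1_N1)
  if (any(rates < 0)) stop("all rate constants must be >= 0", call. = FALSE)
  if (!(Kd_H > 0)) stop("`Kd_H` must be positive (or Inf)", call. = FALSE)
  structure(list(
    name = name,
    Kd_H = Kd_H, koff_H = koff_H, kon_H = kon_from_kd(koff_H, Kd_H),
    kon_R1 = kon_R1, koff_R1 = koff_R1,
    kon_R2 = kon_R2, koff_R2 = koff_R2,
    kon_N1 = kon_N1, koff_N1 = koff_N1,
    kc_VR2_N1 = kc_VR2_N1, kuc_VR2_N1 = kuc_VR2_N1,
    kc_VN1_R2 = kc_VN1_R2, kuc_VN1_R2 = kuc_VN1_R2,
    kon_R1N1 = kon_R1N1, koff_R1N1 = koff_R1N1,
    kc_VR1_N1 = kc_VR1_N1, kuc_VR1_N1 = kuc_VR1_N1,
    cleavable = isTRUE(cleavable)
  ), class = "isoform_spec")
}

#' Canonical VEGF isoform table
#'
#' @param name one of "VEGF121", "VEGF165", "VEGF189", "VEGF114".
#' @param allow_V189_R2 should intact VEGF189 bind VEGFR2 with VEGF165
#'   kinetics? Whether the intact long isoform can engage VEGFR2 at all is
#'   experimentally uncertain; the default allows it.
#' @return an `isoform_spec`.
#' @export
canonical_isoform <- function(name = c("VEGF165", "VEGF121", "VEGF189", "VEGF114"),
                              allow_V189_R2 = TRUE) {
  name <- match.arg(name)
  switch(name,
    VEGF165 = isoform_spec("VEGF165", Kd_H = 165,
                           kon_N1 = 3.2e6, kc_VR2_N1 = 3.1e6, kc_VN1_R2 = 1e7,
                           cleavable = TRUE),
    VEGF189 = isoform_spec("VEGF189", Kd_H = 8.5,
                           kon_R2 = if (allow_V189_R2) 1e7 else 0,
                           kon_N1 = 3.2e6 * (165 / 8.5),
                           kc_VR2_N1 = 3.1e6 * (165 / 8.5), kc_VN1_R2 = 1e7,
                           cleavable = TRUE),
    VEGF121 = isoform_spec("VEGF121", Kd_H = Inf,
                           kon_R1N1 = 1e7, kc_VR1_N1 = 1e7,
                           cleavable = TRUE),
    VEGF114 = isoform_spec("VEGF114", Kd_H = Inf,
                           kon_R1N1 = 1e7, kc_VR1_N1 = 1e7,
                           cleavable = FALSE)
  )
}

#' Hypothetical isoform on the HSPG-affinity continuum
#'
#' Generates an isoform with intermediate properties by smoothly varying the
#' isoform-specific parameters with HSPG affinity, anchored at VEGF165:
#'
#' * NRP1 on-rate: `kon_N1 = kon_N1(165) * (165 / Kd_H)`, and the
#'   VEGF-VEGFR2 to NRP1 coupling rate is scaled by the same factor so the
#'   thermodynamic cycle stays consistent.
#' * VEGFR1-NRP1 complex binding (both the volumetric binding of soluble
#'   ligand to the preformed complex and the coupling of NRP1 onto the
#'   VEGF-VEGFR1 complex): forward rates are
#'   `k_forward * (Kd_H - 165)/165` for `Kd_H > 165`, clamped at
#'   `k_forward` so the non-binding limit (`Kd_H = Inf`) recovers the full
#'   VEGF121 rate of 1e7; reverse rates unchanged. Isoforms with HSPG
#'   affinity at or above VEGF165's have no VEGFR1-NRP1 interaction.
#' * HSPG on-rate from `kon_from_kd(koff_H, Kd_H)`.
#'
#' The three canonical isoforms are recovered exactly at their Kd values
#' (`165`, `8.5`, `Inf`).
#'
#' @param Kd_H HSPG dissociation constant in nM, in (0, Inf].
#' @param reference the canonical VEGF165 spec to anchor the scaling.
#' @param allow_V189_R2 passed through for high-affinity isoforms (controls
#'   whether kon_R2 stays at the VEGF165 value).
#' @return an `isoform_spec`.
#' @export
make_continuum_isoform <- function(Kd_H, reference = canonical_isoform("VEGF165"),
                                   allow_V189_R2 = TRUE) {
  if (!(Kd_H > 0)) stop("`Kd_H` must be positive (or Inf)", call. = FALSE)
  f <- if (is.infinite(Kd_H)) 0 else 165 / Kd_H
  m <- if (is.infinite(Kd_H)) 1 else max(0, min(1, (Kd_H - 165) / 165))
  isoform_spec(
    name = sprintf("VEGF(Kd=%s nM)", format(Kd_H)),
    Kd_H = Kd_H, koff_H = reference$koff_H,
    kon_R1 = reference$kon_R1, koff_R1 = reference$koff_R1,
    kon_R2 = if (!allow_V189_R2 && Kd_H < 165) 0 else reference$kon_R2,
    koff_R2 = reference$koff_R2,
    kon_N1 = reference$kon_N1 * f, koff_N1 = reference$koff_N1,
    kc_VR2_N1 = reference$kc_VR2_N1 * f, kuc_VR2_N1 = reference$kuc_VR2_N1,
    kc_VN1_R2 = if (f > 0) reference$kc_VN1_R2 else 0,
    kuc_VN1_R2 = reference$kuc_VN1_R2,
    kon_R1N1 = 1e7 * m, koff_R1N1 = 0.01,
    kc_VR1_N1 = 1e7 * m, kuc_VR1_N1 = 0.01,
    cleavable = TRUE
  )
}

#' @export
print.isoform_spec <- function(x, ...) {
  cat(sprintf("<isoform_spec> %s\n", x$name))
  cat(sprintf("  HSPG: Kd = %s nM (kon %.3g M-1s-1, koff %.3g s-1)\n",
              format(x$Kd_H), x$kon_H, x$koff_H))
  cat(sprintf("  R1: kon %.3g  R2: kon %.3g  N1: kon %.3g\n",
              x$kon_R1, x$kon_R2, x$kon_N1))
  cat(sprintf("  R1N1-complex binding: kon %.3g (volumetric), kc %.3g (surface)\n",
              x$kon_R1N1, x$kc_VR1_N1))
  cat(sprintf("  cleavable: %s\n", x$cleavable))
  invisible(x)
}
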