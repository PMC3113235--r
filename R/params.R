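#' Model parameter groups
#'
#' Constructors for the parameter blocks that make up a scenario: domain
#' geometry, transport, receptor population, interstitial reaction rates, and
#' the boundary drive. Defaults are the base-model values (tissue cylinder
#' 160 um long and 50 um in radius around a 2 um sprout; D = 68.6 um^2/s;
#' K_ECM = 0.85; HSPG 750 nM; 1e4 VEGFR1 and VEGFR2 and 3e4 NRP1 per 515 um^2
#' tip cell; V0 = 1 pM with a 5%/40 um gradient).
#'
#' @name model_params
NULL

#' @describeIn model_params domain geometry (um).
#' @param L_half half-length of the domain; z spans \[-L, +L\].
#' @param R_edge outer radius of the tissue cylinder.
#' @param R_sprout sprout radius.
#' @param L_tip axial extent of the tip cell (gradient sensing length).
#' @param tip_area tip-cell surface area used to normalise receptor densities.
#' @export
geometry_params <- function(L_half = 80, R_edge = 50, R_sprout = 2,
                            L_tip = 40, tip_area = 515) {
  stopifnot(R_sprout < R_edge, L_tip <= L_half, tip_area > 0, L_half > 0)
  structure(list(L_half = L_half, R_edge = R_edge, R_sprout = R_sprout,
                 L_tip = L_tip, tip_area = tip_area),
            class = "geometry_params")
}

#' @describeIn model_params interstitial transport.
#' @param D effective diffusivity of the soluble species in the matrix,
#'   um^2/s (shared by all isoforms).
#' @param K_ECM available volume fraction of the ECM, in (0, 1\].
#' @export
transport_params <- function(D = 68.6, K_ECM = 0.85) {
  stopifnot(D > 0, K_ECM > 0, K_ECM <= 1)
  structure(list(D = D, K_ECM = K_ECM), class = "transport_params")
}

#' @describeIn model_params sprout receptor population. Totals are molecules
#'   per `tip_area` of sprout surface; insertion of each unligated receptor
#'   balances internalisation (`s_R = k_int * total`), keeping surface totals
#'   constant.
#' @param R1_total,R2_total,N1_total receptor totals per tip-cell area.
#' @param k_int internalisation rate, s^-1 (all surface species).
#' @param kc_R1N1,kuc_R1N1 VEGFR1-NRP1 coupling and uncoupling (surface rate
#'   in 1e15 um^2/(mol s); s^-1).
#' @export
receptor_params <- function(R1_total = 1e4, R2_total = 1e4, N1_total = 3e4,
                            k_int = 2.8e-4, kc_R1N1 = 1e7, kuc_R1N1 = 0.01) {
  stopifnot(R1_total >= 0, R2_total >= 0, N1_total >= 0, k_int >= 0)
  structure(list(R1_total = R1_total, R2_total = R2_total,
                 N1_total = N1_total, k_int = k_int,
                 kc_R1N1 = kc_R1N1, kuc_R1N1 = kuc_R1N1),
            class = "receptor_params")
}

#' @describeIn model_params interstitial HSPG density and reaction rates.
#' @param H_total_ref HSPG binding-site density at z = 0, nM.
#' @param gH0 fractional HSPG gradient per 40 um (0 unless the HSPG-gradient
#'   variant; the density increases toward the secretion face).
#' @param k_P first-order proteolysis rate, s^-1 (acts on soluble and bound
#'   full-length VEGF, producing VEGF114).
#' @param k_deg_V first-order degradation of the soluble secreted isoform.
#' @param k_deg_VH first-order degradation of matrix-bound VEGF.
#' @export
interstitial_params <- function(H_total_ref = 750, gH0 = 0, k_P = 0,
                                k_deg_V = 0, k_deg_VH = 0) {
  stopifnot(H_total_ref >= 0, k_P >= 0, k_deg_V >= 0, k_deg_VH >= 0)
  structure(list(H_total_ref = H_total_ref, gH0 = gH0, k_P = k_P,
                 k_deg_V = k_deg_V, k_deg_VH = k_deg_VH),
            class = "interstitial_params")
}

#' @describeIn model_params boundary drive: either target Dirichlet values
#'   (`V0`, `g0`) for the calibration stage, or calibrated Neumann fluxes
#'   (`q`, `k_clear`) for production runs. Secretion of the full-length
#'   isoform occurs at z = +L; first-order clearance of all soluble species
#'   at z = -L.
#' @param V0 target mean soluble VEGF at z = 0, pM.
#' @param g0 fractional VEGF gradient per 40 um (over the domain).
#' @param q secretion flux at z = +L, molecules/(um^2 s); `NA` until
#'   calibrated.
#' @param k_clear clearance velocity at z = -L, um/s; `NA` until calibrated.
#' @param mode `"neumann_stage"` (q/k_clear drive) or `"dirichlet_stage"`.
#' @export
boundary_drive <- function(V0 = 1, g0 = 0.05, q = NA_real_,
                           k_clear = NA_real_,
                           mode = c("neumann_stage", "dirichlet_stage")) {
  stopifnot(V0 > 0)
  mode <- match.arg(mode)
  structure(list(V0 = V0, g0 = g0, q = q, k_clear = k_clear, mode = mode),
            class = "boundary_drive")
}

#' Assemble a full scenario configuration
#'
#' A scenario fully determines a steady-state run: geometry, transport, the
#' secreted isoform and its cleavage product, the receptor population (or
#' `NULL` for a sprout-free / receptor-free tissue), interstitial parameters,
#' the boundary drive, and the model variant. The variant fixes the
#' degradation switches:
#'
#' * `hspg_only`: reversible HSPG binding only (no degradation).
#' * `hspg_gradient`: as above with a patterned HSPG density
#'   (30%/40 um by default).
#' * `soluble_deg`: soluble secreted VEGF degraded at `k_deg`; matrix-bound
#'   VEGF protected.
#' * `matrix_deg`: both soluble and matrix-bound VEGF degraded
#'   (isoform-specific degradation via matrix residence time).
#'
#' The cleaved product (VEGF114) has no HSPG or NRP1 binding and is not
#' degraded by `k_deg` (it escapes the HSPG/NRP1-mediated degradation
#' pathway); it is removed only by boundary clearance and receptor capture.
#'
#' @param isoform the secreted isoform (`isoform_spec` or canonical name).
#' @param variant model variant, see Details.
#' @param receptors `receptor_params()` or `NULL` for no receptors/sprout
#'   uptake (the sprout geometry remains unless `sprout = FALSE`).
#' @param geometry,transport,interstitial,drive parameter blocks.
#' @param cleaved_isoform kinetics of the cleavage product.
#' @param k_P proteolysis rate, s^-1.
#' @param k_deg degradation rate used by the degradation variants, s^-1.
#' @param gH0 HSPG gradient used by `hspg_gradient`.
#' @param sprout logical; include the sprout geometry (patches exist only if
#'   receptors are present; `sprout = FALSE` removes the excluded cylinder
#'   entirely, for radially-uniform reference solutions).
#' @param allow_V189_R2 whether intact VEGF189 binds VEGFR2.
#' @param label optional run label.
#' @return object of class `vegf_scenario`.
#' @export
scenario_config <- function(isoform = "VEGF165",
                            variant = c("hspg_only", "hspg_gradient",
                                        "soluble_deg", "matrix_deg"),
                            receptors = NULL,
                            geometry = geometry_params(),
                            transport = transport_params(),
                            interstitial = NULL,
                            drive = boundary_drive(),
                            cleaved_isoform = canonical_isoform("VEGF114"),
                            k_P = 0, k_deg = 1e-3, gH0 = 0.30,
                            sprout = TRUE,
                            allow_V189_R2 = TRUE,
                            label = NULL) {
  variant <- match.arg(variant)
  if (is.character(isoform)) {
    isoform <- canonical_isoform(isoform, allow_V189_R2 = allow_V189_R2)
  }
  stopifnot(inherits(isoform, "isoform_spec"),
            inherits(cleaved_isoform, "isoform_spec"))
  if (is.finite(cleaved_isoform$Kd_H) || cleaved_isoform$kon_N1 > 0 ||
      cleaved_isoform$cleavable)
    stop("`cleaved_isoform` must be non-HSPG-binding, non-NRP1-binding and ",
         "not further cleavable", call. = FALSE)
  if (is.null(interstitial)) {
    interstitial <- interstitial_params(
      H_total_ref = 750,
      gH0 = if (variant == "hspg_gradient") gH0 else 0,
      k_P = k_P,
      k_deg_V = if (variant %in% c("soluble_deg", "matrix_deg")) k_deg else 0,
      k_deg_VH = if (variant == "matrix_deg") k_deg else 0
    )
  }
  cfg <- structure(list(
    geometry = geometry, transport = transport,
    isoform = isoform, cleaved_isoform = cleaved_isoform,
    receptors = receptors, interstitial = interstitial, drive = drive,
    variant = variant, sprout = isTRUE(sprout),
    allow_V189_R2 = isTRUE(allow_V189_R2),
    label = label %||% sprintf("%s/%s", isoform$name, variant)
  ), class = "vegf_scenario")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks parameter-block classes, invariants and variant consistency;
#' returns the config invisibly or throws with a message listing every
#' problem found.
#'
#' @param cfg a `vegf_scenario`.
#' @export
validate_scenario <- function(cfg) {
  problems <- character()
  need <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  need(inherits(cfg, "vegf_scenario"), "not a vegf_scenario object")
  for (fld in c("geometry", "transport", "isoform", "cleaved_isoform",
                "interstitial", "drive", "variant")) {
    need(!is.null(cfg[[fld]]), sprintf("missing field `%s`", fld))
  }
  if (length(problems) == 0L) {
    g <- cfg$geometry
    need(g$R_sprout < g$R_edge, "R_sprout must be < R_edge")
    need(g$L_tip <= g$L_half, "L_tip must be <= the sprout z-extent")
    need(cfg$transport$D > 0, "D must be > 0")
    need(cfg$transport$K_ECM > 0 && cfg$transport$K_ECM <= 1,
         "K_ECM must be in (0, 1]")
    iv <- cfg$interstitial
    need(all(c(iv$H_total_ref, iv$k_P, iv$k_deg_V, iv$k_deg_VH) >= 0),
         "interstitial rates must be >= 0")
    if (cfg$variant == "hspg_only") need(iv$k_deg_V == 0 && iv$k_deg_VH == 0,
      "hspg_only variant must have no degradation")
    if (cfg$variant == "soluble_deg") need(iv$k_deg_VH == 0,
      "soluble_deg variant protects matrix-bound VEGF")
    if (cfg$variant != "hspg_gradient") need(iv$gH0 == 0,
      "HSPG gradient requires the hspg_gradient variant")
    need(cfg$drive$V0 > 0, "V0 must be > 0")
    if (!is.null(cfg$receptors)) {
      need(inherits(cfg$receptors, "receptor_params"),
           "`receptors` must be receptor_params() or NULL")
      need(cfg$sprout, "receptors require the sprout geometry")
    }
  }
  if (length(problems)) {
    stop("invalid scenario:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.vegf_scenario <- function(x, ...) {
  cat(sprintf("<vegf_scenario> %s\n", x$label))
  cat(sprintf("  variant: %s | isoform: %s | receptors: %s | sprout: %s\n",
              x$variant, x$isoform$name,
              if (is.null(x$receptors)) "none" else "yes", x$sprout))
  cat(sprintf("  drive: mode=%s V0=%g pM g0=%g q=%s k_clear=%s\n",
              x$drive$mode, x$drive$V0, x$drive$g0,
              format(x$drive$q, digits = 3),
              format(x$drive$k_clear, digits = 3)))
  cat(sprintf("  interstitial: H=%g nM gH0=%g k_P=%g k_deg_V=%g k_deg_VH=%g\n",
              x$interstitial$H_total_ref, x$interstitial$gH0,
              x$interstitial$k_P, x$interstitial$k_deg_V,
              x$interstitial$k_deg_VH))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
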