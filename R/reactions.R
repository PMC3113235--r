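#' Compile a scenario to internal simulation units
#'
#' Converts every literature-unit rate in a scenario to the internal bases
#' (molecules/um^3 for interstitial species, molecules/um^2 for surface
#' species, seconds for time) and precomputes the per-cell HSPG site density
#' profile and the per-patch receptor ingredients. All solver and metric
#' code works from the compiled form.
#'
#' @param cfg a `vegf_scenario`.
#' @param grid a `vegf_grid` (defaults to the standard mesh for the
#'   scenario's geometry).
#' @return a list of class `vegf_compiled`.
#' @keywords internal
compile_scenario <- function(cfg, grid = NULL) {
  validate_scenario(cfg)
  if (is.null(grid)) grid <- build_grid(cfg$geometry, sprout = cfg$sprout)
  iv <- cfg$interstitial

  # HSPG site density per active cell, molecules/um^3 of available fluid;
  # optional linear gradient anchored at z = 0, increasing toward secretion
  zc_cell <- grid$zc[grid$idx[, 1]]
  Htot <- nM_to_molec_um3(iv$H_total_ref) * (1 + iv$gH0 * zc_cell / 40)
  Htot <- pmax(Htot, 0)

  lig <- function(s) list(
    name = s$name,
    kon_H = kon_molar_to_um3(s$kon_H), koff_H = s$koff_H,
    Kd_H = s$Kd_H,
    kon_R1 = kon_molar_to_um3(s$kon_R1), koff_R1 = s$koff_R1,
    kon_R2 = kon_molar_to_um3(s$kon_R2), koff_R2 = s$koff_R2,
    kon_N1 = kon_molar_to_um3(s$kon_N1), koff_N1 = s$koff_N1,
    kc_VR2_N1 = kc_surface_to_um2(s$kc_VR2_N1), kuc_VR2_N1 = s$kuc_VR2_N1,
    kc_VN1_R2 = kc_surface_to_um2(s$kc_VN1_R2), kuc_VN1_R2 = s$kuc_VN1_R2,
    kon_R1N1 = kon_molar_to_um3(s$kon_R1N1), koff_R1N1 = s$koff_R1N1,
    kc_VR1_N1 = kc_surface_to_um2(s$kc_VR1_N1), kuc_VR1_N1 = s$kuc_VR1_N1,
    cleavable = s$cleavable
  )

  rec <- NULL
  if (!is.null(cfg$receptors)) {
    r <- cfg$receptors
    ta <- cfg$geometry$tip_area
    rec <- list(
      R1T = r$R1_total / ta, R2T = r$R2_total / ta, N1T = r$N1_total / ta,
      k_int = r$k_int,
      kc_R1N1 = kc_surface_to_um2(r$kc_R1N1), kuc_R1N1 = r$kuc_R1N1
    )
  }

  structure(list(
    cfg = cfg, grid = grid,
    K_ECM = cfg$transport$K_ECM, D = cfg$transport$D,
    kon_H = kon_molar_to_um3(cfg$isoform$kon_H),
    koff_H = cfg$isoform$koff_H,
    k_P = iv$k_P, k_deg_V = iv$k_deg_V, k_deg_VH = iv$k_deg_VH,
    Htot = Htot,
    full = lig(cfg$isoform), clv = lig(cfg$cleaved_isoform),
    rec = rec,
    V0 = pM_to_molec_um3(cfg$drive$V0),
    g0 = cfg$drive$g0,
    q = cfg$drive$q, k_clear = cfg$drive$k_clear
  ), class = "vegf_compiled")
}

# Surface species layout: 4 receptor states then one 5-block per ligand.
.SURF_SPECIES <- c("R1", "R2", "N1", "R1N1",
                   "V.R1", "V.R2", "V.N1", "V.R2.N1", "V.R1N1",
                   "Vc.R1", "Vc.R2", "Vc.N1", "Vc.R2.N1", "Vc.R1N1")

#' Surface receptor network rates
#'
#' Time derivatives of every sprout-surface species for one or more patches,
#' given the local soluble concentrations. The network comprises: ligand
#' binding to VEGFR1, VEGFR2 and NRP1; bridging `V.R2 + N1 <-> V.R2.N1` and
#' `V.N1 + R2 <-> V.R2.N1`; empty-receptor coupling `R1 + N1 <-> R1N1`;
#' binding of short (non-NRP1-binding) ligands to the preformed R1N1 complex
#' from solution and coupling of N1 onto their `V.R1` complex;
#' internalisation of every species at `k_int`; and insertion of unligated
#' receptors at `s_R = k_int * total`. Receptors do not diffuse along the
#' surface.
#'
#' @param Y numeric matrix `[n_patch, 14]` of surface densities
#'   (molecules/um^2), columns in the order of `vegfgrad:::.SURF_SPECIES`.
#' @param Vloc matrix `[n_patch, 2]` of local soluble full-length and
#'   cleaved VEGF (molecules/um^3).
#' @param comp a compiled scenario (`vegfgrad:::compile_scenario`).
#' @return list with `dY` (same shape as `Y`), `bind` (net solution-to-
#'   surface binding flux per ligand, molecules/um^2/s, positive = uptake)
#'   and `internalised` (ligand internalisation flux per ligand).
#' @export
surface_rates <- function(Y, Vloc, comp) {
  rec <- comp$rec
  if (is.null(rec)) stop("scenario has no receptors", call. = FALSE)
  Y <- matrix(Y, ncol = 14L)
  Vloc <- matrix(Vloc, ncol = 2L)
  kint <- rec$k_int
  R1 <- Y[, 1]; R2 <- Y[, 2]; N1 <- Y[, 3]; R1N1 <- Y[, 4]
  dY <- matrix(0, nrow(Y), 14L)
  bind <- matrix(0, nrow(Y), 2L)
  intern <- matrix(0, nrow(Y), 2L)

  # receptor insertion/internalisation and empty R1-N1 coupling
  cpl <- rec$kc_R1N1 * R1 * N1 - rec$kuc_R1N1 * R1N1
  dY[, 1] <- kint * (rec$R1T - R1) - cpl
  dY[, 2] <- kint * (rec$R2T - R2)
  dY[, 3] <- kint * (rec$N1T - N1) - cpl
  dY[, 4] <- cpl - kint * R1N1

  for (li in 1:2) {
    s <- if (li == 1L) comp$full else comp$clv
    V <- Vloc[, li]
    off <- 4L + (li - 1L) * 5L
    lR1 <- Y[, off + 1L]; lR2 <- Y[, off + 2L]; lN1 <- Y[, off + 3L]
    lR2N1 <- Y[, off + 4L]; lR1N1 <- Y[, off + 5L]

    b_R1 <- s$kon_R1 * V * R1 - s$koff_R1 * lR1
    b_R2 <- s$kon_R2 * V * R2 - s$koff_R2 * lR2
    b_N1 <- s$kon_N1 * V * N1 - s$koff_N1 * lN1
    b_R1N1 <- s$kon_R1N1 * V * R1N1 - s$koff_R1N1 * lR1N1
    c_VR2_N1 <- s$kc_VR2_N1 * lR2 * N1 - s$kuc_VR2_N1 * lR2N1
    c_VN1_R2 <- s$kc_VN1_R2 * lN1 * R2 - s$kuc_VN1_R2 * lR2N1
    c_VR1_N1 <- s$kc_VR1_N1 * lR1 * N1 - s$kuc_VR1_N1 * lR1N1

    dY[, 1] <- dY[, 1] - b_R1
    dY[, 2] <- dY[, 2] - b_R2 - c_VN1_R2
    dY[, 3] <- dY[, 3] - b_N1 - c_VR2_N1 - c_VR1_N1
    dY[, 4] <- dY[, 4] - b_R1N1
    dY[, off + 1L] <- b_R1 - c_VR1_N1 - kint * lR1
    dY[, off + 2L] <- b_R2 - c_VR2_N1 - kint * lR2
    dY[, off + 3L] <- b_N1 - c_VN1_R2 - kint * lN1
    dY[, off + 4L] <- c_VR2_N1 + c_VN1_R2 - kint * lR2N1
    dY[, off + 5L] <- b_R1N1 + c_VR1_N1 - kint * lR1N1

    bind[, li] <- b_R1 + b_R2 + b_N1 + b_R1N1
    intern[, li] <- kint * (lR1 + lR2 + lN1 + lR2N1 + lR1N1)
  }
  colnames(dY) <- .SURF_SPECIES
  list(dY = dY, bind = bind, internalised = intern)
}

#' Linearised surface-uptake ingredients for the interstitial solve
#'
#' For the implicit treatment of the boundary coupling, the net binding flux
#' for ligand l is split as `lambda_l * V_l - sigma_l` with
#' `lambda_l = sum(kon_x * X)` over free receptor states X and
#' `sigma_l = sum(koff_x * lX)` over its complexes, both evaluated at the
#' current surface state.
#'
#' @keywords internal
surface_uptake_coefs <- function(Y, comp) {
  rec <- comp$rec
  Y <- matrix(Y, ncol = 14L)
  lam <- sig <- matrix(0, nrow(Y), 2L)
  for (li in 1:2) {
    s <- if (li == 1L) comp$full else comp$clv
    off <- 4L + (li - 1L) * 5L
    lam[, li] <- s$kon_R1 * Y[, 1] + s$kon_R2 * Y[, 2] +
      s$kon_N1 * Y[, 3] + s$kon_R1N1 * Y[, 4]
    sig[, li] <- s$koff_R1 * Y[, off + 1L] + s$koff_R2 * Y[, off + 2L] +
      s$koff_N1 * Y[, off + 3L] + s$koff_R1N1 * Y[, off + 5L]
  }
  list(lambda = lam, sigma = sig)
}

#' Interstitial reaction source terms
#'
#' Evaluates the volumetric reaction rates of the mass balances for the four
#' interstitial species at a given state: full-length soluble VEGF `V`
#' (HSPG on/off exchange, proteolysis, degradation), matrix-bound `VH`
#' (exchange, proteolysis, degradation; immobile), cleaved soluble `Vc`
#' (produced by proteolysis of both `V` and `VH`; not HSPG-binding, not
#' further cleaved, not degraded), and free HSPG sites `H = Htot - VH`
#' (destroyed `VH` returns its site, so `H + VH` is conserved). The
#' C-terminal cleavage fragment is not tracked (HSPGs are far from
#' saturation).
#'
#' @param state list with numeric vectors `V`, `Vc`, `VH` over active cells
#'   (molecules/um^3).
#' @param comp compiled scenario.
#' @return list of rate vectors `dV`, `dVc`, `dVH`, `dH` (s^-1 units) and a
#'   `fluxes` tibble of domain-integrated channel tallies (molecules/s).
#' @export
interstitial_rates <- function(state, comp) {
  V <- state$V; Vc <- state$Vc; VH <- state$VH
  if (any(!is.finite(c(V, Vc, VH)))) {
    bad <- which(!is.finite(V) | !is.finite(Vc) | !is.finite(VH))[1]
    stop(sprintf("non-finite concentration at cell %d", bad), call. = FALSE)
  }
  if (any(c(V, Vc, VH) < 0)) {
    warning("negative concentrations flagged in interstitial state")
  }
  H <- comp$Htot - VH
  on <- comp$kon_H * V * H
  off <- comp$koff_H * VH
  dV <- -on + off - (comp$k_P + comp$k_deg_V) * V
  dVH <- on - off - (comp$k_P + comp$k_deg_VH) * VH
  dVc <- comp$k_P * (V + VH)
  dH <- -dVH
  w <- comp$K_ECM * comp$grid$vol[comp$grid$idx]  # available volume per cell
  fluxes <- tibble::tibble(
    channel = c("hspg_on", "hspg_off", "proteolysis_V", "proteolysis_VH",
                "degradation_V", "degradation_VH"),
    rate = c(sum(on * w), sum(off * w), sum(comp$k_P * V * w),
             sum(comp$k_P * VH * w), sum(comp$k_deg_V * V * w),
             sum(comp$k_deg_VH * VH * w))
  )
  list(dV = dV, dVc = dVc, dVH = dVH, dH = dH, fluxes = fluxes)
}

#' Map surface reaction fluxes onto adjacent interstitial cells
#'
#' Heterogeneous reactions at the sprout surface are approximated as
#' homogeneous sinks in the adjacent control volumes: a net per-area binding
#' rate `J` on a patch of area `A` removes `J * A / (K_ECM * Vol)` per
#' second from the adjacent cell's concentration.
#'
#' @param grid a `vegf_grid` with sprout patches.
#' @param bind matrix `[n_patch, 2]` of net binding fluxes
#'   (molecules/um^2/s) from [surface_rates()].
#' @param comp compiled scenario.
#' @return matrix `[n_active_cells, 2]` of volumetric sink rates
#'   (molecules/um^3/s), nonzero only beside the sprout.
#' @export
surface_flux_coupling <- function(grid, bind, comp) {
  p <- grid$patches
  if (is.null(p)) stop("grid has no sprout patches", call. = FALSE)
  cells <- grid$id[cbind(p$iz, p$adj_ir)]
  if (anyNA(cells)) stop("patch without adjacent cell: grid construction bug")
  out <- matrix(0, grid$n_active, 2L)
  w <- p$area / (comp$K_ECM * grid$vol[cbind(p$iz, p$adj_ir)])
  out[cells, ] <- matrix(bind, ncol = 2L) * w
  out
}

#' Ligand-free steady state of the surface network
#'
#' With no VEGF anywhere the unligated receptors settle at their totals,
#' partitioned between free R1/N1 and the coupled R1N1 complex by the
#' coupling/uncoupling/internalisation balance. Used as the surface initial
#' condition.
#'
#' @keywords internal
surface_rest_state <- function(comp, n_patch) {
  rec <- comp$rec
  # solve kc x y = (kuc + kint) C, x + C = R1T, y + C = N1T for C
  kc <- rec$kc_R1N1; ku <- rec$kuc_R1N1 + rec$k_int
  a <- kc
  b <- -(kc * (rec$R1T + rec$N1T) + ku)
  cc <- kc * rec$R1T * rec$N1T
  C <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  Y <- matrix(0, n_patch, 14L)
  Y[, 1] <- rec$R1T - C
  Y[, 2] <- rec$R2T
  Y[, 3] <- rec$N1T - C
  Y[, 4] <- C
  colnames(Y) <- .SURF_SPECIES
  Y
}
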