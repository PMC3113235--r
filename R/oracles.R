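#' Independent reduced-dimension oracles
#'
#' Closed-form and dense one-dimensional solutions of the steady transport
#' equations, used to verify the finite-volume solver. At steady state,
#' equilibrium matrix binding retards transport without changing the soluble
#' profile shape except through losses: the soluble fraction of the secreted
#' isoform obeys `D c'' = lambda c` with the variant-assembled loss rate
#' `lambda = (k_P + k_deg_V) + (k_P + k_deg_VH) * H_total/Kd`, equivalently
#' an effective diffusivity `D_eff = D / (1 + H_total/Kd)` acting on the
#' total (soluble + bound) pool -- matrix binding potentiates proteolysis
#' and degradation. These oracles use independent numerics (closed forms and
#' dense central differences) and share no discretisation code with the
#' solver.
#'
#' @name oracles
NULL

#' Reduced 1D slab problem
#'
#' @param D diffusivity, um^2/s.
#' @param K_ECM available volume fraction (enters the flux boundary
#'   condition).
#' @param H_total HSPG density, nM.
#' @param Kd HSPG dissociation constant, nM (Inf for non-binders).
#' @param k_P,k_deg_V,k_deg_VH first-order rates, s^-1.
#' @param L_half slab half-length, um.
#' @param q secretion flux at z = +L, molecules/um^2/s.
#' @param k_clear clearance velocity at z = -L, um/s.
#' @return a `reduced_1d_problem` object, with the derived `bound_ratio`
#'   (H_total/Kd), `lambda` and `D_eff`.
#' @export
reduced_1d_problem <- function(D = 68.6, K_ECM = 0.85, H_total = 750,
                               Kd = Inf, k_P = 0, k_deg_V = 0, k_deg_VH = 0,
                               L_half = 80, q = 4.39e-5, k_clear = 0.0948) {
  stopifnot(D > 0, L_half > 0, all(c(k_P, k_deg_V, k_deg_VH) >= 0))
  br <- if (is.infinite(Kd)) 0 else H_total / Kd
  structure(list(
    D = D, K_ECM = K_ECM, H_total = H_total, Kd = Kd,
    k_P = k_P, k_deg_V = k_deg_V, k_deg_VH = k_deg_VH,
    L_half = L_half, q = q, k_clear = k_clear,
    bound_ratio = br,
    lambda = (k_P + k_deg_V) + (k_P + k_deg_VH) * br,
    D_eff = D / (1 + br)
  ), class = "reduced_1d_problem")
}

#' Closed-form steady soluble profile of the reduced 1D problem
#'
#' Solves `D c'' = lambda c` on z in \[-L, +L\] with influx
#' `D K_ECM c'(+L) = q` and Robin clearance `D c'(-L) = k_clear c(-L)`;
#' for `lambda = 0` the profile is linear. Concentrations are returned in pM
#' (per available fluid volume).
#'
#' @param p a [reduced_1d_problem()].
#' @param z evaluation points, um.
#' @return soluble concentration in pM at `z`.
#' @export
analytic_1d_profile <- function(p, z) {
  L <- p$L_half
  qc <- p$q / .PM_TO_UM3  # flux in pM um/s units
  if (p$lambda <= 0) {
    b <- qc / (p$D * p$K_ECM)
    a <- p$D * b / p$k_clear + b * L
    return(a + b * z)
  }
  mu <- sqrt(p$lambda / p$D)
  s <- sinh(mu * L); ch <- cosh(mu * L)
  M <- rbind(c(p$D * p$K_ECM * mu * s, p$D * p$K_ECM * mu * ch),
             c(-p$D * mu * s - p$k_clear * ch, p$D * mu * ch + p$k_clear * s))
  ab <- solve(M, c(qc, 0))
  ab[1] * cosh(mu * z) + ab[2] * sinh(mu * z)
}

#' Dense 1D finite-difference reference solve (two species)
#'
#' Independent reference for the full solver: central differences at fine
#' resolution for the secreted isoform and the cleaved product (sourced by
#' proteolysis of soluble plus bound VEGF, removed only by clearance). With
#' `binding = "kinetic"` (default) the immobile bound pool is at its local
#' kinetic steady state, `VH = konH V H_total / (koff + k_P + k_deg_VH)`,
#' which matters when the VH sinks are not negligible against `koff`;
#' `binding = "equilibrium"` uses the equilibrium ratio `H_total/Kd` of the
#' reduced theory (the closed form of [analytic_1d_profile()]).
#'
#' @param p a [reduced_1d_problem()].
#' @param n number of cells (default 1600, i.e. 0.1 um at L = 80).
#' @param binding treatment of the bound pool, see Details.
#' @return tibble with `z` (cell centres), `V`, `Vc`, `VH` in pM, plus
#'   attribute `totals`: domain-integrated molecule counts for a cylinder of
#'   the standard radius (r = 50 um), as `c(full_soluble, cleaved, bound)`.
#' @export
solve_reduced_1d <- function(p, n = 1600,
                             binding = c("kinetic", "equilibrium")) {
  binding <- match.arg(binding)
  L <- p$L_half
  h <- 2 * L / n
  zc <- seq(-L + h / 2, L - h / 2, by = h)
  koff <- 0.01  # reference HSPG off-rate behind the Kd of the problem
  ratio <- if (binding == "kinetic") {
    p$bound_ratio * koff / (koff + p$k_P + p$k_deg_VH)
  } else {
    p$bound_ratio
  }
  lam_full <- (p$k_P + p$k_deg_V) + (p$k_P + p$k_deg_VH) * ratio
  main <- rep(2 * p$D / h^2 + lam_full, n)
  offd <- rep(-p$D / h^2, n - 1)
  main[c(1, n)] <- p$D / h^2 + lam_full
  main[1] <- main[1] + p$k_clear / h
  A <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                          diagonals = list(offd, main, offd))
  rhs <- numeric(n)
  rhs[n] <- (p$q / .PM_TO_UM3) / (p$K_ECM * h)
  V <- as.numeric(Matrix::solve(A, rhs))
  # cleaved: no secretion, clearance only, sourced by k_P (V + VH)
  mainc <- rep(2 * p$D / h^2, n)
  mainc[c(1, n)] <- p$D / h^2
  mainc[1] <- mainc[1] + p$k_clear / h
  Ac <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                           diagonals = list(offd, mainc, offd))
  srcC <- p$k_P * (1 + ratio) * V
  Vc <- if (p$k_P > 0) as.numeric(Matrix::solve(Ac, srcC)) else numeric(n)
  VH <- ratio * V
  ring <- pi * 50^2
  tot <- c(full_soluble = sum(V), cleaved = sum(Vc), bound = sum(VH)) *
    .PM_TO_UM3 * p$K_ECM * h * ring
  out <- tibble::tibble(z = zc, V = V, Vc = Vc, VH = VH)
  attr(out, "totals") <- tot
  out
}

#' Local steady matrix-bound fraction under proteolysis
#'
#' Steady-state bound concentration at fixed local soluble VEGF:
#' `VH = kon V H_total / (koff + k_P + k_deg_VH + kon V)`. In the regime
#' `koff >> k_P >> kon V` this reduces to the equilibrium proportionality
#' `VH = V H_total / Kd`.
#'
#' @param V soluble VEGF, pM.
#' @param H_total HSPG site density, nM.
#' @param Kd HSPG dissociation constant, nM.
#' @param k_P proteolysis rate, s^-1.
#' @param koff HSPG off-rate, s^-1.
#' @param k_deg_VH degradation rate of bound VEGF, s^-1.
#' @return bound VEGF in pM.
#' @export
bound_fraction_with_protease <- function(V, H_total, Kd, k_P = 0,
                                         koff = 0.01, k_deg_VH = 0) {
  stopifnot(all(c(k_P, koff, k_deg_VH) >= 0))
  if (is.infinite(Kd)) return(rep(0, length(V)))
  kon <- koff / Kd  # per nM per s
  Vn <- V * 1e-3    # nM
  (kon * Vn * H_total / (koff + k_P + k_deg_VH + kon * Vn)) * 1e3
}

#' Damkohler number for surface reaction vs. receptor diffusion
#'
#' `Da = koff * L_tip^2 / D_surface`; the base-model value of 160 justifies
#' neglecting receptor diffusion along the cell surface.
#'
#' @param koff reaction rate, s^-1.
#' @param L_tip tip-cell length, um.
#' @param D_surface receptor surface diffusivity, um^2/s.
#' @export
damkohler <- function(koff = 1e-3, L_tip = 40, D_surface = 0.01) {
  stopifnot(koff >= 0, L_tip > 0, D_surface > 0)
  koff * L_tip^2 / D_surface
}

#' Damped fixed-point steady state of the surface network (oracle)
#'
#' Independent route to the surface steady state at fixed local soluble
#' concentrations: each species is repeatedly replaced by the value that
#' zeroes its own balance with all other species held fixed, under-relaxed
#' by `damp`. Shares no code with the ODE integration used by the solver.
#'
#' @param comp compiled scenario (needs receptors).
#' @param V_pM,Vc_pM local soluble concentrations, pM.
#' @param damp under-relaxation factor in (0, 1].
#' @param tol convergence tolerance on the relative update.
#' @param max_iter iteration cap.
#' @return named vector of the 14 surface densities (molecules/um^2).
#' @export
surface_steady_fixedpoint <- function(comp, V_pM, Vc_pM = 0, damp = 0.5,
                                      tol = 1e-12, max_iter = 20000) {
  rec <- comp$rec
  V <- pM_to_molec_um3(V_pM); Vc <- pM_to_molec_um3(Vc_pM)
  kint <- rec$k_int
  y <- as.numeric(surface_rest_state(comp, 1L))
  names(y) <- .SURF_SPECIES
  lig <- list(comp$full, comp$clv)
  Vl <- c(V, Vc)
  for (it in seq_len(max_iter)) {
    yo <- y
    upd <- function(k, gain, loss) {
      y[k] <<- (1 - damp) * y[k] + damp * gain / loss
    }
    # complexes first, then free receptors from their own balances
    for (li in 1:2) {
      s <- lig[[li]]; v <- Vl[li]; o <- 4L + (li - 1L) * 5L
      upd(o + 1L, s$kon_R1 * v * y[1] + s$kuc_VR1_N1 * y[o + 5L],
          s$koff_R1 + kint + s$kc_VR1_N1 * y[3])
      upd(o + 2L, s$kon_R2 * v * y[2] + s$kuc_VR2_N1 * y[o + 4L],
          s$koff_R2 + kint + s$kc_VR2_N1 * y[3])
      upd(o + 3L, s$kon_N1 * v * y[3] + s$kuc_VN1_R2 * y[o + 4L],
          s$koff_N1 + kint + s$kc_VN1_R2 * y[2])
      upd(o + 4L, s$kc_VR2_N1 * y[o + 2L] * y[3] + s$kc_VN1_R2 * y[o + 3L] * y[2],
          s$kuc_VR2_N1 + s$kuc_VN1_R2 + kint)
      upd(o + 5L, s$kon_R1N1 * v * y[4] + s$kc_VR1_N1 * y[o + 1L] * y[3],
          s$koff_R1N1 + s$kuc_VR1_N1 + kint)
    }
    upd(4L, rec$kc_R1N1 * y[1] * y[3] +
          sum(vapply(1:2, function(li) {
            s <- lig[[li]]; o <- 4L + (li - 1L) * 5L
            s$koff_R1N1 * y[o + 5L]
          }, numeric(1))),
        rec$kuc_R1N1 + kint +
          comp$full$kon_R1N1 * V + comp$clv$kon_R1N1 * Vc)
    upd(1L, kint * rec$R1T + rec$kuc_R1N1 * y[4] +
          comp$full$koff_R1 * y[5] + comp$clv$koff_R1 * y[10],
        kint + rec$kc_R1N1 * y[3] +
          comp$full$kon_R1 * V + comp$clv$kon_R1 * Vc)
    upd(2L, kint * rec$R2T + comp$full$koff_R2 * y[6] +
          comp$clv$koff_R2 * y[11] + comp$full$kuc_VN1_R2 * y[8] +
          comp$clv$kuc_VN1_R2 * y[13],
        kint + comp$full$kon_R2 * V + comp$clv$kon_R2 * Vc +
          comp$full$kc_VN1_R2 * y[7] + comp$clv$kc_VN1_R2 * y[12])
    upd(3L, kint * rec$N1T + rec$kuc_R1N1 * y[4] +
          comp$full$koff_N1 * y[7] + comp$full$kuc_VR2_N1 * y[8] +
          comp$full$kuc_VR1_N1 * y[9] + comp$clv$kuc_VR1_N1 * y[14],
        kint + rec$kc_R1N1 * y[1] + comp$full$kon_N1 * V +
          comp$full$kc_VR2_N1 * y[6] + comp$full$kc_VR1_N1 * y[5] +
          comp$clv$kc_VR1_N1 * y[10])
    if (max(abs(y - yo) / pmax(abs(y), 1e-12)) < tol) break
  }
  y
}
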