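#' Tip-cell gradient and occupancy metrics
#'
#' Extracts the measured quantities from a converged state: mean tip
#' concentrations, absolute gradients (AG, pM per 40 um), fractional and
#' isoform-fractional gradients (FG/IFG, % per 40 um), receptor occupancies
#' and their gradients, gradient-detection sensitivities, compartment
#' molecule totals, and the receptor capture fraction.
#'
#' Gradients are evaluated between the front (z = 0) and back
#' (z = -L_tip) faces of the tip cell, by linear interpolation of the axial
#' rows; mean tip concentrations average over the whole tip surface.
#' Interstitial fields are read at a fixed sensing radius `r_sense`
#' (default 6 um, the centre of the first 8-um interstitial ring of the
#' reference mesh), which makes the metrics insensitive to the radial
#' spacing. Surface-complex front/back values are the steady response of
#' the (laterally uncoupled) receptor network to the local ligand levels at
#' the tip faces. With `bands = "row"` front/back values are instead the
#' frontmost and rearmost control-volume rows of the tip (gradients then
#' rescaled from the row-centre span to the 40-um reference).
#'
#' @param res a `vegf_steady` result.
#' @param bands `"face"` (default) or `"row"`.
#' @param r_sense sensing radius for interstitial tip metrics, um.
#' @return a list of class `vegf_tip_metrics`; use [generics::tidy()] for a
#'   flat table.
#' @export
tip_metrics <- function(res, bands = c("face", "row"), r_sense = 6) {
  bands <- match.arg(bands)
  grid <- res$grid; comp <- res$comp
  g <- res$cfg$geometry
  Ltip <- g$L_tip
  has_sprout <- !is.null(grid$patches)

  interp_at <- function(zs, ys, z0) {
    # linear interpolation with end extrapolation on a sorted grid
    if (z0 <= zs[1]) {
      i <- 1L
    } else if (z0 >= zs[length(zs)]) {
      i <- length(zs) - 1L
    } else {
      i <- findInterval(z0, zs)
    }
    ys[i] + (ys[i + 1L] - ys[i]) * (z0 - zs[i]) / (zs[i + 1L] - zs[i])
  }

  # axial profile of an interstitial field at the sensing radius (or the
  # volume-weighted radial mean for sprout-free domains, which are radially
  # uniform)
  profile <- function(x) {
    if (has_sprout) {
      y <- vapply(seq_len(grid$nz), function(iz) {
        ir <- which(!is.na(grid$id[iz, ]))
        stats::approx(grid$rc[ir], x[grid$id[iz, ir]], xout = r_sense,
                      rule = 2)$y
      }, numeric(1))
      list(z = grid$zc, y = y)
    } else {
      m <- vapply(seq_len(grid$nz), function(iz) {
        cells <- grid$id[iz, ]
        stats::weighted.mean(x[cells], grid$vol[iz, ])
      }, numeric(1))
      list(z = grid$zc, y = m)
    }
  }

  grad_of <- function(x) {
    p <- profile(x)
    tipsel <- p$z > -Ltip & p$z < 0
    mean_tip <- if (has_sprout) {
      stats::weighted.mean(p$y[tipsel], grid$patches$area[grid$patches$tip])
    } else mean(p$y[tipsel])
    if (bands == "face") {
      dv <- interp_at(p$z, p$y, 0) - interp_at(p$z, p$y, -Ltip)
      span <- Ltip
    } else {
      rows <- which(tipsel)
      dv <- p$y[max(rows)] - p$y[min(rows)]
      span <- p$z[max(rows)] - p$z[min(rows)]
    }
    # per-40-um value: for the default L_tip = 40 the face difference needs
    # no rescaling; row bands span 32 um and are rescaled linearly
    list(mean = mean_tip, agm = dv * (40 / span))
  }

  V <- grad_of(res$V); Vc <- grad_of(res$Vc); VH <- grad_of(res$VH)
  tot_sol_field <- res$V + res$Vc
  TS <- grad_of(tot_sol_field)

  toPM <- molec_um3_to_pM
  out <- list(
    bands = bands,
    mean_tip = c(V = toPM(V$mean), Vc = toPM(Vc$mean), VH = toPM(VH$mean),
                 total_soluble = toPM(TS$mean)),
    AG = c(V = toPM(V$agm), Vc = toPM(Vc$agm), VH = toPM(VH$agm),
           total_soluble = toPM(TS$agm)),
    IFG = c(V = 100 * V$agm / V$mean, Vc = 100 * Vc$agm / max(Vc$mean, 1e-300),
            VH = 100 * VH$agm / max(VH$mean, 1e-300),
            total_soluble = 100 * TS$agm / TS$mean),
    FG = c(V = 100 * V$agm / TS$mean, Vc = 100 * Vc$agm / TS$mean,
           total_soluble = 100 * TS$agm / TS$mean)
  )

  if (!is.null(res$Y)) {
    Y <- res$Y
    p <- grid$patches
    tip <- p$tip
    warea <- p$area[tip]
    occ_cols <- list(
      R1 = c("V.R1", "Vc.R1", "V.R1N1", "Vc.R1N1"),
      R2 = c("V.R2", "Vc.R2", "V.R2.N1", "Vc.R2.N1"),
      N1 = c("V.N1", "V.R2.N1", "V.R1N1", "Vc.R1N1")
    )
    tot_cols <- list(
      R1 = c("R1", "R1N1", occ_cols$R1),
      R2 = c("R2", occ_cols$R2),
      N1 = c("N1", "R1N1", occ_cols$N1)
    )
    if (bands == "face") {
      # surface states are a pointwise steady response to the local ligand
      # levels (no lateral coupling), so the complex densities at the tip
      # faces are the network solved at the face concentrations
      pv <- profile(res$V); pc <- profile(res$Vc)
      face_state <- function(z0) {
        Vf <- c(interp_at(pv$z, pv$y, z0), interp_at(pc$z, pc$y, z0))
        .surface_advance(surface_rest_state(comp, 1L),
                         matrix(Vf, 1, 2), comp, Inf)[1, ]
      }
      y_front <- face_state(0)
      y_back <- face_state(-Ltip)
    }
    occ <- list(); rgrad <- list()
    IFG_lig <- out$IFG[["total_soluble"]]
    for (rn in names(occ_cols)) {
      od <- rowSums(Y[, occ_cols[[rn]], drop = FALSE])
      td <- rowSums(Y[, tot_cols[[rn]], drop = FALSE])
      mean_occ <- stats::weighted.mean(od[tip], warea)
      mean_tot <- stats::weighted.mean(td[tip], warea)
      if (bands == "face") {
        dv <- sum(y_front[occ_cols[[rn]]]) - sum(y_back[occ_cols[[rn]]])
        span <- Ltip
      } else {
        tr <- which(tip)
        dv <- od[max(tr)] - od[min(tr)]
        span <- p$z[max(tr)] - p$z[min(tr)]
      }
      dv40 <- dv * 40 / span
      occ[[rn]] <- c(
        occupied = mean_occ * g$tip_area,
        FO = mean_occ / mean_tot
      )
      rgrad[[rn]] <- c(
        AG_molecules = dv40 * g$tip_area,          # complexes per 40 um
        AG_frac_total = 100 * dv40 / mean_tot,     # normalised by receptor total
        IFG = 100 * dv40 / max(mean_occ, 1e-300),
        S_IFG = (100 * dv40 / max(mean_occ, 1e-300)) / IFG_lig
      )
    }
    out$occupancy <- occ
    out$receptor_gradients <- rgrad
  }

  out$totals <- compartment_totals(res)
  fb <- res$flux_balance
  sec <- fb$rate[fb$channel == "secretion"]
  upt <- sum(fb$rate[fb$channel %in% c("uptake_V", "uptake_Vc")])
  out$capture_fraction <- upt / sec
  if (!is.null(res$Y)) {
    sr <- surface_rates(res$Y, cbind(res$V[res$patch_cells],
                                     res$Vc[res$patch_cells]), comp)
    tipint <- sum(rowSums(sr$internalised)[grid$patches$tip] *
                    grid$patches$area[grid$patches$tip])
    out$capture_fraction_tip <- tipint / sec
  }
  class(out) <- "vegf_tip_metrics"
  out
}

#' Gradient-detection sensitivity
#'
#' `S = IFG(receptor complex) / IFG(ligand)`: the factor by which a
#' fractional change in ligand translates into a fractional change in
#' receptor binding. For a single receptor binding a single ligand the
#' identity `S_IFG = 1 - FO` holds. Returns `NA` where the ligand gradient
#' vanishes.
#'
#' @param metrics a `vegf_tip_metrics` object.
#' @return named vector of sensitivities per receptor.
#' @export
sensitivity <- function(metrics) {
  if (is.null(metrics$receptor_gradients)) {
    return(c(R1 = NA_real_, R2 = NA_real_, N1 = NA_real_))
  }
  lig <- metrics$IFG[["total_soluble"]]
  if (!is.finite(lig) || abs(lig) < 1e-300) {
    return(c(R1 = NA_real_, R2 = NA_real_, N1 = NA_real_))
  }
  vapply(metrics$receptor_gradients, function(x) x[["S_IFG"]], numeric(1))
}

#' Compartment molecule totals
#'
#' Domain-integrated molecule counts at steady state: concentration times
#' available volume per cell, summed per species, plus surface-bound ligand
#' from patch densities times areas.
#'
#' @param res a `vegf_steady` result.
#' @return named vector: `soluble_full`, `soluble_cleaved`, `matrix_bound`,
#'   `surface_bound`, `total`.
#' @export
compartment_totals <- function(res) {
  w <- res$comp$K_ECM * res$grid$vol[res$grid$idx]
  s <- c(soluble_full = sum(res$V * w),
         soluble_cleaved = sum(res$Vc * w),
         matrix_bound = sum(res$VH * w))
  surf <- 0
  if (!is.null(res$Y)) {
    ligcols <- c("V.R1", "V.R2", "V.N1", "V.R2.N1", "V.R1N1",
                 "Vc.R1", "Vc.R2", "Vc.N1", "Vc.R2.N1", "Vc.R1N1")
    surf <- sum(rowSums(res$Y[, ligcols, drop = FALSE]) * res$grid$patches$area)
  }
  c(s, surface_bound = surf, total = sum(s) + surf)
}

#' @export
print.vegf_tip_metrics <- function(x, ...) {
  cat("<vegf_tip_metrics>\n")
  cat(sprintf("  mean tip [V] = %.4g pM; AG = %.4g pM/40um; IFG = %.3f %%/40um\n",
              x$mean_tip[["V"]], x$AG[["V"]], x$IFG[["V"]]))
  if (!is.null(x$occupancy)) {
    cat(sprintf("  VEGF.VEGFR2: %.0f complexes/tip cell (FO %.3f), IFG %.3f %%/40um\n",
                x$occupancy$R2[["occupied"]], x$occupancy$R2[["FO"]],
                x$receptor_gradients$R2[["IFG"]]))
  }
  cat(sprintf("  totals: %.4g molecules; capture %.1f %%\n",
              x$totals[["total"]], 100 * x$capture_fraction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.vegf_tip_metrics <- function(x, ...) {
  rows <- list(
    tibble::tibble(metric = paste0("mean_tip_", names(x$mean_tip)),
                   value = unname(x$mean_tip), units = "pM"),
    tibble::tibble(metric = paste0("AG_", names(x$AG)),
                   value = unname(x$AG), units = "pM/40um"),
    tibble::tibble(metric = paste0("IFG_", names(x$IFG)),
                   value = unname(x$IFG), units = "%/40um"),
    tibble::tibble(metric = paste0("FG_", names(x$FG)),
                   value = unname(x$FG), units = "%/40um"),
    tibble::tibble(metric = paste0("total_", names(x$totals)),
                   value = unname(x$totals), units = "molecules"),
    tibble::tibble(metric = "capture_fraction", value = x$capture_fraction,
                   units = "fraction")
  )
  if (!is.null(x$capture_fraction_tip)) {
    rows <- c(rows, list(tibble::tibble(metric = "capture_fraction_tip",
                                        value = x$capture_fraction_tip,
                                        units = "fraction")))
  }
  if (!is.null(x$occupancy)) {
    for (rn in names(x$occupancy)) {
      rows <- c(rows, list(
        tibble::tibble(
          metric = paste0(c("occupied_", "FO_"), rn),
          value = unname(x$occupancy[[rn]]),
          units = c("molecules/tip", "fraction")),
        tibble::tibble(
          metric = paste0(c("AGmol_", "AGfrac_", "IFG_", "S_IFG_"), rn),
          value = unname(x$receptor_gradients[[rn]]),
          units = c("molecules/40um", "%/40um", "%/40um", "ratio"))
      ))
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
tidy.vegf_steady <- function(x, ...) {
  tab <- grid_table(x$grid)
  toPM <- molec_um3_to_pM
  dplyr::bind_rows(
    dplyr::mutate(tab, species = "V", conc_pM = toPM(x$V)),
    dplyr::mutate(tab, species = "Vc", conc_pM = toPM(x$Vc)),
    dplyr::mutate(tab, species = "VH", conc_pM = toPM(x$VH)),
    dplyr::mutate(tab, species = "H", conc_pM = toPM(x$H))
  )
}

#' @export
glance.vegf_steady <- function(x, ...) {
  tibble::tibble(
    label = x$cfg$label,
    variant = x$cfg$variant,
    isoform = x$cfg$isoform$name,
    receptors = !is.null(x$cfg$receptors),
    cells = x$grid$n_active,
    steps = x$steps,
    final_delta = x$final_delta,
    closure = attr(x$flux_balance, "closure"),
    total_molecules = compartment_totals(x)[["total"]]
  )
}

#' Surface densities as a tidy table
#'
#' @param res a `vegf_steady` with receptors.
#' @return tibble: patch z, species, density (molecules/um^2).
#' @export
surface_table <- function(res) {
  if (is.null(res$Y)) return(tibble::tibble())
  p <- res$grid$patches
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(z = p$z, area = p$area, tip = p$tip),
                     tibble::as_tibble(res$Y)),
    cols = dplyr::all_of(.SURF_SPECIES),
    names_to = "species", values_to = "density")
}
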