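#' Preset scenario builders for the study conditions
#'
#' Returns fully-populated scenario configurations for each figure-level
#' condition of the study. The boundary drive uses the calibrated table
#' values: with receptors `q = 5.27e-5` molecules/um^2/s and
#' `k_clear = 0.0399` um/s; without receptors `q = 4.39e-5` and
#' `k_clear = 0.0948` (these can be re-derived with [calibrate_neumann()]).
#'
#' Tags:
#' * `fig3`: base case; VEGF165, HSPG 750 nM, receptors on.
#' * `fig3_noHSPG`: base case with the HSPG density set to zero.
#' * `fig4A`-`fig4D`: the four model variants (HSPG-binding-only, HSPG
#'   gradient, soluble degradation, matrix-sequestered degradation), no
#'   receptors, isoform selectable.
#' * `fig5_iso`: HSPG-binding-only with proteases (k_P = 2.8e-4 s^-1).
#' * `fig6_iso`: matrix-sequestered degradation with proteases.
#' * `fig7B`, `fig7C`, `fig8`: sweep specifications (see [sweep_spec()]).
#'
#' @param tag condition tag.
#' @param isoform secreted isoform for the isoform-parametrised tags.
#' @param allow_V189_R2 whether intact VEGF189 binds VEGFR2.
#' @return a `vegf_scenario`, or a `sweep_spec` for the sweep tags.
#' @export
build_figure_scenario <- function(tag = c("fig3", "fig3_noHSPG", "fig4A",
                                          "fig4B", "fig4C", "fig4D",
                                          "fig5_iso", "fig6_iso",
                                          "fig7B", "fig7C", "fig8"),
                                  isoform = "VEGF165",
                                  allow_V189_R2 = TRUE) {
  tag <- match.arg(tag)
  drive_rec <- boundary_drive(V0 = 1, g0 = 0.05, q = 5.27e-5, k_clear = 0.0399)
  drive_norec <- boundary_drive(V0 = 1, g0 = 0.05, q = 4.39e-5, k_clear = 0.0948)
  if (tag %in% c("fig7B", "fig7C", "fig8")) {
    return(switch(tag,
      fig7B = sweep_spec(variant = "hspg_only"),
      fig7C = sweep_spec(variant = "matrix_deg"),
      fig8 = sweep_spec(variant = "matrix_deg", receptors = receptor_params())
    ))
  }
  cfg <- switch(tag,
    fig3 = scenario_config("VEGF165", "hspg_only",
                           receptors = receptor_params(), drive = drive_rec,
                           label = "fig3"),
    fig3_noHSPG = {
      x <- scenario_config("VEGF165", "hspg_only",
                           receptors = receptor_params(), drive = drive_rec,
                           label = "fig3_noHSPG")
      x$interstitial$H_total_ref <- 0
      x
    },
    fig4A = scenario_config(isoform, "hspg_only", drive = drive_norec,
                            allow_V189_R2 = allow_V189_R2,
                            label = paste0("fig4A/", isoform)),
    fig4B = scenario_config(isoform, "hspg_gradient", drive = drive_norec,
                            gH0 = 0.30, allow_V189_R2 = allow_V189_R2,
                            label = paste0("fig4B/", isoform)),
    fig4C = scenario_config(isoform, "soluble_deg", drive = drive_norec,
                            k_deg = 1e-3, allow_V189_R2 = allow_V189_R2,
                            label = paste0("fig4C/", isoform)),
    fig4D = scenario_config(isoform, "matrix_deg", drive = drive_norec,
                            k_deg = 1e-3, allow_V189_R2 = allow_V189_R2,
                            label = paste0("fig4D/", isoform)),
    fig5_iso = scenario_config(isoform, "hspg_only", drive = drive_norec,
                               k_P = 2.8e-4, allow_V189_R2 = allow_V189_R2,
                               label = paste0("fig5/", isoform)),
    fig6_iso = scenario_config(isoform, "matrix_deg", drive = drive_norec,
                               k_P = 2.8e-4, k_deg = 1e-3,
                               allow_V189_R2 = allow_V189_R2,
                               label = paste0("fig6/", isoform))
  )
  cfg
}

#' Sweep specification over HSPG affinity and protease activity
#'
#' The affinity sweep varies the secreted isoform along the HSPG-affinity
#' continuum from the VEGF189 value (8.5 nM) to the non-binding limit
#' (`Inf`), log-spaced, at fixed protease activity. The protease sweep
#' varies `k_P` from 1e-6 to 1e-2 s^-1 (log-spaced) for secreted VEGF165.
#' Simulations are performed without receptors.
#'
#' @param variant model variant for the sweep (`hspg_only` or `matrix_deg`).
#' @param Kd_grid HSPG Kd grid, nM (the canonical 8.5, 165, Inf are always
#'   included as markers).
#' @param kP_grid protease-activity grid, s^-1.
#' @param kP_fixed protease rate held during the affinity sweep.
#' @param Kd_fixed affinity held during the protease sweep.
#' @param receptors optional `receptor_params()` used only by the
#'   receptor-binding map (the transport sweep itself is receptor-free).
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(variant = c("matrix_deg", "hspg_only"),
                       Kd_grid = NULL, kP_grid = NULL,
                       kP_fixed = 2.8e-4, Kd_fixed = 165,
                       receptors = NULL) {
  variant <- match.arg(variant)
  if (is.null(Kd_grid)) {
    Kd_grid <- c(exp(seq(log(8.5), log(8.5e3), length.out = 25)), Inf)
  }
  Kd_grid <- sort(unique(c(Kd_grid, 8.5, 165, Inf)))
  if (is.null(kP_grid)) kP_grid <- 10^seq(-6, -2, length.out = 13)
  stopifnot(length(Kd_grid) > 0, length(kP_grid) > 0)
  structure(list(variant = variant, Kd_grid = Kd_grid, kP_grid = kP_grid,
                 kP_fixed = kP_fixed, Kd_fixed = Kd_fixed,
                 receptors = receptors),
            class = "sweep_spec")
}

# tip-region (z in [-L_tip, 0], averaged over r) concentrations of a state
.tip_region_metrics <- function(res) {
  grid <- res$grid
  zc <- grid$zc[grid$idx[, 1]]
  sel <- zc > -res$cfg$geometry$L_tip & zc < 0
  w <- grid$vol[grid$idx][sel]
  m <- function(x) stats::weighted.mean(x[sel], w)
  tm <- tip_metrics(res)
  c(soluble_uncleaved = molec_um3_to_pM(m(res$V)),
    cleaved = molec_um3_to_pM(m(res$Vc)),
    total_soluble = molec_um3_to_pM(m(res$V + res$Vc)),
    matrix_bound = molec_um3_to_pM(m(res$VH)),
    total = molec_um3_to_pM(m(res$V + res$Vc + res$VH)),
    AG_total_soluble = tm$AG[["total_soluble"]],
    FG_total_soluble = tm$FG[["total_soluble"]],
    AG_matrix_bound = tm$AG[["VH"]],
    IFG_matrix_bound = tm$IFG[["VH"]])
}

#' Classify a metric series as monotone or biphasic
#'
#' Successive differences with a relative tolerance (default 1e-3 of the
#' series scale) suppress numerical noise; a series is `monotone-consistent`
#' if all significant differences share one sign, `biphasic` if the sign
#' changes once, `inconsistent` otherwise (flat series are monotone).
#'
#' @param x numeric series ordered along the sweep axis.
#' @param rel_tol relative noise tolerance.
#' @return one of "monotone-consistent", "biphasic", "inconsistent".
#' @export
classify_monotonicity <- function(x, rel_tol = 1e-3) {
  d <- diff(x)
  thr <- rel_tol * max(abs(x), .Machine$double.xmin)
  s <- sign(d[abs(d) > thr])
  if (length(s) == 0) return("monotone-consistent")
  runs <- rle(s)$lengths
  if (length(runs) == 1L) "monotone-consistent"
  else if (length(runs) == 2L) "biphasic"
  else "inconsistent"
}

#' Run the affinity and protease sweeps
#'
#' Solves the steady state (without receptors or sprout uptake) at every
#' grid point of the sweep: the HSPG-affinity axis at fixed `kP_fixed`
#' (plus a protease-free control), and the protease axis at fixed
#' `Kd_fixed`. Tip-region metrics are recorded and classified for (a)
#' monotonicity along decreasing affinity and (b) direction agreement
#' between decreasing affinity and increasing protease activity (the
#' HSPG/MMP-antagonism requirement for a viable patterning signal).
#'
#' @param spec a [sweep_spec()].
#' @param settings,grid passed to [solve_steady()]; the defaults use a
#'   degenerate single-ring radial mesh (sprout-free fields are radially
#'   uniform, so this is exact) and an enlarged pseudo-time cap for the
#'   linear receptor-free system.
#' @return list of class `sweep_result`: `points` (long tibble), and
#'   `classification`.
#' @export
run_sweep <- function(spec, settings = solver_settings(dt_max = 1e5),
                      grid = NULL) {
  if (is.null(grid)) {
    grid <- build_grid(geometry_params(), dr_fine = 48, dr_coarse = 48,
                       r_transition = 50, sprout = FALSE)
  }
  drive <- boundary_drive(V0 = 1, g0 = 0.05, q = 4.39e-5, k_clear = 0.0948)
  solve_point <- function(Kd, kP) {
    iso <- make_continuum_isoform(Kd)
    cfg <- scenario_config(iso, spec$variant, drive = drive, k_P = kP,
                           sprout = FALSE,
                           label = sprintf("sweep Kd=%s kP=%g", format(Kd), kP))
    res <- tryCatch(solve_steady(cfg, settings = settings, grid = grid),
                    vegfgrad_no_convergence = function(e) e)
    if (inherits(res, "condition")) {
      return(tibble::tibble(converged = FALSE))
    }
    m <- .tip_region_metrics(res)
    dplyr::bind_cols(tibble::tibble(converged = TRUE),
                     tibble::as_tibble(as.list(m)))
  }
  rows <- list()
  for (Kd in spec$Kd_grid) {
    for (kP in unique(c(0, spec$kP_fixed))) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(axis = "affinity", Kd = Kd, k_P = kP),
        solve_point(Kd, kP))
    }
  }
  for (kP in spec$kP_grid) {
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(axis = "protease", Kd = spec$Kd_fixed, k_P = kP),
      solve_point(spec$Kd_fixed, kP))
  }
  points <- dplyr::bind_rows(rows)

  metrics <- c("soluble_uncleaved", "cleaved", "total_soluble",
               "matrix_bound", "total")
  # order by increasing Kd (decreasing affinity), Inf last
  aff <- dplyr::arrange(dplyr::filter(points, .data$axis == "affinity",
                                      .data$k_P == spec$kP_fixed,
                                      .data$converged), .data$Kd)
  pro <- dplyr::arrange(dplyr::filter(points, .data$axis == "protease",
                                      .data$converged), .data$k_P)
  classification <- dplyr::bind_rows(lapply(metrics, function(mm) {
    a <- aff[[mm]]; p <- pro[[mm]]
    cls_a <- classify_monotonicity(a)
    cls_p <- classify_monotonicity(p)
    thr_a <- 1e-3 * max(abs(a), .Machine$double.xmin)
    thr_p <- 1e-3 * max(abs(p), .Machine$double.xmin)
    dir_a <- sign(a[length(a)] - a[1])        # along decreasing affinity
    dir_p <- sign(p[length(p)] - p[1])        # along increasing protease
    flat_a <- max(a) - min(a) <= thr_a
    flat_p <- max(p) - min(p) <= thr_p
    agree <- (!flat_a && !flat_p && dir_a == dir_p &&
                cls_a == "monotone-consistent" &&
                cls_p == "monotone-consistent")
    tibble::tibble(metric = mm,
                   affinity_class = cls_a, protease_class = cls_p,
                   affinity_direction = dir_a, protease_direction = dir_p,
                   antagonism_consistent = agree)
  }))
  structure(list(spec = spec, points = points,
                 classification = classification),
            class = "sweep_result")
}

#' Receptor-binding map over the affinity sweep
#'
#' Imposes the receptor-free tip-region concentrations from a sweep onto the
#' surface receptor network (assuming no depletion by the sprout): for each
#' affinity grid point the network is solved to steady state under the fixed
#' local soluble concentrations of the full-length continuum isoform and its
#' cleavage product, and total VEGF-VEGFR2 and VEGF-VEGFR1 occupancies per
#' tip cell are reported with their monotonicity classification and the
#' location of the VEGFR2 peak.
#'
#' @param sweep a `sweep_result` from [run_sweep()].
#' @param receptors a [receptor_params()] population.
#' @param allow_V189_R2 whether high-affinity intact isoforms bind VEGFR2.
#' @return list of class `receptor_map`: `curves` tibble, `classification`,
#'   `peak_Kd` (VEGFR2).
#' @export
receptor_binding_map <- function(sweep, receptors = receptor_params(),
                                 allow_V189_R2 = TRUE) {
  aff <- dplyr::arrange(
    dplyr::filter(sweep$points, .data$axis == "affinity",
                  .data$k_P == sweep$spec$kP_fixed, .data$converged),
    .data$Kd)
  tip_area <- geometry_params()$tip_area
  rows <- purrr::pmap(list(aff$Kd, aff$soluble_uncleaved, aff$cleaved),
    function(Kd, Vfull, Vclv) {
      iso <- make_continuum_isoform(Kd, allow_V189_R2 = allow_V189_R2)
      cfg <- scenario_config(iso, "hspg_only", receptors = receptors,
                             drive = boundary_drive(q = 0, k_clear = 0))
      comp <- compile_scenario(cfg, grid = build_grid(cfg$geometry))
      Y <- .surface_advance(surface_rest_state(comp, 1L),
                            matrix(pM_to_molec_um3(c(Vfull, Vclv)), 1, 2),
                            comp, 1e7)
      occR2 <- sum(Y[1, c("V.R2", "Vc.R2", "V.R2.N1", "Vc.R2.N1")])
      occR1 <- sum(Y[1, c("V.R1", "Vc.R1", "V.R1N1", "Vc.R1N1")])
      tibble::tibble(Kd = Kd, V_full_pM = Vfull, V_cleaved_pM = Vclv,
                     R2_occupied = occR2 * tip_area,
                     R1_occupied = occR1 * tip_area)
    })
  curves <- dplyr::bind_rows(rows)
  cls <- tibble::tibble(
    receptor = c("R2", "R1"),
    class = c(classify_monotonicity(curves$R2_occupied),
              classify_monotonicity(curves$R1_occupied)))
  structure(list(curves = curves, classification = cls,
                 peak_Kd = curves$Kd[which.max(curves$R2_occupied)]),
            class = "receptor_map")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: %d points (%d converged)\n",
              x$spec$variant, nrow(x$points), sum(x$points$converged)))
  print(x$classification)
  invisible(x)
}
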