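#' Axisymmetric cylindrical finite-volume mesh
#'
#' Builds the (z, r) control-volume mesh for the tissue cylinder. The axial
#' spacing is uniform (`dz`, default 8 um). Radially, one cell spans the
#' sprout radius \[0, R_sprout\]; outside the sprout surface the spacing is
#' `dr_fine` out to `r_transition` and `dr_coarse` beyond (defaults 4 and
#' 8 um with the transition at 10 um). Cells inside the sprout cylinder
#' (r < R_sprout, z < 0) are excluded from the interstitial unknowns; the
#' sprout lateral surface is represented as one patch per axial row at
#' r = R_sprout. The sprout end-cap area at z = 0 is folded into the
#' frontmost patch, and patch areas over the tip extent are normalised so
#' the total tip area equals `geometry$tip_area` (receptor totals, not patch
#' geometry, drive the results).
#'
#' @param geometry a [geometry_params()] object.
#' @param dz axial control-volume spacing, um; must divide `2 * L_half`, and
#'   `L_half`, `L_tip` must be multiples of it.
#' @param dr_fine,dr_coarse radial spacings next to the sprout and toward the
#'   outer edge, um (defaults give uniform 8-um rings from the sprout
#'   surface, matching the reference discretisation; `dr_fine = 4` refines
#'   the band next to the sprout).
#' @param r_transition radius at which the spacing switches, um.
#' @param sprout include the sprout (excluded cylinder + surface patches)?
#' @return an object of class `vegf_grid`.
#' @export
build_grid <- function(geometry = geometry_params(), dz = 8,
                       dr_fine = 8, dr_coarse = 8, r_transition = 10,
                       sprout = TRUE) {
  g <- geometry
  near <- function(x) abs(x - round(x)) < 1e-9
  errs <- character()
  if (!near(2 * g$L_half / dz)) {
    errs <- c(errs, sprintf("dz must divide the domain length %g", 2 * g$L_half))
  }
  if (!near(g$L_half / dz) || !near(g$L_tip / dz)) {
    errs <- c(errs, "dz must divide L_half and L_tip")
  }
  if (!near((r_transition - g$R_sprout) / dr_fine)) {
    errs <- c(errs, sprintf(
      "dr_fine must divide [R_sprout, r_transition] = [%g, %g]",
      g$R_sprout, r_transition))
  }
  if (!near((g$R_edge - r_transition) / dr_coarse)) {
    errs <- c(errs, sprintf(
      "dr_coarse must divide [r_transition, R_edge] = [%g, %g]",
      r_transition, g$R_edge))
  }
  if (length(errs)) {
    stop("inadmissible grid spacing:\n", paste0("  - ", errs, collapse = "\n"),
         "\n  admissible: dz in divisors of L_tip (e.g. 8, 4, 2); ",
         "dr_fine dividing the fine band; dr_coarse dividing the outer band",
         call. = FALSE)
  }

  zb <- seq(-g$L_half, g$L_half, by = dz)
  rb <- sort(unique(c(0, seq(g$R_sprout, r_transition, by = dr_fine),
                      seq(r_transition, g$R_edge, by = dr_coarse))))
  nz <- length(zb) - 1L
  nr <- length(rb) - 1L
  zc <- (zb[-1] + zb[-(nz + 1L)]) / 2
  rc <- (rb[-1] + rb[-(nr + 1L)]) / 2

  # cell volumes (um^3): pi (r_o^2 - r_i^2) dz, tensor over (iz, ir)
  ring_area <- pi * diff(rb^2)            # cross-sectional ring area per ir
  vol <- outer(rep(dz, nz), ring_area)    # [iz, ir]

  # sprout occupies ir = 1 for all rows with z-centre < 0
  in_sprout <- matrix(FALSE, nz, nr)
  if (sprout) in_sprout[zc < 0, 1] <- TRUE
  active <- !in_sprout
  id <- matrix(NA_integer_, nz, nr)
  id[active] <- seq_len(sum(active))
  idx <- which(active, arr.ind = TRUE)     # row: (iz, ir) of each active cell
  ord <- order(id[active])
  idx <- idx[ord, , drop = FALSE]

  # sprout surface patches: one per axial row at r = R_sprout, z < 0
  patches <- NULL
  if (sprout) {
    piz <- which(zc < 0)
    lat <- 2 * pi * g$R_sprout * dz
    area <- rep(lat, length(piz))
    names(area) <- NULL
    # end-cap folded into the frontmost (largest-z) patch
    area[length(area)] <- area[length(area)] + pi * g$R_sprout^2
    tip <- zc[piz] > -g$L_tip
    # normalise tip patch areas so the tip totals the stated tip-cell area
    area[tip] <- area[tip] * g$tip_area / sum(area[tip])
    patches <- list(
      iz = piz,
      z = zc[piz],
      area = area,
      tip = tip,
      adj_ir = 2L   # first interstitial ring outside the sprout
    )
  }

  structure(list(
    geometry = g, dz = dz, zb = zb, rb = rb, nz = nz, nr = nr,
    zc = zc, rc = rc, ring_area = ring_area, vol = vol,
    active = active, id = id, idx = idx, n_active = sum(active),
    in_sprout = in_sprout, sprout = sprout, patches = patches
  ), class = "vegf_grid")
}

#' Tidy table of grid cells
#'
#' @param grid a `vegf_grid`.
#' @return a tibble with one row per active control volume: cell id, z, r
#'   (centres, um) and volume (um^3).
#' @export
grid_table <- function(grid) {
  tibble::tibble(
    cell = seq_len(grid$n_active),
    z = grid$zc[grid$idx[, 1]],
    r = grid$rc[grid$idx[, 2]],
    volume = grid$vol[grid$idx]
  )
}

#' @export
print.vegf_grid <- function(x, ...) {
  cat(sprintf("<vegf_grid> %d x %d cells (%d active), dz = %g um\n",
              x$nz, x$nr, x$n_active, x$dz))
  cat(sprintf("  z in [%g, %g], r boundaries: %s\n",
              min(x$zb), max(x$zb), paste(x$rb, collapse = ", ")))
  if (!is.null(x$patches)) {
    cat(sprintf("  sprout: %d patches (%d tip), tip area %g um^2\n",
                length(x$patches$iz), sum(x$patches$tip),
                sum(x$patches$area[x$patches$tip])))
  }
  invisible(x)
}
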