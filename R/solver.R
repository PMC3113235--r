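#' Solver settings
#'
#' Controls for the pseudo-transient march to steady state. Pseudo-time steps
#' are fully implicit (first order); within each step the coupled system is
#' relaxed by successive over-relaxation (SOR) with red-black ordering, and
#' the surface receptor network is advanced by a stiff ODE integration with
#' the adjacent concentrations held fixed (operator splitting; the splitting
#' error vanishes at steady state). The step size grows geometrically from
#' `dt0` to `dt_max`; convergence is declared when the per-node relative
#' change over a step at the maximal step size falls below `tol`.
#'
#' @param tol per-node relative convergence tolerance (default 1e-7).
#' @param max_steps maximum pseudo-time steps.
#' @param dt0,dt_growth,dt_max step-size schedule (s).
#' @param omega SOR relaxation factor in (0, 2).
#' @param inner_tol relative residual target of the linear SOR solves.
#' @param max_sweeps SOR sweep cap per linear solve.
#' @param n_inner field/surface coupling iterations per step.
#' @param red_black use red-black ordering (plain Jacobi sweeps otherwise).
#' @param polish after the march converges, iterate the steady equations
#'   directly (the infinite-step limit of the implicit scheme) until the
#'   per-node fixed-point residual meets `tol`; removes the residual drift
#'   of slow mass-loading modes so the global balance closes tightly.
#' @param verbose print residual trace.
#' @export
solver_settings <- function(tol = 1e-7, max_steps = 5000, dt0 = 1,
                            dt_growth = 1.5, dt_max = 2000, omega = 1.5,
                            inner_tol = 1e-10, max_sweeps = 400,
                            n_inner = 2, red_black = TRUE, polish = TRUE,
                            verbose = FALSE) {
  stopifnot(tol > 0, omega > 0, omega < 2, dt0 > 0, dt_max >= dt0)
  structure(list(tol = tol, max_steps = max_steps, dt0 = dt0,
                 dt_growth = dt_growth, dt_max = dt_max, omega = omega,
                 inner_tol = inner_tol, max_sweeps = max_sweeps,
                 n_inner = n_inner, red_black = red_black,
                 polish = isTRUE(polish), verbose = verbose),
            class = "solver_settings")
}

# SOR (red-black) solve of (diagv I - Loff) x = b, starting from x.
# Without red-black ordering the sweep degenerates to damped Jacobi, which
# needs under-relaxation to contract.
.sor_solve <- function(op, diagv, b, x, settings) {
  red <- op$color; blk <- !red
  omega <- if (settings$red_black) settings$omega else min(settings$omega, 0.8)
  bnorm <- max(sum(abs(b)), .Machine$double.xmin)
  for (sweep in seq_len(settings$max_sweeps)) {
    if (settings$red_black) {
      ax <- as.numeric(op$Loff %*% x)
      x[red] <- (1 - omega) * x[red] + omega * (b[red] + ax[red]) / diagv[red]
      ax <- as.numeric(op$Loff %*% x)
      x[blk] <- (1 - omega) * x[blk] + omega * (b[blk] + ax[blk]) / diagv[blk]
    } else {
      ax <- as.numeric(op$Loff %*% x)
      x <- (1 - omega) * x + omega * (b + ax) / diagv
    }
    res <- sum(abs(b + as.numeric(op$Loff %*% x) - diagv * x)) / bnorm
    if (!is.finite(res)) {
      stop("linear relaxation diverged; use a smaller `omega`", call. = FALSE)
    }
    if (res < settings$inner_tol) break
  }
  x
}

# surface ODE advance over dt with fixed local concentrations (stacked lsoda)
.surface_advance <- function(Y, Vloc, comp, dt) {
  np <- nrow(Y)
  f <- function(t, y, p) {
    list(as.numeric(surface_rates(matrix(y, np, 14L), Vloc, comp)$dY))
  }
  out <- deSolve::lsoda(as.numeric(Y), c(0, min(dt, 1e9)), f, parms = NULL,
                        rtol = 1e-9, atol = 1e-12)
  matrix(out[nrow(out), -1], np, 14L, dimnames = list(NULL, .SURF_SPECIES))
}

#' Solve a scenario to steady state
#'
#' Marches the coupled interstitial/surface system to steady state and
#' returns the converged fields with a full flux-balance table. In
#' `dirichlet_stage` mode the axial boundaries hold the target concentrations
#' `V0 (1 +/- g0 L / L_tip)`; in `neumann_stage` mode the secretion flux `q`
#' is applied at z = +L (full-length isoform only) and first-order clearance
#' `k_clear` at z = -L (both soluble species).
#'
#' @param cfg a `vegf_scenario`.
#' @param settings a [solver_settings()] object.
#' @param grid optional `vegf_grid` (defaults to the standard mesh).
#' @param init optional initial state (a previous `vegf_steady` result or a
#'   list with `V`, `Vc`, `VH`, `Y`); defaults to the imposed linear
#'   profile with equilibrated HSPG binding and a ligand-free surface.
#' @return object of class `vegf_steady`.
#' @export
solve_steady <- function(cfg, settings = solver_settings(), grid = NULL,
                         init = NULL) {
  comp <- compile_scenario(cfg, grid)
  if (cfg$drive$mode == "neumann_stage" &&
      !(is.finite(comp$q) && is.finite(comp$k_clear))) {
    stop("neumann_stage drive requires calibrated `q` and `k_clear` ",
         "(run calibrate_neumann or supply the table values)", call. = FALSE)
  }
  grid <- comp$grid
  op <- assemble_diffusion(grid, cfg$transport)
  n <- grid$n_active
  zc_cell <- grid$zc[grid$idx[, 1]]
  g <- cfg$geometry
  dirichlet <- cfg$drive$mode == "dirichlet_stage"
  V_hi <- comp$V0 * (1 + comp$g0 * g$L_half / g$L_tip)
  V_lo <- comp$V0 * (1 - comp$g0 * g$L_half / g$L_tip)

  has_rec <- !is.null(comp$rec) && !is.null(grid$patches)
  np <- if (has_rec) length(grid$patches$iz) else 0L
  patch_cells <- if (has_rec) grid$id[cbind(grid$patches$iz, grid$patches$adj_ir)]

  if (is.null(init)) {
    V <- comp$V0 * (1 + comp$g0 * zc_cell / g$L_tip)
    VH <- comp$kon_H * V * comp$Htot / comp$koff_H
    Vc <- numeric(n)
    Y <- if (has_rec) surface_rest_state(comp, np)
  } else {
    V <- init$V; Vc <- init$Vc; VH <- init$VH
    Y <- if (has_rec) init$Y %||% surface_rest_state(comp, np)
  }

  # fixed parts of the implicit diagonals
  base_diag_V <- -op$diag + comp$k_P + comp$k_deg_V
  base_diag_C <- -op$diag
  bc_diag_V <- bc_diag_C <- numeric(n)
  bc_src_V <- bc_src_C <- numeric(n)
  if (dirichlet) {
    bc_diag_V[op$dir_hi$idx] <- bc_diag_V[op$dir_hi$idx] + op$dir_hi$coef
    bc_diag_V[op$dir_lo$idx] <- bc_diag_V[op$dir_lo$idx] + op$dir_lo$coef
    bc_src_V[op$dir_hi$idx] <- bc_src_V[op$dir_hi$idx] + op$dir_hi$coef * V_hi
    bc_src_V[op$dir_lo$idx] <- bc_src_V[op$dir_lo$idx] + op$dir_lo$coef * V_lo
    bc_diag_C <- bc_diag_V  # cleaved pinned to zero at both faces
  } else {
    bc_src_V[op$sec$idx] <- bc_src_V[op$sec$idx] + comp$q * op$sec$coef
    bc_diag_V[op$clr$idx] <- bc_diag_V[op$clr$idx] + comp$k_clear * op$clr$coef
    bc_diag_C[op$clr$idx] <- bc_diag_C[op$clr$idx] + comp$k_clear * op$clr$coef
  }

  dt <- settings$dt0
  delta <- Inf
  history <- numeric(0)
  converged <- FALSE
  step <- 0L
  relchange <- function(new, old) {
    sc <- max(abs(new), .Machine$double.xmin)
    if (sc <= 1e-300) return(0)
    max(abs(new - old) / pmax(abs(new), 1e-8 * sc))
  }

  while (step < settings$max_steps) {
    step <- step + 1L
    V0s <- V; Vc0s <- Vc; VH0s <- VH; Y0s <- if (has_rec) Y

    for (inner in seq_len(settings$n_inner)) {
      if (has_rec) {
        Vloc <- cbind(V[patch_cells], Vc[patch_cells])
        Y <- .surface_advance(if (inner == 1L) Y0s else Y, Vloc, comp, dt)
        uc <- surface_uptake_coefs(Y, comp)
        w <- grid$patches$area /
          (comp$K_ECM * grid$vol[cbind(grid$patches$iz, grid$patches$adj_ir)])
        lamV <- lamC <- sigV <- sigC <- numeric(n)
        lamV[patch_cells] <- uc$lambda[, 1] * w
        lamC[patch_cells] <- uc$lambda[, 2] * w
        sigV[patch_cells] <- uc$sigma[, 1] * w
        sigC[patch_cells] <- uc$sigma[, 2] * w
      } else {
        lamV <- lamC <- sigV <- sigC <- numeric(n)
      }

      # matrix binding with the implicit VH update eliminated analytically:
      # substituting VH(V) = (VH0/dt + konH Htot V) / (1/dt + D_VH + konH V)
      # into the V equation turns the stiff on/off exchange into the mild
      # effective loss konH Htot (1/dt + k_P + k_deg_VH) / den, so the
      # iteration does not stall on the exchange-equilibrium mode
      D_VH <- comp$koff_H + comp$k_P + comp$k_deg_VH
      den <- 1 / dt + D_VH + comp$kon_H * V
      exch_diag <- comp$kon_H * comp$Htot *
        (1 / dt + comp$k_P + comp$k_deg_VH) / den
      exch_src <- (comp$kon_H * V + comp$koff_H) * VH0s / (dt * den)

      diag_V <- 1 / dt + base_diag_V + bc_diag_V + exch_diag + lamV
      b_V <- V0s / dt + exch_src + bc_src_V + sigV
      V <- .sor_solve(op, diag_V, b_V, V, settings)
      VH <- (VH0s / dt + comp$kon_H * V * comp$Htot) /
        (1 / dt + D_VH + comp$kon_H * V)

      diag_C <- 1 / dt + base_diag_C + bc_diag_C + lamC
      b_C <- Vc0s / dt + comp$k_P * (V + VH) + bc_src_C + sigC
      Vc <- .sor_solve(op, diag_C, b_C, Vc, settings)
    }

    delta <- max(relchange(V, V0s), relchange(Vc, Vc0s), relchange(VH, VH0s),
                 if (has_rec) relchange(Y, Y0s) else 0)
    history <- c(history, delta)
    if (settings$verbose && step %% 25L == 0L) {
      message(sprintf("step %4d dt=%8.1f delta=%.3e", step, dt, delta))
    }
    if (delta < settings$tol && dt >= settings$dt_max) {
      if (settings$polish && is.finite(dt)) {
        # infinite-step limit: iterate the steady equations to the fixed
        # point, eliminating residual drift of slow mass-loading modes
        dt <- Inf
        next
      }
      converged <- TRUE
      break
    }
    if (is.finite(dt)) dt <- min(dt * settings$dt_growth, settings$dt_max)
  }

  if (!converged) {
    rlang::abort(sprintf(
      "steady state not reached in %d steps (last per-node change %.3e; tol %.1e); %s",
      step, delta, settings$tol,
      "oscillatory residuals may need a smaller `omega`"),
      class = "vegfgrad_no_convergence", residual_history = history)
  }

  res <- structure(list(
    cfg = cfg, grid = grid, comp = comp, settings = settings,
    V = V, Vc = Vc, VH = VH, H = comp$Htot - VH,
    Y = if (has_rec) Y, patch_cells = if (has_rec) patch_cells,
    steps = step, final_delta = delta, residual_history = history,
    dirichlet = dirichlet
  ), class = "vegf_steady")
  res$flux_balance <- flux_balance(res)
  res
}

#' Domain-wide flux balance of a converged state
#'
#' Integrates every source/sink channel (molecules/s): secretion influx,
#' boundary clearance of each soluble species, interstitial degradation,
#' proteolytic transfer, and receptor internalisation. At steady state the
#' closure residual (secretion minus all sinks) vanishes to solver tolerance.
#'
#' @param res a `vegf_steady` result.
#' @return tibble of channels and rates, with the relative closure as
#'   attribute `"closure"`.
#' @export
flux_balance <- function(res) {
  comp <- res$comp; grid <- res$grid
  op <- assemble_diffusion(grid, res$cfg$transport)
  w <- comp$K_ECM * grid$vol[grid$idx]
  if (res$dirichlet) {
    g <- res$cfg$geometry
    V_hi <- comp$V0 * (1 + comp$g0 * g$L_half / g$L_tip)
    V_lo <- comp$V0 * (1 - comp$g0 * g$L_half / g$L_tip)
    secretion <- sum(comp$D * comp$K_ECM *
                       (V_hi - res$V[op$dir_hi$idx]) / op$dir_hi$half *
                       op$dir_hi$area)
    clear_V <- sum(comp$D * comp$K_ECM *
                     (res$V[op$dir_lo$idx] - V_lo) / op$dir_lo$half *
                     op$dir_lo$area)
    clear_C <- 0
  } else {
    secretion <- comp$q * sum(op$sec$area)
    clear_V <- comp$k_clear * comp$K_ECM *
      sum(res$V[op$clr$idx] * op$clr$area)
    clear_C <- comp$k_clear * comp$K_ECM *
      sum(res$Vc[op$clr$idx] * op$clr$area)
  }
  deg_V <- sum(comp$k_deg_V * res$V * w)
  deg_VH <- sum(comp$k_deg_VH * res$VH * w)
  prot <- sum(comp$k_P * (res$V + res$VH) * w)
  upt_V <- upt_C <- 0
  if (!is.null(res$Y)) {
    sr <- surface_rates(res$Y, cbind(res$V[res$patch_cells],
                                     res$Vc[res$patch_cells]), comp)
    upt_V <- sum(sr$internalised[, 1] * grid$patches$area)
    upt_C <- sum(sr$internalised[, 2] * grid$patches$area)
  }
  closure <- (secretion - clear_V - clear_C - deg_V - deg_VH -
                upt_V - upt_C) / max(secretion, .Machine$double.xmin)
  out <- tibble::tibble(
    channel = c("secretion", "clearance_V", "clearance_Vc", "degradation_V",
                "degradation_VH", "proteolysis", "uptake_V", "uptake_Vc"),
    rate = c(secretion, clear_V, clear_C, deg_V, deg_VH, prot, upt_V, upt_C)
  )
  attr(out, "closure") <- closure
  out
}

#' Calibrate secretion and clearance fluxes (two-stage protocol)
#'
#' Stage 1 solves the scenario with Dirichlet boundary values
#' `V0 (1 +/- g0 L/L_tip)` at z = +/-L, with degradation and proteolysis
#' switched off (receptors, if present, equilibrate during the solve; HSPGs
#' may be omitted since they do not influence the steady soluble field).
#' Stage 2 converts the converged boundary fluxes into the Neumann drive:
#' `q` is the area-averaged secretion-face diffusive flux and `k_clear` the
#' area-averaged clearance-face flux divided by the area-averaged adjacent
#' concentration. The averaging only approximately preserves `V0` and `g0`.
#'
#' @param cfg a `vegf_scenario` (drive mode and any q/k_clear are ignored).
#' @param include_hspg keep the HSPG field during stage 1 (the result must
#'   not depend on this; it is a tested property).
#' @param settings,grid passed to [solve_steady()].
#' @return list with `q` (molecules/um^2/s), `k_clear` (um/s), and the
#'   stage-1 `state`.
#' @export
calibrate_neumann <- function(cfg, include_hspg = FALSE,
                              settings = solver_settings(), grid = NULL) {
  cal <- cfg
  cal$variant <- "hspg_only"
  cal$interstitial <- interstitial_params(
    H_total_ref = if (include_hspg) cfg$interstitial$H_total_ref else 0)
  cal$drive$mode <- "dirichlet_stage"
  validate_scenario(cal)
  st <- solve_steady(cal, settings = settings, grid = grid)
  comp <- st$comp
  op <- assemble_diffusion(st$grid, cal$transport)
  g <- cal$geometry
  V_hi <- comp$V0 * (1 + comp$g0 * g$L_half / g$L_tip)
  V_lo <- comp$V0 * (1 - comp$g0 * g$L_half / g$L_tip)
  flux_hi <- comp$D * comp$K_ECM * (V_hi - st$V[op$dir_hi$idx]) / op$dir_hi$half
  flux_lo <- comp$D * comp$K_ECM * (st$V[op$dir_lo$idx] - V_lo) / op$dir_lo$half
  q <- sum(flux_hi * op$dir_hi$area) / sum(op$dir_hi$area)
  k_clear <- sum(flux_lo * op$dir_lo$area) /
    (comp$K_ECM * sum(st$V[op$dir_lo$idx] * op$dir_lo$area))
  list(q = q, k_clear = k_clear, state = st)
}

#' @export
print.vegf_steady <- function(x, ...) {
  cat(sprintf("<vegf_steady> %s\n", x$cfg$label))
  cat(sprintf("  %d cells, %d steps, final per-node change %.2e\n",
              x$grid$n_active, x$steps, x$final_delta))
  cat(sprintf("  mass-balance closure: %.2e (relative)\n",
              attr(x$flux_balance, "closure")))
  cat(sprintf("  mean soluble V at z=0: %.4g pM\n",
              molec_um3_to_pM(mean(x$V[abs(x$grid$zc[x$grid$idx[, 1]]) < x$grid$dz]))))
  invisible(x)
}
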