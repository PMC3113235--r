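#' Discrete diffusion operator with boundary conditions
#'
#' Assembles the sparse flux-balance operator for one soluble species on a
#' [build_grid()] mesh: second-order central differences of the diffusive
#' fluxes across control-volume faces in (z, r), divided by cell volume, with
#' no-flux conditions at r = R_edge, at the symmetry axis r = 0, and along
#' the sprout wall. Concentrations are per available fluid volume, so the
#' available volume fraction cancels from interior flux balances; it enters
#' only the secretion source and the bookkeeping of molecule counts.
#'
#' Axial boundary conditions are returned as separate ingredients so the
#' solver can switch between the Dirichlet calibration stage and the
#' calibrated Neumann drive:
#' * `dir_hi`, `dir_lo`: indices and coefficients `D A / ((dz/2) Vol)` of the
#'   cells adjacent to z = +L (full face) and z = -L (annulus beside the
#'   sprout).
#' * `sec`: secretion ingredients at z = +L, `A / (K_ECM Vol)` per cell, so a
#'   flux `q` (molecules per um^2 of total face area per s) adds
#'   `q * sec$coef` to dc/dt.
#' * `clr`: clearance ingredients at z = -L; a clearance velocity `k_clear`
#'   removes `k_clear * clr$coef * c` (the K_ECM factors cancel).
#'
#' @param grid a `vegf_grid`.
#' @param transport a [transport_params()] object.
#' @return a list of class `diffusion_op` with the sparse matrix `L`
#'   (dc/dt = L c for the interior problem), its diagonal, off-diagonal part,
#'   red/black colouring, and the boundary ingredient lists.
#' @export
assemble_diffusion <- function(grid, transport) {
  D <- transport$D
  n <- grid$n_active
  iz <- grid$idx[, 1]; ir <- grid$idx[, 2]
  id <- grid$id
  dz <- grid$dz

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }

  # axial neighbours (face area = ring area; distance dz)
  for (k in seq_len(n)) {
    z <- iz[k]; r <- ir[k]
    if (z < grid$nz && grid$active[z + 1L, r]) {
      j <- id[z + 1L, r]
      a <- D * grid$ring_area[r] / dz
      add(k, j, a / grid$vol[z, r])
      add(j, k, a / grid$vol[z + 1L, r])
    }
    if (r < grid$nr && grid$active[z, r + 1L]) {
      j <- id[z, r + 1L]
      a <- D * (2 * pi * grid$rb[r + 1L] * dz) / (grid$rc[r + 1L] - grid$rc[r])
      add(k, j, a / grid$vol[z, r])
      add(j, k, a / grid$vol[z, r + 1L])
    }
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)

  # boundary ingredient lists
  hi <- which(iz == grid$nz)                       # adjacent to z = +L
  lo <- which(iz == 1L & grid$active[cbind(1L, ir)])  # z = -L (annulus if sprout)
  face_hi <- grid$ring_area[ir[hi]]
  face_lo <- grid$ring_area[ir[lo]]
  vol_hi <- grid$vol[cbind(iz[hi], ir[hi])]
  vol_lo <- grid$vol[cbind(iz[lo], ir[lo])]

  op <- list(
    L = L,
    diag = Matrix::diag(L),
    n = n,
    color = (iz + ir) %% 2 == 0,
    dir_hi = list(idx = hi, coef = D * face_hi / ((dz / 2) * vol_hi),
                  area = face_hi, half = dz / 2),
    dir_lo = list(idx = lo, coef = D * face_lo / ((dz / 2) * vol_lo),
                  area = face_lo, half = dz / 2),
    sec = list(idx = hi, coef = face_hi / (transport$K_ECM * vol_hi),
               area = face_hi),
    clr = list(idx = lo, coef = face_lo / vol_lo, area = face_lo),
    D = D, K_ECM = transport$K_ECM
  )
  Ld <- L
  Matrix::diag(Ld) <- 0
  op$Loff <- Ld
  class(op) <- "diffusion_op"
  op
}
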