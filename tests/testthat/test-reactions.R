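make_state <- function(comp, V_pM, VH_pM = NULL, Vc_pM = 0) {
  n <- comp$grid$n_active
  V <- rep(pM_to_molec_um3(V_pM), n)
  VH <- if (is.null(VH_pM)) {
    comp$kon_H * V * comp$Htot / (comp$koff_H + comp$kon_H * V)
  } else rep(pM_to_molec_um3(VH_pM), n)
  list(V = V, Vc = rep(pM_to_molec_um3(Vc_pM), n), VH = VH)
}

test_that("detailed balance zeroes the interstitial rates", {
  cfg <- scenario_config("VEGF165", "hspg_only", drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  st <- make_state(comp, 1)   # VH at binding equilibrium
  r <- interstitial_rates(st, comp)
  expect_lt(max(abs(r$dV)), 1e-16)
  expect_lt(max(abs(r$dVH)), 1e-16)
  expect_lt(max(abs(r$dVc)), 1e-16)
})

test_that("equilibrium bound pool and cleavage source match the linear regime", {
  cfg <- scenario_config("VEGF165", "hspg_only", drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  st <- make_state(comp, 1)
  # [VH] = [V] H_total / Kd at 1 pM, 750 nM, 165 nM
  expect_equal(molec_um3_to_pM(st$VH[1]),
               bound_fraction_with_protease(1, 750, 165), tolerance = 1e-5)
  # proteolysis source: k_P ([V] + [VH])
  cfgP <- scenario_config("VEGF165", "hspg_only", drive = norec_drive(),
                          k_P = 2.8e-4)
  compP <- vegfgrad:::compile_scenario(cfgP)
  stP <- make_state(compP, 1, VH_pM = 4.545)
  r <- interstitial_rates(stP, compP)
  expect_equal(molec_um3_to_pM(r$dVc[1]), 2.8e-4 * (1 + 4.545),
               tolerance = 1e-6)
})

test_that("HSPG sites are conserved by the reaction terms", {
  cfg <- scenario_config("VEGF189", "matrix_deg", drive = norec_drive(),
                         k_P = 2.8e-4)
  comp <- vegfgrad:::compile_scenario(cfg)
  st <- make_state(comp, 0.7, VH_pM = 40)
  r <- interstitial_rates(st, comp)
  # d[H]/dt + d[VH]/dt = 0 pointwise: destroyed VH returns its site
  expect_lt(max(abs(r$dH + r$dVH)), 1e-18)
  # free sites gain the VH-destroying fluxes on top of the exchange
  exchange <- comp$kon_H * st$V * (comp$Htot - st$VH) - comp$koff_H * st$VH
  expect_equal(r$dH, -exchange + (comp$k_P + comp$k_deg_VH) * st$VH,
               tolerance = 1e-15)
  # and proteolysis of VH feeds the cleaved pool together with soluble V
  expect_equal(r$dVc, comp$k_P * (st$V + st$VH), tolerance = 1e-15)
})

test_that("interstitial rates flag bad states", {
  cfg <- scenario_config("VEGF165", "hspg_only", drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  st <- make_state(comp, 1)
  st$V[3] <- NaN
  expect_error(interstitial_rates(st, comp), "cell 3")
  st <- make_state(comp, 1)
  st$V[5] <- -1e-6
  expect_warning(interstitial_rates(st, comp), "negative")
})

test_that("ligand-free surface settles at receptor totals with R1N1 partition", {
  cfg <- scenario_config("VEGF165", "hspg_only",
                         receptors = receptor_params(), drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  Y <- vegfgrad:::surface_rest_state(comp, 3L)
  r <- surface_rates(Y, matrix(0, 3, 2), comp)
  expect_lt(max(abs(r$dY)), 1e-12)
  rec <- comp$rec
  expect_equal(unname(Y[1, "R1"] + Y[1, "R1N1"]), rec$R1T, tolerance = 1e-12)
  expect_equal(unname(Y[1, "N1"] + Y[1, "R1N1"]), rec$N1T, tolerance = 1e-12)
  expect_equal(unname(Y[1, "R2"]), rec$R2T)
  # coupling partition satisfies its steady balance
  expect_equal(unname(rec$kc_R1N1 * Y[1, "R1"] * Y[1, "N1"]),
               unname((rec$kuc_R1N1 + rec$k_int) * Y[1, "R1N1"]), tolerance = 1e-9)
})

test_that("single-receptor occupancy follows the insertion/internalisation balance", {
  cfg <- scenario_config("VEGF165", "hspg_only",
                         receptors = receptor_params(R1_total = 0,
                                                     N1_total = 0),
                         drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  for (V_pM in c(10, 100)) {
    Y <- vegfgrad:::.surface_advance(
      vegfgrad:::surface_rest_state(comp, 1L),
      matrix(pM_to_molec_um3(c(V_pM, 0)), 1, 2), comp, Inf)
    konV <- comp$full$kon_R2 * pM_to_molec_um3(V_pM)
    occ_expected <- konV / (konV + comp$full$koff_R2 + comp$rec$k_int)
    expect_equal(unname(Y[1, "V.R2"]) / comp$rec$R2T, occ_expected, tolerance = 1e-6)
  }
  # at V = Kd = 100 pM, ignoring internalisation, occupancy is 1/2; the
  # turnover correction shifts it below
  Y <- vegfgrad:::.surface_advance(
    vegfgrad:::surface_rest_state(comp, 1L),
    matrix(pM_to_molec_um3(c(100, 0)), 1, 2), comp, Inf)
  expect_lt(unname(Y[1, "V.R2"]) / comp$rec$R2T, 0.5)
  expect_equal(unname(Y[1, "V.R2"]) / comp$rec$R2T, 0.5, tolerance = 0.3)
})

test_that("excess NRP1 drives binding into the coupled VEGFR2 complex", {
  cfg <- scenario_config("VEGF165", "hspg_only",
                         receptors = receptor_params(), drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  y <- surface_steady_fixedpoint(comp, V_pM = 1)
  expect_gt(y["V.R2.N1"], 50 * y["V.R2"])
  # and NRP1 sequesters most VEGFR1 as the R1N1 complex
  expect_gt(y["R1N1"], 10 * y["R1"])
})

test_that("receptor totals are conserved at any surface steady state", {
  cfg <- scenario_config("VEGF121", "hspg_only",
                         receptors = receptor_params(), drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  Y <- vegfgrad:::.surface_advance(
    vegfgrad:::surface_rest_state(comp, 1L),
    matrix(pM_to_molec_um3(c(2, 1)), 1, 2), comp, Inf)
  rec <- comp$rec
  r1 <- sum(Y[1, c("R1", "R1N1", "V.R1", "Vc.R1", "V.R1N1", "Vc.R1N1")])
  r2 <- sum(Y[1, c("R2", "V.R2", "Vc.R2", "V.R2.N1", "Vc.R2.N1")])
  n1 <- sum(Y[1, c("N1", "R1N1", "V.N1", "V.R2.N1", "V.R1N1", "Vc.R1N1")])
  expect_equal(r1, rec$R1T, tolerance = 1e-6)
  expect_equal(r2, rec$R2T, tolerance = 1e-6)
  expect_equal(n1, rec$N1T, tolerance = 1e-6)
})

test_that("surface fluxes map onto adjacent cells with the homogenised weight", {
  cfg <- scenario_config("VEGF165", "hspg_only",
                         receptors = receptor_params(), drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  g <- comp$grid
  np <- length(g$patches$iz)
  bind <- matrix(0, np, 2)
  expect_equal(sum(abs(surface_flux_coupling(g, bind, comp))), 0)
  bind[, 1] <- 1  # 1 molecule/um^2/s on every patch
  sink <- surface_flux_coupling(g, bind, comp)
  cells <- g$id[cbind(g$patches$iz, g$patches$adj_ir)]
  vols <- g$vol[cbind(g$patches$iz, g$patches$adj_ir)]
  expect_equal(sink[cells, 1], g$patches$area / (comp$K_ECM * vols))
  expect_equal(sum(sink[-cells, ]), 0)
})
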