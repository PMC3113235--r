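test_that("figure presets encode the table conditions", {
  f3 <- build_figure_scenario("fig3")
  expect_equal(f3$drive$q, 5.27e-5)
  expect_equal(f3$drive$k_clear, 0.0399)
  expect_equal(f3$interstitial$H_total_ref, 750)
  expect_equal(f3$receptors$R1_total, 1e4)
  expect_equal(f3$receptors$N1_total, 3e4)
  expect_equal(build_figure_scenario("fig3_noHSPG")$interstitial$H_total_ref, 0)
  f4b <- build_figure_scenario("fig4B")
  expect_equal(f4b$interstitial$gH0, 0.30)
  expect_equal(f4b$drive$q, 4.39e-5)
  f4c <- build_figure_scenario("fig4C")
  expect_equal(f4c$interstitial$k_deg_V, 1e-3)
  expect_equal(f4c$interstitial$k_deg_VH, 0)
  f6 <- build_figure_scenario("fig6_iso", isoform = "VEGF189")
  expect_equal(f6$variant, "matrix_deg")
  expect_equal(f6$interstitial$k_P, 2.8e-4)
  expect_null(f6$receptors)
  expect_error(build_figure_scenario("fig99"))
})

test_that("monotonicity classifier distinguishes the three shapes", {
  expect_equal(classify_monotonicity(c(1, 2, 3, 4)), "monotone-consistent")
  expect_equal(classify_monotonicity(c(4, 3, 2, 1)), "monotone-consistent")
  expect_equal(classify_monotonicity(c(1, 3, 2)), "biphasic")
  expect_equal(classify_monotonicity(c(1, 3, 2, 4)), "inconsistent")
  # noise below the relative tolerance does not break monotonicity
  expect_equal(classify_monotonicity(c(1, 2, 2 - 1e-6, 3)),
               "monotone-consistent")
  expect_equal(classify_monotonicity(rep(5, 4)), "monotone-consistent")
})

test_that("a sweep point reproduces the standalone run exactly", {
  spec <- sweep_spec("matrix_deg", Kd_grid = c(165), kP_grid = c(2.8e-4))
  sw <- run_sweep(spec)
  pt <- dplyr::filter(sw$points, .data$axis == "affinity", .data$Kd == 165,
                      .data$k_P == 2.8e-4)
  iso <- make_continuum_isoform(165)
  cfg <- scenario_config(iso, "matrix_deg",
                         drive = boundary_drive(q = 4.39e-5,
                                                k_clear = 0.0948),
                         k_P = 2.8e-4, sprout = FALSE)
  g <- build_grid(geometry_params(), dr_fine = 48, dr_coarse = 48,
                  r_transition = 50, sprout = FALSE)
  st <- solve_steady(cfg, solver_settings(dt_max = 1e5), grid = g)
  m <- vegfgrad:::.tip_region_metrics(st)
  expect_identical(pt$total_soluble, m[["total_soluble"]])
  expect_identical(pt$matrix_bound, m[["matrix_bound"]])
})

test_that("total soluble VEGF is flat against proteases in the binding-only model", {
  spec <- sweep_spec("hspg_only", Kd_grid = c(165),
                     kP_grid = c(1e-6, 1e-4, 1e-2))
  sw <- run_sweep(spec)
  pro <- dplyr::filter(sw$points, .data$axis == "protease")
  ts <- pro$total_soluble
  expect_lt(max(ts) - min(ts), 1e-3 * max(ts))
})

test_that("receptor map on a coarse affinity grid peaks between the anchors", {
  spec <- sweep_spec("matrix_deg",
                     Kd_grid = exp(seq(log(8.5), log(4000), length.out = 9)))
  sw <- cached("sweep_coarse", run_sweep(spec))
  rmp <- receptor_binding_map(sw)
  expect_equal(rmp$classification$class[rmp$classification$receptor == "R2"],
               "biphasic")
  expect_gt(rmp$peak_Kd, 165)
  expect_true(is.finite(rmp$peak_Kd))
  # zero VEGF gives zero occupancy
  comp <- vegfgrad:::compile_scenario(
    scenario_config("VEGF165", "hspg_only", receptors = receptor_params(),
                    drive = norec_drive()))
  y0 <- surface_steady_fixedpoint(comp, 0, 0)
  expect_equal(unname(sum(y0[5:14])), 0, tolerance = 1e-12)
})

test_that("without NRP1 occupancy tracks total soluble VEGF across isoforms", {
  spec <- sweep_spec("matrix_deg",
                     Kd_grid = exp(seq(log(8.5), log(4000), length.out = 9)))
  sw <- cached("sweep_coarse", run_sweep(spec))
  rmp <- receptor_binding_map(sw, receptors = receptor_params(N1_total = 0))
  aff <- dplyr::arrange(
    dplyr::filter(sw$points, .data$axis == "affinity",
                  .data$k_P == sw$spec$kP_fixed, .data$converged), .data$Kd)
  # single-receptor linear regime: occupancy proportional to total soluble
  ratio <- rmp$curves$R2_occupied / aff$total_soluble
  expect_lt(stats::sd(ratio) / mean(ratio), 0.01)
})
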