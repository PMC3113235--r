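test_that("on-rates derive from equilibrium constants", {
  expect_equal(kon_from_kd(0.01, 165), 6.06e4, tolerance = 2e-3)
  expect_equal(kon_from_kd(0.01, 8.5), 1.18e6, tolerance = 3e-3)
  expect_identical(kon_from_kd(0, 42), 0)
  expect_identical(kon_from_kd(0.01, Inf), 0)
  # round-trip identity kon * Kd = koff for finite Kd
  for (Kd in c(0.5, 8.5, 165, 1e4)) {
    expect_equal(kon_from_kd(0.01, Kd) * Kd * 1e-9, 0.01, tolerance = 1e-12)
  }
  expect_error(kon_from_kd(-1, 165), "non-negative")
  expect_error(kon_from_kd(0.01, -5), "positive")
})

test_that("concentration unit conversions are exact and invert", {
  expect_equal(concentration_units(1, "pM"), 6.022e-4)
  expect_identical(concentration_units(0, "pM"), 0)
  expect_equal(concentration_units(750, "nM"), 451.65, tolerance = 1e-6)
  x <- c(0.03, 1, 750, 12345)
  expect_equal(molec_um3_to_pM(pM_to_molec_um3(x)), x, tolerance = 1e-12)
  expect_error(concentration_units(-1, "pM"), "non-negative")
})

test_that("canonical isoforms reproduce the kinetic table", {
  v165 <- canonical_isoform("VEGF165")
  expect_equal(v165$Kd_H, 165)
  expect_equal(v165$kon_H, 6.06e4, tolerance = 2e-3)
  expect_equal(v165$koff_H, 0.01)
  expect_equal(v165$kon_R2, 1e7)
  expect_equal(v165$koff_R2, 1e-3)
  expect_equal(v165$kon_R1, 3e7)
  expect_equal(v165$kon_N1, 3.2e6)
  expect_equal(v165$kc_VR2_N1, 3.1e6)
  expect_equal(v165$kc_VN1_R2, 1e7)
  expect_equal(v165$kon_R1N1, 0)

  v189 <- canonical_isoform("VEGF189")
  expect_equal(v189$Kd_H, 8.5)
  expect_equal(v189$kon_H, 1.18e6, tolerance = 3e-3)
  expect_equal(v189$kon_N1, 3.2e6 * 165 / 8.5)
  expect_equal(v189$kon_R1N1, 0)

  v121 <- canonical_isoform("VEGF121")
  expect_identical(v121$Kd_H, Inf)
  expect_identical(v121$kon_H, 0)
  expect_identical(v121$kon_N1, 0)
  expect_equal(v121$kon_R1N1, 1e7)
  expect_equal(v121$koff_R1N1, 0.01)

  v114 <- canonical_isoform("VEGF114")
  expect_false(v114$cleavable)
  for (f in c("kon_R1", "kon_R2", "kon_N1", "kon_R1N1", "kc_VR1_N1")) {
    expect_identical(v114[[f]], v121[[f]])
  }
})

test_that("continuum isoforms recover the canonical anchors and scale as stated", {
  ref <- canonical_isoform("VEGF165")
  same_rates <- function(a, b) {
    for (f in setdiff(names(a), c("name"))) expect_equal(a[[f]], b[[f]])
  }
  same_rates(make_continuum_isoform(165), ref)
  same_rates(make_continuum_isoform(8.5), canonical_isoform("VEGF189"))
  same_rates(make_continuum_isoform(Inf), canonical_isoform("VEGF121"))

  # stated scaling at Kd = 8.5 nM
  iso <- make_continuum_isoform(8.5)
  expect_equal(iso$kon_N1, 3.2e6 * (165 / 8.5), tolerance = 1e-12)
  expect_equal(iso$kon_N1, 6.21e7, tolerance = 2e-3)
  expect_identical(iso$kon_R1N1, 0)

  # the R1N1 forward multiplier ramps over (165, 330] and clamps at 1
  expect_equal(make_continuum_isoform(247.5)$kon_R1N1, 0.5e7)
  expect_equal(make_continuum_isoform(330)$kon_R1N1, 1e7)
  expect_equal(make_continuum_isoform(1e6)$kon_R1N1, 1e7)
  expect_equal(make_continuum_isoform(164)$kon_R1N1, 0)

  # continuity in 1/Kd: rates change smoothly along a fine grid
  grid <- exp(seq(log(8.5), log(5000), length.out = 60))
  kn <- vapply(grid, function(k) make_continuum_isoform(k)$kon_N1, numeric(1))
  expect_true(all(diff(kn) < 0))
  rel_jump <- abs(diff(kn)) / kn[-length(kn)]
  expect_true(max(rel_jump) < 0.15)
  expect_error(make_continuum_isoform(-1), "positive")
})

test_that("scenario validation catches inconsistent configurations", {
  expect_error(geometry_params(R_sprout = 60), "R_sprout")
  expect_error(transport_params(K_ECM = 1.2))
  cfg <- scenario_config("VEGF165", "hspg_only")
  expect_s3_class(cfg, "vegf_scenario")
  cfg$interstitial$k_deg_V <- 1e-3
  expect_error(validate_scenario(cfg), "hspg_only")
  cfg2 <- scenario_config("VEGF165", "soluble_deg")
  expect_equal(cfg2$interstitial$k_deg_V, 1e-3)
  expect_equal(cfg2$interstitial$k_deg_VH, 0)
  cfg3 <- scenario_config("VEGF165", "matrix_deg")
  expect_equal(cfg3$interstitial$k_deg_VH, 1e-3)
  cfg4 <- scenario_config("VEGF165", "hspg_gradient")
  expect_equal(cfg4$interstitial$gH0, 0.30)
  # cleaved product must be a non-binder
  expect_error(
    scenario_config("VEGF165", "hspg_only",
                    cleaved_isoform = canonical_isoform("VEGF165")),
    "cleaved_isoform")
})
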