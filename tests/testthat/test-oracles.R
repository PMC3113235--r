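test_that("Damkohler number evaluates the stated ratio", {
  expect_equal(damkohler(0.001, 40, 0.01), 160)
  expect_equal(damkohler(0, 40, 0.01), 0)
  expect_equal(damkohler(0.01, 40, 0.01), 1600)
})

test_that("local bound fraction reduces to the equilibrium proportionality", {
  expect_equal(bound_fraction_with_protease(1, 750, 165, k_P = 0),
               750 / 165 * 1, tolerance = 1e-4)
  expect_equal(bound_fraction_with_protease(1, 750, 165, k_P = 0), 4.545,
               tolerance = 2e-4)
  expect_equal(bound_fraction_with_protease(1, 750, 165, k_P = 1e9), 0,
               tolerance = 1e-6)
  expect_identical(bound_fraction_with_protease(1, 750, Inf), 0)
  # k_deg_VH also suppresses the bound pool
  expect_lt(bound_fraction_with_protease(1, 750, 165, k_deg_VH = 0.01),
            bound_fraction_with_protease(1, 750, 165))
})

test_that("loss-free profile is linear with the flux-balance slope", {
  p <- reduced_1d_problem(k_P = 0, Kd = Inf)
  z <- seq(-80, 80, by = 5)
  v <- analytic_1d_profile(p, z)
  slope <- diff(v) / diff(z)
  expect_equal(stats::sd(slope), 0, tolerance = 1e-12)
  expect_equal(slope[1], (p$q / 6.022e-4) / (p$D * p$K_ECM), tolerance = 1e-10)
  expect_equal(p$D_eff, p$D)
})

test_that("effective diffusivity and loss assemble per variant", {
  p <- reduced_1d_problem(Kd = 165, k_P = 2.8e-4, k_deg_V = 1e-3,
                          k_deg_VH = 1e-3)
  br <- 750 / 165
  expect_equal(p$lambda, (2.8e-4 + 1e-3) * (1 + br))
  expect_equal(p$D_eff, 68.6 / (1 + br))
  expect_lte(p$D_eff, p$D)
})

test_that("dense finite differences agree with the closed form", {
  # in equilibrium-binding mode the FD solve discretises exactly the
  # reduced equation of the closed form
  for (args in list(list(Kd = Inf, k_deg_V = 1e-3),
                    list(Kd = 165, k_deg_V = 1e-3, k_deg_VH = 1e-3),
                    list(Kd = 8.5, k_P = 2.8e-4))) {
    p <- do.call(reduced_1d_problem, args)
    sol <- solve_reduced_1d(p, n = 3200, binding = "equilibrium")
    expect_equal(sol$V, analytic_1d_profile(p, sol$z), tolerance = 1e-4)
  }
  # the kinetic bound pool is depressed below equilibrium when its sinks
  # compete with unbinding, and coincides without sinks
  pk <- reduced_1d_problem(Kd = 165, k_P = 2.8e-4, k_deg_VH = 1e-3)
  sk <- solve_reduced_1d(pk)
  se <- solve_reduced_1d(pk, binding = "equilibrium")
  expect_true(all(sk$VH / sk$V < se$VH[1] / se$V[1]))
  p0 <- reduced_1d_problem(Kd = 165)
  expect_equal(solve_reduced_1d(p0)$V, solve_reduced_1d(p0, binding = "equilibrium")$V,
               tolerance = 1e-12)
})

test_that("total soluble is protease-invariant in the matrix-binding-only slab", {
  p0 <- reduced_1d_problem(Kd = 165, k_P = 0)
  p1 <- reduced_1d_problem(Kd = 165, k_P = 2.8e-4)
  s0 <- solve_reduced_1d(p0)
  s1 <- solve_reduced_1d(p1)
  expect_equal(s1$V + s1$Vc, s0$V, tolerance = 1e-6)
})

test_that("surface fixed-point oracle matches the stiff ODE route", {
  cfg <- scenario_config("VEGF165", "hspg_only",
                         receptors = receptor_params(),
                         drive = norec_drive())
  comp <- vegfgrad:::compile_scenario(cfg)
  y_fp <- surface_steady_fixedpoint(comp, V_pM = 1, Vc_pM = 0.2)
  y_ode <- vegfgrad:::.surface_advance(
    vegfgrad:::surface_rest_state(comp, 1L),
    matrix(pM_to_molec_um3(c(1, 0.2)), 1, 2), comp, Inf)[1, ]
  expect_equal(unname(y_fp), unname(y_ode), tolerance = 1e-6)
})
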