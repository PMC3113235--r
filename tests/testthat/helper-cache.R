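# Shared fixtures: heavy steady-state solves are computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fig3_state <- function() cached("fig3", solve_steady(build_figure_scenario("fig3")))
fig3_nohspg_state <- function() cached("fig3_noHSPG",
  solve_steady(build_figure_scenario("fig3_noHSPG")))

# degenerate radial mesh for fast sprout-free reference solves
slab_grid <- function() cached("slab_grid",
  build_grid(geometry_params(), dr_fine = 48, dr_coarse = 48,
             r_transition = 50, sprout = FALSE))

fast <- function() solver_settings(dt_max = 1e5)

norec_drive <- function() boundary_drive(V0 = 1, g0 = 0.05,
                                         q = 4.39e-5, k_clear = 0.0948)
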