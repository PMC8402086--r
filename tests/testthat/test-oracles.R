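test_that("radial oracle: no consumption gives the uniform jump solution", {
  orc <- radial_mm_oracle(within_spec(oxygen_spec(), Vmax = 1e-30), 150, 0.2,
                          n_points = 1000)
  expect_equal(orc$c, rep(4.81 * 0.2, length(orc$c)), tolerance = 1e-9)
  expect_equal(orc$necrotic_radius, 0)
})

test_that("radial oracle matches the zero-order kinetics closed form", {
  # c >> Km: c(r) = c_R - (Vmax / 6 D)(R^2 - r^2) for the sphere
  spec <- within_spec(oxygen_spec(), Km = 0.00463 / 1000, Vmax = 5e-3,
                      necrotic_threshold = 1e-6, quiescent_threshold = 2e-6)
  R <- 150e-6
  orc <- radial_mm_oracle(spec, 150, 0.2, n_points = 4000)
  c_exact <- 4.81 * 0.2 - spec$Vmax / (6 * spec$D_spheroid) * (R^2 - orc$r^2)
  expect_lt(max(abs(orc$c - c_exact)) / max(c_exact), 1e-3)
  # cylinder variant: quarter instead of sixth
  orc2 <- radial_mm_oracle(spec, 150, 0.2, n_points = 4000,
                           geometry = "cylinder")
  c_ex2 <- 4.81 * 0.2 - spec$Vmax / (4 * spec$D_spheroid) * (R^2 - orc2$r^2)
  expect_lt(max(abs(orc2$c - c_ex2)) / max(c_ex2), 1e-3)
})

test_that("radial oracle converges at second order in the grid", {
  spec <- oxygen_spec()
  centre <- vapply(c(250, 500, 1000, 2000), function(n) {
    radial_mm_oracle(spec, 150, 0.15, n_points = n)$c[1]
  }, numeric(1))
  # Richardson: successive differences shrink by ~4 per doubling
  d <- abs(diff(centre))
  rates <- d[-length(d)] / d[-1]
  expect_gt(min(rates), 3.4)
  expect_lt(max(rates), 4.6)
})

test_that("resonance scan finds the cavity half-wave and obeys scaling", {
  fl <- water_25C()
  delta <- viscous_penetration_depth(fl, 2 * pi * 2e6)
  coarse <- mesh_spec(n_boundary_layers = 1, bl_total_um = 2,
                      h_well_um = 8, h_channel_um = 8)
  mesh <- generate_mesh(build_validation_geometry(380, 160), coarse, delta)
  f_half <- fl$ca / (2 * 380e-6)
  sc <- resonance_scan(mesh, fl, f_half * c(0.9, 1.1), n = 41,
                       actuation_direction = c(1, 0))
  expect_lt(abs(sc$f_peak - f_half) / f_half, 0.02)
  # doubling the cavity width halves the resonance
  mesh2 <- generate_mesh(build_validation_geometry(760, 160), coarse, delta)
  sc2 <- resonance_scan(mesh2, fl, f_half / 2 * c(0.9, 1.1), n = 41,
                        actuation_direction = c(1, 0))
  expect_lt(abs(sc2$f_peak - f_half / 2) / (f_half / 2), 0.02)
  # weaker damping sharpens the peak
  scd <- resonance_scan(mesh, fl, f_half * c(0.97, 1.03), n = 61,
                        extra_damping = 2e-3, actuation_direction = c(1, 0))
  scs <- resonance_scan(mesh, fl, f_half * c(0.97, 1.03), n = 61,
                        extra_damping = 2e-4, actuation_direction = c(1, 0))
  width <- function(s) {
    half <- max(s$response) / 2
    mean(s$response > half)
  }
  expect_lt(width(scs), width(scd))
})

test_that("diffusion core shows at least second-order convergence", {
  ord <- poisson_mms_order(c(100, 50, 25))
  expect_gte(ord$order, 1.9)
})
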