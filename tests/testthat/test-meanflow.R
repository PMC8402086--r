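test_that("inlet profile is the plane-Poiseuille parabola with the right scale", {
  g <- chip_geometry()
  prof <- inlet_profile(1, g)
  # 1 uL/min over a 1000 x 1000 um cross-section
  expect_equal(attr(prof, "U_mean"), 1e-9 / 60 / (1e-3 * 1e-3))
  expect_equal(attr(prof, "U_mean"), 1.667e-5, tolerance = 1e-3)
  expect_equal(attr(prof, "U_peak"), 1.5 * attr(prof, "U_mean"))
  expect_equal(prof(0.5e-3), attr(prof, "U_peak"))
  expect_equal(prof(0), 0)
  # exact linearity in Q
  expect_equal(attr(inlet_profile(4, g), "U_mean"),
               4 * attr(prof, "U_mean"))
  expect_equal(attr(inlet_profile(0, g), "U_peak"), 0)
  expect_error(chip_geometry(out_of_plane_depth = 0), "out_of_plane_depth")
})

test_that("Couette oracle: uniform shear gives tau = mu * gdot everywhere", {
  fl <- fluid_properties()
  dom <- build_validation_geometry(200, 100)
  dom$side_tags <- list(left = "inlet", right = "outlet",
                        bottom = "floor", top = "lid")
  mesh <- generate_mesh(dom, mesh_spec(n_boundary_layers = 1,
                                       bl_total_um = 5, h_well_um = 10,
                                       h_channel_um = 10), 1e-6)
  H <- 100e-6
  gdot <- 50  # 1/s
  lid <- matrix(0, nrow(mesh$nodes), 2)
  lid_nodes <- acoustochip:::nodes_on_tags(mesh, "lid")
  lid[lid_nodes, 1] <- gdot * H
  flow <- solve_mean_flow(mesh, fl, forcing = NULL, perfusion = NULL,
                          slip = lid)
  # linear velocity profile reproduced to discretization accuracy
  expect_equal(flow$vel_p1[, 1], gdot * mesh$nodes[, 2], tolerance = 1e-6)
  ws <- wall_shear_stress(flow, "floor")
  expect_equal(ws$tau_Pa, rep(fl$mu * gdot, length(ws$tau_Pa)),
               tolerance = 1e-6)
  expect_equal(ws$tau_max_dyn_cm2, fl$mu * gdot * 10, tolerance = 1e-6)
})

test_that("net submerged weight follows the configured density closed form", {
  r <- tiny_case(0, 1, keep_fields = TRUE)
  lf <- lift_force(r$flow)
  expect_equal(lf$net_weight_N,
               (1050 - 993.3) * 9.81 * pi / 6 * (300e-6)^3)
  expect_equal(lf$net_weight_N, 7.86e-9, tolerance = 1e-3)
})

test_that("pure perfusion flow: parallel channel flow, mass conserved, spheroid at rest", {
  r <- tiny_case(0, 1, keep_fields = TRUE)
  flow <- r$flow
  prof <- inlet_profile(1, chip_geometry())
  # peak speed within 10% of the inlet parabola peak
  expect_lt(abs(max(sqrt(flow$ux^2 + flow$uy^2)) - attr(prof, "U_peak")) /
              attr(prof, "U_peak"), 0.1)
  qin <- flow_flux(flow, "inlet")
  qout <- flow_flux(flow, "outlet")
  expect_lt(abs(qin + qout) / abs(qin), 1e-3)
  expect_equal(-qin, attr(prof, "U_mean") * 1e-3, tolerance = 1e-3)
  # no flow inside the spheroid subdomain (excluded from the flow space)
  mesh <- r$mesh
  sph_nodes <- setdiff(seq_len(nrow(mesh$nodes)),
                       attr(acoustochip:::submesh(mesh, 1L), "node_map"))
  vel_full <- matrix(0, nrow(mesh$nodes), 2)
  vel_full[attr(acoustochip:::submesh(mesh, 1L), "node_map"), ] <- flow$vel_p1
  expect_true(all(vel_full[sph_nodes, ] == 0))
})

test_that("no forcing and no inflow yields identically zero flow", {
  sc <- make_scenario_sweep(scenario(), 0, 0)[[1]]
  r <- run_case(sc, mspec = tiny_spec(), cache = tiny_cache(),
                keep_fields = TRUE)
  expect_equal(max(abs(r$flow$ux)), 0)
  expect_equal(max(abs(r$flow$uy)), 0)
  expect_equal(r$report$tau_max_dyn_cm2, 0)
  expect_equal(r$report$lift_N, 0)
})

test_that("creeping flow matches the Stokes limit within 1%", {
  fl <- fluid_properties()
  cache <- tiny_cache()
  sc <- make_scenario_sweep(scenario(), 0, 1)[[1]]
  r <- run_case(sc, mspec = tiny_spec(), cache = cache, keep_fields = TRUE)
  med <- r$flow$mesh
  stokes <- solve_mean_flow(med, fl, perfusion = perfusion_spec(1),
                            max_iter = 1, tol = Inf)
  sc_ref <- max(sqrt(r$flow$ux^2 + r$flow$uy^2))
  dev <- max(sqrt((r$flow$ux - stokes$ux)^2 + (r$flow$uy - stokes$uy)^2))
  expect_lt(dev / sc_ref, 0.01)
})
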