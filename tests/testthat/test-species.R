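test_that("Michaelis-Menten rate: half saturation, zero, and table values", {
  expect_equal(michaelis_menten_rate(0.00463, 0.0203, 0.00463), 0.0203 / 2)
  expect_equal(michaelis_menten_rate(0, 0.0203, 0.00463), 0)
  expect_equal(michaelis_menten_rate(0.2, 0.0203, 0.00463),
               0.0203 * 0.2 / (0.2 + 0.00463))
  expect_equal(michaelis_menten_rate(0.2, 0.0203, 0.00463), 0.019841,
               tolerance = 1e-4)
  expect_warning(michaelis_menten_rate(-0.1, 0.0203, 0.00463), "clamped")
})

test_that("interface coupling transform and its degenerate limits", {
  ict <- interface_coupling_transform(oxygen_spec())
  expect_equal(unname(ict$S_region["spheroid"]), 4.81)
  expect_equal(unname(ict$D_eff["spheroid"]), 1.83e-9 * 4.81)
  # oxygen jump arithmetic: medium 0.2 mM -> aggregate side 0.962 mM
  expect_equal(4.81 * 0.2, 0.962)
  # glucose has no jump
  ict_gl <- interface_coupling_transform(glucose_spec())
  expect_equal(unname(ict_gl$S_region["spheroid"]), 1)
  bad <- oxygen_spec(); bad$S <- -1
  expect_error(interface_coupling_transform(bad), "positive")
})

test_that("species spec invariants", {
  expect_error(species_spec("x", 1e-9, 1e-9, 1, 0.01, 0.04, 5,
                            necrotic_threshold = 0.5,
                            quiescent_threshold = 0.2), "thresholds")
  expect_error(species_spec("x", -1e-9, 1e-9, 1, 0.01, 0.04, 5, 0.2, 0.5),
               "positive")
})

test_that("no sink and no jump degenerates to the uniform inlet solution", {
  r <- tiny_case(0, 1, keep_fields = TRUE)
  mesh <- r$mesh
  vel_full <- matrix(0, nrow(mesh$nodes), 2)
  vel_full[attr(acoustochip:::submesh(mesh, 1L), "node_map"), ] <-
    r$flow$vel_p1
  sp_unif <- species_spec("inert", 2.6e-9, 1.83e-9, S = 1, Vmax = 1e-30,
                          Km = 0.00463, c0_inlet = 0.2,
                          necrotic_threshold = 0.002644,
                          quiescent_threshold = 0.01322)
  conc <- solve_species(mesh, vel_full, sp_unif)
  expect_equal(conc$u, rep(0.2, nrow(mesh$nodes)), tolerance = 1e-9)
  expect_equal(average_concentration(conc), 0.2, tolerance = 1e-9)
  # with a jump but no sink, the aggregate side sits at S * c0
  sp_jump <- sp_unif; sp_jump$S <- 4.81
  conc2 <- solve_species(mesh, vel_full, sp_jump)
  expect_equal(average_concentration(conc2), 4.81 * 0.2, tolerance = 1e-8)
  expect_equal(average_concentration(conc2, "medium"), 0.2, tolerance = 1e-9)
})

test_that("2D disk solve agrees with the 1D cylindrical oracle", {
  # spheroid-only polar mesh with a fixed medium-side surface concentration
  dom <- build_chip_geometry(chip_geometry())
  mesh <- generate_mesh(dom, mesh_spec(n_boundary_layers = 2,
                                       bl_total_um = 6, h_well_um = 10,
                                       h_channel_um = 80), 5e-7)
  disk <- submesh(mesh, 2L)
  spec <- oxygen_spec()
  c_surf <- 0.15
  conc <- solve_species(disk, NULL, spec,
                        dirichlet = list(spheroid_interface = c_surf))
  orc <- radial_mm_oracle(spec, 150, c_surf, n_points = 4000,
                          geometry = "cylinder")
  # compare radial profiles (aggregate side) in L2
  rr <- sqrt((disk$nodes[, 1] - 1000e-6)^2 + (disk$nodes[, 2] + 190e-6)^2)
  c_oracle <- approx(orc$r, orc$c, xout = pmin(rr, 150e-6))$y
  w <- acoustochip:::lumped_area(disk)
  relL2 <- sqrt(sum(w * (conc$c_spheroid - c_oracle)^2) /
                  sum(w * c_oracle^2))
  expect_lt(relL2, 0.005)
})

test_that("steady-state influx balances total consumption", {
  r <- tiny_case(0, 1, keep_fields = TRUE)
  mesh <- r$mesh
  vel_full <- matrix(0, nrow(mesh$nodes), 2)
  vel_full[attr(acoustochip:::submesh(mesh, 1L), "node_map"), ] <-
    r$flow$vel_p1
  cons <- species_conservation(r$concentrations$oxygen, vel_full)
  expect_lt(cons$rel_imbalance, 0.005)
  expect_gt(cons$consumption, 0)
})
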