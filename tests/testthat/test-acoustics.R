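fl25 <- water_25C()

# small shaken strip cavity used by several first-order checks
strip_mesh <- function(W_um = 300, H_um = 60, h_um = 5) {
  dom <- build_validation_geometry(W_um, H_um)
  delta <- viscous_penetration_depth(fl25, 2 * pi * 2e6)
  generate_mesh(dom, mesh_spec(n_boundary_layers = 4, h_well_um = h_um,
                               h_channel_um = h_um, growth_rate = 1.5),
                delta)
}

shaken_bc <- function(om, d0) {
  list(actuated_wall = c(om * d0 + 0i, 0i), rigid_wall = "noslip")
}

test_that("zero actuation short-circuits to identically zero fields", {
  mesh <- strip_mesh(h_um = 15)
  fo <- solve_first_order(mesh, fl25, acoustic_actuation(f = 2e6, d0 = 0))
  expect_true(all(fo$p1 == 0) && all(fo$V1 == 0) && all(fo$T1 == 0))
  fz <- assemble_streaming_forcing(fo, fl25)
  expect_true(all(fz$body_force == 0) && all(fz$mass_source == 0))
  expect_true(all(slip_velocity(fo, "rigid_wall") == 0))
})

test_that("first-order fields scale linearly in d0; forcing quadratically", {
  mesh <- strip_mesh(h_um = 10)
  f <- 1.5e6; om <- 2 * pi * f
  fo1 <- solve_first_order(mesh, fl25, acoustic_actuation(f = f, d0 = 0.1e-9),
                           bc_map = shaken_bc(om, 0.1e-9),
                           include_temperature = TRUE, actuation_phase = 1)
  fo2 <- solve_first_order(mesh, fl25, acoustic_actuation(f = f, d0 = 0.2e-9),
                           bc_map = shaken_bc(om, 0.2e-9),
                           include_temperature = TRUE, actuation_phase = 1)
  expect_lt(max(Mod(fo2$p1 - 2 * fo1$p1)) / max(Mod(fo2$p1)), 1e-6)
  expect_lt(max(Mod(fo2$V1 - 2 * fo1$V1)) / max(Mod(fo2$V1)), 1e-6)
  expect_lt(max(Mod(fo2$T1 - 2 * fo1$T1)) / max(Mod(fo2$T1)), 1e-6)
  fz1 <- assemble_streaming_forcing(fo1, fl25)
  fz2 <- assemble_streaming_forcing(fo2, fl25)
  expect_lt(max(abs(fz2$body_force - 4 * fz1$body_force)) /
              max(abs(fz2$body_force)), 1e-6)
  expect_lt(max(abs(fz2$mass_source - 4 * fz1$mass_source)) /
              max(abs(fz2$mass_source)), 1e-6)
})

test_that("off-resonance strip reproduces the 1D damped-cavity closed form", {
  # shaken 1D cavity: p(x) = i omega rho0 v0 sin(k(x - W/2)) / (k cos(kW/2))
  W <- 300e-6
  mesh <- strip_mesh(300, 60, 5)
  f <- 0.8 * fl25$ca / (2 * W)  # well off the half-wave resonance
  om <- 2 * pi * f
  d0 <- 0.1e-9
  fo <- solve_first_order(mesh, fl25, acoustic_actuation(f = f, d0 = d0),
                          bc_map = shaken_bc(om, d0),
                          include_temperature = FALSE, actuation_phase = 1)
  k <- om / fl25$ca
  v0 <- om * d0
  mid <- abs(mesh$nodes[, 2] - 30e-6) < 3e-6 &
    mesh$nodes[, 1] > 0.1 * W & mesh$nodes[, 1] < 0.9 * W
  p_exact <- 1i * om * fl25$rho0 * v0 *
    sin(k * (mesh$nodes[mid, 1] - W / 2)) / (k * cos(k * W / 2))
  expect_lt(max(Mod(fo$p1[mid] - p_exact)) / max(Mod(p_exact)), 0.05)
})

test_that("uniform-field forcing reduces to the hand-evaluated time average", {
  # V1 uniform, rho1 uniform: convective term and mass source vanish and
  # the body force is -<rho1 dtV1> = -0.5 Re(-i om V1 conj(rho1))
  mesh <- strip_mesh(h_um = 15)
  om <- 2 * pi * 1e6
  fo <- acoustochip:::zero_first_order(mesh, om, 1e-9, "thermoviscous")
  n <- nrow(mesh$nodes)
  fo$V1 <- cbind(rep(0.3 + 0.1i, n), rep(0, n))
  fo$rho1 <- rep(2e-3 - 1e-3i, n)
  fz <- assemble_streaming_forcing(fo, fl25)
  expected_x <- -0.5 * Re(-1i * om * (0.3 + 0.1i) * Conj(2e-3 - 1e-3i))
  expect_equal(fz$body_force[, 1], rep(expected_x, nrow(mesh$tri)))
  expect_equal(max(abs(fz$mass_source)), 0, tolerance = 1e-20)
})

test_that("Rayleigh slip of a synthetic standing wave matches the closed form", {
  mesh <- strip_mesh(300, 60, 5)
  om <- 2 * pi * 2e6
  W <- 300e-6
  k <- 2 * pi / W
  fo <- acoustochip:::zero_first_order(mesh, om, 1e-9, "helmholtz")
  va <- 0.5
  fo$V1[, 1] <- va * sin(k * mesh$nodes[, 1])
  sl <- slip_velocity(fo, "rigid_wall")
  bottom <- acoustochip:::nodes_on_tags(mesh, "rigid_wall")
  bottom <- bottom[mesh$nodes[bottom, 2] < 1e-9]
  x <- mesh$nodes[bottom, 1]
  interior <- x > 0.1 * W & x < 0.9 * W
  u_exact <- -(3 / (8 * om)) * va^2 * k * sin(2 * k * x)
  expect_lt(max(abs(sl[bottom[interior], 1] - u_exact[interior])) /
              max(abs(u_exact)), 0.02)
})

test_that("classical slip scale estimate", {
  expect_equal(rayleigh_slip_estimate(1, 1502), 3 / 8 / 1502)
  expect_equal(rayleigh_slip_estimate(1, 1502), 2.497e-4, tolerance = 1e-3)
  expect_equal(rayleigh_slip_estimate(0, 1502), 0)
  expect_equal(rayleigh_slip_estimate(2, 1502),
               4 * rayleigh_slip_estimate(1, 1502))
})

test_that("acoustic power input through the actuated wall is non-negative", {
  # time-averaged power = int 0.5 Re(p1 conj(v_n)) over the driven wall
  mesh <- strip_mesh(300, 60, 6)
  f <- 1.9 * fl25$ca / (2 * 300e-6) / 2  # near resonance drive
  om <- 2 * pi * f
  d0 <- 0.1e-9
  fo <- solve_first_order(mesh, fl25, acoustic_actuation(f = f, d0 = d0),
                          bc_map = shaken_bc(om, d0),
                          include_temperature = FALSE, actuation_phase = 1)
  ed <- acoustochip:::boundary_edges(mesh, "actuated_wall")
  len <- acoustochip:::edge_lengths(mesh, ed)
  # left wall normal -x, right wall +x; wall velocity (om d0, 0)
  # power in = -int <p1 V1>.n over the fluid boundary (n outward)
  nx <- ifelse(mesh$nodes[ed[, 1], 1] < 150e-6, -1, 1)
  pm <- (fo$p1[ed[, 1]] + fo$p1[ed[, 2]]) / 2
  P <- -sum(0.5 * Re(pm * Conj(om * d0)) * nx * len)
  expect_gt(P, 0)
})
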