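test_that("cavity benchmark reproduces classical Rayleigh streaming", {
  bm <- benchmark_run()
  s <- bm$summary
  # resonant amplification: in-plane first-order velocity far above the
  # wall velocity scale omega*d0, reaching the order of m/s
  wall_v <- 2 * pi * 1.97e6 * 0.1e-9
  expect_gt(s$u1_max, 100 * wall_v)
  expect_gt(s$u1_max, 0.1)
  # transverse component orders of magnitude smaller than the axial one
  expect_lt(s$v1_max, 0.2 * s$u1_max)
  # four bulk vortices per half wavelength: checkerboard vorticity signs
  qv <- bm$quadrant_vorticity
  expect_equal(sign(qv[1, 1]), -sign(qv[1, 2]))
  expect_equal(sign(qv[1, 1]), -sign(qv[2, 1]))
  expect_equal(sign(qv[1, 1]), sign(qv[2, 2]))
  # streaming magnitude within a factor 2 of the classical slip scale
  ratio <- s$streaming_max_bulk / s$slip_scale
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  # half-wave standing pressure: node near the cavity centre, antinodes at
  # the side walls
  fo <- bm$first_order
  mesh <- bm$mesh
  W <- 380e-6; H <- 160e-6
  inner <- mesh$nodes[, 2] > 0.3 * H & mesh$nodes[, 2] < 0.7 * H
  centre <- inner & abs(mesh$nodes[, 1] - W / 2) < 0.05 * W
  wall_l <- inner & mesh$nodes[, 1] < 0.08 * W
  expect_lt(median(Mod(fo$p1[centre])), 0.2 * median(Mod(fo$p1[wall_l])))
})

test_that("benchmark profile is sampled on the quarter-width line", {
  bm <- benchmark_run()
  expect_equal(bm$sample_x, 380e-6 / 4, tolerance = 0.03)
  expect_true(all(diff(bm$profile$y) > 0))
  expect_gt(nrow(bm$profile), 20)
})

test_that("zero-amplitude benchmark yields identically zero profiles", {
  bm0 <- run_muller_benchmark(h_um = 10, d0 = 0)
  expect_true(all(bm0$profile[, -1] == 0))
})

test_that("benchmark warns when driven away from the half-wave resonance", {
  expect_warning(run_muller_benchmark(h_um = 12, f = 1.7e6, d0 = 0),
                 "resonance")
})
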