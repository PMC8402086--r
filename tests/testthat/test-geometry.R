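test_that("chip domain area matches closed-form arithmetic", {
  dom <- build_chip_geometry(chip_geometry())
  expect_equal(dom$area * 1e12, 2000 * 1000 + 450 * 380 - pi * 150^2,
               tolerance = 1e-12)
  expect_equal(dom$area * 1e12, 2.100e6, tolerance = 1e-3)
  # degenerate hole: valid domain without spheroid
  dom0 <- build_chip_geometry(chip_geometry(spheroid_diameter = 0))
  expect_equal(dom0$area * 1e12, 2000 * 1000 + 450 * 380)
})

test_that("geometry invariants are enforced by name", {
  expect_error(chip_geometry(spheroid_diameter = 500), "well_width")
  expect_error(chip_geometry(spheroid_diameter = 400), "well_height")
  expect_error(chip_geometry(channel_height = -1), "channel_height")
  # off-centre spheroid poking out of the well
  expect_error(chip_geometry(spheroid_center = c(1000, -30)),
               "strictly inside")
})

test_that("validation cavity geometry and half-wave resonance", {
  dom <- build_validation_geometry(380, 160)
  expect_equal(dom$area * 1e12, 60800)
  # analytic half-wave estimate ca/(2W) vs the nominal benchmark drive
  f_half <- 1502 / (2 * 380e-6)
  expect_lt(abs(f_half - 1.97e6) / 1.97e6, 0.005)
  sq <- build_validation_geometry(200, 200)
  expect_equal(sq$W, sq$H)
  expect_error(build_validation_geometry(-1, 10), "> 0")
})

test_that("scenario sweeps expand as cartesian products", {
  base <- scenario()
  expect_length(make_scenario_sweep(base, c(0, 0.5), 1), 2)
  s5 <- make_scenario_sweep(base, c(0.1, 0.2, 0.3, 0.4, 0.5), 1)
  expect_length(s5, 5)
  expect_equal(vapply(s5, function(s) s$actuation$d0, 0),
               c(0.1, 0.2, 0.3, 0.4, 0.5) * 1e-9)
  expect_length(make_scenario_sweep(base, c(0, 0.5), numeric(0)), 0)
  lg <- make_scenario_sweep(base, 0.5, 1, overrides = list(low_glucose = TRUE))
  expect_equal(lg[[1]]$species$glucose$c0_inlet, 1)
})
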