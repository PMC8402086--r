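test_that("viscous penetration depth follows sqrt(2 nu / omega)", {
  fl <- fluid_properties()
  om <- 2 * pi * 1e6
  expect_equal(viscous_penetration_depth(fl, om),
               sqrt(2 * (6.92e-4 / 993.3) / om))
  expect_equal(viscous_penetration_depth(fl, om), 4.71e-7,
               tolerance = 1e-3)
  # scaling law: quadrupling omega halves delta
  expect_equal(viscous_penetration_depth(fl, 4 * om),
               viscous_penetration_depth(fl, om) / 2)
  # 25 degC water reproduces the ~0.53 um figure at 1 MHz
  expect_equal(viscous_penetration_depth(
    fluid_properties(mu = 8.9e-4, rho0 = 997, ca = 1497,
                     beta0 = 1 / (997 * 1497^2)), om),
    5.3e-7, tolerance = 0.02)
  expect_error(viscous_penetration_depth(fl, 0), "positive")
})

test_that("fluid state must be acoustically consistent", {
  # ca and the isentropic compressibility must agree within 1%
  expect_error(fluid_properties(ca = 1400), "inconsistent")
  fl <- fluid_properties()
  expect_equal(1 / sqrt(fl$rho0 * fl$beta0), fl$ca, tolerance = 0.003)
  expect_equal(fl$nu, fl$mu / fl$rho0)
  expect_gt(fl$Dth, 0)
  # dilatational viscosity muB + 4mu/3 recovered from the ratio
  expect_equal(fl$mu * (fl$beta_ratio + 1), fl$muB + 4 * fl$mu / 3)
})

test_that("harmonic time averaging of products", {
  expect_equal(harmonic_time_average(1 + 0i, 1 + 0i), 0.5)
  expect_equal(harmonic_time_average(1 + 0i, 1i), 0)  # quadrature signals
  expect_equal(harmonic_time_average(2 + 0i, 1 - 1i), 1.0)
  # direct numerical time integration over one period as oracle
  tt <- seq(0, 2 * pi, length.out = 20001)[-1]
  num <- mean(Re((2 + 0i) * exp(-1i * tt)) * Re((1 - 1i) * exp(-1i * tt)))
  expect_equal(harmonic_time_average(2 + 0i, 1 - 1i), num, tolerance = 1e-6)
  # vectorised
  expect_equal(harmonic_time_average(c(1, 2i), c(1, 2i)), c(0.5, 2))
})
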