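# synthetic concentration fields on a small disk mesh
disk_fixture <- function() {
  memo("disk_fixture", function() {
    dom <- build_chip_geometry(chip_geometry())
    mesh <- generate_mesh(dom, mesh_spec(n_boundary_layers = 2,
                                         bl_total_um = 6, h_well_um = 12,
                                         h_channel_um = 120), 5e-7)
    mesh
  })
}

const_field <- function(mesh, spec, value) {
  structure(list(mesh = mesh, u = rep(value / spec$S, nrow(mesh$nodes)),
                 spec = spec, c_medium = rep(value / spec$S, nrow(mesh$nodes)),
                 c_spheroid = rep(value, nrow(mesh$nodes))),
            class = "concentration_field")
}

test_that("uniform fields classify as single zones and fractions sum to 100", {
  mesh <- disk_fixture()
  cO2 <- const_field(mesh, oxygen_spec(), 0.2)
  cGl <- const_field(mesh, glucose_spec(), 5)
  zf <- zone_fractions(classify_zones(cO2, cGl))
  for (crit in names(zf$fractions)) {
    expect_equal(unname(zf$fractions[[crit]]["proliferating"]), 100)
    expect_equal(sum(zf$fractions[[crit]]), 100, tolerance = 1e-10)
  }
  # far below the lethal oxygen threshold: union rule makes all necrotic
  cO2n <- const_field(mesh, oxygen_spec(), 0.001)
  zfn <- zone_fractions(classify_zones(cO2n, cGl))
  expect_equal(unname(zfn$fractions$combined["necrotic"]), 100)
  expect_equal(unname(zfn$fractions$glucose["necrotic"]), 0)
  # intersection rule instead requires both species below threshold
  zi <- zone_fractions(classify_zones(cO2n, cGl,
                                      zone_thresholds(combination_rule = "intersection")))
  expect_equal(unname(zi$fractions$combined["necrotic"]), 0)
})

test_that("level-set quadrature resolves a constructed half-disc split", {
  mesh <- disk_fixture()
  # linear oxygen field crossing its necrotic threshold on the horizontal
  # diameter: exactly half the disc is necrotic
  thr <- zone_thresholds()
  cy <- -190e-6
  grad <- 1e3  # mM per metre of height
  vals <- thr$necrotic_O2 + grad * (mesh$nodes[, 2] - cy)
  cO2 <- const_field(mesh, oxygen_spec(), 0)
  cO2$c_spheroid <- vals
  cGl <- const_field(mesh, glucose_spec(), 5)
  zf <- zone_fractions(classify_zones(cO2, cGl, thr))
  expect_equal(unname(zf$fractions$oxygen["necrotic"]), 50, tolerance = 0.01)
  expect_equal(sum(zf$fractions$oxygen), 100, tolerance = 1e-8)
})

test_that("flow-rate equivalence factor interpolates the sweep", {
  # reference equals a sweep member
  eq <- equivalent_flow_rate(1:12, seq(45, 1, length.out = 12), 45)
  expect_equal(eq$ratio, 1)
  # constructed piecewise-linear crossing: necrotic = 48 - 4 Q, target 30
  eq2 <- equivalent_flow_rate(1:12, 48 - 4 * (1:12), 30)
  expect_true(eq2$attained)
  expect_equal(eq2$ratio, 4.5)
  # unattainable reference
  eq3 <- equivalent_flow_rate(1:3, c(40, 35, 30), 5)
  expect_false(eq3$attained)
  expect_equal(eq3$closest, 30)
})

test_that("report writer round-trips and handles empty input", {
  tmp <- tempfile(fileext = ".csv")
  jmp <- tempfile(fileext = ".json")
  r <- tiny_case(0, 1)
  df <- write_report(list(r$report, r$report, r$report, r$report, r$report),
                     tmp, jmp)
  expect_equal(nrow(df), 5)
  back <- utils::read.csv(tmp)
  expect_equal(back$avg_O2_mM, df$avg_O2_mM, tolerance = 1e-12)
  expect_true(file.exists(jmp))
  df0 <- write_report(list(), tmp)
  expect_equal(nrow(df0), 0)
  expect_equal(nrow(utils::read.csv(tmp)), 0)
})
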