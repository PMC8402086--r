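fl <- fluid_properties()
delta <- viscous_penetration_depth(fl, 2 * pi * 1e6)

test_that("default chip mesh resolves the protocol scale and partitions the domain", {
  dom <- build_chip_geometry(chip_geometry())
  m <- generate_mesh(dom, mesh_spec(), delta)
  # element count at the full protocol resolution: order 4e4
  expect_gt(n_elements(m), 1.5e4)
  expect_lt(n_elements(m), 2e5)
  A <- tri_areas(m)
  expect_lt(abs(sum(A[m$region == 1]) - dom$area) / dom$area, 1e-3)
  expect_lt(abs(sum(A[m$region == 2]) - dom$spheroid_area) /
              dom$spheroid_area, 1e-3)
  expect_setequal(unique(m$btag),
                  c("inlet", "outlet", "channel_walls", "well_walls",
                    "actuated_wall"))
  expect_gt(nrow(m$iedge), 0)  # conforming spheroid interface recorded

  # every wall-adjacent element is thinner than one boundary layer
  med <- submesh(m, 1L)
  wall_tags <- c("channel_walls", "well_walls", "actuated_wall",
                 "spheroid_interface")
  eo <- acoustochip:::edge_owner(med, wall_tags)
  h_el <- 2 * tri_areas(med)[eo$elem] /
    acoustochip:::edge_lengths(med, eo$edge)
  expect_lt(max(h_el), delta / 6 * 1.01)
})

test_that("mesh refinement is monotone and keeps the tag set", {
  dom <- build_chip_geometry(chip_geometry())
  coarse <- generate_mesh(dom, mesh_spec(n_boundary_layers = 2,
                                         bl_total_um = 6, h_well_um = 30,
                                         h_channel_um = 80), delta)
  fine <- generate_mesh(dom, mesh_spec(n_boundary_layers = 2,
                                       bl_total_um = 6, h_well_um = 15,
                                       h_channel_um = 40), delta)
  expect_gt(n_elements(fine), n_elements(coarse))
  expect_setequal(unique(fine$btag), unique(coarse$btag))
  # maximum triangle size decreases under refinement
  hmax <- function(m) sqrt(max(tri_areas(m)))
  expect_lt(hmax(fine), hmax(coarse))
})

test_that("well-only mesh (no spheroid) and invalid specs", {
  dom <- build_chip_geometry(chip_geometry(spheroid_diameter = 0))
  m <- generate_mesh(dom, mesh_spec(n_boundary_layers = 2, bl_total_um = 6,
                                    h_well_um = 30, h_channel_um = 80), delta)
  expect_true(all(m$region == 1))
  expect_lt(abs(sum(tri_areas(m)) - dom$area) / dom$area, 1e-10)
  expect_error(resolve_mesh_spec <- generate_mesh(
    dom, mesh_spec(bl_total_um = 50, h_well_um = 30, h_channel_um = 80),
    delta), "exceed")
})

test_that("submesh extraction tags the exposed interface", {
  dom <- build_chip_geometry(chip_geometry())
  m <- generate_mesh(dom, mesh_spec(n_boundary_layers = 2, bl_total_um = 6,
                                    h_well_um = 30, h_channel_um = 80), delta)
  med <- submesh(m, 1L)
  expect_true("spheroid_interface" %in% med$btag)
  sph <- submesh(m, 2L)
  expect_true(all(sph$btag == "spheroid_interface"))
  expect_equal(sum(tri_areas(sph)), sum(tri_areas(m)[m$region == 2]))
})
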