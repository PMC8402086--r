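# Shared expensive computations, evaluated lazily once per test session.

memo <- local({
  store <- new.env(parent = emptyenv())
  function(key, fn) {
    if (is.null(store[[key]])) store[[key]] <- fn()
    store[[key]]
  }
})

# Coarse chip mesh/scenario for fast unit tests (not used for acceptance).
tiny_spec <- function() {
  mesh_spec(n_boundary_layers = 2, bl_total_um = 6, h_well_um = 30,
            h_channel_um = 80, growth_rate = 1.8)
}

tiny_case <- function(d0_nm = 0, Q = 1, ...) {
  sc <- make_scenario_sweep(scenario(), d0_nm, Q)[[1]]
  run_case(sc, mspec = tiny_spec(), cache = tiny_cache(), ...)
}

tiny_cache_env <- new.env(parent = emptyenv())
tiny_cache <- function() memo("tiny_cache", new_run_cache)

# Desk-scale sweep shared by the acceptance tests: non-acoustic flow-rate
# sweep, actuation-amplitude sweep, combined cases and low-glucose runs.
study_sweep <- function() memo("study_sweep", function() {
  cache <- new_run_cache()
  base <- scenario()
  scs <- c(make_scenario_sweep(base, 0, 1:12),
           make_scenario_sweep(base, c(0.1, 0.2, 0.3, 0.4, 0.5), 1),
           make_scenario_sweep(base, 0.5, c(4, 8, 12)),
           make_scenario_sweep(base, 0.5, 1, overrides = list(low_glucose = TRUE)))
  res <- run_sweep(scs, cache = cache)
  res$cache <- cache
  res
})

sweep_row <- function(tab, Q, d0, lowGl = FALSE) {
  sel <- tab$Q_uLmin == Q & abs(tab$d0_nm - d0) < 1e-9 &
    grepl("lowGl", tab$label) == lowGl
  stopifnot(sum(sel) == 1)
  tab[sel, ]
}

# Streaming-only (Q = 0) flows at two amplitudes for the quadratic-scaling
# property; returns the two mean_flow_field objects.
streaming_only_runs <- function() memo("streaming_only", function() {
  lapply(c(0.1, 0.2), function(d0) {
    sc <- make_scenario_sweep(scenario(), d0, 0)[[1]]
    run_case(sc, cache = study_sweep()$cache, keep_fields = TRUE)
  })
})

# Boundary-layer-resolved cavity benchmark (the streaming oracle).
benchmark_run <- function() memo("benchmark", function() run_muller_benchmark(h_um = 4))

# Modify fields of a species spec (tests of degenerate limits).
within_spec <- function(spec, ...) {
  mods <- list(...)
  for (nm in names(mods)) spec[[nm]] <- mods[[nm]]
  spec
}

# Full-field desk runs at the base operating points (reuse sweep cache).
base_fields <- function() memo("base_fields", function() {
  sc <- make_scenario_sweep(scenario(), 0, 1)[[1]]
  run_case(sc, cache = study_sweep()$cache, keep_fields = TRUE)
})

acoustic_fields <- function() memo("acoustic_fields", function() {
  sc <- make_scenario_sweep(scenario(), 0.5, 1)[[1]]
  run_case(sc, cache = study_sweep()$cache, keep_fields = TRUE)
})

# Full-mesh nodal velocity of a kept-fields run.
full_velocity <- function(r) {
  med <- r$flow$mesh
  vel <- matrix(0, nrow(r$mesh$nodes), 2)
  vel[attr(med, "node_map"), ] <- r$flow$vel_p1
  vel
}

# L2 agreement between the 2D disk transport solve and the cylindrical
# radial oracle (the 1D/2D bridge).
bridge_l2 <- function() memo("bridge_l2", function() {
  dom <- build_chip_geometry(chip_geometry())
  mesh <- generate_mesh(dom, mesh_spec(n_boundary_layers = 2,
                                       bl_total_um = 6, h_well_um = 10,
                                       h_channel_um = 80), 5e-7)
  disk <- submesh(mesh, 2L)
  spec <- oxygen_spec()
  conc <- solve_species(disk, NULL, spec,
                        dirichlet = list(spheroid_interface = 0.15))
  orc <- radial_mm_oracle(spec, 150, 0.15, n_points = 4000,
                          geometry = "cylinder")
  rr <- sqrt((disk$nodes[, 1] - 1000e-6)^2 + (disk$nodes[, 2] + 190e-6)^2)
  c_or <- approx(orc$r, orc$c, xout = pmin(rr, 150e-6))$y
  w <- acoustochip:::lumped_area(disk)
  list(relL2 = sqrt(sum(w * (conc$c_spheroid - c_or)^2) / sum(w * c_or^2)),
       conc = conc, oracle = orc, disk = disk, rr = rr)
})
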