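#!/usr/bin/env Rscript
# Stage certification before any chip run: the rectangular-cavity
# streaming benchmark (thermoviscous + body-force route), the resonance
# scan, and the 1D radial Michaelis-Menten oracle bridge.
library(acoustochip)
dir.create("results", showWarnings = FALSE)

message("-- cavity streaming benchmark (boundary-layer-resolved) --")
bm <- run_muller_benchmark(h_um = 4)
s <- bm$summary
message(sprintf("first-order velocity: axial %.3g m/s, transverse %.3g m/s", s$u1_max, s$v1_max))
message(sprintf("bulk streaming max %.3g m/s vs classical slip scale %.3g m/s (ratio %.2f)",
                s$streaming_max_bulk, s$slip_scale, s$streaming_max_bulk / s$slip_scale))
message("quadrant vorticity signs (4-vortex Rayleigh pattern):")
print(sign(bm$quadrant_vorticity))
write.csv(bm$profile, "results/benchmark_profile_Wquarter.csv", row.names = FALSE)

message("-- resonance scan of the benchmark cavity --")
fl <- water_25C()
mesh <- generate_mesh(build_validation_geometry(380, 160),
                      mesh_spec(n_boundary_layers = 1, bl_total_um = 2,
                                h_well_um = 6, h_channel_um = 6),
                      viscous_penetration_depth(fl, 2 * pi * 2e6))
f_half <- fl$ca / (2 * 380e-6)
sc <- resonance_scan(mesh, fl, f_half * c(0.9, 1.1), n = 41,
                     actuation_direction = c(1, 0))
message(sprintf("scan peak %.4f MHz vs analytic half-wave %.4f MHz (%.2f%% apart)",
                sc$f_peak / 1e6, f_half / 1e6, 100 * abs(sc$f_peak - f_half) / f_half))
write.csv(data.frame(f_Hz = sc$f, response = sc$response),
          "results/benchmark_resonance_scan.csv", row.names = FALSE)

message("-- radial Michaelis-Menten oracle vs 2D disk solve --")
dom <- build_chip_geometry(chip_geometry())
mesh2 <- generate_mesh(dom, mesh_spec(n_boundary_layers = 2, bl_total_um = 6,
                                      h_well_um = 10, h_channel_um = 80), 5e-7)
disk <- submesh(mesh2, 2L)
conc <- solve_species(disk, NULL, oxygen_spec(),
                      dirichlet = list(spheroid_interface = 0.15))
orc <- radial_mm_oracle(oxygen_spec(), 150, 0.15, n_points = 4000,
                        geometry = "cylinder")
rr <- sqrt((disk$nodes[, 1] - 1000e-6)^2 + (disk$nodes[, 2] + 190e-6)^2)
c_or <- approx(orc$r, orc$c, xout = pmin(rr, 150e-6))$y
w <- acoustochip:::lumped_area(disk)
message(sprintf("2D-vs-1D relative L2 difference: %.4f",
                sqrt(sum(w * (conc$c_spheroid - c_or)^2) / sum(w * c_or^2))))
write.csv(data.frame(r_m = orc$r, c_mM = orc$c),
          "results/radial_oracle_profile.csv", row.names = FALSE)
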