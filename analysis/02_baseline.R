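#!/usr/bin/env Rscript
# The conventional (non-acoustic) perfusion chip at Q = 1 uL/min: flow
# pattern, oxygen/glucose fields and zone fractions of the spheroid.
library(acoustochip)
dir.create("results", showWarnings = FALSE)
cache <- new_run_cache()
r <- run_case(make_scenario_sweep(scenario(), 0, 1)[[1]],
              cache = cache, keep_fields = TRUE)
rep <- r$report
message(sprintf("avg O2 %.4f mM, avg glucose %.3f mM", rep$avg_O2_mM, rep$avg_Gl_mM))
message(sprintf("oxygen-criterion zones: necrotic %.1f%%, quiescent %.1f%%, proliferating %.1f%%",
                rep$nec_O2_pct, rep$qui_O2_pct, rep$pro_O2_pct))
message(sprintf("tau_max %.3g dyne/cm2 (bound 0.5), lift %.3g N (net weight %.3g N)",
                rep$tau_max_dyn_cm2, rep$lift_N, r$log$net_weight_N))
write_report(list(rep), "results/baseline.csv", "results/baseline.json")
write_mesh_vtu(r$mesh, "results/baseline_fields.vtu",
               point_data = list(
                 oxygen_mM = r$concentrations$oxygen$u,
                 glucose_mM = r$concentrations$glucose$u))
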