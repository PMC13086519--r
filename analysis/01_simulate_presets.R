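#!/usr/bin/env Rscript
# Simulate the three reference nitrite-accumulation phenotypes under the
# standard protocol (100 umol NO3-, 1% O2, He headspace, 20 C) and record
# both the dense truth trajectories and instrument-style sampled runs
# (hourly gas autosampling with 1 mL He-replaced draws, NO2- every 2 h).

library(denitkin)

dir.create("results/runs", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

for (nm in c("FNA_ref", "PNA_ref", "LNA_ref")) {
  ps <- preset(nm)
  traj <- simulate_vial(ps$config, ps$phenotype, ps$protocol)
  write_trajectory(traj, file.path("results/runs", paste0(nm, "_truth.csv")))
  run <- autosample(ps$config, ps$phenotype, ps$protocol, seed = seed)
  write_sampled_run(run, "results/runs", prefix = nm)
  ev <- attr(traj, "events")
  cat(sprintf(
    "%-8s induced at %.1f h; true max NO2- %.1f umol at %.1f h; N2-N at end %.1f umol\n",
    nm, ev$t_induction, max(traj$NO2), traj$time_h[which.max(traj$NO2)],
    2 * traj$N2[nrow(traj)]))
}

cat("\nAll three phenotypes fully denitrify the supplied 100 umol NO3--N;\n")
cat("they differ in how much of it transiently pools as NO2-.\n")
cat("Sampled runs (seed", seed, ") written under results/runs/.\n")
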