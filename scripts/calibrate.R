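#!/usr/bin/env Rscript

# Developer script: recalibrates the BRD4 C-blob self-attraction against
# the chromatin-free critical valence (target 6) and re-measures the
# saturation (dilute-phase) density stored in
# inst/extdata/coexistence_reference.csv. Run from the repository root;
# takes a few tens of minutes on one CPU.

suppressPackageStartupMessages(library(condensim))

seed <- 42L
proto <- coexistence_protocol()

eps <- calibrate_self_interaction(6L, c(2.5, 3.0, 3.5, 4.0),
                                  protocol = proto, seed = seed)
cat("calibrated eps_CC:", as.numeric(eps), "kT\n")
print(attr(eps, "scan"))

# dilute-phase density coexisting with the condensate at the calibrated
# eps (valence 6, long dispersed-start run)
p <- default_parameters(eps_cc = as.numeric(eps))
topo <- build_dispersed_system(48, 6, FALSE, 0, proto$box, seed = 21,
                               params = p)
traj <- run(initial_state(topo), topo, p,
            run_config(n_steps = 600000L, dt = 2e-4, output_every = 4000L,
                       seed = 21))
prof <- density_profile(traj, topo, "CORELET", 14, 0.6)
cx <- coexistence_densities(prof)
cat(sprintf("dilute (saturation) density: %.3g /nm^3; dense: %.3g /nm^3\n",
            cx$dilute, cx$dense))
cat("update inst/extdata/coexistence_reference.csv and CALIBRATED_EPS_CC",
    "in R/params.R if these change.\n")
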