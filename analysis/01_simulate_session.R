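#!/usr/bin/env Rscript
# Build the reference synthetic session the rest of the workflow analyzes:
# a 50-unit BLA-like cohort over a 2x4-stimulus battery (5-min baseline /
# event / post blocks), with panresponsive transients, aftereffects,
# depth-clustered event-specific units and four injected monosynaptic
# connections. The session directory (bulky) goes under scratch/; summary
# tables under results/.

suppressMessages(library(ethospike))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

connections <- data.frame(proj = c(3, 7, 11, 15), targ = c(4, 8, 12, 16),
                          delay_ms = c(1.5, 2.0, 1.2, 2.5),
                          transfer_prob = c(0.15, 0.2, 0.12, 0.18))
cfg <- sim_config(n_units = 50, cluster_depths = TRUE,
                  connections = connections, seed = 1)
sim <- simulate_session(cfg)
validate_session(sim$session)
write_session(sim$session, "scratch/session")
jsonlite::write_json(sim$truth$units, "results/ground_truth_units.json",
                     auto_unbox = TRUE, digits = NA)
write.table(sim$truth$connections, "results/ground_truth_connections.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# refractory QC: all thinned-Poisson units should pass the 0.1% criterion
qc <- vapply(sim$session$units, function(u)
  refractory_violation_fraction(u$spike_times), 0)
cat(sprintf("Simulated %d units over %d events (%.0f s of recording).\n",
            length(sim$session$units), length(sim$session$events),
            max(vapply(sim$session$events, `[[`, 0, "t_post_end"))))
cat(sprintf("Refractory QC: %d/%d units pass (<0.1%% ISI violations; max %.4f%%).\n",
            sum(qc < 0.001), length(qc), 100 * max(qc)))
cat("True composition:\n")
print(table(sim$truth$units$category))
cat("Session written to scratch/session; ground truth to results/.\n")
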