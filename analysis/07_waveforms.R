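#!/usr/bin/env Rscript
# Waveform-based cell typing (trough-to-peak vs baseline rate, 2-means) and
# cross-day unit matching by windowed SSIM of centered waveform heatmaps.

suppressMessages(library(ethospike))

session <- read_session("scratch/session")
truth <- jsonlite::read_json("results/ground_truth_units.json",
                             simplifyVector = TRUE)

mets <- lapply(session$units, function(u)
  waveform_metrics(u, baseline_rate_hz =
                     length(spikes_in(u$spike_times, c(0, 300))) / 300))
types <- cell_type_clusters(mets, seed = 12)
ok <- types != "irregular"
cat(sprintf("Cell typing: %d putative pyramidal, %d putative interneurons, %d irregular; %.0f%% agree with ground truth.\n",
            sum(types == "putative_pyramidal"),
            sum(types == "putative_interneuron"), sum(!ok),
            100 * mean(types[ok] == truth$cell_type[ok])))
write.table(data.frame(unit_id = truth$unit_id,
                       trough_to_peak_ms = vapply(mets, `[[`, 0,
                                                  "trough_to_peak_ms"),
                       cell_type = types,
                       true_type = truth$cell_type),
            "results/cell_types.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tw <- simulate_two_day_waveforms(n_units = 100, snr = 10,
                                 max_drift_channels = 2, seed = 13)
m <- match_units_across_days(tw$day1, tw$day2)
truth_map <- stats::setNames(tw$truth$day2_id, tw$truth$day1_id)
correct <- sum(m$accepted & truth_map[m$day1_id] == m$day2_id)
cat(sprintf("Cross-day matching: %d/%d accepted, %d correct (SSIM %.2f-%.2f).\n",
            sum(m$accepted), nrow(m), correct, min(m$ssim), max(m$ssim)))
write.table(m, "results/unit_matches.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
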