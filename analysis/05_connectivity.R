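#!/usr/bin/env Rscript
# Cross-correlogram connectivity: scan all ordered unit pairs of the
# reference session for directional putative monosynaptic peaks, compare
# with the injected ground truth, quantify connection-type enrichment over
# chance, and track connection strength across baseline/event/post epochs.

suppressMessages(library(ethospike))

session <- read_session("scratch/session")
truth_conn <- read.delim("results/ground_truth_connections.tsv")
sc <- score_session(session)

found <- scan_connections(session)
write.table(found, "results/connections.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
key <- function(p, t) paste(p, t)
tp <- sum(key(found$proj, found$targ) %in%
            key(truth_conn$proj_id, truth_conn$targ_id))
cat(sprintf("Detected %d directed pairs; %d/%d injected connections recovered, %d spurious.\n",
            nrow(found), tp, nrow(truth_conn), nrow(found) - tp))
if (nrow(found)) {
  cat(sprintf("Peak lags %.2f-%.2f ms; depth distances %s um.\n",
              min(found$peak_lag_ms), max(found$peak_lag_ms),
              paste(found$depth_dist_um, collapse = ", ")))
}

cats <- stats::setNames(sc$profiles$category, sc$profiles$unit_id)
if (nrow(found) >= 2) {
  en <- connection_type_enrichment(found, cats, n_resample = 1000, seed = 5)
  write.table(round(en$ratio, 3), "results/enrichment.tsv", sep = "\t",
              quote = FALSE)
}

# epoch-wise strength around each class's first presentation
classes <- vapply(session$events, `[[`, "", "stimulus_class")
firsts <- session$events[vapply(session$events, `[[`, 0L,
                                "presentation_index") == 1L]
spikes <- lapply(session$units, `[[`, "spike_times")
ids <- vapply(session$units, `[[`, "", "unit_id")
rows <- list()
for (blk in firsts) {
  ep <- event_epochs(blk)
  for (epoch in names(ep)) {
    for (r in seq_len(nrow(truth_conn))) {
      i <- match(truth_conn$proj_id[r], ids)
      j <- match(truth_conn$targ_id[r], ids)
      cs <- connection_strength(spikes[[i]], spikes[[j]], ep[[epoch]],
                                min_spikes = 50)
      if (is.null(cs)) next
      rows[[length(rows) + 1]] <- data.frame(
        stimulus = blk$stimulus_class, epoch = epoch,
        proj = ids[i], targ = ids[j], strength = cs$strength)
    }
  }
}
ep_tab <- do.call(rbind, rows)
write.table(ep_tab, "results/epoch_strengths.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Mean connection strength by epoch (first presentations):\n")
print(aggregate(strength ~ epoch, ep_tab, mean), row.names = FALSE)
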