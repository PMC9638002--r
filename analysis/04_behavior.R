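#!/usr/bin/env Rscript
# Behavior pipeline: clean the pose tracks, compute the 30 social features,
# cross-validate the 7-class rbf-SVM frame classifier, post-process bouts,
# fit the non-social contact threshold, and relate firing to interaction
# and running speed.

suppressMessages(library(ethospike))

cfg <- sim_config(seed = 1)
trk <- simulate_tracking(cfg)
cl <- clean_tracking(trk$tracking)
ft <- compute_features(cl, cfg$behavior$frame_rate)

set.seed(2)
idx <- sort(sample(nrow(ft), 4000))
cv <- cv_behavior_classifier(ft[idx, ], trk$labels[idx], k = 5, seed = 3)
cat(sprintf("5-fold frame accuracy on scripted bouts: %.1f%% (folds: %s).\n",
            100 * cv$accuracy,
            paste(sprintf("%.1f", 100 * cv$fold_accuracy), collapse = ", ")))

model <- train_behavior_classifier(ft[idx, ], trk$labels[idx])
pred <- classify_behavior(ft, model)
bouts <- postprocess_bouts(pred, cfg$behavior$frame_rate)
write.table(bouts$bouts, "results/behavior_bouts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Predicted %d bouts after gap-merge (<0.25 s) and length filter (>=5 frames).\n",
            nrow(bouts$bouts)))

# contact threshold from the social labels, as applied to toy sessions
contact_labels <- !(bouts$labels %in% c("non-social", "approach",
                                        "following"))
fit <- fit_contact_threshold(ft$dist_head_head, contact_labels)
cat(sprintf("Contact threshold: head-head distance < %.1f (balanced accuracy %.2f).\n",
            fit$threshold, fit$balanced_accuracy))

# interaction-gated firing and speed correlation on synthetic spike trains
set.seed(4)
fr <- cfg$behavior$frame_rate
frame_t <- trk$frame_times
inter <- bouts$labels != "non-social"
r <- rle(inter)
ends <- cumsum(r$lengths)
iv <- cbind(frame_t[ends - r$lengths + 1], frame_t[ends])[r$values, ,
                                                          drop = FALSE]
ev <- new_event_block("male", 1, 0, 0.001, 0.002, max(frame_t),
                      max(frame_t) + 1)
gate <- function(times, gain) {
  g <- rep(1, length(times))
  for (k in seq_len(nrow(iv)))
    g[times >= iv[k, 1] & times < iv[k, 2]] <- gain
  g
}
cand <- sort(runif(rpois(1, 3 * 3 * max(frame_t)), 0, max(frame_t)))
st <- cand[runif(length(cand)) < gate(cand, 3) / 3]
isc <- interaction_response_score(st, list(ev), list(iv), min_spikes = 20)
cat(sprintf("Interaction-gated unit: score %.2f -> %s.\n",
            isc$score, isc$class))

speed <- ft$imp_head_speed
scls <- speed_correlation(st, speed, frame_t,
                          list(range(frame_t)))$class
cat(sprintf("Speed correlation of the gated unit: %s.\n", scls))
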