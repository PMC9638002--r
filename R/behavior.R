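#' The 7 behavior labels
#' @return Character vector of per-frame behavior classes.
#' @export
behavior_labels <- function() {
  c("non-social", "head-head", "head-tail", "approach", "following",
    "conspecific-contact", "other-social")
}

#' Likelihood-threshold and interpolate pose tracking
#'
#' Points below the likelihood threshold (a stricter one for the
#' experimenter-colored body parts, which track more reliably) and points at
#' anatomically impossible distances from the rest of their skeleton are
#' removed, then filled by linear interpolation over frames per body part.
#'
#' @param raw Tracking data.frame (frame, agent, bodypart, x, y,
#'   likelihood).
#' @param colored_thresh Likelihood threshold for colored parts
#'   (default 0.999).
#' @param other_thresh Threshold for all other parts (default 0.9).
#' @param colored_parts `agent.bodypart` names of the colored parts.
#' @param max_part_dist Maximum plausible distance (arena units) of a part
#'   from its skeleton's per-frame median position (default 12).
#' @return The tracking data.frame with cleaned `x`, `y` and a logical
#'   `interpolated` column; parts with > 50% of frames missing raise a
#'   warning and are listed in `attr(, "low_quality")`.
#' @export
clean_tracking <- function(raw, colored_thresh = 0.999, other_thresh = 0.9,
                           colored_parts = c("implanted.tailbase",
                                             "conspecific.ear_left",
                                             "conspecific.ear_right",
                                             "conspecific.tailbase"),
                           max_part_dist = 12) {
  df <- raw[order(raw$agent, raw$bodypart, raw$frame), ]
  key <- paste(df$agent, df$bodypart, sep = ".")
  thr <- ifelse(key %in% colored_parts, colored_thresh, other_thresh)
  bad <- df$likelihood < thr

  # anatomically impossible points: far from the skeleton's median position
  fa <- paste(df$frame, df$agent)
  ok_x <- ifelse(bad, NA, df$x); ok_y <- ifelse(bad, NA, df$y)
  med_x <- stats::ave(ok_x, fa, FUN = function(v) stats::median(v, na.rm = TRUE))
  med_y <- stats::ave(ok_y, fa, FUN = function(v) stats::median(v, na.rm = TRUE))
  bad <- bad | (!is.na(med_x) &
                  sqrt((df$x - med_x)^2 + (df$y - med_y)^2) > max_part_dist)

  df$x[bad] <- NA; df$y[bad] <- NA
  df$interpolated <- bad
  low_quality <- character(0)
  for (k in unique(key)) {
    sel <- which(key == k)
    frac_missing <- mean(is.na(df$x[sel]))
    if (frac_missing > 0.5) low_quality <- c(low_quality, k)
    for (col in c("x", "y")) {
      v <- df[[col]][sel]
      if (anyNA(v) && sum(!is.na(v)) >= 2)
        v <- stats::approx(df$frame[sel][!is.na(v)], v[!is.na(v)],
                           xout = df$frame[sel], rule = 2)$y
      df[[col]][sel] <- v
    }
  }
  if (length(low_quality))
    warning("> 50% of points missing for: ",
            paste(low_quality, collapse = ", "))
  out <- df[order(df$frame, df$agent, df$bodypart), ]
  rownames(out) <- NULL
  attr(out, "low_quality") <- low_quality
  out
}

wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

# frames x 2 coordinate matrix for one agent/bodypart
part_xy <- function(tr, agent, part, frames) {
  sel <- tr$agent == agent & tr$bodypart == part
  d <- tr[sel, ]
  d <- d[match(frames, d$frame), ]
  cbind(d$x, d$y)
}

#' Pose features for social-behavior classification
#'
#' Computes 30 per-frame features from the cleaned two-agent tracking:
#' per-animal head/tailbase velocities, spine length, head angular velocity
#' and 1-s-offset tailbase velocity; inter-individual distances between
#' matched body parts; head-direction angles from each rat to the other's
#' parts; head-angle difference; the head-head minus head-tail differences
#' in distance and head direction; a 1-s head-position correlation; relative
#' head speed and centroid distance. Angles are radians wrapped to
#' (-pi, pi]; velocities are displacement x frame rate. Edge/NA values are
#' filled so every feature is finite.
#'
#' @param tracking Cleaned tracking data.frame (see [clean_tracking()])
#'   containing both agents.
#' @param frame_rate Video frame rate (Hz).
#' @return data.frame: `frame` plus 30 named feature columns.
#' @export
compute_features <- function(tracking, frame_rate) {
  frames <- sort(unique(tracking$frame))
  n <- length(frames)
  agents <- unique(tracking$agent)
  if (!all(c("implanted", "conspecific") %in% agents))
    stop("single-agent session: inter-individual features unavailable")

  ih <- part_xy(tracking, "implanted", "head", frames)
  it <- part_xy(tracking, "implanted", "tailbase", frames)
  inp <- part_xy(tracking, "implanted", "nape_center", frames)
  ib <- part_xy(tracking, "implanted", "back_center", frames)
  ch <- part_xy(tracking, "conspecific", "nose", frames)
  ct <- part_xy(tracking, "conspecific", "tailbase", frames)
  cnp <- part_xy(tracking, "conspecific", "nape_center", frames)
  cb <- part_xy(tracking, "conspecific", "back_center", frames)

  speed <- function(p) {
    d <- sqrt(rowSums(rbind(p[2, ] - p[1, ], diff(p))^2)) * frame_rate
    d
  }
  heading <- function(head, nape) atan2(head[, 2] - nape[, 2],
                                        head[, 1] - nape[, 1])
  angvel <- function(h) c(0, abs(wrap_angle(diff(h)))) * frame_rate
  dist2 <- function(a, b) sqrt(rowSums((a - b)^2))
  lag1 <- function(v) {
    k <- round(frame_rate)
    c(rep(v[1], k), v)[seq_len(n)]
  }
  ang_to <- function(h, from, to)
    wrap_angle(atan2(to[, 2] - from[, 2], to[, 1] - from[, 1]) - h)

  h1 <- heading(ih, inp); h2 <- heading(ch, cnp)
  w <- max(3, round(frame_rate) + 1)
  if (w > n) w <- max(3, n - (1 - n %% 2))  # short clips: shrink the window
  rollcor <- function(a, b) {
    if (w > n) return(rep(0, n))
    k <- rep(1 / w, w)
    rm_ <- function(v) stats::filter(v, k, sides = 2)
    cv <- rm_(a * b) - rm_(a) * rm_(b)
    va <- pmax(rm_(a * a) - rm_(a)^2, 0)
    vb <- pmax(rm_(b * b) - rm_(b)^2, 0)
    r <- as.numeric(cv / sqrt(va * vb))
    r[!is.finite(r)] <- 0
    pmin(pmax(r, -1), 1)
  }

  f <- data.frame(
    frame = frames,
    imp_head_speed = speed(ih),
    imp_tail_speed = speed(it),
    imp_spine_len = dist2(ih, it),
    imp_head_angvel = angvel(h1),
    imp_tail_speed_lag1s = lag1(speed(it)),
    con_head_speed = speed(ch),
    con_tail_speed = speed(ct),
    con_spine_len = dist2(ch, ct),
    con_head_angvel = angvel(h2),
    con_tail_speed_lag1s = lag1(speed(ct)),
    dist_head_head = dist2(ih, ch),
    dist_tail_tail = dist2(it, ct),
    dist_nape_nape = dist2(inp, cnp),
    dist_back_back = dist2(ib, cb),
    dist_imp_head_con_tail = dist2(ih, ct),
    dist_con_head_imp_tail = dist2(ch, it),
    imp_hd_to_con_head = ang_to(h1, ih, ch),
    imp_hd_to_con_tail = ang_to(h1, ih, ct),
    imp_hd_to_con_nape = ang_to(h1, ih, cnp),
    imp_hd_to_con_back = ang_to(h1, ih, cb),
    con_hd_to_imp_head = ang_to(h2, ch, ih),
    con_hd_to_imp_tail = ang_to(h2, ch, it),
    con_hd_to_imp_nape = ang_to(h2, ch, inp),
    con_hd_to_imp_back = ang_to(h2, ch, ib),
    head_angle_diff = wrap_angle(h1 - h2))
  f$dd_headhead_minus_headtail <- f$dist_head_head - f$dist_imp_head_con_tail
  f$hd_diff_headhead_minus_headtail <-
    wrap_angle(f$imp_hd_to_con_head - f$imp_hd_to_con_tail)
  f$poscorr_1s <- (rollcor(ih[, 1], ch[, 1]) + rollcor(ih[, 2], ch[, 2])) / 2
  f$rel_head_speed <- abs(f$imp_head_speed - f$con_head_speed)
  f$dist_centroid <- dist2((ih + it) / 2, (ch + ct) / 2)
  # outlier removal (gross deviations, e.g. velocity spikes from residual
  # tracking glitches) then interpolation, so every feature is finite
  for (col in names(f)[-1]) {
    v <- f[[col]]
    med <- stats::median(v, na.rm = TRUE)
    mad_ <- stats::mad(v, na.rm = TRUE)
    if (is.finite(mad_) && mad_ > 0) v[abs(v - med) > 10 * mad_] <- NA
    if (anyNA(v)) {
      if (sum(!is.na(v)) >= 2)
        v <- stats::approx(frames[!is.na(v)], v[!is.na(v)], xout = frames,
                           rule = 2)$y
      else v[is.na(v)] <- med
      f[[col]] <- v
    } else f[[col]] <- v
  }
  f
}

#' Train the social-behavior frame classifier
#'
#' Radial-basis-kernel support-vector classification of the 7 behavior
#' labels from standardized pose features.
#'
#' @param features Feature data.frame from [compute_features()] (the
#'   `frame` column, if present, is dropped).
#' @param labels Manual per-frame labels; every label in
#'   [behavior_labels()] must be present.
#' @return Object of class `behavior_model`.
#' @export
train_behavior_classifier <- function(features, labels) {
  x <- as.matrix(features[, setdiff(names(features), "frame")])
  missing <- setdiff(behavior_labels(), unique(labels))
  if (length(missing))
    stop("training labels missing class(es): ",
         paste(missing, collapse = ", "))
  fit <- e1071::svm(x, factor(labels, levels = behavior_labels()),
                    kernel = "radial", scale = TRUE)
  structure(list(svm = fit, feature_names = colnames(x)),
            class = "behavior_model")
}

#' Predict per-frame behavior labels
#' @param features Feature data.frame (same columns as used for training).
#' @param model A `behavior_model` from [train_behavior_classifier()].
#' @return Character vector of per-frame labels.
#' @export
classify_behavior <- function(features, model) {
  x <- as.matrix(features[, model$feature_names])
  as.character(stats::predict(model$svm, x))
}

#' Cross-validated frame accuracy of the behavior classifier
#'
#' Either k-fold (frames shuffled into folds) or leave-one-recording-out
#' when `groups` is given.
#'
#' @param features Feature data.frame.
#' @param labels Per-frame labels.
#' @param k Folds (default 5; ignored when `groups` given).
#' @param groups Optional recording id per frame for
#'   leave-one-recording-out.
#' @param seed RNG seed for fold assignment.
#' @return List `fold_accuracy`, `accuracy` (overall frame accuracy),
#'   `predicted`.
#' @export
cv_behavior_classifier <- function(features, labels, k = 5, groups = NULL,
                                   seed = 1) {
  x <- features[, setdiff(names(features), "frame")]
  n <- nrow(x)
  set.seed(seed)
  fold <- if (is.null(groups)) sample(rep_len(seq_len(k), n))
  else as.integer(factor(groups))
  pred <- character(n)
  for (f in sort(unique(fold))) {
    te <- fold == f
    fit <- e1071::svm(as.matrix(x[!te, ]),
                      factor(labels[!te], levels = behavior_labels()),
                      kernel = "radial", scale = TRUE)
    pred[te] <- as.character(stats::predict(fit, as.matrix(x[te, ])))
  }
  acc_by <- vapply(sort(unique(fold)),
                   function(f) mean(pred[fold == f] == labels[fold == f]), 0)
  list(fold_accuracy = acc_by, accuracy = mean(pred == labels),
       predicted = pred)
}

#' Clean per-frame labels into behavior bouts
#'
#' Same-label runs separated by a sub-threshold gap (a single intervening
#' run shorter than `min_gap_s`) are merged, then non-background runs
#' shorter than `min_frames` are dissolved into the background
#' (`non-social`) class; the merge/delete sweep repeats until the labeling
#' is a fixed point, so the operation is idempotent.
#'
#' @param labels Per-frame label vector.
#' @param frame_rate Frame rate (Hz).
#' @param min_gap_s Gaps shorter than this are merged (default 0.25 s).
#' @param min_frames Minimum bout length in frames (default 5).
#' @param background Background label (default `"non-social"`).
#' @return List `labels` (cleaned per-frame vector) and `bouts`
#'   (data.frame label, start_frame, end_frame, n_frames).
#' @export
postprocess_bouts <- function(labels, frame_rate, min_gap_s = 0.25,
                              min_frames = 5, background = "non-social") {
  lab <- as.character(labels)
  repeat {
    before <- lab
    r <- rle(lab)
    # merge: relabel short gaps flanked by the same label
    if (length(r$lengths) >= 3) {
      for (i in 2:(length(r$lengths) - 1)) {
        if (r$lengths[i] / frame_rate < min_gap_s &&
            r$values[i - 1] == r$values[i + 1] &&
            r$values[i] != r$values[i - 1])
          r$values[i] <- r$values[i - 1]
      }
      lab <- inverse.rle(r)
      r <- rle(lab)
    }
    # delete: dissolve short non-background runs
    short <- r$lengths < min_frames & r$values != background
    r$values[short] <- background
    lab <- inverse.rle(r)
    if (identical(lab, before)) break
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  list(labels = lab,
       bouts = data.frame(label = r$values,
                          start_frame = ends - r$lengths + 1,
                          end_frame = ends, n_frames = r$lengths,
                          stringsAsFactors = FALSE))
}

#' Contact threshold for non-social stimuli from social data
#'
#' Grid-searches the inter-individual distance threshold that maximizes
#' balanced accuracy of contact vs no-contact on labeled social frames; the
#' threshold is then applied to toy sessions ([toy_interaction()]); food
#' sessions use a region of interest instead ([food_interaction()]).
#'
#' @param distances Inter-individual distance per social frame.
#' @param contact Logical per frame: social contact?
#' @param n_grid Grid resolution (default 200).
#' @return List `threshold`, `balanced_accuracy`.
#' @export
fit_contact_threshold <- function(distances, contact, n_grid = 200) {
  contact <- as.logical(contact)
  if (length(unique(contact)) < 2)
    stop("degenerate training: need both contact and no-contact frames")
  grid <- seq(min(distances), max(distances), length.out = n_grid)
  ba <- vapply(grid, function(th) {
    pred <- distances < th
    (mean(pred[contact]) + mean(!pred[!contact])) / 2
  }, 0)
  list(threshold = grid[which.max(ba)], balanced_accuracy = max(ba))
}

#' @rdname fit_contact_threshold
#' @param threshold Distance threshold from [fit_contact_threshold()].
#' @return `toy_interaction`: logical interaction mask per frame.
#' @export
toy_interaction <- function(distances, threshold) distances < threshold

#' @rdname fit_contact_threshold
#' @param head_xy Two-column matrix of head coordinates per frame.
#' @param roi_polygon List/data.frame with `x`, `y` polygon vertices.
#' @return `food_interaction`: logical mask, head inside the ROI.
#' @export
food_interaction <- function(head_xy, roi_polygon) {
  pracma::inpolygon(head_xy[, 1], head_xy[, 2],
                    roi_polygon$x, roi_polygon$y, boundary = TRUE)
}

#' auROC score of interaction vs non-interaction firing
#'
#' Within each event's post-contact period, 1-s firing-rate bins are split
#' by the interaction mask and compared by the same auROC score as
#' stimulus responsivity; scores are averaged over the supplied events
#' (callers restrict these to the unit's responsive events) and classified
#' as increase/decrease/none at `+/- theta`.
#'
#' @param spike_times Unit spike times (s).
#' @param events List of `ethospike_event` blocks to analyze.
#' @param interaction_intervals List (one per event) of 2-column matrices
#'   of interaction `start`, `end` times (s, ephys clock).
#' @param bin_s Bin width (s, default 1).
#' @param min_spikes Pooled spike minimum per event (default 50).
#' @param theta Classification threshold (default 0.2).
#' @return List `per_event` (scores), `score` (mean), `class`
#'   (`increase`/`decrease`/`none`, `NA` if no event was scorable).
#' @export
interaction_response_score <- function(spike_times, events,
                                       interaction_intervals, bin_s = 1,
                                       min_spikes = 50, theta = 0.2) {
  per <- rep(NA_real_, length(events))
  for (e in seq_along(events)) {
    blk <- events[[e]]
    span <- c(blk$t_contact, blk$t_event_end)
    if (diff(span) < 2 * bin_s) next
    n_bins <- floor(diff(span) / bin_s)
    mids <- span[1] + (seq_len(n_bins) - 0.5) * bin_s
    iv <- interaction_intervals[[e]]
    inter <- rep(FALSE, n_bins)
    if (!is.null(iv) && nrow(iv) > 0)
      for (r in seq_len(nrow(iv)))
        inter <- inter | (mids >= iv[r, 1] & mids < iv[r, 2])
    rates <- binned_rates(spike_times, span, bin_s)[seq_len(n_bins)]
    if (!any(inter) || all(inter)) {
      warning("event ", e, ": no post-contact ",
              if (all(inter)) "non-interaction" else "interaction",
              " period; score undefined")
      next
    }
    per[e] <- response_score(rates[!inter], rates[inter], min_spikes, bin_s)
  }
  sc <- if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  cls <- if (is.na(sc)) NA_character_
  else if (sc > theta) "increase"
  else if (sc < -theta) "decrease"
  else "none"
  list(per_event = per, score = sc, class = cls)
}

#' Peri-bout firing histogram with z-flag
#'
#' Average firing around behavior-bout onsets in `bin_s` bins over
#' `window`, z-scored to the `baseline` portion of the window; a unit is
#' flagged responsive to the behavior if any post-onset bin exceeds
#' `+/- z_thresh`.
#'
#' @param spike_times Unit spike times (s).
#' @param bout_starts Bout onset times (s); callers pass bouts longer than
#'   1 s.
#' @param window `c(before, after)` seconds around onset (default
#'   `c(-5, 5)`).
#' @param bin_s Bin width (s, default 0.1).
#' @param baseline Window portion used as z reference (default
#'   `c(-5, -2)`).
#' @param z_thresh Responsiveness threshold (default 5).
#' @param min_bouts Minimum bouts required (default 5); fewer returns
#'   `NULL` with a warning.
#' @return List `z`, `bin_centers` (s relative to onset), `responsive`,
#'   `n_bouts`, or `NULL`.
#' @export
behavior_peth <- function(spike_times, bout_starts, window = c(-5, 5),
                          bin_s = 0.1, baseline = c(-5, -2), z_thresh = 5,
                          min_bouts = 5) {
  if (length(bout_starts) < min_bouts) {
    warning("only ", length(bout_starts), " bouts (< ", min_bouts,
            "); peri-bout histogram skipped")
    return(NULL)
  }
  n_bins <- round(diff(window) / bin_s)
  centers <- window[1] + (seq_len(n_bins) - 0.5) * bin_s
  m <- vapply(bout_starts, function(s)
    binned_rates(spike_times, s + window, bin_s)[seq_len(n_bins)],
    numeric(n_bins))
  avg <- rowMeans(m)
  base_idx <- centers >= baseline[1] & centers < baseline[2]
  mu <- mean(avg[base_idx]); sdv <- stats::sd(avg[base_idx])
  floor_sd <- (1 / bin_s) / length(bout_starts) / sqrt(sum(base_idx))
  z <- if (sdv == 0 && mu == 0) ifelse(avg == 0, 0, avg / floor_sd)
  else (avg - mu) / max(sdv, floor_sd)
  list(z = z, bin_centers = centers,
       responsive = any(abs(z[centers >= 0]) > z_thresh),
       n_bouts = length(bout_starts))
}

#' Classify a unit's firing-speed relationship
#'
#' Firing is binned at 50 ms and cross-correlated with the animal's speed
#' within each epoch; profiles are averaged over epochs and the unit is
#' classified by whether the correlation at lag 0 exceeds the mean far-lag
#' correlation (lags -20 s to -10 s) by more than `band_sd` far-lag SDs in
#' either direction.
#'
#' @param spike_times Unit spike times (s).
#' @param speed Speed samples.
#' @param speed_times Sample times (s, ephys clock).
#' @param epochs List of `c(start, end)` intervals (e.g. baseline, event,
#'   post).
#' @param bin_s Bin width (s, default 0.05).
#' @param max_lag_s Cross-correlation span (s, default 20).
#' @param far_lag Reference lag window (s, default `c(-20, -10)`).
#' @param band_sd Noise band width in far-lag SDs (default 2).
#' @return List `class` (`positive`/`negative`/`none`), `cc0`, `far_mean`,
#'   `far_sd`, `lags_s`, `cc` (mean profile).
#' @export
speed_correlation <- function(spike_times, speed, speed_times, epochs,
                              bin_s = 0.05, max_lag_s = 20,
                              far_lag = c(-20, -10), band_sd = 2) {
  if (stats::sd(speed) == 0) stop("constant speed: correlation undefined")
  lag_max <- round(max_lag_s / bin_s)
  profs <- NULL
  for (ep in epochs) {
    rates <- binned_rates(spike_times, ep, bin_s)
    mids <- ep[1] + (seq_along(rates) - 0.5) * bin_s
    sp <- stats::approx(speed_times, speed, xout = mids, rule = 2)$y
    if (stats::sd(sp) == 0 || stats::sd(rates) == 0) next
    cc <- stats::ccf(rates, sp, lag.max = lag_max, plot = FALSE)
    profs <- cbind(profs, as.numeric(cc$acf))
  }
  if (is.null(profs)) stop("no epoch with variable speed and firing")
  cc <- rowMeans(profs)
  lags_s <- seq(-lag_max, lag_max) * bin_s
  cc0 <- cc[lags_s == 0]
  far <- cc[lags_s >= far_lag[1] & lags_s <= far_lag[2]]
  diffv <- cc0 - mean(far)
  cls <- if (diffv > band_sd * stats::sd(far)) "positive"
  else if (diffv < -band_sd * stats::sd(far)) "negative"
  else "none"
  list(class = cls, cc0 = cc0, far_mean = mean(far),
       far_sd = stats::sd(far), lags_s = lags_s, cc = cc)
}
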