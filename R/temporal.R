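#' Baseline-referenced z-scored PSTH for one unit and event
#'
#' Firing rates in `bin_s` bins across the whole block (baseline start to
#' post end) are z-scored against the mean and SD of the same event's
#' baseline bins. A silent baseline (SD 0, mean 0) gives z = 0 wherever the
#' rate is 0; any non-zero rate is scored against a configurable SD floor
#' (default: the SD a single baseline spike would produce) instead of
#' returning an infinite-effect sentinel.
#'
#' @param unit An `ethospike_unit` or a numeric spike-time vector.
#' @param event An `ethospike_event`.
#' @param bin_s Bin width (s), default 0.1.
#' @param sd_floor Minimum baseline SD (Hz); default
#'   `(1/bin_s)/sqrt(n_baseline_bins)`.
#' @return Object of class `ethospike_psth`: `bin_centers` (s, absolute),
#'   `z`, `rate`, `baseline_mean`, `baseline_sd`, `anchors`
#'   (presentation/contact/event_end), `bin_s`, `unit_id`.
#' @export
zscore_psth <- function(unit, event, bin_s = 0.1, sd_floor = NULL) {
  st <- if (inherits(unit, "ethospike_unit")) unit$spike_times else unit
  uid <- if (inherits(unit, "ethospike_unit")) unit$unit_id else NA_character_
  span <- c(event$t_baseline_start, event$t_post_end)
  if (diff(span) < bin_s) stop("degenerate event interval")
  rate <- binned_rates(st, span, bin_s)
  centers <- span[1] + (seq_along(rate) - 0.5) * bin_s
  base_idx <- centers < event$t_presentation
  n_base <- sum(base_idx)
  if (n_base < 1) stop("baseline must contain at least one bin")
  mu <- mean(rate[base_idx])
  sdv <- stats::sd(rate[base_idx])
  if (is.na(sdv)) sdv <- 0
  if (is.null(sd_floor)) sd_floor <- (1 / bin_s) / sqrt(n_base)
  z <- if (sdv == 0 && mu == 0) {
    ifelse(rate == 0, 0, (rate - mu) / sd_floor)
  } else {
    (rate - mu) / max(sdv, sd_floor)
  }
  structure(list(unit_id = uid, bin_centers = centers, z = z, rate = rate,
                 baseline_mean = mu, baseline_sd = sdv, bin_s = bin_s,
                 anchors = c(presentation = event$t_presentation,
                             contact = event$t_contact,
                             event_end = event$t_event_end)),
            class = "ethospike_psth")
}

#' Time-warp a z-scored trace into a common frame
#'
#' The trace is cut at the presentation and contact anchors (snapped to the
#' nearest bin centers so the anchors are interpolation knots) and each of
#' the three segments is resampled by cubic spline interpolation to a fixed
#' number of samples. Anchor values are therefore preserved exactly, and
#' segment boundaries land at fixed common-frame positions. Warped traces
#' are for visualization/averaging only; quantification always runs on the
#' raw unwarped z data.
#'
#' @param psth An `ethospike_psth` (from [zscore_psth()]).
#' @param lengths Integer vector of 3 segment lengths (samples), default
#'   `c(50, 100, 50)` for baseline-to-presentation, presentation-to-contact
#'   and contact-to-end.
#' @return Object of class `ethospike_warped`: `values` (common-frame
#'   samples), `anchor_index` (positions of presentation and contact in the
#'   common frame), `lengths`.
#' @export
timewarp <- function(psth, lengths = c(50, 100, 50)) {
  x <- psth$bin_centers; y <- psth$z
  tp <- psth$anchors[["presentation"]]; tc <- psth$anchors[["contact"]]
  if (tp <= x[1] || tc >= x[length(x)] || tc <= tp)
    stop("anchors out of range of the trace")
  ip <- which.min(abs(x - tp))
  ic <- which.min(abs(x - tc))
  if (ic <= ip) stop("anchors collapse onto the same bin")
  seg <- function(i0, i1, n) {
    xs <- x[i0:i1]; ys <- y[i0:i1]
    xo <- seq(xs[1], xs[length(xs)], length.out = n)
    stats::spline(xs, ys, xout = xo, method = "natural")$y
  }
  s1 <- seg(1, ip, lengths[1])
  s2 <- seg(ip, ic, lengths[2])
  s3 <- seg(ic, length(x), lengths[3])
  structure(list(values = c(s1, s2[-1], s3[-1]),
                 anchor_index = c(presentation = lengths[1],
                                  contact = lengths[1] + lengths[2] - 1L),
                 lengths = lengths),
            class = "ethospike_warped")
}

# latency (s, from presentation) of the peak of the smoothed z trace in
# [presentation, contact); ties broken by earliest bin; NA if trace is flat
peak_latency <- function(psth, smooth_bins = 10) {
  sel <- psth$bin_centers >= psth$anchors[["presentation"]] &
    psth$bin_centers < psth$anchors[["contact"]]
  z <- psth$z[sel]
  if (!length(z) || all(z == z[1])) return(NA_real_)
  if (smooth_bins > 1 && length(z) > smooth_bins) {
    k <- rep(1 / smooth_bins, smooth_bins)
    zs <- stats::filter(z, k, sides = 2)
    z[!is.na(zs)] <- zs[!is.na(zs)]
  }
  psth$bin_centers[sel][which.max(z)] - psth$anchors[["presentation"]]
}

#' Onset synchrony of responsive units within vs across events
#'
#' For every responsive unit and every event of its driving class, the
#' latency to peak z-scored firing after presentation but before first
#' contact is measured (argmax of the boxcar-smoothed 100-ms z trace, ties
#' to the earliest bin). Within-event distances pair different units inside
#' the same trial; across-event distances pair the same unit pairs across
#' different trials. The two distance sets are compared with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param session An `ethospike_session`.
#' @param scoring Result of [score_session()].
#' @param bin_s PSTH bin width (s).
#' @param smooth_bins Boxcar width (bins) used before the argmax.
#' @param max_pairs Cap on the number of distances kept per set (subsampled
#'   reproducibly if exceeded).
#' @return List `within`, `across` (distance vectors, s), `latencies`
#'   (long data.frame) and `test` (the KS test).
#' @export
onset_synchrony <- function(session, scoring, bin_s = 0.1, smooth_bins = 10,
                            max_pairs = 20000) {
  ev <- session$events
  classes <- vapply(ev, `[[`, "", "stimulus_class")
  prof <- scoring$profiles
  lat <- list()
  for (i in seq_along(session$units)) {
    if (!prof$responsive[i]) next
    cat_i <- prof$category[i]
    drives <- if (cat_i == "panresponsive") seq_along(ev)
    else if (grepl("_specific$", cat_i))
      which(classes == sub("_specific$", "", cat_i))
    else seq_along(ev)  # multimodal: use all events
    for (e in drives) {
      l <- peak_latency(zscore_psth(session$units[[i]], ev[[e]], bin_s),
                        smooth_bins)
      if (is.na(l)) next  # flat trace: unit skipped for this event
      lat[[length(lat) + 1]] <- data.frame(unit = i, event = e, latency = l)
    }
  }
  if (!length(lat)) stop("no responsive unit produced a latency")
  lat <- do.call(rbind, lat)
  within <- numeric(0); across <- numeric(0)
  by_event <- split(lat, lat$event)
  for (d in by_event) {
    if (nrow(d) < 2) next
    m <- abs(outer(d$latency, d$latency, "-"))
    within <- c(within, m[upper.tri(m)])
  }
  evs <- unique(lat$event)
  if (length(evs) >= 2) {
    for (a in seq_along(evs)) for (b in seq_along(evs)) {
      if (a == b) next
      da <- by_event[[as.character(evs[a])]]
      db <- by_event[[as.character(evs[b])]]
      common_pairs <- expand.grid(i = da$unit, j = db$unit)
      keep <- common_pairs$i < common_pairs$j
      if (!any(keep)) next
      li <- da$latency[match(common_pairs$i[keep], da$unit)]
      lj <- db$latency[match(common_pairs$j[keep], db$unit)]
      across <- c(across, abs(li - lj))
    }
  }
  sub <- function(x) if (length(x) > max_pairs)
    x[round(seq(1, length(x), length.out = max_pairs))] else x
  within <- sub(within); across <- sub(across)
  test <- if (length(within) >= 2 && length(across) >= 2)
    suppressWarnings(stats::ks.test(within, across)) else NULL
  list(within = within, across = across, latencies = lat, test = test)
}

#' Detect minutes-long aftereffects following stimulus removal
#'
#' For each responsive unit and each event of its driving class, firing is
#' z-scored in `bin_s` bins against the event's own baseline and averaged
#' over the first `horizon_s` seconds after stimulus removal. A unit/event
#' is flagged when that mean exceeds `z_thresh`; the unit-level flag uses
#' the unit's mean across its analyzed events. A per-bin flag-proportion
#' curve is also returned.
#'
#' @param session An `ethospike_session`.
#' @param scoring Result of [score_session()].
#' @param z_thresh Flag threshold on the mean bin z (default 1).
#' @param bin_s Bin width (s, default 10).
#' @param horizon_s Post-removal horizon (s, default 180). If the post
#'   period is shorter, the available span is analyzed and flagged as
#'   truncated.
#' @return List `per_event` (unit, event, mean_z, flagged), `per_unit`
#'   (unit_id, category, mean_z, flagged), `proportions` (per category),
#'   `bin_curve` (per-bin flagged proportion across unit/events),
#'   `truncated`.
#' @export
detect_aftereffects <- function(session, scoring, z_thresh = 1, bin_s = 10,
                                horizon_s = 180) {
  ev <- session$events
  classes <- vapply(ev, `[[`, "", "stimulus_class")
  prof <- scoring$profiles
  per_event <- list()
  n_bins <- floor(horizon_s / bin_s)
  bin_z <- NULL
  truncated <- FALSE
  for (i in seq_along(session$units)) {
    if (!prof$responsive[i]) next
    cat_i <- prof$category[i]
    drives <- if (cat_i == "panresponsive") seq_along(ev)
    else if (grepl("_specific$", cat_i))
      which(classes == sub("_specific$", "", cat_i))
    else seq_along(ev)
    st <- session$units[[i]]$spike_times
    for (e in drives) {
      blk <- ev[[e]]
      avail <- blk$t_post_end - blk$t_event_end
      if (avail < horizon_s) truncated <- TRUE
      span <- min(horizon_s, avail)
      if (span < bin_s) next
      base <- binned_rates(st, c(blk$t_baseline_start, blk$t_presentation),
                           bin_s)
      mu <- mean(base); sdv <- stats::sd(base)
      floor_sd <- (1 / bin_s) / sqrt(length(base))
      sdv <- max(sdv, floor_sd, na.rm = TRUE)
      post <- binned_rates(st, c(blk$t_event_end, blk$t_event_end + span),
                           bin_s)
      z <- (post - mu) / sdv
      zpad <- c(z, rep(NA, n_bins - length(z)))
      bin_z <- rbind(bin_z, zpad)
      per_event[[length(per_event) + 1]] <-
        data.frame(unit = i, unit_id = prof$unit_id[i], event = e,
                   mean_z = mean(z), flagged = mean(z) > z_thresh)
    }
  }
  if (!length(per_event)) stop("no responsive unit/event to analyze")
  per_event <- do.call(rbind, per_event)
  agg <- stats::aggregate(mean_z ~ unit + unit_id, per_event, mean)
  agg$flagged <- agg$mean_z > z_thresh
  agg$category <- prof$category[agg$unit]
  props <- stats::aggregate(flagged ~ category, agg, mean)
  list(per_event = per_event,
       per_unit = agg[order(agg$unit), c("unit_id", "category", "mean_z",
                                         "flagged")],
       proportions = props,
       bin_curve = colMeans(bin_z > z_thresh, na.rm = TRUE),
       truncated = truncated)
}

#' Decoding accuracy around event start and stop
#'
#' Response scores are recomputed in `bin_s` windows from `pre_s` before
#' event start through the event to `post_s` after event stop, and each
#' window's population vector is fed to a stimulus decoder trained (leave
#' one event out) on the full event-period scores. The returned accuracy
#' trace shows when stimulus identity becomes and remains decodable.
#'
#' @param session An `ethospike_session`.
#' @param scoring Result of [score_session()].
#' @param bin_s Window width (s, default 10).
#' @param pre_s Seconds before event start (default 120).
#' @param post_s Seconds after event stop (default 120).
#' @param min_spikes Passed to [response_score()] for the window scores.
#' @return data.frame `segment` (pre/event/post), `offset_s` (window start
#'   relative to the segment's anchor), `accuracy`.
#' @export
event_period_decode_timecourse <- function(session, scoring, bin_s = 10,
                                           pre_s = 120, post_s = 120,
                                           min_spikes = 10) {
  ev <- session$events
  prof <- scoring$profiles
  keep <- which(prof$responsive)
  if (length(keep) < 2) stop("need at least 2 responsive units")
  labels <- scoring$events$stimulus_class
  train <- t(scoring$scores[keep, , drop = FALSE])  # events x units

  offsets <- list(
    pre = seq(-pre_s, -bin_s, by = bin_s),
    event = seq(0, session$events[[1]]$t_event_end -
                  session$events[[1]]$t_presentation - bin_s, by = bin_s),
    post = seq(0, post_s - bin_s, by = bin_s))
  out <- list()
  for (segname in names(offsets)) {
    for (off in offsets[[segname]]) {
      feats <- matrix(NA_real_, length(ev), length(keep))
      ok <- rep(TRUE, length(ev))
      for (e in seq_along(ev)) {
        blk <- ev[[e]]
        t0 <- switch(segname,
                     pre = blk$t_presentation + off,
                     event = blk$t_presentation + off,
                     post = blk$t_event_end + off)
        if (t0 < blk$t_baseline_start || t0 + bin_s > blk$t_post_end) {
          ok[e] <- FALSE; next
        }
        base <- c(blk$t_baseline_start, blk$t_presentation)
        for (u in seq_along(keep)) {
          st <- session$units[[keep[u]]]$spike_times
          feats[e, u] <- response_score(binned_rates(st, base, 1),
                                        binned_rates(st, c(t0, t0 + bin_s), 1),
                                        min_spikes, 1)
        }
      }
      if (sum(ok) < 2) next
      pred <- character(length(ev))
      for (e in which(ok)) {
        fit <- lda_fit(train[-e, , drop = FALSE], labels[-e])
        pred[e] <- lda_predict(fit, feats[e, , drop = FALSE])
      }
      out[[length(out) + 1]] <- data.frame(
        segment = segname, offset_s = off,
        accuracy = mean(pred[ok] == labels[ok]))
    }
  }
  do.call(rbind, out)
}
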