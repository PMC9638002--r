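#' Simulation configuration
#'
#' Collects every knob of the synthetic-session generator. Defaults emulate
#' the recorded sessions the pipeline is designed for: a battery of four
#' stimulus classes presented twice each in 5-min baseline / 5-min event /
#' 5-min post blocks; mostly low-rate units (median baseline 0.5 spikes/s)
#' whose firing increases 3-6x during their preferred event beginning before
#' first contact; brief presentation/removal transients in panresponsive
#' units; minutes-long exponentially decaying aftereffects in ~30% of
#' responsive units; millisecond-latency pairwise spike coupling; and an 80%
#' random sync-pulse pattern with a small clock offset and drift.
#'
#' @param n_units Number of units.
#' @param class_mix Named proportions over `male_specific`, `female_specific`,
#'   `toy_specific`, `food_specific`, `panresponsive`, `decreased`,
#'   `nonresponsive`; must sum to 1. Counts are allocated by largest
#'   remainder so the simulated cohort composition equals the mix exactly.
#' @param baseline_rate List with `meanlog`, `sdlog` of the log-normal
#'   baseline-rate distribution (median `exp(meanlog)` = 0.5 spikes/s by
#'   default) and `pan_meanlog` used for panresponsive units.
#' @param event_gain_range Range the per-unit multiplicative event gain is
#'   drawn from (uniform), default `c(3, 6)`.
#' @param presentation_transient List `amp` (additive gain) and `dur_s` for
#'   the panresponsive on/off bursts at presentation and removal.
#' @param aftereffect List `prob` (fraction of responsive units that persist;
#'   assigned as an exact rounded count) and `tau_s` (exponential decay time
#'   constant, seconds).
#' @param decreased_gain Multiplicative gain (< 1) for `decreased` units
#'   during their suppressed class.
#' @param connections Optional data.frame with columns `proj`, `targ` (unit
#'   indices), `delay_ms` in (0, 5], `transfer_prob` in \[0, 1\]; spikes are
#'   coupled with [inject_connection()].
#' @param connection_jitter_ms Half-width of the uniform synaptic jitter
#'   (ms) applied to induced spikes.
#' @param n_presentations Presentations per stimulus class.
#' @param baseline_s,event_s,post_s Epoch durations (s).
#' @param contact_delay_range Range (s) of the presentation-to-first-contact
#'   delay, drawn uniformly per trial.
#' @param onset_jitter_s SD (s) of the per-unit Gaussian jitter around each
#'   trial's common response onset.
#' @param interneuron_frac Fraction of units given narrow waveforms and a
#'   `interneuron_rate_mult`-fold higher baseline rate.
#' @param interneuron_rate_mult Baseline-rate multiplier for interneurons.
#' @param cluster_depths If `TRUE`, male/toy/food-specific units are placed
#'   at category-specific depth clusters along the probe.
#' @param probe List `n_channels`, `spacing_um`, `sample_rate`,
#'   `waveform_samples`.
#' @param sync List `frame_rate` (Hz), `p_sent` (pulse probability per
#'   frame), `clock_offset_s`, `clock_drift` (relative).
#' @param behavior List of tracking-simulation parameters: `frame_rate`,
#'   `duration_s`, `social_bout_range` (s), `nonsocial_frac`,
#'   `dropout_rate`, `arena` (width, height in cm), `noise_sd` (cm).
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_units = 50,
                       class_mix = c(male_specific = 0.06,
                                     female_specific = 0.06,
                                     toy_specific = 0.06,
                                     food_specific = 0.06,
                                     panresponsive = 0.12,
                                     decreased = 0.08,
                                     nonresponsive = 0.56),
                       baseline_rate = list(meanlog = log(0.5), sdlog = 0.5,
                                            pan_meanlog = log(2)),
                       event_gain_range = c(3, 6),
                       presentation_transient = list(amp = 3, dur_s = 2),
                       aftereffect = list(prob = 0.3, tau_s = 120),
                       decreased_gain = 0.2,
                       connections = NULL,
                       connection_jitter_ms = 0.5,
                       n_presentations = 2,
                       baseline_s = 300, event_s = 300, post_s = 300,
                       contact_delay_range = c(5, 20),
                       onset_jitter_s = 0.5,
                       interneuron_frac = 0.2,
                       interneuron_rate_mult = 8,
                       cluster_depths = FALSE,
                       probe = list(n_channels = 64, spacing_um = 20,
                                    sample_rate = 30000,
                                    waveform_samples = 48),
                       sync = list(frame_rate = 30, p_sent = 0.8,
                                   clock_offset_s = 3, clock_drift = 2e-5),
                       behavior = list(frame_rate = 30, duration_s = 600,
                                       social_bout_range = c(1, 3),
                                       nonsocial_frac = 0.6,
                                       dropout_rate = 0.03,
                                       arena = c(100, 70), noise_sd = 0.3),
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$class_mix) - 1) > 1e-8)
    stop("config error: class_mix proportions must sum to 1")
  if (any(cfg$event_gain_range <= 0))
    stop("config error: event_gain must be > 0")
  if (cfg$decreased_gain <= 0 || cfg$decreased_gain >= 1)
    stop("config error: decreased_gain must be in (0, 1)")
  if (!is.null(cfg$connections)) {
    cn <- cfg$connections
    if (any(cn$transfer_prob < 0 | cn$transfer_prob > 1))
      stop("config error: transfer_prob must be in [0, 1]")
    if (any(cn$delay_ms <= 0 | cn$delay_ms > 5))
      stop("config error: delay_ms must be in (0, 5]")
  }
  if (cfg$aftereffect$prob < 0 || cfg$aftereffect$prob > 1)
    stop("config error: aftereffect prob must be in [0, 1]")
  invisible(TRUE)
}

# largest-remainder allocation of n into proportions p
allocate_counts <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  k
}

# sequential dead-time deletion: drop any spike within `ref_s` of the last
# retained spike
apply_dead_time <- function(st, ref_s = 0.002) {
  repeat {
    bad <- which(diff(st) < ref_s) + 1L
    if (!length(bad)) return(st)
    bad <- bad[c(TRUE, diff(bad) > 1L)]  # keep the first of each burst
    st <- st[-bad]
  }
}

#' Homogeneous Poisson spike train
#' @param rate_hz Rate (spikes/s).
#' @param duration_s Duration (s).
#' @param t0 Start time (s).
#' @return Sorted spike times in `[t0, t0 + duration_s)`.
#' @export
simulate_poisson_train <- function(rate_hz, duration_s, t0 = 0) {
  n <- stats::rpois(1, rate_hz * duration_s)
  sort(stats::runif(n, t0, t0 + duration_s))
}

#' Superimpose coupled spikes onto a target train
#'
#' Each projection spike independently emits a target spike at
#' `+delay_ms` plus a uniform jitter of `+/- jitter_ms`, with probability
#' `transfer_prob` — the generative model behind a short-latency
#' cross-correlogram peak.
#'
#' @param projection_spikes Sorted projection spike times (s).
#' @param delay_ms Synaptic delay (ms), in (0, 5].
#' @param transfer_prob Spike transmission probability in \[0, 1\].
#' @param jitter_ms Half-width (ms) of the uniform latency jitter.
#' @return Sorted induced target spike times (s).
#' @export
inject_connection <- function(projection_spikes, delay_ms, transfer_prob,
                              jitter_ms = 0.5) {
  if (transfer_prob < 0 || transfer_prob > 1)
    stop("config error: transfer_prob must be in [0, 1]")
  sel <- stats::runif(length(projection_spikes)) < transfer_prob
  n <- sum(sel)
  if (n == 0) return(numeric(0))
  jit <- if (jitter_ms > 0) stats::runif(n, -jitter_ms, jitter_ms) else 0
  sort(projection_spikes[sel] + (delay_ms + jit) / 1000)
}

#' Merge spike trains, dropping near-coincident duplicates
#' @param a,b Sorted spike-time vectors (s).
#' @param min_sep_ms Minimum separation (ms); later spikes closer than this
#'   to their predecessor are dropped.
#' @return Sorted merged train.
#' @export
merge_spike_trains <- function(a, b, min_sep_ms = 0.05) {
  s <- sort(c(a, b))
  if (length(s) < 2) return(s)
  s[c(TRUE, diff(s) >= min_sep_ms / 1000)]
}

# per-unit template shape parameters beyond trough-to-peak delay; real mean
# waveforms differ in trough/peak widths, amplitude ratios, pre-trough bumps,
# spatial asymmetry and along-probe propagation, which is what makes units
# distinguishable across days
draw_waveform_shape <- function() {
  list(trough_w = stats::runif(1, 1.5, 3.5),
       peak_w = stats::runif(1, 3, 6),
       peak_ratio = stats::runif(1, 0.25, 0.7),
       bump_amp = stats::runif(1, 0, 0.2),
       bump_w = stats::runif(1, 2, 4),
       center_off = stats::runif(1, -0.5, 0.5),
       prof_asym = stats::runif(1, 0.7, 1.4),
       lag_per_ch = stats::runif(1, -0.3, 0.3))
}

# spike template across probe channels: gaussian trough + later peak with a
# gaussian spatial profile, optionally asymmetric and propagating
make_waveform <- function(n_channels, center_ch, ttp_ms, amp_uv,
                          sample_rate = 30000, n_samples = 48,
                          chan_sd = 1.5, inverted = FALSE,
                          shape = list()) {
  def <- list(trough_w = 2, peak_w = 4, peak_ratio = 0.45, bump_amp = 0,
              bump_w = 3, center_off = 0, prof_asym = 1, lag_per_ch = 0)
  sh <- utils::modifyList(def, shape)
  s <- seq_len(n_samples)
  s_trough <- 16
  s_peak <- s_trough + max(1, round(ttp_ms / 1000 * sample_rate))
  wf <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    d <- ch - center_ch - sh$center_off
    sdc <- chan_sd * if (d > 0) sh$prof_asym else 1
    prof <- exp(-d^2 / (2 * sdc^2))
    if (prof < 1e-6) next
    lag <- sh$lag_per_ch * (ch - center_ch)
    w <- sh$bump_amp * exp(-(s - (s_trough - 6) - lag)^2 / (2 * sh$bump_w^2)) -
      exp(-(s - s_trough - lag)^2 / (2 * sh$trough_w^2)) +
      sh$peak_ratio * exp(-(s - s_peak - lag)^2 / (2 * sh$peak_w^2))
    wf[ch, ] <- prof * w
  }
  if (inverted) wf <- -wf
  amp_uv * wf
}

#' Simulate a full recording session with ground truth
#'
#' Units are inhomogeneous-Poisson with rate `lambda(t) = baseline x
#' gain(t)`: gain is 1 at baseline, the unit's event gain during its
#' preferred event(s) starting at a per-trial onset between presentation and
#' first contact (one common onset per trial, shared across responsive units
#' up to a per-unit Gaussian jitter), plus additive panresponsive transients
#' at presentation and removal, plus an exponential aftereffect decay
#' `1 + (gain - 1) exp(-(t - t_event_end)/tau)` for flagged units, truncated
#' at the start of the next block. `decreased` units use a gain < 1 during
#' one class. Pairwise coupling is superimposed with [inject_connection()].
#'
#' @param config A [sim_config()].
#' @return List with elements `session` (an `ethospike_session`) and
#'   `truth` (per-unit categories, cell types, gains, aftereffect flags,
#'   trial onsets, injected connections, true frame times).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  classes <- stimulus_classes()

  ## event schedule: randomized presentation order, contiguous blocks
  sched <- sample(rep(classes, config$n_presentations))
  block_len <- config$baseline_s + config$event_s + config$post_s
  pres_count <- stats::setNames(integer(length(classes)), classes)
  events <- vector("list", length(sched))
  for (k in seq_along(sched)) {
    cls <- sched[k]
    pres_count[cls] <- pres_count[cls] + 1L
    t0 <- (k - 1) * block_len
    tp <- t0 + config$baseline_s
    tc <- tp + stats::runif(1, config$contact_delay_range[1],
                            config$contact_delay_range[2])
    te <- tp + config$event_s
    events[[k]] <- new_event_block(cls, pres_count[cls], t0, tp, tc, te,
                                   te + config$post_s)
  }
  t_total <- length(sched) * block_len

  ## unit composition (exact rounded counts, randomly allocated)
  n <- config$n_units
  counts <- allocate_counts(n, config$class_mix)
  category <- sample(rep(names(config$class_mix), counts))
  pref_class <- ifelse(grepl("_specific$", category),
                       sub("_specific$", "", category), NA)
  decreased_class <- ifelse(category == "decreased", sample(classes, n,
                                                            replace = TRUE), NA)
  is_interneuron <- seq_len(n) %in%
    sample(n, round(config$interneuron_frac * n))
  base <- stats::rlnorm(n,
                        ifelse(category == "panresponsive",
                               config$baseline_rate$pan_meanlog,
                               config$baseline_rate$meanlog),
                        config$baseline_rate$sdlog)
  base[is_interneuron] <- base[is_interneuron] * config$interneuron_rate_mult
  gain <- stats::runif(n, config$event_gain_range[1],
                       config$event_gain_range[2])
  responsive <- category %in% c("male_specific", "female_specific",
                                "toy_specific", "food_specific",
                                "panresponsive")
  aff <- rep(FALSE, n)
  n_resp <- sum(responsive)
  if (n_resp > 0 && config$aftereffect$prob > 0) {
    pick <- sample(which(responsive),
                   round(config$aftereffect$prob * n_resp))
    aff[pick] <- TRUE
  }

  ## probe placement
  nch <- config$probe$n_channels
  if (config$cluster_depths) {
    centers <- stats::setNames(round(seq(0.15, 0.85, length.out = 4) * nch),
                               classes)
    channel <- integer(n)
    for (i in seq_len(n)) {
      channel[i] <- if (!is.na(pref_class[i]) && pref_class[i] != "female")
        max(1, min(nch, round(stats::rnorm(1, centers[pref_class[i]], 3))))
      else sample(nch, 1)
    }
  } else channel <- sample(nch, n, replace = TRUE)
  depth <- (channel - 1) * config$probe$spacing_um

  ## per-trial common onsets + per-unit jitter
  tp_all <- vapply(events, `[[`, 0, "t_presentation")
  tc_all <- vapply(events, `[[`, 0, "t_contact")
  te_all <- vapply(events, `[[`, 0, "t_event_end")
  pe_all <- vapply(events, `[[`, 0, "t_post_end")
  common_onset <- stats::runif(length(events), tp_all, tc_all)
  onset <- matrix(NA_real_, n, length(events))
  for (i in seq_len(n)) {
    o <- common_onset + stats::rnorm(length(events), 0, config$onset_jitter_s)
    onset[i, ] <- pmin(pmax(o, tp_all), tc_all - 1e-6)
  }

  tr_amp <- config$presentation_transient$amp
  tr_dur <- config$presentation_transient$dur_s
  tau <- config$aftereffect$tau_s

  gain_fn <- function(i, t) {
    g <- rep(1, length(t))
    drives <- if (category[i] == "panresponsive") seq_along(events)
    else if (!is.na(pref_class[i])) which(vapply(events, `[[`, "",
                                                 "stimulus_class") ==
                                            pref_class[i])
    else integer(0)
    for (e in drives) {
      g[t >= onset[i, e] & t < te_all[e]] <- gain[i]
      if (aff[i]) {
        sel <- t >= te_all[e] & t < pe_all[e]
        g[sel] <- 1 + (gain[i] - 1) * exp(-(t[sel] - te_all[e]) / tau)
      }
    }
    if (category[i] == "panresponsive") {
      for (e in seq_along(events)) {
        g[t >= tp_all[e] & t < tp_all[e] + tr_dur] <-
          g[t >= tp_all[e] & t < tp_all[e] + tr_dur] + tr_amp
        g[t >= te_all[e] & t < te_all[e] + tr_dur] <-
          g[t >= te_all[e] & t < te_all[e] + tr_dur] + tr_amp
      }
    }
    if (category[i] == "decreased") {
      e_dec <- which(vapply(events, `[[`, "", "stimulus_class") ==
                       decreased_class[i])
      for (e in e_dec) g[t >= tp_all[e] & t < te_all[e]] <- config$decreased_gain
    }
    g
  }

  ## thinned inhomogeneous Poisson trains with a 2-ms absolute dead time,
  ## so simulated units satisfy the refractory QC real sorted units meet
  spikes <- vector("list", n)
  for (i in seq_len(n)) {
    lam_max <- base[i] * (max(gain[i], 1) + tr_amp + 0.01)
    ncand <- stats::rpois(1, lam_max * t_total)
    tc_cand <- sort(stats::runif(ncand, 0, t_total))
    keep <- stats::runif(ncand) < base[i] * gain_fn(i, tc_cand) / lam_max
    spikes[[i]] <- apply_dead_time(unique(tc_cand[keep]))
  }

  ## pairwise coupling
  if (!is.null(config$connections)) {
    cn <- config$connections
    for (r in seq_len(nrow(cn))) {
      ind <- inject_connection(spikes[[cn$proj[r]]], cn$delay_ms[r],
                               cn$transfer_prob[r],
                               config$connection_jitter_ms)
      spikes[[cn$targ[r]]] <- merge_spike_trains(spikes[[cn$targ[r]]],
                                                 ind[ind < t_total])
    }
  }

  ## waveforms + cell types
  ttp <- ifelse(is_interneuron, stats::rnorm(n, 0.30, 0.04),
                stats::rnorm(n, 0.75, 0.08))
  ttp <- pmax(ttp, 0.12)
  amp <- stats::runif(n, 50, 150)
  ids <- sprintf("u%03d", seq_len(n))
  units <- vector("list", n)
  for (i in seq_len(n)) {
    wf <- make_waveform(nch, channel[i], ttp[i], amp[i],
                        config$probe$sample_rate,
                        config$probe$waveform_samples,
                        shape = draw_waveform_shape())
    units[[i]] <- new_unit(ids[i], spikes[[i]], channel[i], depth[i], wf)
  }

  ## sync pulses with offset + drift
  fr <- config$sync$frame_rate
  n_frames <- floor(t_total * fr)
  sent_times <- (seq_len(n_frames) - 1) / fr
  true_frame_times <- config$sync$clock_offset_s +
    sent_times * (1 + config$sync$clock_drift)
  flags <- stats::runif(n_frames) < config$sync$p_sent
  flags[1] <- TRUE; flags[n_frames] <- TRUE
  sync <- new_sync_train(flags, sent_times, true_frame_times[flags], fr)

  session <- new_session(units, events, sync,
                         metadata = list(generator = "ethospike::simulate_session",
                                         seed = config$seed))
  truth <- list(
    units = data.frame(unit_id = ids, category = category,
                       pref_class = pref_class,
                       decreased_class = decreased_class,
                       baseline_hz = base, event_gain = gain,
                       aftereffect = aff, tau_s = ifelse(aff, tau, NA),
                       cell_type = ifelse(is_interneuron,
                                          "putative_interneuron",
                                          "putative_pyramidal"),
                       trough_to_peak_ms = ttp,
                       channel = channel, depth_um = depth,
                       stringsAsFactors = FALSE),
    onsets = onset, common_onset = common_onset,
    connections = if (is.null(config$connections)) NULL else
      data.frame(proj_id = ids[config$connections$proj],
                 targ_id = ids[config$connections$targ],
                 config$connections),
    frame_times = true_frame_times)
  list(session = session, truth = truth)
}

#' Simulate two-agent pose tracking with scripted behavior bouts
#'
#' Two rigid-ish 10-body-part skeletons move in a rectangular arena.
#' Scripted bouts realize each of the 7 behavior labels by construction
#' (head-to-head: snouts close and facing; approach: implanted moves toward
#' a stationary conspecific; following: aligned co-motion; etc.), separated
#' by non-social stretches whose durations are scaled so the long-run
#' non-social frame fraction equals `behavior$nonsocial_frac`. Body-part
#' coordinates get Gaussian noise and i.i.d. low-likelihood dropouts at
#' `behavior$dropout_rate`.
#'
#' @param config A [sim_config()]; only `behavior` and `seed` are used.
#' @return List with `tracking` (data.frame: frame, agent, bodypart, x, y,
#'   likelihood), `labels` (true behavior label per frame) and
#'   `frame_times` (s, camera clock).
#' @export
simulate_tracking <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 104729L)  # decoupled from the spike stream
  bh <- config$behavior
  fr <- bh$frame_rate
  n_frames <- round(bh$duration_s * fr)
  soc <- c("head-head", "head-tail", "approach", "following",
           "conspecific-contact", "other-social")

  ## bout schedule with exact non-social fraction in expectation
  labels <- character(0)
  cyc <- character(0)
  while (length(labels) < n_frames) {
    if (length(cyc) == 0) cyc <- sample(soc)
    s_dur <- stats::runif(1, bh$social_bout_range[1], bh$social_bout_range[2])
    ns_dur <- s_dur * bh$nonsocial_frac / (1 - bh$nonsocial_frac)
    labels <- c(labels, rep("non-social", round(ns_dur * fr)),
                rep(cyc[1], round(s_dur * fr)))
    cyc <- cyc[-1]
  }
  labels <- labels[seq_len(n_frames)]

  W <- bh$arena[1]; H <- bh$arena[2]
  clip <- function(p) c(min(max(p[1], 4), W - 4), min(max(p[2], 4), H - 4))
  uv <- function(a) c(cos(a), sin(a))
  p1 <- c(W * 0.3, H * 0.5); h1 <- 0
  p2 <- c(W * 0.7, H * 0.5); h2 <- pi
  dt <- 1 / fr

  imp_parts <- list(head = c(4, 0), headstage_left = c(3, 1),
                    headstage_right = c(3, -1), nape_left = c(1.5, 1),
                    nape_center = c(1.5, 0), nape_right = c(1.5, -1),
                    back_left = c(0, 1), back_center = c(0, 0),
                    back_right = c(0, -1), tailbase = c(-3, 0))
  con_parts <- list(nose = c(4, 0), ear_left = c(3, 1), ear_right = c(3, -1),
                    nape_left = c(1.5, 1), nape_center = c(1.5, 0),
                    nape_right = c(1.5, -1), back_left = c(0, 1),
                    back_center = c(0, 0), back_right = c(0, -1),
                    tailbase = c(-3, 0))
  colored <- c("implanted.tailbase", "conspecific.ear_left",
               "conspecific.ear_right", "conspecific.tailbase")

  P1 <- matrix(0, n_frames, 2); H1 <- numeric(n_frames)
  P2 <- matrix(0, n_frames, 2); H2 <- numeric(n_frames)
  prev_label <- ""
  for (f in seq_len(n_frames)) {
    lab <- labels[f]
    new_bout <- lab != prev_label
    if (lab == "non-social") {
      h1 <- h1 + stats::rnorm(1, 0, 0.25)
      h2 <- h2 + stats::rnorm(1, 0, 0.25)
      if (sqrt(sum((p1 - p2)^2)) < 25) {
        h1 <- atan2(p1[2] - p2[2], p1[1] - p2[1])
        h2 <- atan2(p2[2] - p1[2], p2[1] - p1[1])
      }
      p1 <- clip(p1 + 8 * dt * uv(h1))
      p2 <- clip(p2 + 8 * dt * uv(h2))
    } else if (lab == "approach") {
      if (new_bout) {
        ang <- stats::runif(1, 0, 2 * pi)
        p1 <- clip(p2 + 22 * uv(ang))  # restart 22 cm away
      }
      h1 <- atan2(p2[2] - p1[2], p2[1] - p1[1])
      d <- sqrt(sum((p2 - p1)^2))
      p1 <- clip(p1 + min(12, max(2, (d - 8) / 0.5)) * dt * uv(h1))
      p2 <- p2 + stats::rnorm(2, 0, 0.05)  # stationary conspecific
    } else if (lab == "head-head") {
      if (new_bout) {
        m <- clip((p1 + p2) / 2)
        ang <- stats::runif(1, 0, 2 * pi)
        p1 <- clip(m - 4.5 * uv(ang)); p2 <- clip(m + 4.5 * uv(ang))
      }
      h1 <- atan2(p2[2] - p1[2], p2[1] - p1[1]); h2 <- h1 + pi
      p1 <- p1 + stats::rnorm(2, 0, 0.05); p2 <- p2 + stats::rnorm(2, 0, 0.05)
      # re-pin snout gap to ~1 cm
      d <- sqrt(sum((p2 - p1)^2)); mid <- (p1 + p2) / 2
      u <- (p2 - p1) / d
      p1 <- mid - 4.5 * u; p2 <- mid + 4.5 * u
    } else if (lab == "head-tail") {
      h2 <- h2 + stats::rnorm(1, 0, 0.1)
      p2 <- clip(p2 + 3 * dt * uv(h2))
      tail2 <- p2 - 3 * uv(h2)
      h1 <- h2
      p1 <- tail2 - 5 * uv(h1)  # implanted head ~1 cm behind tailbase
    } else if (lab == "following") {
      # well beyond one body length behind, both moving fast: clearly
      # distinct from the near-contact head-to-tail geometry
      if (new_bout) { h <- stats::runif(1, 0, 2 * pi); h1 <- h; h2 <- h }
      h2 <- h2 + stats::rnorm(1, 0, 0.1); h1 <- h2
      p2 <- clip(p2 + 15 * dt * uv(h2))
      p1 <- p2 - 16 * uv(h1)
      if (any(p1 < 4 | p1 > c(W, H) - 4)) { h2 <- h2 + pi; p1 <- clip(p1) }
    } else if (lab == "conspecific-contact") {
      h1 <- h1 + stats::rnorm(1, 0, 0.05)
      p1 <- p1 + stats::rnorm(2, 0, 0.05)
      tail1 <- p1 - 3 * uv(h1)
      h2 <- atan2(tail1[2] - p2[2], tail1[1] - p2[1])
      p2 <- tail1 - 5 * uv(h2)
    } else { # other-social
      if (new_bout) {
        ang <- stats::runif(1, 0, 2 * pi)
        p2 <- clip(p1 + 5 * uv(ang))
      }
      h1 <- h1 + stats::rnorm(1, 0, 0.4); h2 <- h2 + stats::rnorm(1, 0, 0.4)
      p1 <- clip(p1 + stats::rnorm(2, 0, 0.3))
      p2 <- clip(p2 + stats::rnorm(2, 0, 0.3))
    }
    P1[f, ] <- p1; H1[f] <- h1; P2[f, ] <- p2; H2[f] <- h2
    prev_label <- lab
  }

  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  n_parts <- length(imp_parts) + length(con_parts)
  total <- n_frames * n_parts
  out_frame <- integer(total); out_agent <- character(total)
  out_part <- character(total); out_x <- numeric(total)
  out_y <- numeric(total); out_lik <- numeric(total)
  row <- 1L
  for (f in seq_len(n_frames)) {
    for (ag in c("implanted", "conspecific")) {
      parts <- if (ag == "implanted") imp_parts else con_parts
      p <- if (ag == "implanted") P1[f, ] else P2[f, ]
      hh <- if (ag == "implanted") H1[f] else H2[f]
      for (nm in names(parts)) {
        xy <- p + rot(parts[[nm]], hh) + stats::rnorm(2, 0, bh$noise_sd)
        lik <- if (paste(ag, nm, sep = ".") %in% colored)
          stats::runif(1, 0.9992, 1) else stats::runif(1, 0.93, 0.995)
        if (stats::runif(1) < bh$dropout_rate) {
          lik <- stats::runif(1, 0, 0.88)
          xy <- xy + stats::rnorm(2, 0, 15)
        }
        out_frame[row] <- f; out_agent[row] <- ag; out_part[row] <- nm
        out_x[row] <- xy[1]; out_y[row] <- xy[2]; out_lik[row] <- lik
        row <- row + 1L
      }
    }
  }
  list(tracking = data.frame(frame = out_frame, agent = out_agent,
                             bodypart = out_part, x = out_x, y = out_y,
                             likelihood = out_lik, stringsAsFactors = FALSE),
       labels = labels,
       frame_times = (seq_len(n_frames) - 1) / fr)
}

#' Simulate matched two-day waveform cohorts
#'
#' Day-2 waveforms are the day-1 templates shifted by up to
#' `max_drift_channels` probe channels with additive Gaussian noise at the
#' requested SNR (peak amplitude / noise SD); unit order is shuffled.
#'
#' @param n_units Number of units.
#' @param n_channels Probe channels.
#' @param snr Peak-amplitude-to-noise-SD ratio.
#' @param max_drift_channels Maximum absolute channel drift between days.
#' @param related If `FALSE`, day-2 waveforms are fresh unrelated templates
#'   (null cohort for false-acceptance calibration).
#' @param seed RNG seed.
#' @return List `day1`, `day2` (lists of `ethospike_unit` with waveforms)
#'   and `truth` (data.frame day1_id, day2_id, drift; NULL when unrelated).
#' @export
simulate_two_day_waveforms <- function(n_units = 100, n_channels = 120,
                                       snr = 10, max_drift_channels = 2,
                                       related = TRUE, seed = 1) {
  set.seed(seed)
  ch <- sample(seq(6, n_channels - 5), n_units, replace = TRUE)
  ttp <- stats::runif(n_units, 0.2, 0.9)
  amp <- stats::runif(n_units, 50, 150)
  csd <- stats::runif(n_units, 1.0, 2.5)
  shapes <- replicate(n_units, draw_waveform_shape(), simplify = FALSE)
  d1 <- lapply(seq_len(n_units), function(i)
    new_unit(sprintf("d1_%03d", i), numeric(0), ch[i], (ch[i] - 1) * 20,
             make_waveform(n_channels, ch[i], ttp[i], amp[i],
                           chan_sd = csd[i], shape = shapes[[i]])))
  if (related) {
    drift <- sample(-max_drift_channels:max_drift_channels, n_units,
                    replace = TRUE)
    ch2 <- pmin(pmax(ch + drift, 1), n_channels)
    ord <- sample(n_units)
    d2 <- lapply(seq_len(n_units), function(j) {
      i <- ord[j]
      wf <- make_waveform(n_channels, ch2[i], ttp[i], amp[i],
                          chan_sd = csd[i], shape = shapes[[i]])
      wf <- wf + stats::rnorm(length(wf), 0, amp[i] / snr)
      new_unit(sprintf("d2_%03d", j), numeric(0), ch2[i],
               (ch2[i] - 1) * 20, wf)
    })
    truth <- data.frame(day1_id = sprintf("d1_%03d", ord),
                        day2_id = sprintf("d2_%03d", seq_len(n_units)),
                        drift = drift[ord], stringsAsFactors = FALSE)
  } else {
    # unrelated random waveforms: smooth random traces under a spatial
    # envelope, sharing no spike-template structure with day 1
    ch2 <- sample(seq(6, n_channels - 5), n_units, replace = TRUE)
    smooth_kernel <- exp(-((-6:6)^2) / (2 * 2^2))
    smooth_kernel <- smooth_kernel / sum(smooth_kernel)
    d2 <- lapply(seq_len(n_units), function(j) {
      prof <- exp(-((seq_len(n_channels) - ch2[j])^2) /
                    (2 * stats::runif(1, 1.0, 2.5)^2))
      n_samp <- 48
      tr <- stats::filter(stats::rnorm(n_samp + 12), smooth_kernel,
                          sides = 2)
      tr <- tr[!is.na(tr)][seq_len(n_samp)]
      wf <- stats::runif(1, 50, 150) * outer(prof, tr / max(abs(tr)))
      wf <- wf + stats::rnorm(length(wf), 0, 10)
      new_unit(sprintf("d2_%03d", j), numeric(0), ch2[j],
               (ch2[j] - 1) * 20, wf)
    })
    truth <- NULL
  }
  list(day1 = d1, day2 = d2, truth = truth)
}
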