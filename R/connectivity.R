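#' Cross-correlogram of two spike trains
#'
#' Histogram of target-minus-projection spike-time lags in `bin_ms` bins
#' over `+/- span_ms`. Noise statistics (mean, SD of bin counts) are taken
#' from the bins with |lag| in (5, span] ms, i.e. outside the putative
#' synaptic window. When the two trains are identical (autocorrelogram) the
#' zero self-lags are excluded.
#'
#' @param proj,targ Sorted spike times (s) of the projection and target
#'   unit over a common epoch.
#' @param bin_ms Bin width (ms, default 0.25).
#' @param span_ms Half-span (ms, default 50).
#' @return Object of class `ethospike_ccg`: `centers` (ms), `counts`,
#'   `noise_mean`, `noise_sd`, `proj_n`, `targ_n`, `bin_ms`, `span_ms`,
#'   `empty` flag.
#' @export
cross_correlogram <- function(proj, targ, bin_ms = 0.25, span_ms = 50) {
  n_bins <- 2L * as.integer(round(span_ms / bin_ms))
  edges <- seq(-span_ms, span_ms, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  empty <- length(proj) == 0 || length(targ) == 0
  counts <- integer(n_bins)
  if (!empty) {
    span_s <- span_ms / 1000
    lo <- findInterval(proj - span_s, targ)
    hi <- findInterval(proj + span_s, targ)
    nper <- hi - lo
    has <- nper > 0
    if (any(has)) {
      j <- sequence(nper[has]) + rep(lo[has], nper[has])
      lags_ms <- (targ[j] - rep(proj[has], nper[has])) * 1000
      if (identical(proj, targ)) lags_ms <- lags_ms[lags_ms != 0]
      idx <- pmin(pmax(floor((lags_ms + span_ms) / bin_ms) + 1, 1), n_bins)
      counts <- tabulate(idx, nbins = n_bins)
    }
  }
  noise_idx <- abs(centers) > 5 & abs(centers) <= span_ms
  structure(list(centers = centers, counts = counts,
                 noise_mean = mean(counts[noise_idx]),
                 noise_sd = stats::sd(counts[noise_idx]),
                 proj_n = length(proj), targ_n = length(targ),
                 bin_ms = bin_ms, span_ms = span_ms, empty = empty),
            class = "ethospike_ccg")
}

# half-prominence width of the peak at bin `p` by linear interpolation;
# half level is midway between the peak height and the CCG noise mean
peak_extent <- function(counts, centers, p, noise_mean, bin_ms) {
  half <- (counts[p] + noise_mean) / 2
  n <- length(counts)
  # walk left
  l <- p
  while (l > 1 && counts[l - 1] >= half) l <- l - 1
  left <- if (l == 1) centers[1] - bin_ms / 2 else {
    frac <- (half - counts[l - 1]) / (counts[l] - counts[l - 1])
    centers[l - 1] + frac * bin_ms
  }
  r <- p
  while (r < n && counts[r + 1] >= half) r <- r + 1
  right <- if (r == n) centers[n] + bin_ms / 2 else {
    frac <- (half - counts[r + 1]) / (counts[r] - counts[r + 1])
    centers[r + 1] - frac * bin_ms
  }
  list(left_ms = left, right_ms = right, width_ms = right - left,
       bins = l:r)
}

#' Detect a directional putative monosynaptic peak in a CCG
#'
#' Searches the (-5, +5) ms window for bins exceeding the noise mean by
#' `sd_thresh` noise SDs, measures each candidate's half-prominence width
#' by linear interpolation, and retains a peak only if its width is at
#' least `min_width_ms`, its lag is positive and its left edge does not
#' start before 0 ms (directionality). Pairs where either train has fewer
#' than `min_spikes` spikes, or where the tallest bin is below `min_peak`
#' counts, are excluded. Ties are broken by the highest peak, then the
#' smallest lag.
#'
#' @param ccg An `ethospike_ccg`.
#' @param min_spikes Minimum spikes per train (default 100).
#' @param min_peak Minimum peak-bin count (default 20).
#' @param sd_thresh Height threshold in noise SDs above the mean
#'   (default 3).
#' @param min_width_ms Minimum half-prominence peak width (ms,
#'   default 0.75).
#' @param search_ms Half-width of the search window (ms, default 5).
#' @return The CCG with fields `significant`, and when significant
#'   `peak_lag_ms`, `peak_height`, `peak_width_ms`, `peak_left_ms`,
#'   `peak_right_ms`, `peak_bins`.
#' @export
detect_connection <- function(ccg, min_spikes = 100, min_peak = 20,
                              sd_thresh = 3, min_width_ms = 0.75,
                              search_ms = 5) {
  ccg$significant <- FALSE
  if (ccg$empty || ccg$proj_n < min_spikes || ccg$targ_n < min_spikes)
    return(ccg)
  if (!is.finite(ccg$noise_sd) || ccg$noise_sd == 0) return(ccg)
  counts <- ccg$counts; centers <- ccg$centers
  thresh <- ccg$noise_mean + sd_thresh * ccg$noise_sd
  win <- which(abs(centers) < search_ms)
  n <- length(counts)
  cand <- win[counts[win] > thresh & counts[win] >= min_peak]
  # local maxima only (plateaus: keep the first bin)
  cand <- cand[vapply(cand, function(p) {
    (p == 1 || counts[p] > counts[p - 1]) &&
      (p == n || counts[p] >= counts[p + 1])
  }, TRUE)]
  if (!length(cand)) return(ccg)
  best <- NULL
  for (p in cand[order(-counts[cand], abs(centers[cand]))]) {
    ext <- peak_extent(counts, centers, p, ccg$noise_mean, ccg$bin_ms)
    if (ext$width_ms < min_width_ms) next
    if (centers[p] <= 0 || ext$left_ms < 0) next
    best <- c(list(peak_lag_ms = centers[p], peak_height = counts[p]), ext)
    break
  }
  if (is.null(best)) return(ccg)
  ccg$significant <- TRUE
  ccg$peak_lag_ms <- best$peak_lag_ms
  ccg$peak_height <- best$peak_height
  ccg$peak_width_ms <- best$width_ms
  ccg$peak_left_ms <- best$left_ms
  ccg$peak_right_ms <- best$right_ms
  ccg$peak_bins <- best$bins
  ccg
}

#' Connection strength of a detected pair over an epoch
#'
#' Recomputes the CCG on the epoch-restricted trains, re-evaluates
#' significance with the same criteria (noise statistics are per-epoch, so
#' shorter epochs carry larger SDs), and reports the spikes inside the
#' detected peak's lag extent divided by the target's total spikes in the
#' epoch.
#'
#' @param proj,targ Full spike-time vectors (s).
#' @param interval `c(start, end)` epoch (s); `NULL` uses the whole trains.
#' @param ... Passed to [detect_connection()].
#' @param bin_ms,span_ms Passed to [cross_correlogram()].
#' @return `NULL` when the pair is not significant in the epoch (or the
#'   target is silent); otherwise a one-row data.frame with
#'   `spikes_in_peak`, `target_total_spikes`, `strength`, `peak_lag_ms`,
#'   `peak_width_ms`.
#' @export
connection_strength <- function(proj, targ, interval = NULL, bin_ms = 0.25,
                                span_ms = 50, ...) {
  if (!is.null(interval)) {
    proj <- spikes_in(proj, interval)
    targ <- spikes_in(targ, interval)
  }
  if (length(targ) == 0) {
    warning("target silent in epoch; strength undefined")
    return(NULL)
  }
  ccg <- detect_connection(cross_correlogram(proj, targ, bin_ms, span_ms),
                           ...)
  if (!ccg$significant) return(NULL)
  sp <- sum(ccg$counts[ccg$peak_bins])
  data.frame(spikes_in_peak = sp, target_total_spikes = length(targ),
             strength = sp / length(targ), peak_lag_ms = ccg$peak_lag_ms,
             peak_width_ms = ccg$peak_width_ms)
}

#' Scan all ordered unit pairs for putative monosynaptic connections
#'
#' @param spikes List of sorted spike-time vectors (or an
#'   `ethospike_session`, whose units are used).
#' @param interval Optional epoch restriction `c(start, end)` (s).
#' @param ids Optional unit identifiers (default names/indices).
#' @param depths Optional unit depths (um) for the pair-distance report.
#' @param ... Detection parameters passed to [detect_connection()].
#' @param bin_ms,span_ms CCG parameters.
#' @return data.frame of significant directed pairs: `proj`, `targ`,
#'   `peak_lag_ms`, `peak_height`, `peak_width_ms`, `strength`,
#'   `depth_dist_um`.
#' @export
scan_connections <- function(spikes, interval = NULL, ids = NULL,
                             depths = NULL, bin_ms = 0.25, span_ms = 50,
                             ...) {
  if (inherits(spikes, "ethospike_session")) {
    session <- spikes
    spikes <- lapply(session$units, `[[`, "spike_times")
    if (is.null(ids)) ids <- unit_ids(session)
    if (is.null(depths))
      depths <- vapply(session$units, `[[`, 0, "depth_um")
  }
  n <- length(spikes)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (!is.null(interval))
    spikes <- lapply(spikes, spikes_in, interval = interval)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ccg <- detect_connection(
      cross_correlogram(spikes[[i]], spikes[[j]], bin_ms, span_ms), ...)
    if (!ccg$significant) next
    sp <- sum(ccg$counts[ccg$peak_bins])
    out[[length(out) + 1]] <- data.frame(
      proj = ids[i], targ = ids[j], peak_lag_ms = ccg$peak_lag_ms,
      peak_height = ccg$peak_height, peak_width_ms = ccg$peak_width_ms,
      strength = sp / length(spikes[[j]]),
      depth_dist_um = if (is.null(depths)) NA_real_ else
        abs(depths[i] - depths[j]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(proj = character(0), targ = character(0),
                      peak_lag_ms = numeric(0), peak_height = numeric(0),
                      peak_width_ms = numeric(0), strength = numeric(0),
                      depth_dist_um = numeric(0)))
  do.call(rbind, out)
}

#' Enrichment of connection types over chance
#'
#' Observed count of each (projection category -> target category) cell
#' divided by its mean count under random rewiring, obtained by shuffling
#' category labels over the observed projection and target node sets
#' (`n_resample` times, seeded).
#'
#' @param pairs data.frame with `proj`, `targ` unit ids (e.g. from
#'   [scan_connections()]).
#' @param categories Named character vector: category per unit id.
#' @param n_resample Number of label shuffles (default 1000).
#' @param seed RNG seed.
#' @return List `ratio` (matrix proj-category x targ-category; > 1 = more
#'   often than chance; `NA` where a category never occurs), `observed`,
#'   `expected`.
#' @export
connection_type_enrichment <- function(pairs, categories,
                                       n_resample = 1000, seed = 1) {
  cats <- sort(unique(categories))
  tab <- function(pc, tc)
    table(factor(pc, levels = cats), factor(tc, levels = cats))
  obs <- tab(categories[pairs$proj], categories[pairs$targ])
  proj_nodes <- unique(pairs$proj)
  targ_nodes <- unique(pairs$targ)
  set.seed(seed)
  acc <- matrix(0, length(cats), length(cats))
  for (r in seq_len(n_resample)) {
    pshuf <- stats::setNames(sample(categories[proj_nodes]), proj_nodes)
    tshuf <- stats::setNames(sample(categories[targ_nodes]), targ_nodes)
    acc <- acc + tab(pshuf[pairs$proj], tshuf[pairs$targ])
  }
  expd <- acc / n_resample
  ratio <- unclass(obs) / unclass(expd)
  ratio[expd == 0] <- NA
  present_p <- cats %in% categories[proj_nodes]
  present_t <- cats %in% categories[targ_nodes]
  ratio[!present_p, ] <- NA
  ratio[, !present_t] <- NA
  dimnames(ratio) <- list(proj = cats, targ = cats)
  list(ratio = ratio, observed = unclass(obs), expected = unclass(expd))
}

#' Per-pair connection-strength change between consecutive epochs
#'
#' For pairs significant in both epochs, the per-pair strength difference
#' (second minus first) and a paired t test.
#'
#' @param strengths_a,strengths_b data.frames with `proj`, `targ`,
#'   `strength` for the two epochs.
#' @return List `pairs` (per-pair deltas), `mean_delta`, `test` (paired t
#'   test, or NULL with < 2 common pairs).
#' @export
paired_epoch_strength_change <- function(strengths_a, strengths_b) {
  key <- function(d) paste(d$proj, d$targ, sep = "->")
  common <- intersect(key(strengths_a), key(strengths_b))
  a <- strengths_a$strength[match(common, key(strengths_a))]
  b <- strengths_b$strength[match(common, key(strengths_b))]
  deltas <- b - a
  test <- if (length(common) >= 2 && stats::sd(deltas) > 0)
    stats::t.test(b, a, paired = TRUE) else NULL
  list(pairs = data.frame(pair = common, strength_a = a, strength_b = b,
                          delta = deltas, stringsAsFactors = FALSE),
       mean_delta = if (length(deltas)) mean(deltas) else NA_real_,
       test = test)
}
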