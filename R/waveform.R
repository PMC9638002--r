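#' Waveform metrics for cell typing
#'
#' On the peak-amplitude channel, the trough is the global minimum and the
#' peak the subsequent maximum; the trough-to-peak delay separates putative
#' interneurons (short) from pyramidal cells (long). Waveforms whose
#' positive peak precedes the trough are marked inverted and typed
#' `irregular`. The metric is invariant to amplitude scaling.
#'
#' @param unit An `ethospike_unit` with a waveform, or a waveform matrix
#'   (channels x samples).
#' @param sample_rate Samples per second (default 30000).
#' @param baseline_rate_hz Optional baseline rate to carry along (first
#'   5 min of the day; used by [cell_type_clusters()]).
#' @return List `unit_id`, `trough_to_peak_ms`, `inverted`,
#'   `baseline_rate_hz`, `peak_channel`.
#' @export
waveform_metrics <- function(unit, sample_rate = 30000,
                             baseline_rate_hz = NA_real_) {
  wf <- if (inherits(unit, "ethospike_unit")) unit$waveform else unit
  uid <- if (inherits(unit, "ethospike_unit")) unit$unit_id else NA_character_
  if (is.null(wf)) stop("unit has no waveform")
  if (all(wf == 0)) stop("flat waveform: metrics undefined")
  pk_ch <- which.max(apply(abs(wf), 1, max))
  w <- wf[pk_ch, ]
  i_min <- which.min(w); i_max <- which.max(w)
  inverted <- i_max < i_min && abs(w[i_max]) >= abs(w[i_min])
  ttp <- NA_real_
  if (!inverted) {
    after <- w[i_min:length(w)]
    ttp <- (which.max(after) - 1) / sample_rate * 1000
  }
  list(unit_id = uid, trough_to_peak_ms = ttp, inverted = inverted,
       baseline_rate_hz = baseline_rate_hz, peak_channel = pk_ch)
}

#' Split units into putative pyramidal cells and interneurons
#'
#' 2-means clustering on standardized (trough-to-peak delay, baseline rate)
#' with a seeded multi-start; the cluster with the longer mean
#' trough-to-peak delay is labeled `putative_pyramidal`, the other
#' `putative_interneuron`. Inverted waveforms are typed `irregular` and
#' excluded from the clustering.
#'
#' @param metrics List of [waveform_metrics()] results (or a data.frame
#'   with `trough_to_peak_ms`, `inverted`, `baseline_rate_hz`).
#' @param seed RNG seed for the k-means starts.
#' @return Character vector of cell types, one per input unit.
#' @export
cell_type_clusters <- function(metrics, seed = 1) {
  df <- if (is.data.frame(metrics)) metrics else
    data.frame(trough_to_peak_ms = vapply(metrics, `[[`, 0,
                                          "trough_to_peak_ms"),
               inverted = vapply(metrics, `[[`, TRUE, "inverted"),
               baseline_rate_hz = vapply(metrics, `[[`, 0,
                                         "baseline_rate_hz"))
  type <- rep("irregular", nrow(df))
  ok <- !df$inverted & is.finite(df$trough_to_peak_ms) &
    is.finite(df$baseline_rate_hz)
  if (sum(ok) < 2) stop("need at least 2 non-irregular units to cluster")
  x <- scale(cbind(df$trough_to_peak_ms[ok], df$baseline_rate_hz[ok]))
  if (any(!is.finite(x)))
    stop("degenerate metrics: zero variance across units")
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2, nstart = 25)
  mean_ttp <- tapply(df$trough_to_peak_ms[ok], km$cluster, mean)
  pyr <- as.integer(names(mean_ttp)[which.max(mean_ttp)])
  type[ok] <- ifelse(km$cluster == pyr, "putative_pyramidal",
                     "putative_interneuron")
  type
}

# mean over w x w sliding windows via integral images
boxmean <- function(m, w) {
  I <- rbind(0, apply(m, 2, cumsum))
  I <- cbind(0, t(apply(I, 1, cumsum)))
  nr <- nrow(m) - w + 1; nc <- ncol(m) - w + 1
  i <- seq_len(nr); j <- seq_len(nc)
  (I[i + w, j + w, drop = FALSE] - I[i, j + w, drop = FALSE] -
     I[i + w, j, drop = FALSE] + I[i, j, drop = FALSE]) / w^2
}

#' Structural similarity index of two equally sized matrices
#'
#' Mean local SSIM over sliding `window` x `window` patches (luminance x
#' contrast x structure with the standard stabilizing constants), used to
#' compare normalized waveform heatmaps; local windows weight the
#' small-amplitude off-center structure that distinguishes nearby units.
#' With `window = NULL` (or inputs smaller than the window) the global
#' single-window SSIM is returned.
#'
#' @param x,y Numeric matrices of identical dimension.
#' @param window Odd window side length (default 7).
#' @return SSIM in `[-1, 1]`; 1 for identical inputs.
#' @export
ssim <- function(x, y, window = 7) {
  stopifnot(all(dim(x) == dim(y)))
  L <- max(x, y) - min(x, y)
  if (L == 0) return(1)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  if (is.null(window) || any(dim(x) < window)) {
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(as.numeric(x)); vy <- stats::var(as.numeric(y))
    cxy <- stats::cov(as.numeric(x), as.numeric(y))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mx <- boxmean(x, window); my <- boxmean(y, window)
  vx <- boxmean(x * x, window) - mx^2
  vy <- boxmean(y * y, window) - my^2
  cxy <- boxmean(x * y, window) - mx * my
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

# n_channels-wide waveform heatmap centered on the unit's channel,
# zero-padded at the array edge and normalized by absolute peak
centered_heatmap <- function(unit, n_channels = 20) {
  wf <- unit$waveform
  half <- n_channels %/% 2
  rows <- (unit$channel - half + 1):(unit$channel + half)
  out <- matrix(0, n_channels, ncol(wf))
  ok <- rows >= 1 & rows <= nrow(wf)
  out[ok, ] <- wf[rows[ok], ]
  pk <- max(abs(out))
  if (pk > 0) out <- out / pk
  out
}

#' Match units across two recording days by waveform similarity
#'
#' For each day-1 unit, every day-2 unit within `channel_window` channels
#' is compared via the structural similarity of their centered, normalized
#' waveform heatmaps (`n_channels` consecutive channels) with the mean
#' per-channel Pearson correlation as tie-breaker; one-to-one assignment is
#' enforced greedily by similarity. A match is accepted only when both the
#' similarity and the correlation clear their thresholds.
#'
#' @param day1,day2 Lists of `ethospike_unit` with waveforms and channels.
#' @param channel_window Candidate day-2 units within this many channels
#'   (default 5).
#' @param n_channels Heatmap height in channels (default 20).
#' @param min_ssim,min_cor Acceptance thresholds (defaults 0.3 / 0.7,
#'   calibrated for the windowed SSIM so that noise-limited true matches
#'   pass while structure-free waveforms are rejected).
#' @return data.frame `day1_id`, `day2_id`, `ssim`, `channel_cor`,
#'   `accepted`; day-1 units without any candidate are omitted.
#' @export
match_units_across_days <- function(day1, day2, channel_window = 5,
                                    n_channels = 20, min_ssim = 0.3,
                                    min_cor = 0.7) {
  h1 <- lapply(day1, centered_heatmap, n_channels = n_channels)
  h2 <- lapply(day2, centered_heatmap, n_channels = n_channels)
  ch1 <- vapply(day1, `[[`, 0L, "channel")
  ch2 <- vapply(day2, `[[`, 0L, "channel")
  cand <- list()
  for (i in seq_along(day1)) {
    js <- which(abs(ch2 - ch1[i]) <= channel_window)
    for (j in js) {
      s <- ssim(h1[[i]], h2[[j]])
      # per-channel correlations, weighted by signal amplitude so that
      # channels carrying no waveform do not dilute the statistic
      rc <- vapply(seq_len(n_channels), function(r) {
        a <- h1[[i]][r, ]; b <- h2[[j]][r, ]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
        stats::cor(a, b)
      }, 0)
      wt <- apply(abs(h1[[i]]), 1, max)  # day-1 mean waveform as template
      pc <- if (sum(wt) > 0) sum(rc * wt) / sum(wt) else 0
      cand[[length(cand) + 1]] <- data.frame(
        i = i, j = j, ssim = s, channel_cor = pc)
    }
  }
  if (!length(cand))
    return(data.frame(day1_id = character(0), day2_id = character(0),
                      ssim = numeric(0), channel_cor = numeric(0),
                      accepted = logical(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$ssim, -cand$channel_cor), ]
  used_i <- logical(length(day1)); used_j <- logical(length(day2))
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      day1_id = day1[[i]]$unit_id, day2_id = day2[[j]]$unit_id,
      ssim = cand$ssim[r], channel_cor = cand$channel_cor[r],
      accepted = cand$ssim[r] >= min_ssim & cand$channel_cor[r] >= min_cor,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
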