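#' Map video frames onto the ephys clock
#'
#' Frames whose pulse was sent are pinned to their received pulse time, in
#' order. Frames whose pulse was withheld (a random ~20%) are placed by
#' linear interpolation between the neighbouring pulses indexed by frame
#' number, i.e. at the locally estimated frame period; frames before the
#' first or after the last pulse are extrapolated at the nominal frame
#' period.
#'
#' @param sync An `ethospike_sync`.
#' @return Numeric vector, one ephys-clock time (s) per video frame,
#'   strictly increasing.
#' @export
align_sync <- function(sync) {
  flags <- sync$sent_flags
  rec <- sync$received_times
  n <- length(flags)
  idx <- which(flags)
  if (length(idx) != length(rec))
    stop("sync error: sent-true flag count (", length(idx),
         ") does not match received pulse count (", length(rec), ")")
  if (length(rec) >= 2 && any(diff(rec) <= 0))
    stop("data error: received_times not strictly increasing")
  if (length(idx) == 0) stop("sync error: no pulses sent")
  period <- 1 / sync$frame_rate
  ft <- rep(NA_real_, n)
  ft[idx] <- rec
  if (length(idx) >= 2) {
    interp <- stats::approx(idx, rec, xout = seq_len(n), rule = 1)$y
    miss <- is.na(ft) & !is.na(interp)
    ft[miss] <- interp[miss]
  }
  # leading/trailing unsent frames: nominal frame period off the edge pulses
  lead <- seq_len(n) < idx[1]
  ft[lead] <- rec[1] - (idx[1] - which(lead)) * period
  trail <- seq_len(n) > idx[length(idx)]
  ft[trail] <- rec[length(rec)] + (which(trail) - idx[length(idx)]) * period
  if (any(diff(ft) <= 0))
    stop("sync error: aligned frame times are not strictly increasing")
  ft
}

#' Fraction of refractory-period violations
#'
#' Quality-control statistic for sorted single units: the fraction of
#' inter-spike intervals shorter than the refractory period. Units with a
#' fraction at or above `max_fraction` (default 0.1%) fail QC.
#'
#' @param spike_times Sorted spike times (s).
#' @param refractory_ms Refractory period in ms (default 2).
#' @return Fraction in `[0, 1]`: violating ISIs / number of spikes.
#' @export
refractory_violation_fraction <- function(spike_times, refractory_ms = 2) {
  n <- length(spike_times)
  if (n < 2) {
    warning("fewer than 2 spikes; refractory fraction set to 0")
    return(0)
  }
  sum(diff(spike_times) < refractory_ms / 1000) / n
}

#' Refractory QC predicate
#'
#' @param spike_times Sorted spike times (s).
#' @param refractory_ms Refractory period in ms.
#' @param max_fraction Maximum tolerated violation fraction (default 0.001).
#' @return `TRUE` if the unit passes QC.
#' @export
passes_refractory_qc <- function(spike_times, refractory_ms = 2,
                                 max_fraction = 0.001) {
  refractory_violation_fraction(spike_times, refractory_ms) < max_fraction
}
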