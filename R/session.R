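#' Construct a single-unit record
#'
#' A `Unit` bundles everything the pipeline knows about one isolated neuron:
#' its spike times on the ephys clock, its probe location (channel index and
#' depth in micrometers along the shank) and its mean spike waveform
#' (channels x samples).
#'
#' @param unit_id Character scalar, opaque identifier.
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing.
#' @param channel Integer probe-channel index (1-based).
#' @param depth_um Depth along the probe in micrometers (>= 0).
#' @param waveform Optional numeric matrix (channels x samples) of mean spike
#'   voltage.
#' @param region Optional anatomical label, one of `"LA"`, `"BA"`, `"BMA"`,
#'   `"unknown"`.
#' @return An object of class `ethospike_unit`.
#' @export
new_unit <- function(unit_id, spike_times, channel = NA_integer_,
                     depth_um = NA_real_, waveform = NULL,
                     region = "unknown") {
  u <- structure(
    list(unit_id = as.character(unit_id),
         spike_times = as.numeric(spike_times),
         channel = as.integer(channel),
         depth_um = as.numeric(depth_um),
         waveform = waveform,
         region = region),
    class = "ethospike_unit")
  validate_unit(u)
  u
}

validate_unit <- function(u) {
  st <- u$spike_times
  if (length(st) && any(diff(st) <= 0))
    stop("unit ", u$unit_id, ": spike_times must be strictly increasing")
  if (!is.na(u$depth_um) && u$depth_um < 0)
    stop("unit ", u$unit_id, ": depth_um must be >= 0")
  if (!is.null(u$waveform) && !is.matrix(u$waveform))
    stop("unit ", u$unit_id, ": waveform must be a channels x samples matrix")
  invisible(TRUE)
}

#' Construct an event block
#'
#' One stimulus presentation with its five time anchors (seconds, ephys
#' clock): baseline start, stimulus presentation, first direct contact, event
#' end (stimulus removal) and end of the post period. All analysis windows
#' are half-open `[start, end)`.
#'
#' @param stimulus_class One of `"male"`, `"female"`, `"toy"`, `"food"`.
#' @param presentation_index Integer >= 1, which presentation of this class.
#' @param t_baseline_start,t_presentation,t_contact,t_event_end,t_post_end
#'   Anchor times in seconds.
#' @return An object of class `ethospike_event`.
#' @export
new_event_block <- function(stimulus_class, presentation_index,
                            t_baseline_start, t_presentation, t_contact,
                            t_event_end, t_post_end) {
  stimulus_class <- match.arg(stimulus_class, stimulus_classes())
  e <- structure(
    list(stimulus_class = stimulus_class,
         presentation_index = as.integer(presentation_index),
         t_baseline_start = as.numeric(t_baseline_start),
         t_presentation = as.numeric(t_presentation),
         t_contact = as.numeric(t_contact),
         t_event_end = as.numeric(t_event_end),
         t_post_end = as.numeric(t_post_end)),
    class = "ethospike_event")
  validate_event(e)
  e
}

#' The four stimulus classes
#' @return Character vector `c("male", "female", "toy", "food")`.
#' @export
stimulus_classes <- function() c("male", "female", "toy", "food")

validate_event <- function(e) {
  with(e, {
    if (!(t_baseline_start < t_presentation && t_presentation <= t_contact &&
          t_contact < t_event_end && t_event_end < t_post_end))
      stop("event ", stimulus_class, "#", presentation_index,
           ": anchors must satisfy baseline_start < presentation <= contact",
           " < event_end < post_end")
  })
  invisible(TRUE)
}

#' Epoch intervals of an event block
#'
#' @param event An `ethospike_event`.
#' @return Named list of `c(start, end)` intervals (half-open) for
#'   `baseline`, `event` and `post`.
#' @export
event_epochs <- function(event) {
  list(baseline = c(event$t_baseline_start, event$t_presentation),
       event = c(event$t_presentation, event$t_event_end),
       post = c(event$t_event_end, event$t_post_end))
}

#' Construct a sync-pulse record
#'
#' During acquisition each video frame has a fixed chance (80% in the
#' reference design) of triggering a TTL pulse to the ephys system. The
#' sent-pattern booleans plus the received pulse times form a shared random
#' code that aligns the two clocks.
#'
#' @param sent_flags Logical vector, one per video frame: pulse emitted?
#' @param sent_times Numeric vector, per-frame timestamps on the camera clock.
#' @param received_times Numeric vector of pulse times on the ephys clock,
#'   strictly increasing, one per `TRUE` flag.
#' @param frame_rate Video frame rate in Hz.
#' @return An object of class `ethospike_sync`.
#' @export
new_sync_train <- function(sent_flags, sent_times, received_times, frame_rate) {
  s <- structure(
    list(sent_flags = as.logical(sent_flags),
         sent_times = as.numeric(sent_times),
         received_times = as.numeric(received_times),
         frame_rate = as.numeric(frame_rate)),
    class = "ethospike_sync")
  if (length(s$sent_flags) != length(s$sent_times))
    stop("sent_flags and sent_times must have equal length")
  s
}

#' Assemble a recording session
#'
#' @param units List of [new_unit()] objects.
#' @param events List of [new_event_block()] objects.
#' @param sync Optional [new_sync_train()] object.
#' @param tracking Optional tracking data.frame
#'   (frame, agent, bodypart, x, y, likelihood).
#' @param metadata Free-form named list.
#' @return An object of class `ethospike_session`.
#' @export
new_session <- function(units, events, sync = NULL, tracking = NULL,
                        metadata = list()) {
  s <- structure(
    list(units = units, events = events, sync = sync, tracking = tracking,
         metadata = metadata),
    class = "ethospike_session")
  validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks unit and event invariants, event ordering/overlap and sync pulse
#' counts, reporting violations with unit/event identity.
#'
#' @param session An `ethospike_session`.
#' @return `TRUE` invisibly; stops with an informative message on violation.
#' @export
validate_session <- function(session) {
  for (u in session$units) validate_unit(u)
  for (e in session$events) validate_event(e)
  ids <- vapply(session$units, `[[`, "", "unit_id")
  if (anyDuplicated(ids))
    stop("duplicate unit ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  ev <- session$events
  if (length(ev) > 1) {
    starts <- vapply(ev, `[[`, 0, "t_baseline_start")
    o <- order(starts)
    for (k in seq_len(length(ev) - 1)) {
      a <- ev[[o[k]]]; b <- ev[[o[k + 1]]]
      if (a$t_post_end > b$t_baseline_start + 1e-9)
        stop("events ", a$stimulus_class, "#", a$presentation_index, " and ",
             b$stimulus_class, "#", b$presentation_index, " overlap")
    }
  }
  if (!is.null(session$sync)) {
    sy <- session$sync
    if (length(sy$received_times) != sum(sy$sent_flags))
      stop("sync: received pulse count (", length(sy$received_times),
           ") != sent-true flag count (", sum(sy$sent_flags), ")")
    if (any(diff(sy$received_times) <= 0))
      stop("sync: received_times must be strictly increasing")
  }
  invisible(TRUE)
}

#' @export
print.ethospike_session <- function(x, ...) {
  cat("<ethospike_session>\n")
  cat("  units: ", length(x$units), "\n", sep = "")
  cat("  events:", length(x$events),
      paste0("(", paste(vapply(x$events, `[[`, "", "stimulus_class"),
                        collapse = ", "), ")"), "\n")
  cat("  sync:  ", if (is.null(x$sync)) "absent" else
    paste0(length(x$sync$sent_flags), " frames @ ", x$sync$frame_rate, " Hz"),
    "\n", sep = "")
  cat("  tracking: ", if (is.null(x$tracking)) "absent" else
    paste0(length(unique(x$tracking$frame)), " frames"), "\n", sep = "")
  invisible(x)
}

session_span <- function(session) {
  lo <- min(vapply(session$events, `[[`, 0, "t_baseline_start"))
  hi <- max(vapply(session$events, `[[`, 0, "t_post_end"))
  c(lo, hi)
}

#' Spikes within a half-open interval
#' @param spike_times Sorted numeric vector (seconds).
#' @param interval `c(start, end)`, half-open.
#' @return Numeric vector of the spikes in `[start, end)`.
#' @export
spikes_in <- function(spike_times, interval) {
  spike_times[spike_times >= interval[1] & spike_times < interval[2]]
}

unit_ids <- function(session) vapply(session$units, `[[`, "", "unit_id")
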