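#' Write a session to a plain-text directory layout
#'
#' The on-disk layout is deliberately inspectable and language-agnostic:
#' `units.tsv` (unit_id, channel, depth_um, region), `spikes/<unit_id>.txt`
#' (one float64 second per line), `waveforms/<unit_id>.tsv` (channels x
#' samples), `events.tsv` (stimulus_class, presentation_index and the five
#' anchor times), `sync.tsv` (frame, sent_flag, sent_time),
#' `sync_received.txt`, `tracking.tsv` (frame, agent, bodypart, x, y,
#' likelihood) and `metadata.json`. Floats are written with 17 significant
#' digits so that a read/write round trip is bit-exact.
#'
#' @param session An `ethospike_session`.
#' @param path Directory to create/populate.
#' @return `path` invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)

  fmt <- function(x) sprintf("%.17g", x)
  units_df <- data.frame(
    unit_id = vapply(session$units, `[[`, "", "unit_id"),
    channel = vapply(session$units, `[[`, NA_integer_, "channel"),
    depth_um = vapply(session$units, `[[`, NA_real_, "depth_um"),
    region = vapply(session$units, `[[`, "", "region"))
  utils::write.table(units_df, file.path(path, "units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  have_wf <- FALSE
  for (u in session$units) {
    writeLines(fmt(u$spike_times),
               file.path(path, "spikes", paste0(u$unit_id, ".txt")))
    if (!is.null(u$waveform)) {
      if (!have_wf) {
        dir.create(file.path(path, "waveforms"), showWarnings = FALSE)
        have_wf <- TRUE
      }
      wf_chr <- matrix(fmt(u$waveform), nrow = nrow(u$waveform))
      utils::write.table(wf_chr,
                         file.path(path, "waveforms", paste0(u$unit_id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  ev <- session$events
  events_df <- data.frame(
    stimulus_class = vapply(ev, `[[`, "", "stimulus_class"),
    presentation_index = vapply(ev, `[[`, 0L, "presentation_index"),
    t_baseline_start = fmt(vapply(ev, `[[`, 0, "t_baseline_start")),
    t_presentation = fmt(vapply(ev, `[[`, 0, "t_presentation")),
    t_contact = fmt(vapply(ev, `[[`, 0, "t_contact")),
    t_event_end = fmt(vapply(ev, `[[`, 0, "t_event_end")),
    t_post_end = fmt(vapply(ev, `[[`, 0, "t_post_end")))
  utils::write.table(events_df, file.path(path, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(session$sync)) {
    sy <- session$sync
    sync_df <- data.frame(frame = seq_along(sy$sent_flags),
                          sent_flag = as.integer(sy$sent_flags),
                          sent_time = fmt(sy$sent_times))
    utils::write.table(sync_df, file.path(path, "sync.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(c(fmt(sy$frame_rate), fmt(sy$received_times)),
               file.path(path, "sync_received.txt"))
  }
  if (!is.null(session$tracking)) {
    tr <- session$tracking
    tr$x <- fmt(tr$x); tr$y <- fmt(tr$y); tr$likelihood <- fmt(tr$likelihood)
    utils::write.table(tr, file.path(path, "tracking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(session$metadata, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from its directory layout
#'
#' Counterpart of [write_session()]. All invariants are re-validated on load;
#' violations are reported with the offending unit/event identity.
#'
#' @param path Session directory.
#' @return An `ethospike_session`.
#' @export
read_session <- function(path) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("session load error: missing required file ", f)
    fp
  }
  units_df <- utils::read.delim(need("units.tsv"),
                                colClasses = c(unit_id = "character"))
  events_df <- utils::read.delim(need("events.tsv"))
  units <- lapply(seq_len(nrow(units_df)), function(i) {
    id <- units_df$unit_id[i]
    st <- scan(need(file.path("spikes", paste0(id, ".txt"))),
               what = double(), quiet = TRUE)
    wf_path <- file.path(path, "waveforms", paste0(id, ".tsv"))
    wf <- if (file.exists(wf_path))
      as.matrix(utils::read.delim(wf_path, header = FALSE)) else NULL
    if (!is.null(wf)) dimnames(wf) <- NULL
    new_unit(id, st, units_df$channel[i], units_df$depth_um[i], wf,
             units_df$region[i])
  })
  events <- lapply(seq_len(nrow(events_df)), function(i)
    new_event_block(events_df$stimulus_class[i],
                    events_df$presentation_index[i],
                    events_df$t_baseline_start[i],
                    events_df$t_presentation[i],
                    events_df$t_contact[i],
                    events_df$t_event_end[i],
                    events_df$t_post_end[i]))
  sync <- NULL
  if (file.exists(file.path(path, "sync.tsv"))) {
    sync_df <- utils::read.delim(file.path(path, "sync.tsv"))
    rec <- scan(need("sync_received.txt"), what = double(), quiet = TRUE)
    sync <- new_sync_train(sync_df$sent_flag == 1L, sync_df$sent_time,
                           rec[-1], frame_rate = rec[1])
  }
  tracking <- NULL
  if (file.exists(file.path(path, "tracking.tsv")))
    tracking <- utils::read.delim(file.path(path, "tracking.tsv"))
  metadata <- if (file.exists(file.path(path, "metadata.json")))
    jsonlite::read_json(file.path(path, "metadata.json"), simplifyVector = TRUE)
  else list()
  new_session(units, events, sync, tracking, metadata)
}
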