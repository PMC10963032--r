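# Session and event-table containers.
#
# A session is the universal input record for all analyses: raw and neuropil
# fluorescence (neurons x frames), per-frame behaviour (running speed, pupil
# area) and per-neuron cell-type labels. Virtual-tunnel sessions additionally
# carry per-frame tunnel position, trial index and section label.

#' Construct an imaging session
#'
#' @param F raw fluorescence matrix, neurons x frames (arbitrary units)
#' @param Fneu neuropil fluorescence, same shape as `F`
#' @param frame_rate imaging frame rate in Hz
#' @param speed running speed in cm/s, one value per frame
#' @param pupil pupil area (arbitrary units), one value per frame
#' @param cell_type character vector per neuron; one of `"ChC"`, `"PyC"`,
#'   `"L5PyC"`
#' @param position optional tunnel position in cm per frame (tunnel sessions)
#' @param trial optional trial index per frame (tunnel sessions)
#' @param section optional section label per frame (`"visual"`/`"nonvisual"`)
#' @return an object of class `chc_session`
#' @export
new_session <- function(F, Fneu, frame_rate, speed, pupil, cell_type,
                        position = NULL, trial = NULL, section = NULL) {
  F <- as.matrix(F); Fneu <- as.matrix(Fneu)
  n_frames <- ncol(F)
  stopifnot(all(dim(F) == dim(Fneu)))
  if (frame_rate <= 0) stop("frame_rate must be positive")
  stopifnot(length(speed) == n_frames, length(pupil) == n_frames)
  if (any(speed < 0)) stop("speed must be non-negative")
  stopifnot(length(cell_type) == nrow(F))
  if (!all(cell_type %in% c("ChC", "PyC", "L5PyC")))
    stop("cell_type must be ChC, PyC or L5PyC")
  for (extra in list(position, trial, section)) {
    if (!is.null(extra)) stopifnot(length(extra) == n_frames)
  }
  structure(list(F = F, Fneu = Fneu, frame_rate = frame_rate,
                 speed = as.numeric(speed), pupil = as.numeric(pupil),
                 cell_type = cell_type, position = position,
                 trial = trial, section = section),
            class = "chc_session")
}

#' @export
print.chc_session <- function(x, ...) {
  cat(sprintf("<chc_session> %d neurons x %d frames @ %.1f Hz\n",
              nrow(x$F), ncol(x$F), x$frame_rate))
  cat("  cell types:",
      paste(sprintf("%s=%d", names(table(x$cell_type)),
                    as.integer(table(x$cell_type))), collapse = ", "), "\n")
  if (!is.null(x$position)) cat("  tunnel session with position/trial data\n")
  invisible(x)
}

#' Construct an event table
#'
#' Stimulus and behavioural events in 0-based frame coordinates. The `value`
#' column carries the stimulus attribute relevant to the event type
#' (direction in degrees, image id, tunnel position in cm, ...); `contrast`
#' is kept as its own column for grating events.
#'
#' @param frame 0-based frame index of each event
#' @param type event type string (e.g. `grating_on`, `image_on`,
#'   `trial_start`, `visual_exit`, `mismatch`, `reward`, `cue`, `flow_halt`,
#'   `flow_on`)
#' @param value numeric attribute per event
#' @param contrast optional grating contrast per event
#' @param n_frames optional session length for bounds checking
#' @return a `data.frame` with class `chc_events`
#' @export
event_table <- function(frame, type, value = NA_real_, contrast = NA_real_,
                        n_frames = NULL) {
  frame <- as.integer(frame)
  if (is.unsorted(frame)) stop("event frames must be sorted ascending")
  if (any(frame < 0)) stop("event frames must be >= 0")
  if (!is.null(n_frames) && any(frame >= n_frames))
    stop("event frames outside session bounds")
  df <- data.frame(frame = frame, type = as.character(type),
                   value = as.numeric(value),
                   contrast = as.numeric(contrast))
  class(df) <- c("chc_events", class(df))
  df
}

#' Neuropil-corrected delta-F/F traces for a session
#'
#' Convenience wrapper: neuropil correction followed by moving-percentile
#' delta-F/F (see [neuropil_correct()] and [compute_dff()]).
#'
#' @param session a `chc_session`
#' @param factor neuropil subtraction factor
#' @param window moving-baseline window in frames
#' @param percentile baseline percentile
#' @return neurons x frames matrix of delta-F/F
#' @export
session_dff <- function(session, factor = 0.7, window = 5000,
                        percentile = 10) {
  compute_dff(neuropil_correct(session$F, session$Fneu, factor),
              window = window, percentile = percentile)
}

#' Write a session to a directory of plain-text files
#'
#' Traces and per-frame behaviour go to CSV files (`F.csv`, `Fneu.csv`,
#' `speed.csv`, ...), scalar metadata to `meta.csv`. The companion
#' [read_session()] restores the object. Plain text keeps sessions
#' diffable and language-agnostic.
#'
#' @param session a `chc_session`
#' @param dir output directory (created if missing)
#' @param events optional `chc_events` table written to `events.csv`
#' @export
write_session <- function(session, dir, events = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$F, file.path(dir, "F.csv"), row.names = FALSE)
  utils::write.csv(session$Fneu, file.path(dir, "Fneu.csv"),
                   row.names = FALSE)
  beh <- data.frame(speed = session$speed, pupil = session$pupil)
  if (!is.null(session$position)) beh$position <- session$position
  if (!is.null(session$trial)) beh$trial <- session$trial
  if (!is.null(session$section)) beh$section <- session$section
  utils::write.csv(beh, file.path(dir, "behavior.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_type = session$cell_type),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(data.frame(frame_rate = session$frame_rate),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  if (!is.null(events))
    utils::write.csv(as.data.frame(events), file.path(dir, "events.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing the CSV files
#' @return a list with elements `session` and (if present) `events`
#' @export
read_session <- function(dir) {
  F <- as.matrix(utils::read.csv(file.path(dir, "F.csv")))
  Fneu <- as.matrix(utils::read.csv(file.path(dir, "Fneu.csv")))
  dimnames(F) <- dimnames(Fneu) <- NULL
  beh <- utils::read.csv(file.path(dir, "behavior.csv"))
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  session <- new_session(F, Fneu, meta$frame_rate[1], beh$speed, beh$pupil,
                         cells$cell_type,
                         position = beh$position, trial = beh$trial,
                         section = beh$section)
  out <- list(session = session)
  ev_path <- file.path(dir, "events.csv")
  if (file.exists(ev_path)) {
    ev <- utils::read.csv(ev_path)
    out$events <- event_table(ev$frame, ev$type, ev$value, ev$contrast)
  }
  out
}
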