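#' Construct a single-channel sEMG recording
#'
#' A recording is a uniformly sampled amplitude trace in microvolts together
#' with its sampling rate and acquisition metadata. Sample `i` (1-based)
#' corresponds to time `t0 + (i - 1) / fs` seconds.
#'
#' @param samples Numeric vector of amplitudes (µV). Must be finite and
#'   non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_name Channel label.
#' @param muscle_site Electrode site, e.g. `"trapezius_descendens"` or
#'   `"platysma"`.
#' @param participant_id Participant identifier.
#' @param t0 Start time of the first sample in seconds.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_name = "emg",
                          muscle_site = "unspecified",
                          participant_id = "unknown", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_name = as.character(channel_name),
         muscle_site = as.character(muscle_site),
         participant_id = as.character(participant_id),
         t0 = as.numeric(t0)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %s @ %s\n  %d samples @ %g Hz (%.3f s), t0 = %g s\n  range [%.3g, %.3g] uV\n",
    x$channel_name, x$muscle_site, length(x$samples), x$fs,
    recording_duration(x), x$t0, min(x$samples), max(x$samples)))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param r An `emg_recording`.
#' @return Duration `length(samples) / fs` in seconds.
#' @export
recording_duration <- function(r) length(r$samples) / r$fs

#' Time axis of a recording
#'
#' @param r An `emg_recording`.
#' @return Numeric vector of per-sample times (s).
#' @export
recording_times <- function(r) r$t0 + (seq_along(r$samples) - 1) / r$fs

#' Read a recording from CSV
#'
#' Accepts either a two-column layout with header `time_s,emg_uV` (the
#' sampling rate is inferred from the time axis, which must be uniform to
#' within 1 part in 1e4) or a single `emg_uV` column together with
#' `fs_override`.
#'
#' @param path CSV file path.
#' @param fs_override Sampling rate in Hz, required when the file has no time
#'   column; when a time column is present it overrides the inferred rate.
#' @param ... Metadata passed on to [emg_recording()].
#' @return An `emg_recording`.
#' @export
read_recording <- function(path, fs_override = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"emg_uV" %in% names(df))
    stop("recording format error: missing 'emg_uV' column")
  emg <- df$emg_uV
  if (!is.numeric(emg) || anyNA(emg))
    stop("recording format error: non-numeric 'emg_uV' values")
  if ("time_s" %in% names(df)) {
    tt <- df$time_s
    if (!is.numeric(tt) || anyNA(tt))
      stop("recording format error: non-numeric 'time_s' values")
    if (length(tt) >= 2) {
      dt <- diff(tt)
      mdt <- stats::median(dt)
      if (mdt <= 0 || any(abs(dt - mdt) > 1e-4 * mdt))
        stop("recording sampling error: time axis not uniform within 1e-4")
      fs <- 1 / mdt
    } else {
      if (is.null(fs_override))
        stop("recording sampling error: cannot infer fs from one sample")
      fs <- fs_override
    }
    if (!is.null(fs_override)) fs <- fs_override
    t0 <- tt[1]
  } else {
    if (is.null(fs_override))
      stop("recording format error: no 'time_s' column and no fs_override")
    fs <- fs_override
    t0 <- 0
  }
  emg_recording(emg, fs = fs, t0 = t0, ...)
}

#' Write a recording to CSV
#'
#' Writes the `time_s,emg_uV` layout read back by [read_recording()].
#'
#' @param r An `emg_recording`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(r, path) {
  stopifnot(inherits(r, "emg_recording"))
  df <- data.frame(time_s = recording_times(r), emg_uV = r$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an event log
#'
#' An event log records when each action instruction was given, the action
#' label, and the nominal duration of the action. Rows are sorted by
#' instruction time; duplicate instruction times are invalid.
#'
#' @param t_instruction_s Instruction times (s).
#' @param action Action labels (e.g. `"SR"`, `"SF"`, `"SB"`, `"SRH"`, `"OR"`,
#'   `"PC"`); unknown labels are kept verbatim.
#' @param nominal_duration_s Nominal action durations (s, > 0).
#' @return A `data.frame` of class `emg_events`.
#' @export
emg_events <- function(t_instruction_s, action, nominal_duration_s) {
  df <- data.frame(t_instruction_s = as.numeric(t_instruction_s),
                   action = as.character(action),
                   nominal_duration_s = as.numeric(nominal_duration_s),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(!is.finite(df$t_instruction_s)) ||
        any(!is.finite(df$nominal_duration_s)))
      stop("event format error: non-finite times or durations")
    if (any(df$nominal_duration_s <= 0))
      stop("event format error: nominal_duration_s must be > 0")
    if (anyDuplicated(df$t_instruction_s))
      stop("event format error: duplicate instruction timestamps")
    if (is.unsorted(df$t_instruction_s, strictly = TRUE)) {
      warning("events were not sorted by instruction time; sorting")
      df <- df[order(df$t_instruction_s), , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  class(df) <- c("emg_events", "data.frame")
  df
}

#' Read an event log from CSV/TSV
#'
#' Expects columns `t_instruction_s,action,nominal_duration_s` (comma or tab
#' separated). Unsorted rows are sorted with a warning; duplicate timestamps
#' are an error.
#'
#' @param path File path.
#' @return An `emg_events` data frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("t_instruction_s", "action", "nominal_duration_s")
  if (!all(need %in% names(df)))
    stop("event format error: need columns ", paste(need, collapse = ", "))
  if (!is.numeric(df$t_instruction_s) || !is.numeric(df$nominal_duration_s))
    stop("event format error: non-numeric time columns")
  emg_events(df$t_instruction_s, df$action, df$nominal_duration_s)
}

#' Write an event log to CSV
#'
#' @param events An `emg_events` data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "emg_events"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
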