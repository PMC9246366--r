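# Session containers and event tables.
#
# A session is stored as a directory: `traces.feather` holds the two named
# channels as double columns (Arrow/Feather round-trips doubles bit-exactly),
# `session.json` mirrors the sampling rate, fish metadata, format version and
# optional stimulus schedule. Event tables are deterministic CSV with
# documented headers and 9-significant-digit floats.

SESSION_FORMAT_VERSION <- "1.0"

io_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lateralline_io_error", "error")))
}

#' Write a recording session to disk
#'
#' @param session A [recording_session()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrow::write_feather(
    data.frame(afferent = session$afferent, motor = session$motor),
    file.path(path, "traces.feather"))
  meta <- list(format_version = SESSION_FORMAT_VERSION,
               sampling_rate = session$sampling_rate,
               metadata = unclass(session$metadata))
  if (!is.null(session$schedule)) {
    meta$schedule <- list(
      frequency_hz = session$schedule$frequency_hz,
      onset_s = session$schedule$onset_s,
      stim_duration = attr(session$schedule, "stim_duration"),
      rest_duration = attr(session$schedule, "rest_duration"),
      n_sweeps = attr(session$schedule, "n_sweeps"))
  }
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recording session from disk
#'
#' Validates the format version, channel presence and metadata vocabulary;
#' raises distinct error classes (`lateralline_corrupt_file`,
#' `lateralline_version_mismatch`, `lateralline_missing_channel`,
#' `lateralline_invalid_metadata`).
#'
#' @param path Directory written by [write_session()].
#' @return A [recording_session()].
#' @export
read_session <- function(path) {
  json_path <- file.path(path, "session.json")
  feather_path <- file.path(path, "traces.feather")
  if (!dir.exists(path) || !file.exists(json_path) || !file.exists(feather_path)) {
    io_error(sprintf("'%s' is not a session directory (missing traces.feather or session.json)",
                     path), "lateralline_corrupt_file")
  }
  meta <- tryCatch(jsonlite::read_json(json_path, simplifyVector = TRUE),
                   error = function(e) {
                     io_error(sprintf("cannot parse %s: %s", json_path,
                                      conditionMessage(e)),
                              "lateralline_corrupt_file")
                   })
  if (is.null(meta$format_version) || !identical(as.character(meta$format_version),
                                                 SESSION_FORMAT_VERSION)) {
    io_error(sprintf("session format version '%s' not supported (expected %s)",
                     as.character(meta$format_version), SESSION_FORMAT_VERSION),
             "lateralline_version_mismatch")
  }
  traces <- tryCatch(as.data.frame(arrow::read_feather(feather_path)),
                     error = function(e) {
                       io_error(sprintf("cannot read %s: %s", feather_path,
                                        conditionMessage(e)),
                                "lateralline_corrupt_file")
                     })
  for (ch in c("afferent", "motor")) {
    if (!ch %in% names(traces)) {
      io_error(sprintf("channel '%s' missing from %s", ch, feather_path),
               "lateralline_missing_channel")
    }
  }
  md <- do.call(session_metadata, meta$metadata)
  sched <- NULL
  if (!is.null(meta$schedule)) {
    s <- meta$schedule
    sched <- structure(
      data.frame(frequency_hz = s$frequency_hz, onset_s = s$onset_s),
      stim_duration = s$stim_duration, rest_duration = s$rest_duration,
      n_sweeps = s$n_sweeps, class = c("stimulus_schedule", "data.frame"))
  }
  recording_session(traces$afferent, traces$motor, meta$sampling_rate,
                    metadata = md, schedule = sched)
}

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

#' Write a spike event table as CSV
#'
#' Columns: `fish_id`, `time_s` (9 significant digits; deterministic
#' formatting and column order).
#'
#' @param spikes A [spike_train()] (or list of them).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(spikes, path) {
  if (inherits(spikes, "spike_train")) spikes <- list(spikes)
  df <- do.call(rbind, lapply(spikes, function(st) {
    data.frame(fish_id = st$fish_id, time_s = fmt_num(st$times),
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike event table
#'
#' Validates headers and per-fish strictly increasing times.
#'
#' @param path CSV path with columns `fish_id`, `time_s`.
#' @return A named list of [spike_train()] objects, one per fish.
#' @export
read_spike_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("fish_id", "time_s") %in% names(df))) {
    io_error(sprintf("%s: expected columns fish_id, time_s", path),
             "lateralline_bad_table")
  }
  if (!is.numeric(df$time_s)) {
    io_error(sprintf("%s: time_s must be numeric", path), "lateralline_bad_table")
  }
  by_fish <- split(seq_len(nrow(df)), df$fish_id)
  out <- lapply(names(by_fish), function(fid) {
    ix <- by_fish[[fid]]
    tt <- df$time_s[ix]
    bad <- which(diff(tt) <= 0)
    if (length(bad)) {
      io_error(sprintf("%s: spike times for fish %s not strictly increasing at row(s) %s",
                       path, fid, paste(ix[bad + 1L], collapse = ", ")),
               "lateralline_bad_table")
    }
    spike_train(tt, fish_id = fid)
  })
  setNames(out, names(by_fish))
}

#' Write a swim-bout table as CSV
#'
#' Columns: `fish_id`, `onset_s`, `offset_s`, `n_bursts`, `duration_s`,
#' `swim_frequency_hz` (9 significant digits, fixed order).
#'
#' @param bouts Bout table as from [detect_swim_bouts()] (the `burst_times`
#'   list column, if present, is not serialized).
#' @param path Output CSV path.
#' @param fish_id Fish identifier column value (scalar, or already a column
#'   of `bouts`).
#' @return `path`, invisibly.
#' @export
write_bout_table <- function(bouts, path, fish_id = NA_character_) {
  fid <- if ("fish_id" %in% names(bouts)) bouts$fish_id else
    rep(as.character(fish_id), nrow(bouts))
  n_bursts <- if ("n_bursts" %in% names(bouts)) bouts$n_bursts else
    rep(NA_integer_, nrow(bouts))
  dur <- bouts$offset_s - bouts$onset_s
  freq <- if ("swim_frequency_hz" %in% names(bouts)) bouts$swim_frequency_hz else
    n_bursts / dur
  df <- data.frame(fish_id = fid,
                   onset_s = fmt_num(bouts$onset_s),
                   offset_s = fmt_num(bouts$offset_s),
                   n_bursts = n_bursts,
                   duration_s = fmt_num(dur),
                   swim_frequency_hz = fmt_num(freq),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a swim-bout table
#'
#' Validates headers, interval sanity (`offset_s > onset_s`, no overlap) per
#' fish; errors name the offending row numbers.
#'
#' @param path CSV path written by [write_bout_table()].
#' @return A named list of bout data.frames, one per fish.
#' @export
read_bout_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "onset_s", "offset_s")
  if (!all(need %in% names(df))) {
    io_error(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")),
             "lateralline_bad_table")
  }
  by_fish <- split(seq_len(nrow(df)), df$fish_id)
  out <- lapply(names(by_fish), function(fid) {
    ix <- by_fish[[fid]]
    b <- df[ix, , drop = FALSE]
    bad <- which(b$offset_s <= b$onset_s)
    if (length(bad)) {
      io_error(sprintf("%s: offset_s <= onset_s at row(s) %s (fish %s)",
                       path, paste(ix[bad], collapse = ", "), fid),
               "lateralline_bad_table")
    }
    o <- order(b$onset_s)
    b <- b[o, , drop = FALSE]
    if (nrow(b) > 1) {
      over <- which(b$onset_s[-1] < b$offset_s[-nrow(b)]) + 1L
      if (length(over)) {
        io_error(sprintf("%s: overlapping bouts at row(s) %s (fish %s)",
                         path, paste(ix[o][over], collapse = ", "), fid),
                 "lateralline_bad_table")
      }
    }
    rownames(b) <- NULL
    b
  })
  setNames(out, names(by_fish))
}
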