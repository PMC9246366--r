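#' Session metadata
#'
#' Per-fish metadata attached to a recording session. Population and treatment
#' labels are closed vocabularies.
#'
#' @param fish_id Character identifier for the fish.
#' @param population One of `"surface"`, `"pachon"`, `"tinaja"`, `"molino"`.
#' @param treatment One of `"control"`, `"ablated"`.
#' @param age_dpf Age in days post fertilization.
#' @return A named list of class `session_metadata`.
#' @export
session_metadata <- function(fish_id = "fish01", population = "surface",
                             treatment = "control", age_dpf = 6) {
  pops <- c("surface", "pachon", "tinaja", "molino")
  trts <- c("control", "ablated")
  if (!(is.character(population) && length(population) == 1L && population %in% pops)) {
    stop(errorCondition(
      sprintf("unknown population '%s'; allowed values: %s",
              as.character(population)[1], paste(pops, collapse = ", ")),
      class = c("lateralline_invalid_metadata", "error")))
  }
  if (!(is.character(treatment) && length(treatment) == 1L && treatment %in% trts)) {
    stop(errorCondition(
      sprintf("unknown treatment '%s'; allowed values: %s",
              as.character(treatment)[1], paste(trts, collapse = ", ")),
      class = c("lateralline_invalid_metadata", "error")))
  }
  if (!is.numeric(age_dpf) || length(age_dpf) != 1L || age_dpf <= 0) {
    stop(errorCondition("age_dpf must be a positive number",
                        class = c("lateralline_invalid_metadata", "error")))
  }
  structure(list(fish_id = as.character(fish_id), population = population,
                 treatment = treatment, age_dpf = as.numeric(age_dpf)),
            class = "session_metadata")
}

#' Two-channel recording session
#'
#' Container for a paired afferent / ventral-motor-root recording: two
#' equal-length voltage traces sampled uniformly at `sampling_rate`, plus fish
#' metadata and an optional stimulus schedule.
#'
#' @param afferent Numeric vector, afferent-nerve voltage trace (volts).
#' @param motor Numeric vector, ventral-root voltage trace (volts); same
#'   length as `afferent`.
#' @param sampling_rate Samples per second (> 0).
#' @param metadata A [session_metadata()] object.
#' @param schedule Optional [stimulus_schedule()] for evoked recordings.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(afferent, motor, sampling_rate,
                              metadata = session_metadata(),
                              schedule = NULL) {
  if (!is.numeric(afferent) || !is.numeric(motor)) {
    stop("afferent and motor traces must be numeric vectors")
  }
  if (length(afferent) != length(motor)) {
    stop("afferent and motor traces must have the same length")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar")
  }
  if (!inherits(metadata, "session_metadata")) {
    metadata <- do.call(session_metadata, as.list(metadata))
  }
  if (!is.null(schedule) && !inherits(schedule, "stimulus_schedule")) {
    stop("schedule must be a stimulus_schedule or NULL")
  }
  structure(list(afferent = as.numeric(afferent), motor = as.numeric(motor),
                 sampling_rate = as.numeric(sampling_rate),
                 metadata = metadata, schedule = schedule),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  dur <- length(x$afferent) / x$sampling_rate
  cat("<recording_session>\n")
  cat(sprintf("  %d samples/channel (%.4g s at %g kHz)\n",
              length(x$afferent), dur, x$sampling_rate / 1000))
  cat(sprintf("  fish %s | %s | %s | %g dpf\n", x$metadata$fish_id,
              x$metadata$population, x$metadata$treatment, x$metadata$age_dpf))
  if (!is.null(x$schedule)) {
    cat(sprintf("  stimulus schedule: %d sweeps at %s Hz\n",
                nrow(x$schedule),
                paste(unique(x$schedule$frequency_hz), collapse = "/")))
  }
  invisible(x)
}

#' Duration of a recording session in seconds
#' @param session A [recording_session()].
#' @return Length of the traces divided by the sampling rate, seconds.
#' @export
session_duration <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  length(session$afferent) / session$sampling_rate
}

#' Sorted afferent spike times
#'
#' @param times Numeric vector of spike times in seconds, strictly increasing.
#' @param fish_id Source fish identifier.
#' @param amplitude Optional per-spike amplitudes (volts), as detected.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, fish_id = NA_character_, amplitude = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  if (!is.null(amplitude) && length(amplitude) != length(times)) {
    stop("amplitude must match times in length")
  }
  structure(list(times = times, fish_id = as.character(fish_id),
                 amplitude = amplitude),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x$times)))
  if (length(x$times) > 1) {
    cat(sprintf(" over %.4g s (mean rate %.3g Hz)",
                diff(range(x$times)),
                (length(x$times) - 1) / diff(range(x$times))))
  }
  if (!is.na(x$fish_id)) cat(sprintf(" [fish %s]", x$fish_id))
  cat("\n")
  invisible(x)
}

# Coerce numeric vectors / data.frames to spike_train
as_spike_train <- function(x, fish_id = NA_character_) {
  if (inherits(x, "spike_train")) return(x)
  if (is.data.frame(x)) return(spike_train(x$time_s, fish_id = fish_id))
  spike_train(x, fish_id = fish_id)
}

# Canonical empty bout table (shared column layout)
empty_bout_table <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             n_bursts = integer(0), duration_s = numeric(0),
             swim_frequency_hz = numeric(0))
}

# Validate a bout table: offset > onset, sorted, disjoint
validate_bouts <- function(bouts, context = "bout table") {
  if (nrow(bouts) == 0) return(invisible(bouts))
  bad <- which(bouts$offset_s <= bouts$onset_s)
  if (length(bad)) {
    stop(errorCondition(
      sprintf("%s: offset <= onset in row(s) %s", context,
              paste(bad, collapse = ", ")),
      class = c("lateralline_invalid_bouts", "error")))
  }
  if (is.unsorted(bouts$onset_s)) {
    stop(errorCondition(sprintf("%s: bout onsets must be sorted", context),
                        class = c("lateralline_invalid_bouts", "error")))
  }
  if (nrow(bouts) > 1) {
    over <- which(bouts$onset_s[-1] < bouts$offset_s[-nrow(bouts)]) + 1L
    if (length(over)) {
      stop(errorCondition(
        sprintf("%s: overlapping bouts in row(s) %s", context,
                paste(over, collapse = ", ")),
        class = c("lateralline_invalid_bouts", "error")))
    }
  }
  invisible(bouts)
}
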