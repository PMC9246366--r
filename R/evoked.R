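# Evoked-response analysis: stimulus schedules, peristimulus time histograms,
# and per-frequency evoked rates.

#' Sinusoidal-stimulation sweep schedule
#'
#' One block per stimulus frequency; within a block, sweeps of
#' `stim_duration` seconds of stimulation followed by `rest_duration` seconds
#' of rest repeat `n_sweeps` times. Default protocol: 5/10/20/30/40 Hz, 1 s
#' on, 4 s rest, 60 sweeps per frequency.
#'
#' @param frequencies Stimulus frequencies in Hz.
#' @param n_sweeps Sweeps per frequency.
#' @param stim_duration,rest_duration Seconds of stimulation / rest per sweep.
#' @param start_s Onset of the first sweep (default 0).
#' @return A data.frame of class `stimulus_schedule` with columns
#'   `frequency_hz`, `onset_s` and attributes `stim_duration`,
#'   `rest_duration`, `n_sweeps`.
#' @export
stimulus_schedule <- function(frequencies = c(5, 10, 20, 30, 40),
                              n_sweeps = 60, stim_duration = 1,
                              rest_duration = 4, start_s = 0) {
  stopifnot(length(frequencies) >= 1, all(frequencies > 0),
            n_sweeps >= 1, stim_duration > 0, rest_duration >= 0)
  period <- stim_duration + rest_duration
  blocks <- lapply(seq_along(frequencies), function(b) {
    block_start <- start_s + (b - 1) * n_sweeps * period
    data.frame(frequency_hz = frequencies[b],
               onset_s = block_start + (seq_len(n_sweeps) - 1) * period)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "stim_duration") <- stim_duration
  attr(out, "rest_duration") <- rest_duration
  attr(out, "n_sweeps") <- n_sweeps
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}

#' Peristimulus time histogram
#'
#' Spikes are binned by time from sweep onset and pooled across sweeps;
#' counts are converted to rate by dividing by `bin_width_s * n_sweeps`, so
#' `sum(count) == rate %*% bin_width * n_sweeps` holds exactly.
#'
#' @param spikes A [spike_train()] or numeric vector of spike times.
#' @param schedule A [stimulus_schedule()] (optionally filtered by
#'   `frequency`).
#' @param bin_width_s Bin width in seconds (default 10 ms); must divide the
#'   analysis window.
#' @param window Length-2 analysis window relative to sweep onset, seconds
#'   (default `c(-0.5, 1.5)`).
#' @param frequency Optional: restrict to sweeps of this stimulus frequency.
#' @return A data.frame with `bin_left_s`, `bin_right_s`, `count`, `rate_hz`;
#'   attribute `n_sweeps`.
#' @export
build_psth <- function(spikes, schedule, bin_width_s = 0.01,
                       window = c(-0.5, 1.5), frequency = NULL) {
  if (!is.null(frequency)) {
    schedule <- schedule[schedule$frequency_hz == frequency, , drop = FALSE]
  }
  if (nrow(schedule) == 0) {
    stop(errorCondition("empty stimulus schedule",
                        class = c("lateralline_empty_schedule", "error")))
  }
  span <- window[2] - window[1]
  n_bins <- span / bin_width_s
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin_width_s must divide the analysis window")
  }
  n_bins <- as.integer(round(n_bins))
  edges <- window[1] + bin_width_s * (0:n_bins)
  st <- as_spike_train(spikes)
  counts <- integer(n_bins)
  for (onset in schedule$onset_s) {
    rel <- st$times - onset
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      bin <- findInterval(rel, edges, rightmost.closed = FALSE)
      bin <- bin[bin >= 1 & bin <= n_bins]
      tb <- tabulate(bin, nbins = n_bins)
      counts <- counts + tb
    }
  }
  n_sweeps <- nrow(schedule)
  out <- data.frame(bin_left_s = edges[-length(edges)], bin_right_s = edges[-1],
                    count = counts,
                    rate_hz = counts / (bin_width_s * n_sweeps))
  attr(out, "n_sweeps") <- n_sweeps
  out
}

#' Per-frequency evoked spike rate
#'
#' For each sweep, the spike count within the stimulus period
#' `[onset, onset + stim_duration)` divided by the stimulus duration; mean
#' and standard error across sweeps are reported per stimulus frequency.
#' Rest-period spiking never enters the computation.
#'
#' @param spikes A [spike_train()] or numeric vector of spike times.
#' @param schedule A [stimulus_schedule()].
#' @return A data.frame with one row per frequency: `frequency_hz`,
#'   `mean_rate_hz`, `se_hz`, `n_sweeps`.
#' @export
evoked_rate <- function(spikes, schedule) {
  if (nrow(schedule) == 0) {
    stop(errorCondition("empty stimulus schedule",
                        class = c("lateralline_empty_schedule", "error")))
  }
  stim_dur <- attr(schedule, "stim_duration")
  if (is.null(stim_dur)) stim_dur <- 1
  st <- as_spike_train(spikes)
  per_sweep <- vapply(schedule$onset_s, function(onset) {
    window_count(st, c(onset, onset + stim_dur)) / stim_dur
  }, numeric(1))
  freqs <- unique(schedule$frequency_hz)
  rows <- lapply(freqs, function(f) {
    r <- per_sweep[schedule$frequency_hz == f]
    data.frame(frequency_hz = f, mean_rate_hz = mean(r),
               se_hz = if (length(r) > 1) sd(r) / sqrt(length(r)) else 0,
               n_sweeps = length(r))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
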