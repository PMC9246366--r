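#' Simulation configuration for synthetic recordings
#'
#' Bundles every parameter of the synthetic-recording generator. Defaults
#' describe a typical larval-fish preparation: spontaneous afferent rates in
#' the low tens of Hz, swim bouts a few hundred milliseconds long at roughly
#' one bout every couple of seconds, motor bursts at tail-beat frequencies
#' (5--40 Hz), and 20 kHz acquisition.
#'
#' @param baseline_rate Spontaneous afferent spike rate lambda, events/s.
#'   This is the *target observed* rate: the generator compensates its Poisson
#'   intensity for the absolute refractory period so the realized rate equals
#'   `baseline_rate`.
#' @param inhibition_fraction Multiplicative reduction of the afferent rate
#'   during swim bouts, in `[0, 1]`; the in-bout rate is
#'   `baseline_rate * (1 - inhibition_fraction)`.
#' @param bout_rate Swim-bout initiation rate, bouts/s (exponential renewal of
#'   bout onsets; overlapping candidate bouts are merged).
#' @param bout_duration_mean,bout_duration_sd Mean and SD of bout duration in
#'   seconds (normal, truncated below at `bout_duration_floor`).
#' @param bout_duration_floor Minimum bout duration in seconds (default 50 ms).
#' @param burst_frequency Motor bursts per second within a bout (tail-beat
#'   analogue), must be positive.
#' @param burst_jitter_frac Jitter SD on burst times, as a fraction of the
#'   inter-burst interval (default 0.1).
#' @param session_duration Recording length in seconds.
#' @param sampling_rate Samples per second for rendered traces (default 20000).
#' @param spike_amplitude,burst_amplitude Peak template amplitudes in volts
#'   used when rendering raw traces.
#' @param noise_sd SD of i.i.d. Gaussian noise added to rendered traces, volts.
#' @param refractory_s Absolute refractory period enforced on afferent spike
#'   times by deletion, seconds (default 1 ms).
#' @param rng_seed Optional integer seed consumed by the top-level generators
#'   ([simulate_session()], [simulate_evoked_session()], [simulate_cohort()]).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(baseline_rate = 12.4, inhibition_fraction = 0.685)
#' cfg
#' @export
sim_config <- function(baseline_rate = 15,
                       inhibition_fraction = 0.5,
                       bout_rate = 0.5,
                       bout_duration_mean = 0.3,
                       bout_duration_sd = 0.1,
                       bout_duration_floor = 0.05,
                       burst_frequency = 20,
                       burst_jitter_frac = 0.1,
                       session_duration = 60,
                       sampling_rate = 20000,
                       spike_amplitude = 1e-3,
                       burst_amplitude = 5e-4,
                       noise_sd = 1e-4,
                       refractory_s = 1e-3,
                       rng_seed = NULL) {
  cfg <- list(
    baseline_rate = baseline_rate,
    inhibition_fraction = inhibition_fraction,
    bout_rate = bout_rate,
    bout_duration_mean = bout_duration_mean,
    bout_duration_sd = bout_duration_sd,
    bout_duration_floor = bout_duration_floor,
    burst_frequency = burst_frequency,
    burst_jitter_frac = burst_jitter_frac,
    session_duration = session_duration,
    sampling_rate = sampling_rate,
    spike_amplitude = spike_amplitude,
    burst_amplitude = burst_amplitude,
    noise_sd = noise_sd,
    refractory_s = refractory_s,
    rng_seed = rng_seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_invalid <- function(msg) {
    stop(errorCondition(msg, class = c("lateralline_invalid_config", "error")))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("baseline_rate", "inhibition_fraction", "bout_rate",
              "bout_duration_mean", "bout_duration_sd", "bout_duration_floor",
              "burst_frequency", "burst_jitter_frac", "session_duration",
              "sampling_rate", "spike_amplitude", "burst_amplitude",
              "noise_sd", "refractory_s")) {
    if (!num1(cfg[[f]])) stop_invalid(sprintf("'%s' must be a finite numeric scalar", f))
  }
  if (cfg$baseline_rate <= 0) stop_invalid("baseline_rate must be > 0")
  if (cfg$inhibition_fraction < 0 || cfg$inhibition_fraction > 1)
    stop_invalid("inhibition_fraction must lie in [0, 1]")
  if (cfg$bout_rate < 0) stop_invalid("bout_rate must be >= 0")
  if (cfg$bout_duration_mean <= 0) stop_invalid("bout_duration_mean must be > 0")
  if (cfg$bout_duration_sd < 0) stop_invalid("bout_duration_sd must be >= 0")
  if (cfg$bout_duration_floor <= 0) stop_invalid("bout_duration_floor must be > 0")
  if (cfg$burst_frequency <= 0) stop_invalid("burst_frequency must be > 0")
  if (cfg$session_duration <= 0) stop_invalid("session_duration must be > 0")
  # rendered templates contain energy up to ~3 kHz; require Nyquist above that
  if (cfg$sampling_rate < 8000) stop_invalid("sampling_rate must be >= 8000 samples/s")
  if (cfg$refractory_s < 0) stop_invalid("refractory_s must be >= 0")
  if (cfg$baseline_rate * cfg$refractory_s >= 0.5)
    stop_invalid("baseline_rate * refractory_s must be < 0.5 (dead-time compensation)")
  if (cfg$noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  baseline rate        %.3g Hz (inhibition %.1f%% during bouts)\n",
              x$baseline_rate, 100 * x$inhibition_fraction))
  cat(sprintf("  bouts                %.3g /s, duration %.0f +/- %.0f ms (floor %.0f ms)\n",
              x$bout_rate, 1000 * x$bout_duration_mean, 1000 * x$bout_duration_sd,
              1000 * x$bout_duration_floor))
  cat(sprintf("  bursts               %.3g /s within bouts (jitter %.0f%% of interval)\n",
              x$burst_frequency, 100 * x$burst_jitter_frac))
  cat(sprintf("  session              %.4g s at %g kHz\n",
              x$session_duration, x$sampling_rate / 1000))
  cat(sprintf("  render               spike %.2g V, burst %.2g V, noise sd %.2g V\n",
              x$spike_amplitude, x$burst_amplitude, x$noise_sd))
  invisible(x)
}
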