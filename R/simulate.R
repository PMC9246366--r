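# ---- internal helpers -------------------------------------------------------

# Membership of times in a set of disjoint, sorted, half-open [onset, offset)
# intervals given as a data.frame with onset_s/offset_s columns.
in_intervals <- function(times, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(times)))
  }
  edges <- as.vector(rbind(intervals$onset_s, intervals$offset_s))
  findInterval(times, edges) %% 2L == 1L
}

# Truncated-normal sampler (lower truncation only), inverse-CDF, exact.
rtnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

# Delete events falling within `refractory` of the last *kept* event.
apply_refractory <- function(times, refractory) {
  n <- length(times)
  if (n < 2 || refractory <= 0) return(times)
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

# Inhomogeneous Poisson sampler with dead-time compensation.
#
# `rate_fn(t)` returns the *target observed* rate at time t. The realized
# process is obtained by thinning a homogeneous process at `rate_max_comp`
# with the compensated intensity r/(1 - r*tau) and then deleting events within
# the refractory period tau of the last kept event: the kept rate of a
# compensated Poisson stream equals the target exactly in steady state.
sim_poisson_deadtime <- function(rate_fn, duration, refractory, rate_max) {
  comp <- function(r) if (refractory > 0) r / (1 - r * refractory) else r
  lam_max <- comp(rate_max)
  if (lam_max <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, lam_max * duration)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, duration))
  r <- rate_fn(cand)
  keep <- stats::runif(n_cand) < comp(r) / lam_max
  apply_refractory(cand[keep], refractory)
}

# ---- bout generation --------------------------------------------------------

#' Simulate fictive-swim bout intervals
#'
#' Bout onsets follow an exponential renewal process at `config$bout_rate`;
#' durations are drawn from a normal distribution truncated below at
#' `config$bout_duration_floor`. A candidate onset that would overlap the
#' previous bout is redrawn; by memorylessness of the exponential this is
#' realized deterministically as an exponential gap from the previous bout
#' offset, so the intervals are always disjoint and sorted and the realized
#' durations keep exactly the configured distribution (the final bout may be
#' clipped at the session end).
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `onset_s`, `offset_s`, `duration_s`.
#' @examples
#' set.seed(1)
#' simulate_bouts(sim_config(bout_rate = 0.5, session_duration = 120))
#' @export
simulate_bouts <- function(config) {
  validate_sim_config(config)
  T_end <- config$session_duration
  r <- config$bout_rate
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0))
  if (r == 0) return(empty)
  onsets <- numeric(0)
  offsets <- numeric(0)
  t_now <- stats::rexp(1, rate = r)
  while (t_now < T_end) {
    dur <- rtnorm_lower(1, config$bout_duration_mean,
                        config$bout_duration_sd, config$bout_duration_floor)
    off <- min(t_now + dur, T_end)
    onsets <- c(onsets, t_now)
    offsets <- c(offsets, off)
    t_now <- off + stats::rexp(1, rate = r)
  }
  data.frame(onset_s = onsets, offset_s = offsets,
             duration_s = offsets - onsets)
}

# ---- afferent spike generation ----------------------------------------------

#' Simulate an afferent spike train with swim-locked inhibition
#'
#' Realizes an inhomogeneous Poisson process whose observed rate is
#' `baseline_rate` outside swim bouts and
#' `baseline_rate * (1 - inhibition_fraction)` inside bouts (step modulation),
#' with an absolute refractory period enforced by deletion. The generating
#' intensity is dead-time compensated so the observed rates match the
#' configured targets.
#'
#' @param config A [sim_config()].
#' @param bouts Bout intervals as returned by [simulate_bouts()] (disjoint).
#' @return Numeric vector of sorted, unique spike times in seconds.
#' @export
simulate_afferent_train <- function(config, bouts) {
  validate_sim_config(config)
  validate_bouts(bouts, context = "simulate_afferent_train")
  lam <- config$baseline_rate
  lam_in <- lam * (1 - config$inhibition_fraction)
  rate_fn <- function(t) ifelse(in_intervals(t, bouts), lam_in, lam)
  sim_poisson_deadtime(rate_fn, config$session_duration,
                       config$refractory_s, lam)
}

# ---- motor burst generation -------------------------------------------------

#' Simulate motor burst times within swim bouts
#'
#' Within each bout, bursts occur at regular intervals of
#' `1 / burst_frequency` starting at the bout onset, with Gaussian jitter of
#' SD `burst_jitter_frac / burst_frequency`. Bursts never fall outside their
#' bout; every bout contains at least one burst.
#'
#' @param config A [sim_config()].
#' @param bouts Bout intervals (disjoint, as from [simulate_bouts()]).
#' @return Numeric vector of sorted burst times in seconds.
#' @export
simulate_motor_train <- function(config, bouts) {
  validate_sim_config(config)
  validate_bouts(bouts, context = "simulate_motor_train")
  if (nrow(bouts) == 0) return(numeric(0))
  f <- config$burst_frequency
  out <- vector("list", nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    dur <- bouts$offset_s[i] - bouts$onset_s[i]
    n <- max(1L, floor(dur * f + 1e-9))
    base <- bouts$onset_s[i] + (seq_len(n) - 1) / f
    if (config$burst_jitter_frac > 0) {
      base <- base + stats::rnorm(n, 0, config$burst_jitter_frac / f)
    }
    out[[i]] <- sort(pmin(pmax(base, bouts$onset_s[i]),
                          bouts$offset_s[i] - 1e-9))
  }
  sort(unlist(out))
}

# ---- rendering --------------------------------------------------------------

# Biphasic extracellular spike template: one cycle of a 1 kHz sinusoid under a
# Hann window, ~1 ms wide. Energy sits inside the 300-3000 Hz afferent band.
spike_template <- function(sampling_rate, amplitude) {
  half <- round(0.0005 * sampling_rate)
  t <- (-half:half) / sampling_rate
  w <- 0.5 * (1 + cos(pi * t / (half / sampling_rate)))
  tpl <- sin(2 * pi * 1000 * t) * w
  amplitude * tpl / max(abs(tpl))
}

# Motor burst template: one cycle of a 100 Hz sinusoid under a Hann window,
# ~10 ms wide. Energy sits inside the 10-200 Hz motor band.
burst_template <- function(sampling_rate, amplitude) {
  half <- round(0.005 * sampling_rate)
  t <- (-half:half) / sampling_rate
  w <- 0.5 * (1 + cos(pi * t / (half / sampling_rate)))
  tpl <- sin(2 * pi * 100 * t) * w
  amplitude * tpl / max(abs(tpl))
}

add_templates <- function(trace, times, template, sampling_rate) {
  half <- (length(template) - 1L) %/% 2L
  n <- length(trace)
  for (tt in times) {
    c_idx <- round(tt * sampling_rate) + 1L
    lo <- c_idx - half
    hi <- c_idx + half
    t_lo <- max(1L, lo)
    t_hi <- min(n, hi)
    if (t_lo > t_hi) next
    trace[t_lo:t_hi] <- trace[t_lo:t_hi] +
      template[(t_lo - lo + 1L):(t_hi - lo + 1L)]
  }
  trace
}

#' Render event times into a raw two-channel voltage session
#'
#' Channel 1 (afferent) is a sum of biphasic ~1 ms spike templates centered at
#' each spike time; channel 2 (motor) a sum of ~10 ms burst envelopes at each
#' burst time; both with i.i.d. Gaussian noise of SD `config$noise_sd`.
#'
#' @param config A [sim_config()].
#' @param spikes Numeric vector of spike times (s), all within the session.
#' @param bursts Numeric vector of motor burst times (s).
#' @param metadata A [session_metadata()] attached to the session.
#' @param schedule Optional [stimulus_schedule()] carried on the session.
#' @return A [recording_session()].
#' @export
render_session <- function(config, spikes, bursts,
                           metadata = session_metadata(), schedule = NULL) {
  validate_sim_config(config)
  fs <- config$sampling_rate
  n <- round(config$session_duration * fs)
  if (length(spikes) && (min(spikes) < 0 || max(spikes) > config$session_duration))
    stop("spike times must lie within the session")
  if (length(bursts) && (min(bursts) < 0 || max(bursts) > config$session_duration))
    stop("burst times must lie within the session")
  aff <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
  mot <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
  aff <- add_templates(aff, spikes, spike_template(fs, config$spike_amplitude), fs)
  mot <- add_templates(mot, bursts, burst_template(fs, config$burst_amplitude), fs)
  recording_session(aff, mot, fs, metadata = metadata, schedule = schedule)
}

# ---- full-session convenience -----------------------------------------------

#' Simulate a complete spontaneous-activity session with ground truth
#'
#' Draws bouts, the inhibited afferent train, and motor bursts, optionally
#' renders the raw two-channel traces, and returns everything together with
#' the generating ground truth.
#'
#' @param config A [sim_config()]; `config$rng_seed` (if non-NULL) seeds the
#'   generator so identical configs reproduce bit-identical sessions.
#' @param metadata A [session_metadata()].
#' @param render If `TRUE` (default) raw voltage traces are rendered into a
#'   [recording_session()]; set `FALSE` for event-level simulation only.
#' @return A list with elements `session` (or `NULL` when `render = FALSE`)
#'   and `truth` (list: `spike_times`, `bouts`, `burst_times`,
#'   `inhibition_fraction`, `config`).
#' @export
simulate_session <- function(config, metadata = session_metadata(),
                             render = TRUE) {
  validate_sim_config(config)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  bouts <- simulate_bouts(config)
  spikes <- simulate_afferent_train(config, bouts)
  bursts <- simulate_motor_train(config, bouts)
  session <- if (render) render_session(config, spikes, bursts, metadata) else NULL
  list(session = session,
       truth = list(spike_times = spikes, bouts = bouts, burst_times = bursts,
                    inhibition_fraction = config$inhibition_fraction,
                    config = config))
}

# ---- evoked stimulation -----------------------------------------------------

#' Simulate an evoked-response session under sinusoidal neuromast stimulation
#'
#' For each stimulus frequency, `n_sweeps` sweeps of a `stim_duration`-second
#' stimulus followed by `rest_duration` seconds of rest are laid out
#' sequentially. During a stimulus the target afferent rate is
#' `baseline_rate + gain * max(0, sin(2*pi*f*t))` (half-wave phase-locked
#' inhomogeneous Poisson); at rest it is `baseline_rate`.
#'
#' @param config A [sim_config()]; `rng_seed` honored as in
#'   [simulate_session()].
#' @param stim_frequencies Stimulus frequencies in Hz (nonempty).
#' @param gain Peak evoked-rate increment in events/s (>= 0).
#' @param n_sweeps Sweeps per frequency (default 60).
#' @param stim_duration,rest_duration Stimulus-on and rest durations per sweep
#'   in seconds (defaults 1 and 4).
#' @param metadata A [session_metadata()].
#' @param render If `TRUE`, render raw traces (can be large: the session lasts
#'   `length(stim_frequencies) * n_sweeps * (stim_duration + rest_duration)`
#'   seconds). Default `FALSE` returns event-level output.
#' @return A list with `session` (or `NULL`), `schedule`
#'   (a [stimulus_schedule()]), and `truth` (spike times, gain, config).
#' @export
simulate_evoked_session <- function(config, stim_frequencies = c(5, 10, 20, 30, 40),
                                    gain, n_sweeps = 60,
                                    stim_duration = 1, rest_duration = 4,
                                    metadata = session_metadata(),
                                    render = FALSE) {
  validate_sim_config(config)
  if (length(stim_frequencies) == 0) {
    stop(errorCondition("stim_frequencies must be nonempty",
                        class = c("lateralline_invalid_config", "error")))
  }
  if (!is.numeric(gain) || length(gain) != 1L || gain < 0) {
    stop(errorCondition("gain must be a nonnegative scalar",
                        class = c("lateralline_invalid_config", "error")))
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  schedule <- stimulus_schedule(frequencies = stim_frequencies,
                                n_sweeps = n_sweeps,
                                stim_duration = stim_duration,
                                rest_duration = rest_duration)
  total <- length(stim_frequencies) * n_sweeps * (stim_duration + rest_duration)
  lam <- config$baseline_rate
  onsets <- schedule$onset_s
  freqs <- schedule$frequency_hz
  rate_fn <- function(t) {
    r <- rep(lam, length(t))
    k <- findInterval(t, onsets)
    has <- k >= 1
    trel <- t[has] - onsets[k[has]]
    on <- trel < stim_duration
    idx <- which(has)[on]
    trel_on <- trel[on]
    r[idx] <- lam + gain * pmax(0, sin(2 * pi * freqs[k[idx]] * trel_on))
    r
  }
  cfg_total <- config
  cfg_total$session_duration <- total
  spikes <- sim_poisson_deadtime(rate_fn, total, config$refractory_s, lam + gain)
  session <- if (render) {
    render_session(cfg_total, spikes, numeric(0), metadata, schedule = schedule)
  } else NULL
  list(session = session, schedule = schedule,
       truth = list(spike_times = spikes, gain = gain, config = config))
}

# ---- cohorts ----------------------------------------------------------------

#' Simulate an event-level cohort of fish
#'
#' Generates per-fish sessions whose baseline rate and inhibition fraction are
#' drawn from between-fish normal distributions (inhibition truncated to
#' `[0, 1]`), emulating population-level variability. Event-level only; use
#' [render_session()] per fish if raw traces are needed.
#'
#' @param n_fish Number of fish.
#' @param baseline_mean,baseline_sd Between-fish mean and SD of the
#'   spontaneous rate (Hz).
#' @param inhibition_mean,inhibition_sd Between-fish mean and SD of the true
#'   inhibition fraction.
#' @param population,treatment Metadata labels applied to every fish.
#' @param config Template [sim_config()]; per-fish rate/inhibition override
#'   its `baseline_rate`/`inhibition_fraction`.
#' @param seed Optional integer seed.
#' @return A list of per-fish lists: `metadata`, `truth` (as in
#'   [simulate_session()]), with `truth$spike_times` etc.
#' @export
simulate_cohort <- function(n_fish, baseline_mean, baseline_sd,
                            inhibition_mean, inhibition_sd,
                            population = "surface", treatment = "control",
                            config = sim_config(session_duration = 600),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_fish), function(i) {
    cfg <- config
    cfg$baseline_rate <- max(1, stats::rnorm(1, baseline_mean, baseline_sd))
    cfg$inhibition_fraction <- min(1, max(0, stats::rnorm(1, inhibition_mean,
                                                          inhibition_sd)))
    cfg$rng_seed <- NULL
    md <- session_metadata(fish_id = sprintf("%s_%s_%02d", population, treatment, i),
                           population = population, treatment = treatment)
    sim <- simulate_session(cfg, metadata = md, render = FALSE)
    list(metadata = md, truth = sim$truth)
  })
}
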