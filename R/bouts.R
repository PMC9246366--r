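# Per-bout statistics: duration-matched windows, windowed rates, the
# relative-rate / inhibition statistic, bout classification, event-aligned
# rate curves, and the relative-rate density.

#' Duration-matched pre-swim / swim / post-swim windows
#'
#' The pre-swim window immediately precedes the bout and has duration equal to
#' the bout itself; the post-swim window mirrors it after the offset. All
#' intervals are half-open `[a, b)`. A bout whose pre or post window would
#' extend past the recording boundaries is flagged unusable.
#'
#' @param bout One-row bout (list or data.frame row with `onset_s`,
#'   `offset_s`).
#' @param recording_duration Total recording length in seconds (`Inf` to skip
#'   the upper boundary check).
#' @return List with `pre`, `swim`, `post` (each `c(start, end)`) and
#'   `usable` (logical).
#' @export
bout_windows <- function(bout, recording_duration = Inf) {
  onset <- bout$onset_s
  offset <- bout$offset_s
  if (offset <= onset) stop("bout offset must exceed onset")
  dur <- offset - onset
  pre <- c(onset - dur, onset)
  swim <- c(onset, offset)
  post <- c(offset, offset + dur)
  usable <- pre[1] >= 0 && post[2] <= recording_duration
  list(pre = pre, swim = swim, post = post, usable = usable)
}

#' Windowed spike rate
#'
#' Number of spikes in the half-open interval `[interval[1], interval[2])`
#' divided by its width.
#'
#' @param spikes A [spike_train()] or numeric vector of spike times.
#' @param interval Length-2 numeric, `interval[2] > interval[1]`.
#' @return Rate in events/s.
#' @export
window_rate <- function(spikes, interval) {
  width <- interval[2] - interval[1]
  if (width <= 0) {
    stop(errorCondition("window width must be positive",
                        class = c("lateralline_invalid_window", "error")))
  }
  window_count(spikes, interval) / width
}

# spike count in half-open [a, b)
window_count <- function(spikes, interval) {
  st <- as_spike_train(spikes)
  sum(st$times >= interval[1] & st$times < interval[2])
}

#' Score one swim bout
#'
#' Computes pre-swim, swim and post-swim rates over duration-matched windows,
#' the relative spike rate (swim / pre-swim), the inhibition statistic
#' (1 - relative rate), the retention flag (at least one pre-swim spike), and
#' the bout class: `quiescent` when no spike falls in the swim window,
#' otherwise `reduced` when the swim rate is strictly below the pre-swim rate,
#' else `non_reduced`.
#'
#' @param spikes A [spike_train()] or numeric vector of spike times.
#' @param bout One-row bout (`onset_s`, `offset_s`).
#' @param recording_duration Recording length in seconds.
#' @return A one-row data.frame (`onset_s`, `offset_s`, `duration_s`,
#'   `usable`, `pre_count`, `swim_count`, `post_count`, `pre_rate`,
#'   `swim_rate`, `post_rate`, `retained`, `relative_rate`, `inhibition`,
#'   `label`). Rates and derived quantities are `NA` for unusable bouts;
#'   `relative_rate`/`inhibition`/`label` are `NA` for non-retained bouts.
#' @export
score_bout <- function(spikes, bout, recording_duration = Inf) {
  w <- bout_windows(bout, recording_duration)
  dur <- bout$offset_s - bout$onset_s
  row <- data.frame(onset_s = bout$onset_s, offset_s = bout$offset_s,
                    duration_s = dur, usable = w$usable,
                    pre_count = NA_integer_, swim_count = NA_integer_,
                    post_count = NA_integer_,
                    pre_rate = NA_real_, swim_rate = NA_real_,
                    post_rate = NA_real_, retained = NA,
                    relative_rate = NA_real_, inhibition = NA_real_,
                    label = NA_character_, pre_clear = TRUE,
                    stringsAsFactors = FALSE)
  if (!w$usable) return(row)
  st <- as_spike_train(spikes)
  row$pre_count <- window_count(st, w$pre)
  row$swim_count <- window_count(st, w$swim)
  row$post_count <- window_count(st, w$post)
  row$pre_rate <- row$pre_count / dur
  row$swim_rate <- row$swim_count / dur
  row$post_rate <- row$post_count / dur
  row$retained <- row$pre_count >= 1L
  if (row$retained) {
    row$relative_rate <- row$swim_rate / row$pre_rate
    row$inhibition <- 1 - row$relative_rate
    row$label <- if (row$swim_count == 0L) {
      "quiescent"
    } else if (row$swim_rate < row$pre_rate) {
      "reduced"
    } else {
      "non_reduced"
    }
  }
  row
}

#' Score every bout in a session
#'
#' Applies [score_bout()] to each bout. Bouts overlapping any excluded
#' interval (e.g. stimulus epochs) are flagged unusable; their windows are
#' taken relative to the full recording.
#'
#' @param spikes A [spike_train()] or numeric vector of spike times.
#' @param bouts Bout table (`onset_s`, `offset_s`, ...).
#' @param recording_duration Recording length in seconds.
#' @param exclude_intervals Optional data.frame of disjoint intervals
#'   (`onset_s`, `offset_s`); bouts whose pre/swim/post windows overlap any
#'   of them are dropped from analysis (flagged unusable).
#' @return A data.frame with one [score_bout()] row per bout.
#' @export
score_bouts <- function(spikes, bouts, recording_duration = Inf,
                        exclude_intervals = NULL) {
  validate_bouts(bouts, context = "score_bouts")
  st <- as_spike_train(spikes)
  rows <- lapply(seq_len(nrow(bouts)), function(i) {
    score_bout(st, bouts[i, , drop = FALSE], recording_duration)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- score_bout(st, data.frame(onset_s = 0, offset_s = 1), Inf)[0, ]
  }
  rownames(out) <- NULL
  if (nrow(out) > 0) {
    # pre-window free of the preceding bout (a contaminated pre-swim baseline
    # underestimates the non-swimming rate)
    prev_off <- c(-Inf, out$offset_s[-nrow(out)])
    out$pre_clear <- (out$onset_s - out$duration_s) >= prev_off
  }
  if (!is.null(exclude_intervals) && nrow(exclude_intervals) > 0 && nrow(out) > 0) {
    dur <- out$offset_s - out$onset_s
    lo <- out$onset_s - dur
    hi <- out$offset_s + dur
    hit <- vapply(seq_len(nrow(out)), function(i) {
      any(exclude_intervals$onset_s < hi[i] & exclude_intervals$offset_s > lo[i])
    }, logical(1))
    if (any(hit)) {
      out$usable[hit] <- FALSE
      out[hit, c("pre_count", "swim_count", "post_count", "pre_rate",
                 "swim_rate", "post_rate", "relative_rate", "inhibition")] <- NA
      out$retained[hit] <- NA
      out$label[hit] <- NA_character_
    }
  }
  out
}

#' Classify retained bouts
#'
#' Counts, over retained bouts only, how many showed any reduction of the swim
#' rate below the pre-swim rate (which includes the quiescent bouts) and how
#' many were completely quiescent, with percentages of the retained total.
#'
#' @param bout_rates Output of [score_bouts()].
#' @return A list: `n_retained`, `n_reduced`, `n_quiescent`, `pct_reduced`,
#'   `pct_quiescent`.
#' @export
classify_counts <- function(bout_rates) {
  if (nrow(bout_rates) == 0) stop("bout_rates must be nonempty")
  kept <- bout_rates[!is.na(bout_rates$retained) & bout_rates$retained, ]
  n <- nrow(kept)
  if (n == 0) {
    stop(errorCondition("no retained bouts: percentages undefined",
                        class = c("lateralline_no_retained_bouts", "error")))
  }
  n_red <- sum(kept$swim_rate < kept$pre_rate)  # includes quiescent bouts
  n_qui <- sum(kept$label == "quiescent")
  list(n_retained = n, n_reduced = n_red, n_quiescent = n_qui,
       pct_reduced = 100 * n_red / n, pct_quiescent = 100 * n_qui / n)
}

#' Cohort-level inhibition estimate
#'
#' Two estimators of the swim-locked inhibition: `"pooled"` (default) uses
#' the ratio of total swim to total pre-swim spike counts over all usable
#' bouts, `1 - (sum(swim_count)/sum(dur)) / (sum(pre_count)/sum(dur))`, which
#' is a consistent estimate of the underlying rate-reduction fraction (it
#' needs no per-bout division, so the >= 1-pre-spike restriction - and its
#' conditioning bias - does not apply; bouts whose pre-swim window overlaps
#' the preceding bout are also dropped, since their baseline is itself
#' partly inhibited); `"per_bout"` averages the per-bout
#' inhibition values over retained bouts (the per-bout statistic; biased
#' toward lower inhibition at low pre-swim counts because of the 1/N
#' conditioning - see the methods vignette).
#'
#' @param bout_rates Output of [score_bouts()].
#' @param method `"pooled"` or `"per_bout"`.
#' @return Inhibition estimate (dimensionless; 1 = complete suppression).
#' @export
inhibition_estimate <- function(bout_rates, method = c("pooled", "per_bout")) {
  method <- match.arg(method)
  if (method == "per_bout") {
    kept <- bout_rates[!is.na(bout_rates$retained) & bout_rates$retained, ]
    if (nrow(kept) == 0) {
      stop(errorCondition("no retained bouts",
                          class = c("lateralline_no_retained_bouts", "error")))
    }
    mean(kept$inhibition)
  } else {
    use <- bout_rates[bout_rates$usable & !is.na(bout_rates$pre_count), ]
    if ("pre_clear" %in% names(use)) {
      use <- use[is.na(use$pre_clear) | use$pre_clear, ]
    }
    if (nrow(use) == 0 || sum(use$pre_count) == 0) {
      stop(errorCondition("no usable bouts with pre-swim spikes",
                          class = c("lateralline_no_retained_bouts", "error")))
    }
    tot_dur <- sum(use$duration_s)
    1 - (sum(use$swim_count) / tot_dur) / (sum(use$pre_count) / tot_dur)
  }
}

#' Bout-onset-aligned mean firing-rate curve
#'
#' For each bout, the instantaneous rate (boxcar moving average) is evaluated
#' on a grid of lags relative to the bout onset; curves are averaged across
#' bouts. Every bout contributes to every grid point (what changes around the
#' onset is the rate modulation, not the set of bouts).
#'
#' @param spikes A [spike_train()], numeric vector, or list of either (one
#'   per session).
#' @param bouts Bout table, or list of bout tables matching `spikes`.
#' @param span_before_s,span_after_s Extent of the lag grid around the onset,
#'   seconds (both > 0).
#' @param window_s Moving-average window (default 0.1 s).
#' @param grid_step Lag-grid spacing (default 1 ms).
#' @return A data.frame with `time_s` (lag from onset), `mean_rate_hz`, and
#'   `n_bouts`.
#' @export
event_aligned_rate <- function(spikes, bouts, span_before_s = 0.5,
                               span_after_s = 0.5, window_s = 0.1,
                               grid_step = 0.001) {
  stopifnot(span_before_s > 0, span_after_s > 0)
  if (!is.list(spikes) || inherits(spikes, "spike_train") || is.data.frame(spikes)) {
    spikes <- list(spikes)
    bouts <- list(bouts)
  }
  grid <- seq(-span_before_s, span_after_s, by = grid_step)
  acc <- numeric(length(grid))
  n_bouts <- 0L
  for (k in seq_along(spikes)) {
    st <- as_spike_train(spikes[[k]])
    b <- bouts[[k]]
    if (is.null(b) || nrow(b) == 0) next
    for (i in seq_len(nrow(b))) {
      centers <- b$onset_s[i] + grid
      acc <- acc + count_closed(st$times, centers - window_s / 2,
                                centers + window_s / 2) / window_s
      n_bouts <- n_bouts + 1L
    }
  }
  if (n_bouts == 0L) {
    stop(errorCondition("no bouts to align",
                        class = c("lateralline_no_bouts", "error")))
  }
  data.frame(time_s = grid, mean_rate_hz = acc / n_bouts, n_bouts = n_bouts)
}

#' Kernel density estimate of relative spike rates
#'
#' Gaussian-kernel density of swim/pre-swim relative rates on a grid covering
#' `[0, max(2, max(values))]`, with reflection at zero (relative rates are
#' nonnegative) and renormalization so the grid integral is 1.
#'
#' @param relative_rates Finite, nonnegative values (length >= 2).
#' @param bandwidth Kernel SD; default Silverman's rule-of-thumb
#'   ([stats::bw.nrd0()]).
#' @param n_grid Number of grid points (default 512).
#' @return A data.frame with `relative_rate` and `density`.
#' @export
relative_rate_density <- function(relative_rates, bandwidth = NULL,
                                  n_grid = 512) {
  x <- relative_rates[!is.na(relative_rates)]
  if (length(x) < 2) {
    stop(errorCondition("need at least 2 values for a density estimate",
                        class = c("lateralline_too_few_values", "error")))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("relative rates must be finite and nonnegative")
  }
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(bw.nrd0(x), error = function(e) NA_real_)
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      bandwidth <- max(0.01, 0.05 * max(1, mean(x)))
    }
  }
  grid <- seq(0, max(2, max(x)), length.out = n_grid)
  # reflected Gaussian KDE on [0, Inf)
  f <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = x, sd = bandwidth) +
           stats::dnorm(-g, mean = x, sd = bandwidth))
  }, numeric(1))
  step <- grid[2] - grid[1]
  integral <- sum((f[-1] + f[-length(f)]) / 2) * step
  data.frame(relative_rate = grid, density = f / integral)
}
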