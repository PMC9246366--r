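# Duration-matched windows, windowed rates, the inhibition statistic, bout
# classification, event-aligned curves, relative-rate density.

test_that("bout windows are duration-matched and boundary-clipped", {
  w <- bout_windows(list(onset_s = 2.0, offset_s = 2.3), 100)
  expect_equal(w$pre, c(1.7, 2.0))
  expect_equal(w$swim, c(2.0, 2.3))
  expect_equal(w$post, c(2.3, 2.6))
  expect_true(w$usable)

  # pre window would start before the recording: flagged unusable
  expect_false(bout_windows(list(onset_s = 0.1, offset_s = 0.4), 100)$usable)
  # post window would run past the end
  expect_false(bout_windows(list(onset_s = 99.5, offset_s = 99.9), 100)$usable)

  # equal widths for arbitrary bouts
  set.seed(1)
  for (i in 1:25) {
    on <- runif(1, 1, 50)
    w <- bout_windows(list(onset_s = on, offset_s = on + runif(1, 0.05, 2)), 100)
    widths <- c(diff(w$pre), diff(w$swim), diff(w$post))
    expect_equal(max(widths) - min(widths), 0, tolerance = 1e-12)
  }
})

test_that("window rate matches a brute-force membership scan", {
  expect_equal(window_rate(c(1.01, 1.1, 1.25), c(1.0, 1.3)), 10)
  expect_equal(window_rate(numeric(0), c(0, 1)), 0)
  expect_error(window_rate(c(1), c(2, 2)), class = "lateralline_invalid_window")

  set.seed(2)
  spikes <- sort(runif(300, 0, 20))
  for (i in 1:1000) {
    a <- runif(1, 0, 19)
    b <- a + runif(1, 0.01, 1)
    brute <- sum(vapply(spikes, function(s) s >= a && s < b, logical(1))) / (b - a)
    expect_identical(window_rate(spikes, c(a, b)), brute)
  }
})

test_that("score_bout computes the relative-rate and inhibition statistic", {
  # 13 pre-swim spikes and 4 swim spikes in 1-s duration-matched windows
  spikes <- c(seq(9.02, 9.98, length.out = 13), seq(10.1, 10.9, length.out = 4))
  r <- score_bout(spikes, list(onset_s = 10, offset_s = 11), 100)
  expect_true(r$retained)
  expect_equal(r$pre_rate, 13)
  expect_equal(r$swim_rate, 4)
  expect_equal(r$relative_rate, 4 / 13)
  expect_equal(r$inhibition, 1 - 4 / 13)
  expect_equal(r$label, "reduced")

  # the reported group means imply ~71% inhibition
  expect_equal(1 - 3.9 / 13.7, 0.7153, tolerance = 1e-4)

  # quiescent bout: no swim spikes, inhibition exactly 1
  rq <- score_bout(c(9.5, 9.7), list(onset_s = 10, offset_s = 11), 100)
  expect_equal(rq$label, "quiescent")
  expect_equal(rq$inhibition, 1)
  expect_equal(rq$relative_rate, 0)

  # no pre-swim spikes: not retained, statistic undefined
  rn <- score_bout(c(10.2, 10.4), list(onset_s = 10, offset_s = 11), 100)
  expect_false(rn$retained)
  expect_true(is.na(rn$relative_rate))

  # rate increase: non_reduced, inhibition negative
  ri <- score_bout(c(9.5, 10.1, 10.2, 10.3), list(onset_s = 10, offset_s = 11), 100)
  expect_equal(ri$label, "non_reduced")
  expect_lt(ri$inhibition, 0)
})

test_that("inhibition + relative_rate = 1 exactly for every retained bout", {
  set.seed(3)
  cfg <- sim_config(baseline_rate = 15, inhibition_fraction = 0.6,
                    bout_rate = 0.6, session_duration = 300)
  sim <- simulate_session(cfg, render = FALSE)
  br <- score_bouts(sim$truth$spike_times, sim$truth$bouts, 300)
  kept <- br[!is.na(br$retained) & br$retained, ]
  expect_gt(nrow(kept), 50)
  expect_true(all(kept$inhibition + kept$relative_rate == 1))
  # retention filter: retained exactly when >= 1 pre-swim spike
  ok <- br[br$usable, ]
  expect_identical(ok$retained, ok$pre_count >= 1L)
  # quiescent implies zero swim count and inhibition 1
  q <- kept[kept$label == "quiescent", ]
  if (nrow(q) > 0) {
    expect_true(all(q$swim_count == 0))
    expect_true(all(q$inhibition == 1))
  }
})

test_that("classification counts and percentages follow the definitions", {
  mk <- function(pre, swim) {
    score_bout(c(seq(0.5, 0.99, length.out = pre),
                 if (swim > 0) seq(1.01, 1.49, length.out = swim)),
               list(onset_s = 1, offset_s = 1.5), 10)
  }
  br <- rbind(mk(5, 2), mk(5, 0), mk(5, 0), mk(4, 6), mk(3, 3))
  cc <- classify_counts(br)
  expect_equal(cc$n_retained, 5)
  expect_equal(cc$n_reduced, 3)   # the two quiescent bouts also count as reduced
  expect_equal(cc$n_quiescent, 2)
  expect_equal(cc$pct_reduced, 60)
  expect_equal(cc$pct_quiescent, 40)
  expect_gte(cc$pct_reduced, cc$pct_quiescent)

  # percentage arithmetic at published scale
  expect_equal(round(100 * 1966 / 2291, 1), 85.8)
  expect_equal(round(100 * 275 / 2439, 1), 11.3)

  # all-quiescent: both percentages 100
  brq <- rbind(mk(5, 0), mk(2, 0))
  ccq <- classify_counts(brq)
  expect_equal(ccq$pct_reduced, 100)
  expect_equal(ccq$pct_quiescent, 100)

  # zero retained bouts is an error
  brn <- mk(0, 3)
  expect_error(classify_counts(brn), class = "lateralline_no_retained_bouts")
})

test_that("pooled inhibition estimate recovers the generator truth", {
  set.seed(4)
  for (inh in c(0.2, 0.8)) {
    cfg <- sim_config(baseline_rate = 15, inhibition_fraction = inh,
                      bout_rate = 0.5, session_duration = 1500)
    sim <- simulate_session(cfg, render = FALSE)
    br <- score_bouts(sim$truth$spike_times, sim$truth$bouts, 1500)
    expect_gt(sum(br$retained, na.rm = TRUE), 400)
    expect_lt(abs(inhibition_estimate(br, "pooled") - inh), 0.05)
  }
})

test_that("per-bout mean relative rate shows the predicted conditioning bias", {
  # with fixed bout duration d and pre-swim count N ~ Poisson(lambda*d),
  # E[swim_rate/pre_rate | N >= 1] = (1 - i) * lambda*d * E[1/N | N >= 1]
  set.seed(5)
  lam <- 15
  d <- 0.3
  inh <- 0.5
  cfg <- sim_config(baseline_rate = lam, inhibition_fraction = inh,
                    bout_rate = 0.4, bout_duration_mean = d,
                    bout_duration_sd = 0, session_duration = 6000)
  sim <- simulate_session(cfg, render = FALSE)
  br <- score_bouts(sim$truth$spike_times, sim$truth$bouts, 6000)
  kept <- br[!is.na(br$retained) & br$retained & abs(br$duration_s - d) < 1e-9, ]
  expect_gt(nrow(kept), 1500)
  oracle <- (1 - inh) * lam * d * poisson_inv_moment(lam * d)
  se <- sd(kept$relative_rate) / sqrt(nrow(kept))
  expect_lt(abs(mean(kept$relative_rate) - oracle), 4 * se)
  # i.e. the naive mean is measurably biased away from (1 - inh)
  expect_gt(oracle, (1 - inh) * 1.2)
})

test_that("event-aligned rate curves show the step modulation", {
  set.seed(6)
  cfg <- sim_config(baseline_rate = 20, inhibition_fraction = 0.7,
                    bout_rate = 0.5, bout_duration_mean = 0.4,
                    session_duration = 1200)
  sim <- simulate_session(cfg, render = FALSE)
  curve <- event_aligned_rate(sim$truth$spike_times, sim$truth$bouts,
                              span_before_s = 0.5, span_after_s = 0.3)
  # baseline before the onset (clear of the smoothing window); neighboring
  # bouts of the renewal process depress it below lambda by at most
  # lambda * bout_rate * mean_duration * inhibition
  base <- mean(curve$mean_rate_hz[curve$time_s < -0.15])
  se3 <- 3 * sqrt(20 / (0.35 * curve$n_bouts[1]))
  expect_lt(base, 20 + se3)
  expect_gt(base, 20 * (1 - 0.5 * 0.4 * 0.7) - se3)
  # suppressed plateau one window after onset
  plateau <- mean(curve$mean_rate_hz[curve$time_s > 0.1 & curve$time_s < 0.25])
  expect_lt(abs(plateau - 20 * 0.3) / (20 * 0.3), 0.2)

  # no inhibition: flat within sampling noise
  cfg0 <- sim_config(baseline_rate = 20, inhibition_fraction = 0,
                     bout_rate = 0.5, session_duration = 1200)
  sim0 <- simulate_session(cfg0, render = FALSE)
  c0 <- event_aligned_rate(sim0$truth$spike_times, sim0$truth$bouts, 0.4, 0.2)
  expect_lt(diff(range(tapply(c0$mean_rate_hz,
                              cut(c0$time_s, 6), mean))) / 20, 0.1)

  no_bouts <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  expect_error(event_aligned_rate(c(1, 2), no_bouts, 0.5, 0.5),
               class = "lateralline_no_bouts")
})

test_that("relative-rate density integrates to one and resolves mixtures", {
  set.seed(7)
  x <- c(abs(rnorm(300, 0, 0.02)), rnorm(300, 1, 0.1))
  d <- relative_rate_density(x)
  step <- diff(d$relative_rate[1:2])
  integral <- sum((d$density[-1] + d$density[-nrow(d)]) / 2) * step
  expect_lt(abs(integral - 1), 1e-3)

  # two local maxima near 0 and 1
  peaks <- which(diff(sign(diff(d$density))) == -2) + 1
  modes <- d$relative_rate[peaks]
  boundary_mode <- d$density[1] > d$density[2]  # reflected mass peaks at 0
  expect_true(boundary_mode || any(modes < 0.2))
  expect_true(any(abs(modes - 1) < 0.2))

  # identical values: density peaks at that value
  d2 <- relative_rate_density(rep(0.5, 20))
  expect_lt(abs(d2$relative_rate[which.max(d2$density)] - 0.5), 0.05)

  expect_error(relative_rate_density(0.3),
               class = "lateralline_too_few_values")
})
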