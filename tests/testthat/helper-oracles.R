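# Shared fixtures and independent oracles used across test files.

# Greedy one-to-one matching of detected against true event times within a
# tolerance; returns true/false positive/negative counts.
match_events <- function(detected, truth, tol_s = 0.002) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    i <- which(!used & d <= tol_s)
    if (length(i)) {
      used[i[which.min(d[i])]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}

f1_score <- function(m) {
  prec <- m[["tp"]] / max(1, m[["tp"]] + m[["fp"]])
  rec <- m[["tp"]] / max(1, m[["tp"]] + m[["fn"]])
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# The detector defines a bout as bursts grouped within merge_gap; true bouts
# closer together than the gap are therefore one bout by that operational
# definition. Merge them before comparing.
merge_close_bouts <- function(bouts, gap_s = 0.2) {
  if (nrow(bouts) < 2) return(bouts)
  on <- bouts$onset_s[1]
  off <- bouts$offset_s[1]
  for (i in 2:nrow(bouts)) {
    k <- length(on)
    if (bouts$onset_s[i] - off[k] < gap_s) {
      off[k] <- max(off[k], bouts$offset_s[i])
    } else {
      on <- c(on, bouts$onset_s[i])
      off <- c(off, bouts$offset_s[i])
    }
  }
  data.frame(onset_s = on, offset_s = off, duration_s = off - on)
}

# E[1/N | N >= 1] for N ~ Poisson(m): numeric oracle for the per-bout
# relative-rate conditioning bias.
poisson_inv_moment <- function(m, n_max = 500) {
  n <- seq_len(n_max)
  p <- dpois(n, m)
  sum(p / n) / sum(p)
}

# Build a tiny noiseless rendered session from explicit event times.
render_fixture <- function(spikes, bursts = numeric(0), duration = 2,
                           noise_sd = 0, fs = 20000) {
  cfg <- sim_config(session_duration = duration, sampling_rate = fs,
                    noise_sd = noise_sd)
  render_session(cfg, spikes, bursts)
}
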