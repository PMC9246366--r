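---
title: "Quantifying corollary-discharge inhibition in lateral-line afferents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying corollary-discharge inhibition in lateral-line afferents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateralline)
```

## The measurement problem

Fish sense water flow with lateral-line neuromasts. During swimming, hindbrain
efferent neurons send a copy of the motor command — a corollary discharge — to
the hair cells, suppressing the afferent spike train so the animal does not
deafen its own flow sensors. `lateralline` implements the analysis needed to
quantify that suppression from paired extracellular recordings: one electrode
on the posterior lateral-line afferent ganglion, one on a ventral motor root
reporting fictive swimming in a paralyzed larva, both digitized at 20 kHz.

The pipeline has four stages:

1. **Signal detection** — recover afferent spike times and fictive-swim bouts
   from the raw traces.
2. **Bout analysis** — for each swim bout, compare the spike rate during the
   bout with the rate in a *duration-matched pre-swim window*, yielding the
   relative rate and the inhibition statistic.
3. **Evoked analysis** — peristimulus time histograms and per-frequency
   evoked rates under 1-s sinusoidal neuromast stimulation.
4. **Population statistics** — per-fish averages, weighted regression of swim
   on pre-swim rates against the line of unity, paired/unpaired t-tests, and
   one-way ANOVA with Tukey letter groupings.

A synthetic-recording generator with exact ground truth closes the loop:
every stage is validated against data whose answer is known.

## The inhibition statistic

For a bout with onset $t_0$, offset $t_1$ and duration $d = t_1 - t_0$, three
half-open windows of equal width are scored:

$$\text{pre} = [t_0 - d, t_0), \quad \text{swim} = [t_0, t_1), \quad
  \text{post} = [t_1, t_1 + d).$$

Each window's rate is its spike count over $d$. The relative rate is
$\rho = r_\text{swim} / r_\text{pre}$ and the inhibition is $1 - \rho$ (1 =
complete quiescence, 0 = no change, negative = facilitation). Because $\rho$
divides by the pre-swim count, bouts with an empty pre-swim window are
excluded ("retained" requires at least one pre-swim spike), and bouts whose
pre or post window would cross a recording boundary, or overlap a stimulus
epoch, are flagged unusable. Retained bouts are classified `quiescent` (no
swim-window spike), `reduced` (swim rate strictly below pre-swim rate), or
`non_reduced` (ties count as non-reduced).

### Two estimators of cohort-level inhibition

The mean of per-bout inhibition values is the classical per-bout statistic,
but it is *biased* at physiological spike counts: conditioned on
$N_\text{pre} \ge 1$,

$$E[\rho] = (1 - i)\, m\, E[1/N \mid N \ge 1], \qquad N \sim \text{Poisson}(m),
  \; m = \lambda d,$$

and $m \, E[1/N \mid N \ge 1]$ is 1.31 at $m = 4.4$ (e.g. 15 Hz × 0.3 s) —
the per-bout mean understates inhibition by tens of percent of the effect.
`inhibition_estimate(..., "per_bout")` reports this statistic as defined;
`inhibition_estimate(..., "pooled")` (the default) instead divides total swim
counts by total pre-swim counts across bouts, which needs no per-bout
division and is consistent. The pooled estimator additionally drops bouts
whose pre-swim window overlaps the preceding bout: such a baseline is itself
partly inhibited and depresses the denominator by roughly
$r\,E[d]/2 \times i$ (about 2 percentage points at half-a-bout-per-second
swim rates). Parameter-recovery tests and the acceptance script use the
pooled estimator; the per-bout statistic is kept exactly as defined for
comparability, and its bias is itself verified against the closed-form
oracle above.

## Signal detection choices

* **Bands.** Afferent spikes are band-passed at 300–3000 Hz, motor activity
  at 10–200 Hz, with 4th-order zero-phase Butterworth filters (applied
  forward and backward). At 20 kHz these bands separate ~1-ms unit spikes
  from ~10-ms motor burst envelopes.
* **Spike threshold.** Events exceed `threshold_k` × the robust noise SD
  `median(|x|)/0.6745`; each supra-threshold excursion contributes its local
  extremum, and events closer than the 1-ms refractory period collapse to the
  larger one. The default `threshold_k = 4.5`: at a 20-kHz broadband noise
  floor the Gaussian upcrossing rate at 4 robust SDs is on the order of one
  false event per second, which visibly biases spike counts at 10–20 Hz
  spontaneous rates, while 4.5 SDs keeps false events below 0.1/s and costs
  no recall at SNR ≥ 8. Both polarities are detected (spike sign is not
  assumed).
* **Bout segmentation.** The motor trace is rectified and smoothed with a
  20-ms RMS window; bursts are envelope excursions above median + 4 MAD.
  Excursions separated by less than 8 ms are fused into one burst
  (oscillatory burst content makes the envelope dip within a burst; genuine
  tail-beat intervals are ≥ 25 ms), and excursions shorter than 5 ms are
  discarded as noise blips. Bursts separated by less than the 200-ms merge
  gap form one bout — within-bout intervals at 5–40 Hz tail-beat frequencies
  never exceed 200 ms. Bout onset/offset are the first/last burst edges;
  swim frequency is burst count over duration.
* **Time conventions.** Seconds from recording start; intervals half-open
  `[onset, offset)`; the instantaneous-rate boxcar uses a closed window so a
  lone spike yields a symmetric 100-ms plateau.

## What the generator emulates

`sim_config()` + `simulate_session()` produce sessions with known truth:

* **Afferent train** — Poisson with target rate λ outside bouts and
  λ(1 − *i*) inside (step modulation), 1-ms absolute refractory period. The
  generating intensity is *dead-time compensated* (r/(1 − rτ)) so the
  *observed* rate equals the configured target exactly; without compensation
  a 50-Hz train would fall ~5% short, breaking rate calibration.
* **Bouts** — onsets renew with exponential gaps (rate `bout_rate`);
  durations are normal (mean/SD configurable, floored at 50 ms). A candidate
  onset overlapping the previous bout is redrawn, which by memorylessness
  equals drawing the gap from the previous offset; realized durations
  therefore keep the configured distribution exactly (merging overlapping
  bouts instead would inflate mean durations by ~(1 + r·E[d]/2)).
* **Motor bursts** — regular at `burst_frequency` within each bout with 10%
  jitter, at least one per bout.
* **Rendering** — a biphasic 1-ms spike template (1-kHz carrier under a Hann
  window) and a 10-ms burst template (100-Hz carrier) summed at event times
  plus white Gaussian noise. The templates put their energy inside the
  respective detection bands by construction.
* **Evoked sweeps** — per stimulus frequency, sweeps of 1-s stimulation and
  4-s rest (60 per frequency by default); during stimulation the rate is
  λ + gain·max(0, sin 2πft), so the sweep-averaged evoked rate is λ + gain/π,
  a closed form the evoked pipeline is tested against.

Defaults describe the study conditions the package addresses: spontaneous
rates of roughly 12–21 Hz, bouts of 250–450 ms at about one every two
seconds (surface fish produced ~0.5 bouts/s of recording in the cohort
sizes reported), tail-beat analogues at 5–40 Hz, 20-kHz sampling. Cohort
simulations draw per-fish baselines (SD 1.5 Hz) and inhibition fractions
(SD 0.05) around the population means — enough spread to give the unity-test
regression a usable x-axis, and consistent with cohorts of 5–15 fish
resolving the reported effects.

**What it does not emulate.** Within-bout rate dynamics (onset/offset
transients and gradual recovery) are deliberately absent — the modulation is
a step. Relative-rate distributions are therefore unimodal given the
parameters; the bimodal mixture of full quiescence and partial reduction
seen in real surface fish is *not* reproduced by a single inhibition
fraction, so bout-classification proportions from synthetic cohorts need
not match any particular empirical mixture. Spike waveforms are stylized,
there is no multi-unit overlap, no electrode drift, no movement artifacts.
Passing tests demonstrate the estimators and detectors are correct under
the generative assumptions, not that those assumptions exhaust real data.

## Population statistics

Per-fish summaries average bout-level variables over retained bouts, with
regression weight √(number of swims) — per-fish precision grows with swim
count. The unity-slope test regresses per-fish swim rate on pre-swim rate by
weighted least squares; the 95% slope CI uses the t distribution with n − 2
df. A CI excluding 1 means swimming changes the rate beyond what chance
allows; slopes well below 1 with CIs excluding unity are the signature of
corollary-discharge suppression. With unit weights the fit reduces to OLS
(tested to machine precision), and when per-fish noise variance scales as
1/weight the test is exactly calibrated (5% null exclusion rate, verified
over 2000 simulations).

The "N-way" comparison of rates across population × treatment × period is
implemented as a one-way ANOVA over the combined cells — with 2×2×2 cells
and fish-level replication this reproduces the 7-and-40 style degrees of
freedom of an 8-cell design — followed by Tukey HSD and a compact letter
display computed by insert-and-absorb on the Tukey p-values (no letter is
ever shared by a pair differing at α; verified as a property). A full
factorial decomposition is available via `factorial = TRUE`. Variables whose
group means and variances are rank-correlated (Spearman, α = 0.05) are
log-transformed first, with a half-minimum offset when zeros occur; the
false-flag rate of this screen is itself tested against α. The
"unpaired two-way t-test" wording in the source literature is interpreted as
a two-tailed unpaired t-test with pooled variance.

## Numerical and degenerate-input choices

* Relative-rate KDE: Gaussian kernels with Silverman bandwidth, reflected at
  zero (relative rates are nonnegative) and renormalized on the grid
  `[0, max(2, max(x))]` so the integral is 1 within 10⁻³; identical inputs
  fall back to a small fixed bandwidth.
* PSTH: 10-ms bins on a [−0.5, 1.5]-s window (≥ 2 bins per half-cycle at
  40 Hz); counts are integers and rate × bin width × sweeps reproduces them
  exactly. Sweep alignment uses the schedule, not artifact detection.
* Zero-variance paired differences with zero mean return t = 0, p = 1
  (identical pairs are evidence of no difference, not an error).
* Errors are classed conditions (`lateralline_invalid_config`,
  `lateralline_undefined_rate`, `lateralline_missing_channel`, ...) so
  callers can distinguish validation failures programmatically.
* Session files: a directory holding a Feather trace table (bit-exact double
  round-trip) and a JSON sidecar with sampling rate, closed-vocabulary fish
  metadata and optional stimulus schedule, under a format version tag. CSV
  event tables use 9 significant digits and fixed column order, so writers
  are byte-deterministic.

## Problem sizes used in the test suite

Calibration checks use 600-s event-level sessions (3-SE Poisson bands);
inhibition recovery uses 3600-s sessions (~1500 bouts per condition) so the
Monte-Carlo error of the pooled estimator is well inside the 0.05 acceptance
band; detection fidelity uses rendered 60–120-s sessions at SNR 8–10; the
unity-test calibration runs 2000 null regressions. Cohort-level checks use
10 surface-like and 5 cave-like fish with 600–1800-s sessions, matching the
reported cohort sizes. The acceptance script regenerates all of these from
scratch at the published group means.

## Known limitations

* The per-bout statistic's conditioning bias means per-bout and pooled
  inhibition estimates differ systematically at low pre-swim counts; both
  are reported so the user can choose deliberately.
* Bout detection cannot split two true bouts separated by less than the
  merge gap — by the operational definition they *are* one bout; evaluation
  against ground truth merges truth intervals with the same rule.
* The step-modulation generator cannot produce the bimodal relative-rate
  mixtures of real surface fish (see above).
* Evoked analysis assumes the stimulus schedule is known; there is no
  stimulus-artifact-based realignment.
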