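Package: lateralline
Title: Corollary-Discharge Inhibition Analysis for Lateral-Line Afferent Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired extracellular recordings of posterior
    lateral-line afferent neurons and ventral motor roots in larval fish.
    Detects afferent spikes and fictive-swim bouts from raw two-channel voltage
    traces, computes duration-matched pre-swim/swim/post-swim firing rates and
    the per-bout inhibition statistic used to quantify corollary-discharge
    suppression, builds peristimulus time histograms and evoked-rate tables for
    sinusoidal neuromast stimulation, and aggregates per-fish summaries for
    weighted regressions against the line of unity, paired and unpaired t-tests,
    and one-way ANOVA with Tukey post-hoc letter groupings. A synthetic-recording
    generator with known ground truth (inhomogeneous Poisson afferent trains
    with multiplicative swim-locked inhibition, renewal swim bouts with motor
    bursts, rendered voltage traces, and sinusoidal stimulus sweeps) makes every
    stage verifiable without access to experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
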