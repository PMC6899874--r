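Package: shamblind
Title: Time-Resolved Assessment of Sham Blinding in Transcranial
    Direct Current Stimulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether the placebo ("sham") protocol of a
    transcranial direct current stimulation (tDCS) experiment actually
    blinds participants, resolved over the time course of a session
    rather than retrospectively.  Implements confidence-weighted
    detection scores from in-task "is the stimulation on?" probes,
    percentile-bootstrap confidence bands for the per-probe group
    medians, detection and merging of time windows where the active and
    sham bands do not overlap, per-participant binomial logistic
    crossover fits with a failure taxonomy, a reaction-time pipeline
    (per-block medians, baseline-corrected paired tests with Cohen's dz,
    TOST equivalence, accuracy, and a sub-block bootstrap time course),
    Wilcoxon signed-rank side-effect comparisons, an exact binomial
    guess-rate test, and noncentral-t power calculations for paired
    designs.  A synthetic-cohort generator emulates a two-session
    within-subject crossover so the full pipeline runs and is testable
    without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
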