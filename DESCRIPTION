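Package: pcmcr
Title: Post-Conflict Matched-Control Analysis of Reconciliation and
    Vocal Behaviour
Version: 0.1.0
Authors@R:
    person("N.", "Kato", email = "nkato@example.org", role = c("aut", "cre"))
Description: Tools for post-conflict/matched-control (PC-MC) studies of
    reconciliation in group-living primates. Reads and validates focal
    behavioural event streams, pairs post-conflict sessions with their
    matched controls, classifies pairs as attracted, dispersed or neutral
    minute by minute, and computes per-subject proportions and the
    conciliatory tendency. Includes an exact Wilcoxon signed-rank test
    (shift-algorithm null distribution with midranks), dominance rank
    inference with Landau's h and de Vries' h-prime linearity statistics,
    directional dyadic familiarity indices from line-census records, a
    registry of binomial mixed models for affiliation, aggression risk and
    vocal use, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    optparse
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
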