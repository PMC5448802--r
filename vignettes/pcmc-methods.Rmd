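---
title: "Methods: the PC-MC reconciliation analysis in pcmcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PC-MC reconciliation analysis in pcmcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, the numerical conventions, and the
design choices made where the method description left the design open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The design

A *post-conflict* (PC) session is a 5-minute focal observation of one
former opponent starting when a dyadic conflict between adult females
ends; it is postponed if aggression between the opponents resumes within
30 s. Its *matched control* (MC) follows the same subject at least one
observation day later but within two weeks, at the same time of day
(±2 h), beginning only after 5 min without social interaction. Each PC-MC
pair carries the conflict's attributes (physical aggression?
counter-aggression by the victim?) on both sessions.

Sessions are divided into five one-minute timeframes, `[60(m−1), 60m)`
seconds (half-open, so an event at exactly 60 s is minute 2 — no double
counting). The first qualifying affiliative behaviour defines the
session's affiliation minute:

* contact, grooming given or received, approach within arm's length, or a
  vocalization (grunt/girney/coo) *oriented at the recipient within 5 m*;
* in PC sessions only affiliation **with the former opponent** counts; in
  MC sessions affiliation **with any partner** counts. This asymmetry is
  the design's own and is enforced by default (overridable in
  `classify_pairs()`).

With `m_PC` and `m_MC` the two minutes (absent allowed), the pair is
**attracted** at timeframe `t` iff `m_PC = t` and `m_MC` is absent or
later, **dispersed** at `t` in the mirror case, **neutral** otherwise —
ties at the same minute and double absence are neutral. A pair is
therefore attracted (dispersed) at exactly the minute of its earlier first
affiliation or at none, so the per-timeframe labels *partition* the
pair-level categories. The method description defines the pair-level rule
and reports per-timeframe proportions without spelling out the
attribution; this partition is the only reading we found consistent with
both (per-timeframe proportions that decline after minute 1, pair-level
labels that the timeframe labels sum to), and it is frozen as a design
decision, cross-checked in the tests against a 36-case brute-force
enumeration.

Per-subject proportions are means over that subject's pairs; subjects with
fewer than `min_pairs = 3` pairs are excluded (and logged). The
**conciliatory tendency** of a subject is
`(attracted pairs − dispersed pairs) / n pairs` on the pair-level
classification, and the group value is the unweighted mean over subjects.
One caveat worth knowing: in the study this package re-implements, the
published group figure equals the *first-minute* attracted-minus-dispersed
difference, not the overall CT; `conciliatory_tendency()` implements the
overall definition, and the minute-1 difference is available from the
report's timeframe table.

## Exact signed-rank inference

Attracted vs dispersed proportions are compared per timeframe with a
paired exact Wilcoxon signed-rank test, built here rather than borrowed
because it is part of the analysis contract:

* zero differences are dropped before ranking (the dominant convention for
  exact variants; the count dropped is reported, because many subjects
  have attracted = dispersed = 0);
* remaining `|d|` are ranked with midranks; `V` is the sum of ranks of
  positive differences, so `V` can be half-integral;
* the null is the distribution of `V` over the `2^n` equiprobable sign
  assignments, *conditional on the observed midranks* — an exact
  permutation null, not a normal approximation. It is computed by a shift
  (convolution) recursion on doubled ranks, exact for any `n`; a full
  `2^n` enumeration engine (capped at n = 25) is retained purely as the
  independent oracle;
* the default two-sided p doubles the smaller tail, capped at 1
  (`p_method = "minlike"`, summing outcomes no more likely than the
  observed one, is exposed as the alternative since the original
  software's convention cannot be recovered from printed values).

## Dominance

Dyadic aggression and supplant outcomes populate a win matrix; `i`
dominates `j` by strict majority of wins, equal nonzero counts are tied
dyads, and 0–0 dyads are unknown. `rank_order()` minimizes first the
number and then the total rank distance (strength) of inconsistencies
(dyads where the lower-ranked beats the higher-ranked), I&SI-style:
exhaustive for N ≤ 8 — which doubles as the test oracle — and a seeded
simulated-annealing pass with greedy sweeps above, ties broken
deterministically by id. Isolated individuals are placed last and flagged.

Linearity: Landau's `h = 12/(N³−N) Σᵢ (Vᵢ − (N−1)/2)²` with `Vᵢ` the
number of individuals `i` dominates. de Vries' improved `h′` resolves each
unknown/tied dyad by a fair coin per randomization and averages `h`; the
linearity p-value is the fraction of *fully* random tournaments with
`h ≥ h′` (the two-step randomization of the method this index comes
from). With no unknown or tied dyads `h′ = h` exactly. The seed is
mandatory (default replicates 10,000); the emulated study reports using
the index but prints no value, so only property tests pin this module.

The rank-difference covariate is `rank(subject) − rank(opponent)`;
positive = subject subordinate (rank 1 is most dominant).

## Familiarity

From line-census records (each visible female recorded as *social* — in
contact or within 3 m of named partners — or *alone*), the familiarity of
A with B in a period is (sessions A had contact/proximity with B) /
(sessions A was recorded). The index is directional and **undefined, not
zero**, when A was never recorded: an uncensused female is not an
unfamiliar female, and conflating the two would bias every downstream
model. Records split into two periods at a configurable boundary (default
1 April 2014, halving a March 2013–March 2015 span); model tables look up
the index of the period containing each session's date. The between-period
Pearson correlation is restricted, by default, to dyads appearing in
analyzed PC-MC pairs — the published dyad universe behind its N is not
derivable, so the restriction is an interpretation and is configurable.

## The model registry (M1–M6′)

Seven binomial (logit) mixed models, all with random intercepts for
subject and former opponent, fitted separately by focal role where both
roles are analyzed:

| id | rows | response | fixed effects |
|----|------|----------|---------------|
| M1 | all paired PC | affiliation with opponent | physical, counter, rank diff, familiarity |
| M2 | all PC + MC | received aggression (anyone) | PC vs MC |
| M3 | victim PC | received aggression from opponent, windowed | affiliation, physical, counter, rank diff, familiarity |
| M4 | sessions with affiliation | vocal use during affiliation | PC vs MC |
| M5 | victim PC with affiliation | vocal use toward opponent | physical, counter, rank diff, familiarity |
| M6 | victim PC with affiliation | aggression after affiliation onset | physical, rank diff, familiarity, vocal use |
| M6′ | victim PC with affiliation | aggression after affiliation onset | physical, rank diff, familiarity, behaviour type (3 levels) |

M3's exposure window is the design's: aggression from the opponent counts
from the initiation of affiliation when affiliation occurred, otherwise
over the whole session minus the first minute. M6 deliberately omits
counter-aggression (that cell is too sparse to estimate — our synthetic
worked example reproduces the separation). M6′'s behaviour type has
reference level *contact/approach only* against *vocalizations only* and
*vocalizations with contact/approach*, and its multilevel effect is tested
by a 2-df likelihood ratio test against the model without it.

Estimation is Laplace-approximate maximum likelihood (lme4). Random
slopes "where applicable" is operationalized deterministically
(`slopes = "auto"`): attempt the full slope structure over the fixed
effects, on non-convergence drop slopes one at a time from the end of the
registry's fixed-effect list, ending at intercepts only, and record the
final structure and every reduction in the fit's notes. The pipeline
default is `slopes = "none"`: the published slope structures are
unknowable, slope models on these data sizes rarely converge, and a
predictable run time matters for reproducible reports; the choice is
echoed in the report's provenance block. Complete separation is flagged
(`|β| > 15`), never silently inflated. The full-vs-null LRT uses the null
with the same random structure, `χ² = 2(ℓ_full − ℓ_null)` on as many df as
fixed-effect coefficients.

## The synthetic world

`simulation_config()` states one world and the tests live in it:

* ~90 adult females in a strictly linear hierarchy (ids in rank order),
  win matrix complete by default; ~605 conflicts, focal role alternating,
  victim subordinate with probability 0.9; physical aggression 0.35 and
  counter-aggression 0.15 per conflict (plausible field rates; the
  emulated study does not print its own);
* symmetric ground-truth familiarity from a zero-inflated Beta mixture
  (point mass 0.6 at zero, else `0.73·Beta(1.2, 3)`), echoing a reported
  "0 to 0.73, median 0" spread;
* PC affiliation with the opponent from a logistic model whose defaults
  echo the published effect sizes (familiarity slope 5.4; counter
  −1.35); the affiliation minute is drawn mostly in minute 1
  (weights 0.75/0.11/0.06/0.05/0.03), and event times are uniform within
  their minute — the analyses only consume minute bins and window
  membership;
* vocal use given affiliation from a logistic with familiarity slope
  −7.8 (echoing the published vocal-use effect); oriented, within 5 m;
* renewed aggression from the opponent at rates matching the printed
  aggression-after-affiliation fractions (0.073 none / 0.146 with vocal /
  0.208 without), third-party aggression as background hazard;
* 172 census sessions split 87:85 across the two periods, detectability
  0.3 per female per session, per-dyad proximity drawn with probability
  equal to true familiarity — making the familiarity index a consistent
  estimator (verified at 10,000 sessions in the acceptance suite).

All randomness flows from the mandatory seed (stage substreams are
`seed`, `seed+1`, `seed+2`). What the generator does **not** emulate:
kinship structure, seasonal variation, observer error in behaviour
coding, spatially explicit movement (proximity is probabilistic per
dyad), and within-subject temporal correlation beyond what the logistic
models induce. A green test therefore establishes that the *pipeline*
recovers a known world of this shape — not that the world matches any
particular field site.

## Numerical conventions and degenerate inputs

* Times are seconds from session start, 0-based, half-open intervals;
  calendar timestamps ISO-8601 UTC.
* Several eligible MCs for one PC: the earliest is chosen, with a
  warning; an MC not later than its PC is a reported pairing issue, never
  silently dropped.
* All-zero signed-rank differences: degenerate result, V = 0, p = 1,
  flagged.
* Empty classified input: empty proportions table with a warning.
* A female never recorded in a census period: familiarity undefined (NA).
* Zero variance in a period's familiarity vector: correlation undefined,
  flagged.
* Degenerate (single-valued) GLMM responses raise an error; LRTs between
  fits on different row sets raise an error.

## Known limitations

* The deposited dataset of the emulated study is not shipped; the
  deposited-style adapter reads the package's own synthetic layout (and
  real XLSX via readxl), so published-value reproduction remains
  conditional on obtaining that workbook.
* Coefficient-level agreement with published tables can only ever be
  approximate: the published random-slope structures are unknown, and
  Laplace approximation plus slope-structure differences legitimately
  move third-decimal values.
* No Elo/David's-score alternatives for rank, no Bayesian fitting, no
  triadic/redirection analyses — all out of scope by design.
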