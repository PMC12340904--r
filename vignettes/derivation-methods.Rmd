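---
title: "Deriving lines of therapy and real-world survival endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving lines of therapy and real-world survival endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwevents)
```

`rwevents` converts heterogeneous longitudinal clinical tables into
survival-ready data. This vignette documents the models and conventions the
package commits to, why each was chosen, and what the synthetic test bed
does and does not establish about real data.

## The event model

Every record becomes an event `(patient, name, category, start age, end
age)` with ages in real-valued **days**. Days were chosen because they are
the finest granularity routine-care data realistically carries; a per-table
`time_unit` declaration (days, months, years) converts other units on load
with 1 month = 30.4375 days and 1 year = 365.25 days (the civil averages),
so the 3-month default clustering window equals 91.3125 days. Intervals are
closed, and point events (a scan, a diagnosis date) have `start == end`.

Real-world tables contain malformed rows. Rather than failing, the loader
drops rows with unparseable or negative times, ends before starts, or
missing patient ids, and returns them in a first-class rejection log; the
row count of kept plus rejected always equals the input. An analysis that
silently loses rows is not auditable; one that aborts on the first bad row
is unusable on registry data.

Per-patient timelines sort events by `(start, end, name)` — a total order,
so every downstream computation is invariant to input row order. Three
anchors drive the endpoint rules: diagnosis age, death age, and
last-contact age. When no explicit last-contact event exists, the maximum
observed event end is used as a conservative censoring time: the patient
was verifiably under observation until then, and no later.

## Lines of therapy

Treatments are clustered into lines by comparing **start times only**
against a window `w`: the start of a drug is the clinical decision point,
and an unusually long infusion interval should not extend a line's
recruitment period. Two semantics are provided because "temporally
proximal within a window" admits two natural readings:

* **anchor** (default): the earliest unassigned start `s0` seeds a line
  that absorbs every start `<= s0 + w`; the next unassigned start seeds
  the next line. This matches the common line-of-therapy convention of a
  fixed induction window.
* **gap**: a start joins the current line if it is within `w` of the
  line's *latest* member start, so chains of closely spaced starts merge
  regardless of total span.

Both are deterministic under permutation, partition the treatment events
exactly, and satisfy two limit laws used as test oracles: `w -> Inf` gives
one line per treated patient and `w -> 0+` one line per distinct start
time. The window boundary is inclusive, and a drug re-administered beyond
the window starts a new line — maintenance therapy is not folded back into
the induction line, a deliberate conservative choice.

A line's label is the sorted, lower-cased, de-duplicated `"+"`-join of its
member names (`"cisplatin+gemcitabine"`), giving regimens a stable identity
across patients for the Sankey graph and the heatmap.

## Endpoint derivation

Three analyses are declarative configurations over the same scan:

| analysis | start | endpoints (tie-break order) |
|---|---|---|
| OS | diagnosis | death |
| TTE | a treatment start | treatment change, toxicity, death |
| rwPFS | a treatment start | next-line start, progression, metastasis, pathological recurrence, death |

The record is the earliest qualifying event **strictly after** the start
(open lower bound: a same-day start-and-progress patient is excluded with
reason "non-positive follow-up" rather than given a zero time, which
removes immortal-time artifacts by construction); otherwise the patient is
censored at last contact. "Change in treatment line" is resolved
structurally — the start of line *k+1* where *k* is the index line — never
by name matching. Progression, metastasis, recurrence and toxicity are
matched by case-insensitive substrings over response-type categories,
because real-world vocabularies are dialects of the uploading institution.
The defaults are `progress` and `pd` (progression), `metasta`
(metastasis), `recurren` (recurrence), `toxic` (toxicity); `pd` is
included because "PD" is the standard response-criteria shorthand for
progressive disease and appears verbatim in routine imaging tables. Ties
on the same day are broken by rule order with death last, so a same-day
progression-and-death is recorded as progression.

Patients whose start cannot be resolved are excluded with a logged reason,
mirroring the harmonizer's drop-and-log philosophy.

## Survival statistics

All four estimators are implemented from first principles in the package;
the `survival` package appears only as an independent cross-check in the
test suite.

* **Kaplan-Meier**: the product-limit estimate over distinct event times
  with Greenwood standard errors. Censored observations tied with an event
  time count as at risk for that event time and are removed after it — the
  convention must be stated because day-granularity data produces such
  ties routinely. The median is the smallest event time with survival at
  or below 0.5, without interpolation.
* **Log-rank**: observed-minus-expected event counts over pooled event
  times with the multivariate hypergeometric variance, referred to
  chi-square on groups − 1 degrees of freedom. Variance terms with a
  single subject at risk are zero.
* **Cox proportional hazards**: damped Newton-Raphson from β = 0 on the
  partial likelihood, Breslow ties by default (simplest well-defined
  choice) with Efron available. Convergence is a score norm below 1e-8
  within 50 iterations. Step acceptance tolerates a relative decrease of
  1e-9·|loglik|, because near the optimum the change in the partial
  likelihood is dominated by summation rounding noise and a strict
  improvement test strangles the step. Complete separation is flagged as
  non-convergence, not an error, detected either by a coefficient passing
  |β| > 50 or by the information diagonal collapsing below 1e-6 of its
  β = 0 value — under separation the score vanishes as β diverges, so a
  gradient criterion alone would "converge" on a flat likelihood.
  Confidence intervals are Wald, β ± 1.96·SE.
* **Fisher's exact test**: two-sided p by enumeration of the
  hypergeometric support (probabilities at or below the observed table's,
  with a 1e-7 relative guard against floating-point ties); the odds ratio
  is the sample (a·d)/(b·c), infinite when b·c = 0 with a·d > 0.

p-values are kept at full float precision; rounding is a presentation
concern.

## Cohort analytics

The Sankey graph counts **patients**, not events: a node `(line k,
regimen)` has size equal to its distinct patients, links count patients
transitioning to each line-k+1 node, and the remainder are terminal, so
`node = Σ outgoing + terminal` is an exact conservation law tested on
random cohorts. Sparse regimens at a line can collapse into an `"other"`
node (default threshold 1 = no collapse) to keep long-tail second lines
readable. The treatment-by-line heatmap also counts distinct patients, and
a combination line increments each constituent agent. Duration outliers
use the Tukey upper fence (duration > Q3 + 1.5·IQR, quantile type 7)
within regimen groups of at least 4 lines — only the upper tail, because
the clinically interesting flag is the unusually extended regimen. Swimmer
lanes default to absolute patient age, matching the age-indexed event
stream; re-zeroing on each patient's first treatment is opt-in.

## The synthetic test bed

`generate_cohort()` emits raw tables in the same dialect the loader
consumes, plus ground truth. The default configuration emulates a
neoadjuvant bladder-cancer registry cohort: diagnosis age uniform over
45–82 years; a first-line platinum doublet that is carboplatin-based with
probability 10/31 and cisplatin-based otherwise; diverse single-agent later
lines; imaging events that deliberately mix vocabulary ("Progression",
"Progressive Disease", "PD", "Metastatic lesion") together with
non-endpoint noise reads; and death or loss to follow-up. Progression-free
times are exponential with hazard `baseline · exp(0.7 · carboplatin)`
(baseline 1/600 per day, censoring hazard 1/1500 per day, ~25% censoring),
so the group contrast has a known log hazard ratio with closed-form
checks; a Weibull option was considered and rejected as adding nothing the
tests need.

Two structural guarantees make recovery exact by construction: successive
line starts are separated by at least 200 days (more than twice the
91.3-day window) while within-line agent starts jitter by at most 30 days
(less than half the window); and the next line begins only *after* the
progression event that motivates the switch, so the earliest qualifying
rwPFS endpoint is the planted one. Under these conditions the pipeline
recovers 100% of line partitions and endpoint kinds, and the Cox estimate
averages to the planted log hazard ratio across replicate seeds (the test
suite uses 20 replicates of 1000 patients; the acceptance script reports
the same quantities).

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: overlapping or interrupted regimens with
gaps shorter than the window (where the true partition is ambiguous even
to clinicians), vocabulary outside the planted dialect, informative
censoring, non-proportional hazards, measurement error in dates, and
changepoint-style disease-stage evolution. On real data the clustering
window and the matcher patterns are analysis choices the user must
justify, not estimates the package produces.

## Known limitations

* Endpoint matchers are substring-based; free-text sources must be reduced
  to tabular events upstream.
* No time-varying covariates, stratified Cox, or competing-risks
  estimators.
* Toxicity endpoints fire only on explicitly labeled toxicity events; no
  adjudication or grading is attempted.
* The swimmer and Kaplan-Meier plots are static base-graphics renderings;
  the plot-ready tables (`km_plot_data()`, `build_swimmer()`) are the
  interface for richer front ends.
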