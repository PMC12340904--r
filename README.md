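# rwevents

Real-world clinical data — treatment administrations, imaging reads,
pathology findings, vital status — arrives as a pile of heterogeneous
longitudinal tables with inconsistent vocabularies and no ready-made
survival endpoints. `rwevents` turns such tables into analyzable survival
data in four steps:

1. **Harmonize.** A small parameter file declares, per table, the event-name
   column, an event category (Treatment, Pathology, Clinical Response,
   Imaging Assessment, plus the reserved anchors Diagnosis, Death, Last
   Contact), and start/end time columns. `build_event_table()` merges
   everything into one event stream indexed by patient age in days,
   dropping-and-logging malformed rows instead of failing.
2. **Cluster lines of therapy.** Treatments whose *starts* fall within a
   user-defined window (default 3 months) are grouped into lines of therapy
   with canonical regimen labels (`"cisplatin+gemcitabine"`), under either a
   fixed induction window seeded by the earliest unassigned start (`anchor`,
   the default) or a chaining rule (`gap`).
3. **Derive endpoints.** Declarative start/endpoint rules produce per-patient
   survival records for overall survival (diagnosis → death), time to
   treatment end, and real-world progression-free survival (treatment-line
   start → earliest of next-line start, radiological progression/metastasis,
   pathological recurrence, or death; censored at last contact).
4. **Analyze.** First-principles survival statistics — the Kaplan-Meier
   product-limit estimator S(t) = ∏_{t_j ≤ t} (1 − d_j/n_j) with Greenwood
   errors, the log-rank test (O−E)ᵀV⁻¹(O−E) with hypergeometric variance,
   Cox proportional hazards h(t|x) = h₀(t)·exp(βᵀx) fitted by damped
   Newton-Raphson with Breslow/Efron ties, and Fisher's exact test by
   hypergeometric enumeration — plus cohort analytics: treatment-sequence
   Sankey graphs, treatment-by-line heatmaps, duration outlier flags
   (Tukey upper fence), swimmer-plot lanes, and relative event-position
   annotation.

A seeded synthetic-cohort generator (`generate_cohort()`) emulating an
oncology registry cohort makes the entire pipeline testable without access
to any clinical dataset, and `recovery_suite()` scores the pipeline against
the generator's ground truth.

## Worked example

```r
library(rwevents)

sim       <- generate_cohort(sim_config(n_patients = 200, seed = 42))
events    <- build_event_table(sim$spec, sim$tables)
timelines <- build_timelines(events)
lines     <- cluster_cohort(timelines, cluster_config("3mo"))
surv      <- cohort_survival_table(timelines, lines, endpoint_config("rwPFS"),
                                   grouping = list(type = "line1_regimen"))
surv$carbo <- as.numeric(surv$group == "carboplatin+gemcitabine")

table(surv$group)
#> carboplatin+gemcitabine   cisplatin+gemcitabine
#>                      67                     133

km_by_group(surv)           # medians: 201.9 vs 414.5 days
logrank_test(surv)
#> Chi-square = 13.93 on 1 df, p = 0.0001893
cox_ph(surv, "carbo")
#>        coef        se       HR HR lower .95 HR upper .95        z         p
#> carbo 0.6409 0.1745 1.898242     1.348323     2.672447 3.672443 0.000240243
```

Patients whose first line is carboplatin-based progress roughly twice as
fast as the cisplatin-based group (HR 1.90, 95% CI 1.35–2.67): the
generator plants a true log hazard ratio of 0.7 (HR ≈ 2.01) on that
contrast, and the pipeline recovers it from nothing but the raw tables.

`plot(km_by_group(surv))` draws the stratified survival curves;
`build_sankey(lines)`, `line_heatmap(lines)` and
`build_swimmer(timelines)` produce the cohort-level summaries.

## Command line

A thin Rscript front end covers the whole pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/rwevents.R", package="rwevents"))')
Rscript $CLI simulate --n 200 --seed 42 --out-dir sim
Rscript $CLI build    --params sim/params.tsv --out events.tsv
Rscript $CLI cluster  --events events.tsv --window 3mo --out lines.tsv
Rscript $CLI survive  --events events.tsv --lines lines.tsv \
                      --endpoint rwPFS --group line1_regimen --out survival.tsv
Rscript $CLI km       --survival survival.tsv --out km.tsv --plot km.png
Rscript $CLI sankey   --lines lines.tsv --out sankey.json
```

Exit status is 0 on success and 2 on a schema/configuration error;
rejected input rows are reported on stderr and via `--log`.

## Vignette

`vignettes/derivation-methods.Rmd` documents the models and conventions:
the window semantics and their limits, the endpoint rules and tie-breaks,
the tie conventions in the estimators, what the synthetic generator does
and does not emulate, and the package's known limitations.
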