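Package: rwevents
Title: Harmonizing Longitudinal Clinical Events for Real-World Survival Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Harmonizes heterogeneous longitudinal clinical tables into a
    unified, patient-age-indexed event stream, clusters temporally proximal
    treatment events into lines of therapy, derives real-world survival
    endpoints (overall survival, time-to-treatment-end, real-world
    progression-free survival) from declarative start/endpoint rules, and
    provides first-principles survival statistics (Kaplan-Meier, log-rank,
    Cox proportional hazards, Fisher's exact test) together with cohort-level
    analytics: treatment-sequence Sankey graphs, treatment-by-line heatmaps,
    duration outlier flagging, swimmer-plot lanes, and relative event-position
    annotation. A seeded synthetic-cohort generator emulating oncology
    real-world data makes the full pipeline testable without any external
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), survival, jsonlite, withr
Config/testthat/edition: 3
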