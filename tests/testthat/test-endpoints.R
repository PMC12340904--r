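# Common fixture: one patient with diagnosis, two treatment lines, a
# progression scan and death.
endpoint_fixture <- function() {
  ev <- make_events(
    rep("P1", 6),
    c("Diagnosis", "Cisplatin", "CT - progression", "Pembrolizumab",
      "Death", "Last Contact"),
    c("Diagnosis", "Treatment", "ImagingAssessment", "Treatment", "Death",
      "LastContact"),
    start_age = c(20000, 20100, 20200, 20250, 20400, 20400),
    end_age = c(20000, 20160, 20200, 20310, 20400, 20400))
  tl <- build_timelines(ev)
  lines <- cluster_cohort(tl, cluster_config(90))
  list(timelines = tl, lines = lines)
}

test_that("OS runs from diagnosis to death per the endpoint table", {
  fx <- endpoint_fixture()
  rec <- derive_survival(fx$timelines$P1, fx$lines, endpoint_config("OS"))
  expect_equal(rec$time, 400)
  expect_equal(rec$event, 1L)
  expect_identical(rec$endpoint_kind, "Death")
})

test_that("rwPFS takes the earliest qualifying endpoint after the start", {
  ev <- make_events(
    rep("P1", 4),
    c("DrugA", "scan progression", "DrugB", "Last Contact"),
    c("Treatment", "ImagingAssessment", "Treatment", "LastContact"),
    start_age = c(0.5, 100, 150, 900))
  tl <- build_timelines(ev)
  lines <- cluster_cohort(tl, cluster_config(90))
  expect_equal(nrow(lines), 2L)
  rec <- derive_survival(tl$P1, lines, endpoint_config("rwPFS"))
  # progression at 100 beats the line-2 start at 150
  expect_equal(rec$time, 99.5)
  expect_identical(rec$endpoint_kind, "Progression")

  # with no progression event, the next line start fires instead
  ev2 <- make_events(rep("P1", 3), c("DrugA", "DrugB", "Last Contact"),
                     c("Treatment", "Treatment", "LastContact"),
                     start_age = c(0.5, 150, 900))
  tl2 <- build_timelines(ev2)
  lines2 <- cluster_cohort(tl2, cluster_config(90))
  rec2 <- derive_survival(tl2$P1, lines2, endpoint_config("rwPFS"))
  expect_equal(rec2$time, 149.5)
  expect_identical(rec2$endpoint_kind, "NextLineStart")
})

test_that("patients without qualifying endpoints censor at last contact", {
  ev <- make_events(rep("P1", 2), c("DrugA", "Last Contact"),
                    c("Treatment", "LastContact"),
                    start_age = c(100, 900))
  tl <- build_timelines(ev)
  lines <- cluster_cohort(tl, cluster_config(90))
  rec <- derive_survival(tl$P1, lines, endpoint_config("rwPFS"))
  expect_equal(rec$time, 800)
  expect_equal(rec$event, 0L)
  expect_identical(rec$endpoint_kind, "censored")
})

test_that("dialect defaults match PD shorthand and metastasis variants", {
  for (nm in c("Progressive Disease", "PD", "progression noted")) {
    ev <- make_events(rep("P1", 3), c("DrugA", nm, "Last Contact"),
                      c("Treatment", "ImagingAssessment", "LastContact"),
                      start_age = c(10, 50, 600))
    tl <- build_timelines(ev)
    rec <- derive_survival(tl$P1, cluster_cohort(tl, cluster_config(90)),
                           endpoint_config("rwPFS"))
    expect_identical(rec$endpoint_kind, "Progression", label = nm)
  }
  ev <- make_events(rep("P1", 3), c("DrugA", "Metastatic lesion", "LC"),
                    c("Treatment", "ImagingAssessment", "LastContact"),
                    start_age = c(10, 50, 600))
  tl <- build_timelines(ev)
  rec <- derive_survival(tl$P1, cluster_cohort(tl, cluster_config(90)),
                         endpoint_config("rwPFS"))
  expect_identical(rec$endpoint_kind, "Metastasis")
})

test_that("same-day ties are broken by endpoint rule order (death last)", {
  ev <- make_events(rep("P1", 4),
                    c("DrugA", "progression", "Death", "LC"),
                    c("Treatment", "ImagingAssessment", "Death", "LastContact"),
                    start_age = c(10, 200, 200, 200))
  tl <- build_timelines(ev)
  rec <- derive_survival(tl$P1, cluster_cohort(tl, cluster_config(90)),
                         endpoint_config("rwPFS"))
  expect_identical(rec$endpoint_kind, "Progression")
})

test_that("unresolvable starts and non-positive follow-up are excluded with reasons", {
  # no diagnosis -> OS start unresolvable
  ev <- make_events("P1", "DrugA", "Treatment", start_age = 10)
  tl <- build_timelines(ev)
  r <- derive_survival(tl$P1, rwevents:::empty_lines(), endpoint_config("OS"))
  expect_s3_class(r, "rw_exclusion")
  expect_match(r$reason, "diagnosis")

  # start-and-progress on the same day -> excluded, never a zero time
  ev2 <- make_events(rep("P1", 2), c("DrugA", "progression"),
                     c("Treatment", "ImagingAssessment"),
                     start_age = c(10, 10))
  tl2 <- build_timelines(ev2)
  r2 <- derive_survival(tl2$P1, cluster_cohort(tl2, cluster_config(90)),
                        endpoint_config("rwPFS"))
  expect_s3_class(r2, "rw_exclusion")
  expect_match(r2$reason, "non-positive")
})

test_that("endpoint config enforces the per-analysis invariants", {
  expect_error(endpoint_config("OS", start_rule = list(type = "line", index = 1)),
               "diagnosis")
  expect_error(endpoint_config("OS", event_rules = "Progression"), "Death")
  expect_error(endpoint_config("TTE", event_rules = "NextLineStart"),
               "TreatmentChange")
  cfg <- endpoint_config("rwPFS", event_rules = c("TreatmentChange", "Death"))
  expect_identical(cfg$event_rules, c("NextLineStart", "Death"))
})

test_that("TTE fires on treatment change and on labeled toxicity", {
  ev <- make_events(rep("P1", 3), c("DrugA", "DrugB", "LC"),
                    c("Treatment", "Treatment", "LastContact"),
                    start_age = c(10, 300, 900))
  tl <- build_timelines(ev)
  lines <- cluster_cohort(tl, cluster_config(90))
  rec <- derive_survival(tl$P1, lines, endpoint_config("TTE"))
  expect_equal(rec$time, 290)
  expect_identical(rec$endpoint_kind, "TreatmentChange")

  ev2 <- make_events(rep("P1", 3),
                     c("DrugA", "Grade 3 toxicity", "LC"),
                     c("Treatment", "ClinicalResponse", "LastContact"),
                     start_age = c(10, 100, 900))
  tl2 <- build_timelines(ev2)
  rec2 <- derive_survival(tl2$P1, cluster_cohort(tl2, cluster_config(90)),
                          endpoint_config("TTE"))
  expect_equal(rec2$time, 90)
  expect_identical(rec2$endpoint_kind, "Toxicity")
})

test_that("rwPFS never exceeds OS from a shared start (dominance)", {
  set.seed(501)
  for (rep in 1:200) {
    n_ev <- sample(2:8, 1)
    starts <- sort(round(runif(n_ev, 0, 800)))
    cats <- sample(c("Treatment", "ImagingAssessment"), n_ev, replace = TRUE)
    cats[1] <- "Treatment"
    names <- ifelse(cats == "ImagingAssessment",
                    sample(c("progression", "stable", "PD", "metastasis"),
                           n_ev, replace = TRUE),
                    sample(LETTERS[1:3], n_ev, replace = TRUE))
    died <- runif(1) < 0.5
    if (died) {
      starts <- c(starts, max(starts) + round(runif(1, 1, 200)))
      cats <- c(cats, "Death"); names <- c(names, "Death")
    }
    ev <- make_events(rep("P1", length(starts)), names, cats, starts)
    tl <- build_timelines(ev)
    lines <- cluster_cohort(tl, cluster_config(90))
    start_rule <- list(type = "line", index = 1)
    pfs <- derive_survival(tl$P1, lines,
                           endpoint_config("rwPFS", start_rule = start_rule))
    os_like <- derive_survival(tl$P1, lines,
                               endpoint_config("rwPFS", start_rule = start_rule,
                                               event_rules = "Death"))
    if (!inherits(pfs, "rw_exclusion")) {
      expect_gt(pfs$time, 0)
      if (!inherits(os_like, "rw_exclusion")) {
        expect_lte(pfs$time, os_like$time)
      }
    }
  }
})

test_that("non-matching events never change a record; earlier matches shorten it", {
  ev <- make_events(rep("P1", 3), c("DrugA", "progression", "LC"),
                    c("Treatment", "ImagingAssessment", "LastContact"),
                    start_age = c(10, 300, 900))
  tl <- build_timelines(ev)
  cfg <- endpoint_config("rwPFS")
  base <- derive_survival(tl$P1, cluster_cohort(tl, cluster_config(90)), cfg)

  with_noise <- make_events(rep("P1", 4),
                            c("DrugA", "stable disease", "progression", "LC"),
                            c("Treatment", "ImagingAssessment",
                              "ImagingAssessment", "LastContact"),
                            start_age = c(10, 150, 300, 900))
  tln <- build_timelines(with_noise)
  same <- derive_survival(tln$P1, cluster_cohort(tln, cluster_config(90)), cfg)
  expect_equal(same$time, base$time)
  expect_identical(same$endpoint_kind, base$endpoint_kind)

  earlier <- make_events(rep("P1", 4),
                         c("DrugA", "progression", "progression", "LC"),
                         c("Treatment", "ImagingAssessment",
                           "ImagingAssessment", "LastContact"),
                         start_age = c(10, 120, 300, 900))
  tle <- build_timelines(earlier)
  short <- derive_survival(tle$P1, cluster_cohort(tle, cluster_config(90)), cfg)
  expect_lt(short$time, base$time)
})

test_that("group assignment resolves, drops and errors as configured", {
  fx <- endpoint_fixture()
  rec <- cohort_survival_table(fx$timelines, fx$lines, endpoint_config("OS"))
  grouped <- assign_groups(rec, fx$lines, list(type = "line1_regimen"))
  expect_identical(grouped$group, "cisplatin")

  two <- rbind(rec, rec)
  two$patient_id <- c("P1", "P2")
  custom <- assign_groups(two, NULL, list(type = "custom", map = c(P1 = "A")))
  expect_identical(custom$group, "A")
  expect_identical(attr(custom, "dropped")$patient_id, "P2")

  expect_error(assign_groups(rec, NULL,
                             list(type = "annotation", var = "grade",
                                  data = data.frame(patient_id = "P1"))),
               "grade")
})

test_that("cohort survival table pairs records with an exclusion log", {
  ev <- make_events(c("P1", "P1", "P2", "P2", "P3"),
                    c("Diagnosis", "Death", "Diagnosis", "Last Contact", "DrugA"),
                    c("Diagnosis", "Death", "Diagnosis", "LastContact",
                      "Treatment"),
                    start_age = c(100, 500, 200, 900, 50),
                    end_age = c(100, 500, 200, 900, 110))
  tls <- build_timelines(ev)
  lines <- cluster_cohort(tls, cluster_config(90))
  tab <- cohort_survival_table(tls, lines, endpoint_config("OS"))
  expect_equal(nrow(tab), 2L)          # P3 has no diagnosis
  excl <- attr(tab, "exclusions")
  expect_identical(excl$patient_id, "P3")

  empty <- cohort_survival_table(build_timelines(rwevents:::empty_events()),
                                 rwevents:::empty_lines(),
                                 endpoint_config("OS"))
  expect_equal(nrow(empty), 0L)
})

test_that("derived records are invariant under event-row permutation", {
  set.seed(502)
  ev <- make_events(rep("P1", 6),
                    c("Diagnosis", "DrugA", "progression", "DrugB", "Death", "X"),
                    c("Diagnosis", "Treatment", "ImagingAssessment",
                      "Treatment", "Death", "Other"),
                    start_age = c(0, 100, 350, 420, 600, 50))
  cfg <- endpoint_config("rwPFS")
  tl <- build_timelines(ev)
  base <- derive_survival(tl$P1, cluster_cohort(tl, cluster_config(90)), cfg)
  for (i in 1:10) {
    shuf <- rwevents:::as_rw_events(ev[sample(nrow(ev)), ])
    tls <- build_timelines(shuf)
    again <- derive_survival(tls$P1, cluster_cohort(tls, cluster_config(90)), cfg)
    expect_equal(again$time, base$time)
    expect_identical(again$endpoint_kind, base$endpoint_kind)
  }
})
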