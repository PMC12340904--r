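#' Configuration for the synthetic cohort generator
#'
#' Describes a seeded synthetic oncology cohort with the structure typical of
#' registry-derived real-world data: a diagnosis, a first-line platinum
#' doublet, diverse later lines separated by wide gaps, imaging/response
#' events (including dialect noise such as "PD" for progressive disease),
#' and death or loss to follow-up. Defaults emulate a neoadjuvant bladder
#' cancer cohort: diagnosis age uniform over 45-82 years, first line
#' carboplatin+gemcitabine vs cisplatin+gemcitabine in roughly a 10:21
#' ratio, and a positive log hazard ratio for the carboplatin-based group.
#'
#' Inter-line start gaps are drawn wider than twice the default clustering
#' window while within-line agent starts are jittered by less than half the
#' window, so the true line partition is recoverable exactly by
#' construction. Progression-free survival times are exponential with
#' hazard `baseline_hazard * exp(true_log_hr * group)` (group 1 =
#' carboplatin-based), giving closed-form sanity checks; censoring is an
#' independent exponential.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param true_log_hr True log hazard ratio of the carboplatin-based group.
#' @param baseline_hazard Event hazard per day in the reference
#'   (cisplatin-based) group.
#' @param censor_rate Censoring hazard per day.
#' @param window_days Clustering window the design is separated against.
#' @param jitter_days Maximum within-line agent start jitter (must stay
#'   below `window_days / 2` for guaranteed line recovery).
#' @param gap_min_days,gap_max_days Range of gaps between successive line
#'   starts (`gap_min_days` must exceed `2 * window_days`).
#' @param p_carboplatin Probability the first line is carboplatin-based.
#' @param p_second_line,p_third_line Probability of switching to a next
#'   line after progression / after the previous line.
#' @param p_kind Probabilities of the true endpoint kind given an event:
#'   named vector over `Progression`, `Metastasis`, `Death`.
#' @param p_sequencing Probability a patient has a tumor-sequencing event.
#' @return A list of class `rw_sim_config`.
#' @export
sim_config <- function(n_patients = 200L, seed = 42L,
                       true_log_hr = 0.7, baseline_hazard = 1 / 600,
                       censor_rate = 1 / 1500, window_days = 91.3125,
                       jitter_days = 30, gap_min_days = 200,
                       gap_max_days = 400, p_carboplatin = 10 / 31,
                       p_second_line = 0.8, p_third_line = 0.4,
                       p_kind = c(Progression = 0.55, Metastasis = 0.15,
                                  Death = 0.30),
                       p_sequencing = 0.8) {
  if (n_patients < 0) stop("n_patients must be non-negative", call. = FALSE)
  if (baseline_hazard <= 0 || censor_rate <= 0) {
    stop("hazard rates must be positive", call. = FALSE)
  }
  if (gap_min_days <= window_days) {
    stop("gap_min_days must exceed the clustering window for a separated design",
         call. = FALSE)
  }
  if (jitter_days >= window_days) {
    stop("jitter_days must be smaller than the clustering window", call. = FALSE)
  }
  probs <- c(p_carboplatin, p_second_line, p_third_line, p_sequencing, p_kind)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  if (abs(sum(p_kind) - 1) > 1e-12) stop("p_kind must sum to 1", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 true_log_hr = true_log_hr, baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, window_days = window_days,
                 jitter_days = jitter_days, gap_min_days = gap_min_days,
                 gap_max_days = gap_max_days, p_carboplatin = p_carboplatin,
                 p_second_line = p_second_line, p_third_line = p_third_line,
                 p_kind = p_kind, p_sequencing = p_sequencing),
            class = "rw_sim_config")
}

# Regimen vocabulary. Later-line names deliberately mix case to exercise
# the case-normalized regimen labels.
first_line_menu <- function() {
  list(carbo = c("Carboplatin", "Gemcitabine"),
       cis = c("Cisplatin", "Gemcitabine"))
}
later_line_menu <- function() {
  c("Pembrolizumab", "Atezolizumab", "Nivolumab", "Erdafitinib",
    "Enfortumab Vedotin")
}
progression_dialect <- function() {
  c("Progression", "Progressive Disease", "PD")
}
metastasis_dialect <- function() {
  c("Metastasis", "Metastatic lesion")
}

#' Generate a synthetic cohort
#'
#' Emits the raw clinical tables (diagnosis, medications, imaging, death,
#' follow-up, sequencing), a matching parameter specification, patient-level
#' annotations and the ground truth (true line assignments, true group,
#' true endpoint time and kind before censoring). Deterministic given the
#' seed; when `dir` is given the same tables and the parameter file are
#' also written as TSV in the pipeline's input dialect.
#'
#' @param config An `rw_sim_config`.
#' @param dir Optional output directory.
#' @return A list of class `rw_sim` with elements `tables` (named list of
#'   data frames), `spec` (`rw_param_spec`), `annotations` (patient-level
#'   data frame with `patient_id`, `group`, `sex`, `age_at_dx_years`) and
#'   `truth` (list with `patients` and `treatment_lines` data frames).
#' @export
generate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "rw_sim_config"))
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_patients
  rnd <- function(x) round(x, 3)
  diag_rows <- med_rows <- img_rows <- death_rows <- fup_rows <- seq_rows <- list()
  truth_pat <- truth_lines <- list()
  ann <- list()

  for (i in seq_len(n)) {
    pid <- sprintf("P%04d", i)
    dx_age <- rnd(stats::runif(1, 45 * 365.25, 82 * 365.25))
    carbo <- stats::runif(1) < config$p_carboplatin
    group <- if (carbo) 1L else 0L
    regimen <- if (carbo) first_line_menu()$carbo else first_line_menu()$cis
    t1 <- rnd(dx_age + stats::runif(1, 30, 90))

    # true progression-free survival from first-line start
    rate <- config$baseline_hazard * exp(config$true_log_hr * group)
    e_gap <- stats::rexp(1, rate)
    c_gap <- stats::rexp(1, config$censor_rate)
    kind <- sample(names(config$p_kind), 1, prob = config$p_kind)
    true_event <- e_gap <= c_gap
    e_age <- rnd(t1 + e_gap)
    c_age <- rnd(t1 + c_gap)
    # observation ends at death or at the censoring time
    f_age <- if (true_event && kind == "Death") e_age else c_age

    # line starts: line 2 follows the progression event (treatment changes
    # because the disease progressed), pushed out to at least gap_min for a
    # separated design; line 3 one gap further.
    line_starts <- t1
    line_agents <- list(regimen)
    if (true_event && kind != "Death" && stats::runif(1) < config$p_second_line) {
      s2 <- max(e_age + stats::runif(1, 30, 90),
                t1 + config$gap_min_days)
      line_starts <- c(line_starts, rnd(s2))
      line_agents <- c(line_agents, list(sample(later_line_menu(), 1)))
      if (stats::runif(1) < config$p_third_line) {
        s3 <- s2 + stats::runif(1, config$gap_min_days, config$gap_max_days)
        line_starts <- c(line_starts, rnd(s3))
        line_agents <- c(line_agents,
                         list(sample(setdiff(later_line_menu(),
                                             line_agents[[2]]), 1)))
      }
    }

    for (k in seq_along(line_starts)) {
      if (line_starts[k] >= f_age) next
      agents <- line_agents[[k]]
      for (j in seq_along(agents)) {
        s <- if (j == 1L) line_starts[k] else
          rnd(line_starts[k] + stats::runif(1, 0, config$jitter_days))
        if (s >= f_age) s <- line_starts[k]
        e <- rnd(min(s + stats::runif(1, 60, 120), f_age))
        med_rows[[length(med_rows) + 1L]] <- data.frame(
          patient_id = pid, medication = agents[j], start_days = s,
          end_days = e, stringsAsFactors = FALSE)
        truth_lines[[length(truth_lines) + 1L]] <- data.frame(
          patient_id = pid, agent = tolower(agents[j]), start_age = s,
          line_index = k, stringsAsFactors = FALSE)
      }
      # a routine response assessment inside the line (non-endpoint noise)
      scan <- rnd(line_starts[k] + stats::runif(1, 10, 60))
      if (scan < f_age) {
        img_rows[[length(img_rows) + 1L]] <- data.frame(
          patient_id = pid,
          finding = sample(c("Stable Disease", "Partial Response"), 1),
          scan_days = scan, stringsAsFactors = FALSE)
      }
    }

    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      patient_id = pid, event = "Diagnosis", age_days = dx_age,
      stringsAsFactors = FALSE)
    if (config$p_sequencing > 0 && stats::runif(1) < config$p_sequencing) {
      seq_rows[[length(seq_rows) + 1L]] <- data.frame(
        patient_id = pid, assay = "Tumor Sequencing",
        collection_days = rnd(dx_age + stats::runif(1, 0, 60)),
        stringsAsFactors = FALSE)
    }
    if (true_event) {
      if (kind == "Death") {
        death_rows[[length(death_rows) + 1L]] <- data.frame(
          patient_id = pid, status = "Death", age_days = e_age,
          stringsAsFactors = FALSE)
      } else {
        nm <- if (kind == "Progression") sample(progression_dialect(), 1)
          else sample(metastasis_dialect(), 1)
        img_rows[[length(img_rows) + 1L]] <- data.frame(
          patient_id = pid, finding = nm, scan_days = e_age,
          stringsAsFactors = FALSE)
        fup_rows[[length(fup_rows) + 1L]] <- data.frame(
          patient_id = pid, contact = "Last Contact", age_days = c_age,
          stringsAsFactors = FALSE)
      }
    } else {
      fup_rows[[length(fup_rows) + 1L]] <- data.frame(
        patient_id = pid, contact = "Last Contact", age_days = c_age,
        stringsAsFactors = FALSE)
    }

    truth_pat[[length(truth_pat) + 1L]] <- data.frame(
      patient_id = pid, group = group,
      group_label = if (carbo) "carboplatin-based" else "cisplatin-based",
      t0 = t1, true_time = rnd(if (true_event) e_age - t1 else c_age - t1),
      true_event = as.integer(true_event),
      true_kind = if (true_event) kind else "censored",
      n_lines_true = sum(line_starts < f_age),
      stringsAsFactors = FALSE)
    ann[[length(ann) + 1L]] <- data.frame(
      patient_id = pid, sex = sample(c("M", "F"), 1, prob = c(0.75, 0.25)),
      age_at_dx_years = round(dx_age / 365.25, 1),
      group = if (carbo) "carboplatin-based" else "cisplatin-based",
      stringsAsFactors = FALSE)
  }

  bind <- function(rows, template) {
    if (length(rows)) do.call(rbind, rows) else template
  }
  tables <- list(
    diagnosis = bind(diag_rows, data.frame(patient_id = character(0),
                                           event = character(0),
                                           age_days = numeric(0))),
    medications = bind(med_rows, data.frame(patient_id = character(0),
                                            medication = character(0),
                                            start_days = numeric(0),
                                            end_days = numeric(0))),
    imaging = bind(img_rows, data.frame(patient_id = character(0),
                                        finding = character(0),
                                        scan_days = numeric(0))),
    death = bind(death_rows, data.frame(patient_id = character(0),
                                        status = character(0),
                                        age_days = numeric(0))),
    followup = bind(fup_rows, data.frame(patient_id = character(0),
                                         contact = character(0),
                                         age_days = numeric(0))),
    sequencing = bind(seq_rows, data.frame(patient_id = character(0),
                                           assay = character(0),
                                           collection_days = numeric(0)))
  )
  tables <- lapply(tables, function(t) { rownames(t) <- NULL; t })

  spec <- data.frame(
    table_id = names(tables),
    file = paste0(names(tables), ".tsv"),
    event_name_col = c("event", "medication", "finding", "status", "contact",
                       "assay"),
    category = c("Diagnosis", "Treatment", "ImagingAssessment", "Death",
                 "LastContact", "Pathology"),
    start_col = c("age_days", "start_days", "scan_days", "age_days",
                  "age_days", "collection_days"),
    end_col = c("", "end_days", "", "", "", ""),
    detail_cols = "",
    time_unit = "days",
    stringsAsFactors = FALSE
  )
  class(spec) <- c("rw_param_spec", "data.frame")

  out <- list(
    tables = tables, spec = spec,
    annotations = bind(ann, data.frame(patient_id = character(0),
                                       sex = character(0),
                                       age_at_dx_years = numeric(0),
                                       group = character(0))),
    truth = list(
      patients = bind(truth_pat, data.frame(
        patient_id = character(0), group = integer(0),
        group_label = character(0), t0 = numeric(0), true_time = numeric(0),
        true_event = integer(0), true_kind = character(0),
        n_lines_true = integer(0))),
      treatment_lines = bind(truth_lines, data.frame(
        patient_id = character(0), agent = character(0),
        start_age = numeric(0), line_index = integer(0)))),
    config = config
  )
  out$truth$patients <- local({ x <- out$truth$patients; rownames(x) <- NULL; x })
  out$truth$treatment_lines <- local({
    x <- out$truth$treatment_lines; rownames(x) <- NULL; x })
  class(out) <- "rw_sim"

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(tables)) {
      utils::write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(as.data.frame(spec), file.path(dir, "params.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$annotations, file.path(dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    attr(out$spec, "dir") <- normalizePath(dir)
  }
  out
}

#' @export
print.rw_sim <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_patients, "patient(s), seed",
      x$config$seed, "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-12s %d row(s)\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}

#' Run the full pipeline on a synthetic cohort and score recovery
#'
#' Generates a cohort, harmonizes the raw tables, clusters the treatment
#' lines, derives real-world progression-free survival, fits the Cox model
#' on the carboplatin-vs-cisplatin contrast, and scores each stage against
#' the generator's ground truth: the fraction of patients whose derived
#' line partition matches the true one exactly, the fraction of uncensored
#' patients whose derived endpoint kind matches the true kind, and the Cox
#' log hazard ratio estimate versus the configured truth.
#'
#' @param config An `rw_sim_config`.
#' @return An object of class `rw_recovery`: list with `n_patients`,
#'   `line_recovery_rate`, `endpoint_accuracy`, `n_uncensored`, `beta_hat`,
#'   `se_beta`, `true_log_hr`, `cox` (the `rw_cox` fit), `survival`
#'   (the `rw_survival` table) and `events` / `lines` row counts.
#' @export
recovery_suite <- function(config = sim_config()) {
  sim <- generate_cohort(config)
  events <- build_event_table(sim$spec, sim$tables)
  timelines <- build_timelines(events)
  lines <- cluster_cohort(timelines,
                          cluster_config(config$window_days, "anchor"))

  # line recovery: derived (agent, start) -> line index must reproduce the
  # true assignment for every treatment event of the patient
  derived <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
    m <- lines$members[[i]]
    data.frame(patient_id = lines$patient_id[i],
               agent = tolower(m$event_name), start_age = m$start_age,
               line_index = lines$line_index[i], stringsAsFactors = FALSE)
  }))
  truth_l <- sim$truth$treatment_lines
  key <- function(d) paste(d$patient_id, d$agent, sprintf("%.3f", d$start_age),
                           sep = "|")
  ok_by_pat <- if (is.null(derived) || nrow(truth_l) == 0L) logical(0) else {
    truth_l$derived_index <- derived$line_index[match(key(truth_l), key(derived))]
    tapply(truth_l$derived_index == truth_l$line_index, truth_l$patient_id,
           function(z) all(!is.na(z) & z))
  }
  line_recovery <- if (length(ok_by_pat)) mean(ok_by_pat) else NA_real_

  cfg <- endpoint_config("rwPFS")
  surv <- cohort_survival_table(timelines, lines, cfg,
                                grouping = list(type = "line1_regimen"))
  surv$carbo <- as.numeric(grepl("carboplatin", surv$group, fixed = TRUE))

  tp <- sim$truth$patients
  mi <- match(surv$patient_id, tp$patient_id)
  unc <- which(tp$true_event[mi] == 1L)
  endpoint_accuracy <- if (length(unc)) {
    mean(surv$endpoint_kind[unc] == tp$true_kind[mi[unc]] &
           surv$event[unc] == 1L)
  } else NA_real_

  fit <- if (nrow(surv) && stats::var(surv$carbo) > 0 && sum(surv$event) > 0) {
    cox_ph(surv, "carbo")
  } else NULL

  out <- list(n_patients = config$n_patients,
              line_recovery_rate = line_recovery,
              endpoint_accuracy = endpoint_accuracy,
              n_uncensored = length(unc),
              beta_hat = if (is.null(fit)) NA_real_ else unname(fit$coefficients),
              se_beta = if (is.null(fit)) NA_real_ else unname(fit$standard_errors),
              true_log_hr = config$true_log_hr,
              cox = fit, survival = surv,
              n_events_table = nrow(events), n_lines = nrow(lines))
  class(out) <- "rw_recovery"
  out
}

#' @export
print.rw_recovery <- function(x, ...) {
  cat("Pipeline recovery on synthetic cohort (n =", x$n_patients, ")\n")
  cat(sprintf("  line recovery:      %.1f%%\n", 100 * x$line_recovery_rate))
  cat(sprintf("  endpoint accuracy:  %.1f%% (%d uncensored)\n",
              100 * x$endpoint_accuracy, x$n_uncensored))
  cat(sprintf("  Cox log-HR: %.3f (SE %.3f), truth %.3f\n",
              x$beta_hat, x$se_beta, x$true_log_hr))
  invisible(x)
}
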