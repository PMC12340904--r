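#' Declarative survival endpoint configuration
#'
#' Encodes the start-point and endpoint rules for the three supported
#' real-world analyses:
#' \describe{
#'   \item{OS}{overall survival — from diagnosis to death, censored at last
#'     follow-up/contact.}
#'   \item{TTE}{time to treatment end — from a treatment start to change of
#'     treatment line, treatment-associated toxicity, or death.}
#'   \item{rwPFS}{real-world progression-free survival — from a treatment
#'     start to change of treatment line, radiological
#'     progression/metastasis, pathological recurrence, or death.}
#' }
#' Start rules: `list(type = "diagnosis")`,
#' `list(type = "first_treatment", names = <optional agent names>)`,
#' `list(type = "line", index = k)`, or
#' `list(type = "line_regimen", label = <regimen label>)`.
#'
#' Endpoint matchers are identified by kind. `NextLineStart` (alias
#' `TreatmentChange`) is resolved structurally as the start of line
#' \eqn{k+1} where \eqn{k} is the index line — no name matching involved.
#' `Progression`, `Metastasis`, `PathRecurrence` and `Toxicity` match
#' case-insensitive name substrings against response-type event categories,
#' since real-world vocabularies vary by institution; `Death` matches the
#' Death category. The default patterns cover the common dialect, including
#' the "PD" shorthand for progressive disease.
#'
#' @param analysis `"OS"`, `"TTE"` or `"rwPFS"`.
#' @param start_rule Start-point rule (see above). Defaults: diagnosis for
#'   OS, line 1 for TTE/rwPFS.
#' @param event_rules Ordered character vector of matcher kinds; the order
#'   breaks ties when several endpoints fall on the same day (Death is
#'   placed last by default so a same-day progression is recorded as
#'   progression). Defaults: OS `"Death"`; TTE
#'   `c("TreatmentChange", "Toxicity", "Death")`; rwPFS
#'   `c("NextLineStart", "Progression", "Metastasis", "PathRecurrence",
#'   "Death")`.
#' @param patterns Named list overriding the default name patterns per kind.
#' @return A list of class `rw_endpoint_config`.
#' @export
endpoint_config <- function(analysis = c("OS", "TTE", "rwPFS"),
                            start_rule = NULL, event_rules = NULL,
                            patterns = list()) {
  analysis <- match.arg(analysis)
  allowed <- switch(analysis,
    OS = "Death",
    TTE = c("TreatmentChange", "Toxicity", "Death"),
    rwPFS = c("NextLineStart", "Progression", "Metastasis", "PathRecurrence",
              "Death"))
  if (is.null(event_rules)) event_rules <- allowed
  event_rules[event_rules == "TreatmentChange" & analysis == "rwPFS"] <- "NextLineStart"
  bad <- setdiff(event_rules, allowed)
  if (length(bad)) {
    stop(analysis, " endpoints must be drawn from {",
         paste(allowed, collapse = ", "), "}; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(start_rule)) {
    start_rule <- if (analysis == "OS") list(type = "diagnosis") else list(type = "line", index = 1L)
  }
  if (analysis == "OS" && !identical(start_rule$type, "diagnosis")) {
    stop("OS starts at diagnosis by definition", call. = FALSE)
  }
  if (!start_rule$type %in% c("diagnosis", "first_treatment", "line", "line_regimen")) {
    stop("unknown start rule type: ", start_rule$type, call. = FALSE)
  }
  defaults <- list(
    Progression = c("progress", "pd"),
    Metastasis = c("metasta"),
    PathRecurrence = c("recurren"),
    Toxicity = c("toxic")
  )
  for (k in names(patterns)) defaults[[k]] <- patterns[[k]]
  structure(list(analysis = analysis, start_rule = start_rule,
                 event_rules = event_rules, patterns = defaults,
                 censor_rule = "last_contact"),
            class = "rw_endpoint_config")
}

# Categories a pattern matcher scans, by matcher kind.
matcher_categories <- function(kind) {
  switch(kind,
    Progression = c("ImagingAssessment", "ClinicalResponse"),
    Metastasis = c("ImagingAssessment", "ClinicalResponse", "Pathology"),
    PathRecurrence = c("Pathology", "ClinicalResponse"),
    Toxicity = c("ClinicalResponse", "Other"),
    NULL)
}

# Resolve the start age t0 for one patient; NA with a reason when missing.
resolve_start <- function(timeline, lines, start_rule) {
  ev <- timeline$events
  switch(start_rule$type,
    diagnosis = {
      t0 <- timeline$anchors$diagnosis_age
      if (is.na(t0)) list(t0 = NA_real_, reason = "no diagnosis event")
      else list(t0 = t0, index_line = 0L)
    },
    first_treatment = {
      tr <- ev[ev$category == "Treatment", , drop = FALSE]
      if (!is.null(start_rule$names)) {
        tr <- tr[tolower(tr$event_name) %in% tolower(start_rule$names), , drop = FALSE]
      }
      if (nrow(tr) == 0L) return(list(t0 = NA_real_, reason = "no qualifying start treatment"))
      t0 <- min(tr$start_age)
      k <- index_line_at(lines, t0)
      list(t0 = t0, index_line = k)
    },
    line = {
      k <- as.integer(start_rule$index)
      row <- which(lines$line_index == k)
      if (!length(row)) return(list(t0 = NA_real_,
                                    reason = sprintf("no line %d", k)))
      list(t0 = lines$line_start[row[1L]], index_line = k)
    },
    line_regimen = {
      row <- which(lines$regimen_label == tolower(start_rule$label))
      if (!length(row)) return(list(t0 = NA_real_,
                                    reason = sprintf("no line with regimen '%s'", start_rule$label)))
      row <- row[which.min(lines$line_start[row])]
      list(t0 = lines$line_start[row], index_line = lines$line_index[row])
    })
}

# The line whose start is the latest at or before t0 (0 when t0 precedes
# every line) — used to resolve "next line" structurally.
index_line_at <- function(lines, t0) {
  if (is.null(lines) || nrow(lines) == 0L) return(0L)
  at <- which(lines$line_start <= t0)
  if (!length(at)) 0L else max(lines$line_index[at])
}

#' Derive one patient's survival record
#'
#' Resolves the start point, scans the timeline for the earliest qualifying
#' endpoint strictly after the start (so that time at risk is always
#' positive and events at or before the start can never fire), and falls
#' back to censoring at last contact. Ties at the same endpoint time are
#' broken by the order of `event_rules` in the configuration.
#'
#' @param timeline An `rw_timeline`.
#' @param lines The patient's `rw_lines` (from the same cohort-wide
#'   clustering); may be an empty lines table for OS.
#' @param config An `rw_endpoint_config`.
#' @return A one-row data frame with `patient_id`, `time` (days), `event`
#'   (0/1), `endpoint_kind`; or `NULL` with attribute-free exclusion — the
#'   reason is returned via attribute `"reason"` on `NULL`-like empty frame.
#'   Use [cohort_survival_table()] for the cohort-level version with an
#'   exclusion log.
#' @export
derive_survival <- function(timeline, lines, config) {
  stopifnot(inherits(config, "rw_endpoint_config"))
  if (!is.null(lines) && nrow(lines)) {
    lines <- lines[lines$patient_id == timeline$patient_id, , drop = FALSE]
  }
  st <- resolve_start(timeline, lines, config$start_rule)
  if (is.na(st$t0)) return(excluded(timeline$patient_id, st$reason))
  t0 <- st$t0
  ev <- timeline$events

  cand_time <- rep(Inf, length(config$event_rules))
  for (j in seq_along(config$event_rules)) {
    kind <- config$event_rules[j]
    if (kind %in% c("NextLineStart", "TreatmentChange")) {
      if (!is.null(lines) && nrow(lines)) {
        k <- st$index_line
        if (is.null(k)) k <- index_line_at(lines, t0)
        nxt <- lines$line_start[lines$line_index == k + 1L]
        if (length(nxt) && nxt > t0) cand_time[j] <- nxt
      }
    } else if (kind == "Death") {
      d <- ev$start_age[ev$category == "Death" & ev$start_age > t0]
      if (length(d)) cand_time[j] <- min(d)
    } else {
      pats <- config$patterns[[kind]]
      cats <- matcher_categories(kind)
      sel <- ev$category %in% cats & ev$start_age > t0
      if (any(sel) && length(pats)) {
        nm <- tolower(ev$event_name[sel])
        hit <- Reduce(`|`, lapply(tolower(pats), function(p) grepl(p, nm, fixed = TRUE)))
        tt <- ev$start_age[sel][hit]
        if (length(tt)) cand_time[j] <- min(tt)
      }
    }
  }

  if (any(is.finite(cand_time))) {
    best <- min(cand_time)
    kind <- config$event_rules[which(cand_time == best)[1L]] # rule order breaks ties
    return(survival_row(timeline$patient_id, best - t0, 1L, kind))
  }
  lc <- timeline$anchors$last_contact_age
  if (is.na(lc) || lc <= t0) {
    return(excluded(timeline$patient_id, "non-positive follow-up"))
  }
  survival_row(timeline$patient_id, lc - t0, 0L, "censored")
}

survival_row <- function(pid, time, event, kind, group = NA_character_) {
  data.frame(patient_id = pid, time = time, event = event,
             group = group, endpoint_kind = kind, stringsAsFactors = FALSE)
}

excluded <- function(pid, reason) {
  structure(list(patient_id = pid, reason = reason), class = "rw_exclusion")
}

#' Assign comparison groups to survival records
#'
#' Populates the `group` field used by the two-group survival comparisons.
#' Records whose group cannot be resolved are dropped and logged.
#'
#' @param records Data frame of survival records (from
#'   [cohort_survival_table()] or [derive_survival()] rows).
#' @param lines Cohort `rw_lines` (needed for `line1_regimen` grouping).
#' @param grouping One of `list(type = "line1_regimen")` (group = the
#'   patient's first-line regimen label), `list(type = "annotation",
#'   var = <name>, data = <patient-level data frame>)`, or
#'   `list(type = "custom", map = <named character vector>)`.
#' @return The records with `group` filled; dropped records are recorded in
#'   attribute `"dropped"` (data frame `patient_id`, `reason`).
#' @export
assign_groups <- function(records, lines = NULL, grouping) {
  if (is.character(grouping)) grouping <- list(type = grouping)
  g <- rep(NA_character_, nrow(records))
  if (grouping$type == "line1_regimen") {
    l1 <- lines[lines$line_index == 1L, , drop = FALSE]
    g <- l1$regimen_label[match(records$patient_id, l1$patient_id)]
  } else if (grouping$type == "annotation") {
    if (is.null(grouping$data) || !grouping$var %in% names(grouping$data)) {
      stop("annotation grouping needs `data` containing variable '",
           grouping$var, "'", call. = FALSE)
    }
    g <- as.character(grouping$data[[grouping$var]][
      match(records$patient_id, grouping$data$patient_id)])
  } else if (grouping$type == "custom") {
    g <- unname(grouping$map[records$patient_id])
  } else {
    stop("unknown grouping type: ", grouping$type, call. = FALSE)
  }
  keep <- !is.na(g) & nzchar(g)
  dropped <- data.frame(patient_id = records$patient_id[!keep],
                        reason = rep("unresolvable group", sum(!keep)),
                        stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  out$group <- g[keep]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Cohort-level survival table
#'
#' Maps [derive_survival()] over every patient, optionally assigns groups,
#' and collects per-patient exclusion reasons into a log — patients with
#' unresolvable start points or non-positive follow-up are excluded with a
#' reason, never silently dropped.
#'
#' @param timelines An `rw_timelines` object.
#' @param lines Cohort `rw_lines` from the same clustering used cohort-wide.
#' @param config An `rw_endpoint_config`.
#' @param grouping Optional grouping spec (see [assign_groups()]).
#' @return A data frame of class `rw_survival` with columns `patient_id`,
#'   `time`, `event`, `group`, `endpoint_kind`; exclusions in attribute
#'   `"exclusions"`, group drops in attribute `"dropped"`.
#' @export
cohort_survival_table <- function(timelines, lines, config, grouping = NULL) {
  rows <- list(); excl <- list()
  for (tl in timelines) {
    r <- derive_survival(tl, lines, config)
    if (inherits(r, "rw_exclusion")) {
      excl[[length(excl) + 1L]] <- data.frame(patient_id = r$patient_id,
                                              reason = r$reason,
                                              stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), time = numeric(0),
               event = integer(0), group = character(0),
               endpoint_kind = character(0), stringsAsFactors = FALSE)
  dropped <- NULL
  if (!is.null(grouping) && nrow(out)) {
    out <- assign_groups(out, lines, grouping)
    dropped <- attr(out, "dropped")
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  class(out) <- c("rw_survival", "data.frame")
  out
}

#' @export
print.rw_survival <- function(x, ...) {
  cat("Survival records:", nrow(x), "patient(s),", sum(x$event), "event(s)\n")
  ex <- attr(x, "exclusions")
  if (!is.null(ex) && nrow(ex)) cat("Excluded:", nrow(ex), "patient(s)\n")
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}
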