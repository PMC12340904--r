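#' Build the harmonized event table
#'
#' Turns the raw clinical tables declared in a parameter specification into a
#' single event table indexed by patient age in days. Each input row becomes
#' one event; rows whose times cannot be parsed, are negative, or have an end
#' before their start are dropped and recorded in the rejection log rather
#' than aborting the run, reflecting the inconsistent quality of routine-care
#' data.
#'
#' @param spec An `rw_param_spec` from [parse_parameter_file()].
#' @param tables Named list of data frames keyed by `table_id`. If `NULL`,
#'   each table is read from the `file` path in `spec`, resolved relative to
#'   the parameter file.
#' @param id_col Name of the patient-identifier column present in every table.
#' @return An `rw_events` data frame with columns `patient_id`, `event_name`,
#'   `category`, `start_age`, `end_age` (days), `source_table`, `event_id`
#'   and `details` (key=value pairs joined by ";"). The rejection log (a data
#'   frame with `table_id`, `row`, `reason`) is attached as attribute
#'   `"rejections"` and available via [rejection_log()].
#' @seealso [build_timelines()], [write_event_table()]
#' @export
build_event_table <- function(spec, tables = NULL, id_col = "patient_id") {
  stopifnot(inherits(spec, "rw_param_spec"))
  if (is.null(tables)) {
    dir <- attr(spec, "dir")
    tables <- lapply(seq_len(nrow(spec)), function(i) {
      path <- spec$file[i]
      if (!file.exists(path) && !is.null(dir)) path <- file.path(dir, spec$file[i])
      if (!file.exists(path)) {
        stop("table file not found for '", spec$table_id[i], "': ",
             spec$file[i], call. = FALSE)
      }
      read_delimited(path)
    })
    names(tables) <- spec$table_id
  }
  missing_tab <- setdiff(spec$table_id, names(tables))
  if (length(missing_tab)) {
    stop("no table supplied for table_id(s): ",
         paste(missing_tab, collapse = ", "), call. = FALSE)
  }

  parts <- vector("list", nrow(spec))
  rejections <- list()
  for (i in seq_len(nrow(spec))) {
    tid <- spec$table_id[i]
    tab <- tables[[tid]]
    need <- c(id_col, spec$event_name_col[i], spec$start_col[i])
    end_col <- spec$end_col[i]
    has_end <- !is.na(end_col) && nzchar(end_col)
    if (has_end) need <- c(need, end_col)
    dcols <- split_detail_cols(spec$detail_cols[i])
    absent <- setdiff(c(need, dcols), names(tab))
    if (length(absent)) {
      stop("table '", tid, "' is missing declared column(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    n <- nrow(tab)
    if (n == 0L) { parts[[i]] <- NULL; next }
    fac <- time_unit_factor(spec$time_unit[i])
    pid <- trimws(as.character(tab[[id_col]]))
    start <- suppressWarnings(as.numeric(tab[[spec$start_col[i]]])) * fac
    if (has_end) {
      end_raw <- as.character(tab[[end_col]])
      end <- suppressWarnings(as.numeric(end_raw)) * fac
      blank_end <- is.na(end_raw) | !nzchar(trimws(end_raw))
      end[blank_end] <- start[blank_end]
    } else {
      end <- start
    }
    reason <- rep(NA_character_, n)
    reason[is.na(reason) & (!nzchar(pid) | is.na(pid))] <- "missing patient id"
    reason[is.na(reason) & is.na(start)] <- "unparseable start time"
    reason[is.na(reason) & is.na(end)] <- "unparseable end time"
    reason[is.na(reason) & start < 0] <- "negative start time"
    reason[is.na(reason) & end < 0] <- "negative end time"
    reason[is.na(reason) & end < start] <- "end before start"
    keep <- is.na(reason)
    if (any(!keep)) {
      rejections[[length(rejections) + 1L]] <- data.frame(
        table_id = tid, row = which(!keep), reason = reason[!keep],
        stringsAsFactors = FALSE)
    }
    if (!any(keep)) { parts[[i]] <- NULL; next }
    details <- if (length(dcols)) {
      vapply(which(keep), function(r) {
        paste(paste0(dcols, "=", as.character(unlist(tab[r, dcols]))),
              collapse = ";")
      }, character(1))
    } else rep("", sum(keep))
    parts[[i]] <- data.frame(
      patient_id = pid[keep],
      event_name = trimws(as.character(tab[[spec$event_name_col[i]]]))[keep],
      category = spec$category[i],
      start_age = start[keep],
      end_age = end[keep],
      source_table = tid,
      event_id = sprintf("%s:%d", tid, which(keep)),
      details = details,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- empty_events()
  rownames(out) <- NULL
  attr(out, "rejections") <- if (length(rejections)) {
    do.call(rbind, rejections)
  } else {
    data.frame(table_id = character(0), row = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  class(out) <- c("rw_events", "data.frame")
  if (nrow(out) == 0L) warning("empty cohort: no valid events after filtering",
                               call. = FALSE)
  out
}

empty_events <- function() {
  data.frame(patient_id = character(0), event_name = character(0),
             category = character(0), start_age = numeric(0),
             end_age = numeric(0), source_table = character(0),
             event_id = character(0), details = character(0),
             stringsAsFactors = FALSE)
}

as_rw_events <- function(df) {
  tmpl <- empty_events()
  for (nm in names(tmpl)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- if (is.numeric(tmpl[[nm]])) NA_real_ else ""
    }
  }
  df <- df[, names(tmpl)]
  class(df) <- c("rw_events", "data.frame")
  df
}

#' Rejection log of a harmonized event table
#'
#' @param events An `rw_events` object.
#' @return Data frame with columns `table_id`, `row`, `reason`.
#' @export
rejection_log <- function(events) {
  attr(events, "rejections")
}

#' Write / read the harmonized event table
#'
#' The on-disk format is a TSV with the event fields in fixed column order.
#' Ages are written with full double precision so that a write/read round
#' trip reproduces the table exactly, field by field.
#'
#' @param events An `rw_events` data frame.
#' @param path Output (or input) file path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns an `rw_events` data frame.
#' @export
write_event_table <- function(events, path) {
  out <- as.data.frame(events)
  out$start_age <- sprintf("%.17g", out$start_age)
  out$end_age <- sprintf("%.17g", out$end_age)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  raw <- read_delimited(path)
  raw$start_age <- as.numeric(raw$start_age)
  raw$end_age <- as.numeric(raw$end_age)
  out <- as_rw_events(raw)
  attr(out, "rejections") <- data.frame(table_id = character(0), row = integer(0),
                                        reason = character(0), stringsAsFactors = FALSE)
  out
}

#' @export
print.rw_events <- function(x, ...) {
  cat("Harmonized event table:", nrow(x), "event(s),",
      length(unique(x$patient_id)), "patient(s)\n")
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej)) cat("Rejected rows:", nrow(rej), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Assemble per-patient timelines
#'
#' Groups the harmonized events by patient and sorts each patient's events
#' into the canonical order (start age, end age, event name), which makes
#' every downstream computation invariant to input row order. The survival
#' anchors (diagnosis, death, last-contact age) are resolved from the
#' reserved categories; when a patient has no explicit LastContact event the
#' last-contact age falls back to the maximum end age over all their events,
#' a conservative censoring time.
#'
#' @param events An `rw_events` data frame.
#' @return A list of class `rw_timelines`; each element is an `rw_timeline`
#'   list with `patient_id`, `events` (sorted data frame) and `anchors`
#'   (list with `diagnosis_age`, `death_age`, `last_contact_age`; `NA` when
#'   unresolvable).
#' @export
build_timelines <- function(events) {
  if (nrow(events) == 0L) {
    out <- list()
    class(out) <- "rw_timelines"
    return(out)
  }
  ord <- order(events$patient_id, events$start_age, events$end_age,
               events$event_name, events$event_id, method = "radix")
  ev <- as.data.frame(events)[ord, , drop = FALSE]
  rownames(ev) <- NULL
  idx <- split(seq_len(nrow(ev)), ev$patient_id)
  # split() orders by factor level (sorted ids); deterministic.
  out <- lapply(names(idx), function(pid) {
    sub <- ev[idx[[pid]], , drop = FALSE]
    rownames(sub) <- NULL
    first_start <- function(cat) {
      s <- sub$start_age[sub$category == cat]
      if (length(s)) min(s) else NA_real_
    }
    lc <- first_start("LastContact")
    if (is.na(lc)) lc <- max(sub$end_age)
    tl <- list(patient_id = pid, events = sub,
               anchors = list(diagnosis_age = first_start("Diagnosis"),
                              death_age = first_start("Death"),
                              last_contact_age = lc))
    class(tl) <- "rw_timeline"
    tl
  })
  names(out) <- names(idx)
  class(out) <- "rw_timelines"
  out
}

#' @export
print.rw_timeline <- function(x, ...) {
  cat("Patient timeline:", x$patient_id, "-", nrow(x$events), "event(s)\n")
  a <- x$anchors
  cat(sprintf("  anchors: diagnosis %s, death %s, last contact %s (days)\n",
              format(a$diagnosis_age), format(a$death_age),
              format(a$last_contact_age)))
  invisible(x)
}

#' @export
print.rw_timelines <- function(x, ...) {
  cat("Cohort of", length(x), "patient timeline(s)\n")
  invisible(x)
}

#' Filter a cohort at the patient level
#'
#' A patient is retained if and only if at least one of their events
#' satisfies all predicates; all events of retained patients are returned.
#' This mirrors interactive cohort filtering: selecting "patients who ever
#' received cisplatin" keeps those patients' full histories.
#'
#' @param events An `rw_events` data frame.
#' @param predicates List of predicates, each a list/vector of
#'   `(field, relation, value)`. `field` is an event field
#'   (`patient_id`, `event_name`, `category`, `start_age`, `end_age`,
#'   `source_table`) or a detail key; `relation` is one of `equals`,
#'   `not_equals`, `contains`, `lt`, `le`, `gt`, `ge`.
#' @return The filtered `rw_events` data frame.
#' @export
filter_cohort <- function(events, predicates = list()) {
  if (!length(predicates)) return(events)
  if (nrow(events) == 0L) return(events)
  core_fields <- c("patient_id", "event_name", "category", "start_age",
                   "end_age", "source_table", "event_id")
  detail_keys <- unique(unlist(lapply(events$details, function(d) {
    if (!nzchar(d)) return(character(0))
    sub("=.*$", "", strsplit(d, ";", fixed = TRUE)[[1]])
  })))
  ok <- rep(TRUE, nrow(events))
  for (p in predicates) {
    p <- as.list(p)
    field <- as.character(p[[1]]); rel <- as.character(p[[2]]); value <- p[[3]]
    if (field %in% core_fields) {
      col <- events[[field]]
    } else if (field %in% detail_keys) {
      col <- vapply(events$details, function(d) {
        if (!nzchar(d)) return(NA_character_)
        kv <- strsplit(d, ";", fixed = TRUE)[[1]]
        keys <- sub("=.*$", "", kv)
        hit <- match(field, keys)
        if (is.na(hit)) NA_character_ else sub("^[^=]*=", "", kv[hit])
      }, character(1), USE.NAMES = FALSE)
    } else {
      stop("unknown filter field '", field, "'; available fields: ",
           paste(c(core_fields, detail_keys), collapse = ", "), call. = FALSE)
    }
    hit <- switch(rel,
      equals = col == value,
      not_equals = col != value,
      contains = grepl(as.character(value), col, ignore.case = TRUE, fixed = FALSE),
      lt = as.numeric(col) < as.numeric(value),
      le = as.numeric(col) <= as.numeric(value),
      gt = as.numeric(col) > as.numeric(value),
      ge = as.numeric(col) >= as.numeric(value),
      stop("unknown relation '", rel, "'", call. = FALSE))
    hit[is.na(hit)] <- FALSE
    ok <- ok & hit
  }
  keep_pat <- unique(events$patient_id[ok])
  out <- events[events$patient_id %in% keep_pat, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- attr(events, "rejections")
  class(out) <- c("rw_events", "data.frame")
  out
}

#' Tabular cohort summary
#'
#' Summarizes patient-level annotations over a cohort: frequency tables for
#' categorical variables (missing values counted as their own level) and
#' five-number summaries (min, Q1, median, Q3, max) for numeric variables,
#' optionally stratified.
#'
#' @param timelines An `rw_timelines` object (defines the patient set).
#' @param annotations Data frame of patient-level variables with a
#'   `patient_id` column.
#' @param strata Optional name of a categorical annotation variable to
#'   stratify by.
#' @return An object of class `rw_cohort_summary`: list with `n_patients`,
#'   `strata` and per-stratum `tables` (one element per variable).
#' @export
summarize_cohort <- function(timelines, annotations, strata = NULL) {
  pids <- if (length(timelines)) names(timelines) else character(0)
  ann <- annotations[match(pids, annotations$patient_id), , drop = FALSE]
  ann$patient_id <- pids
  if (!is.null(strata)) {
    if (!strata %in% names(annotations)) {
      stop("stratum variable '", strata, "' not found in annotations",
           call. = FALSE)
    }
    svals <- as.character(ann[[strata]])
    svals[is.na(svals)] <- "(missing)"
  } else {
    svals <- rep("(all)", length(pids))
  }
  vars <- setdiff(names(ann), c("patient_id", strata))
  groups <- split(seq_along(pids), svals)
  res <- lapply(groups, function(ix) {
    sub <- ann[ix, , drop = FALSE]
    tabs <- lapply(vars, function(v) {
      x <- sub[[v]]
      if (is.numeric(x)) {
        q <- stats::quantile(x, c(0, .25, .5, .75, 1), na.rm = TRUE, names = FALSE)
        data.frame(stat = c("min", "q1", "median", "q3", "max"),
                   value = q, stringsAsFactors = FALSE)
      } else {
        x <- as.character(x); x[is.na(x)] <- "(missing)"
        tab <- table(x)
        data.frame(level = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
      }
    })
    names(tabs) <- vars
    list(n_patients = length(ix), tables = tabs)
  })
  out <- list(n_patients = length(pids), strata = names(groups),
              by_stratum = res)
  class(out) <- "rw_cohort_summary"
  out
}

#' @export
print.rw_cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$n_patients, "patient(s)\n")
  for (s in x$strata) {
    cat("\nStratum:", s, "(n =", x$by_stratum[[s]]$n_patients, ")\n")
    for (v in names(x$by_stratum[[s]]$tables)) {
      cat(" ", v, ":\n")
      print(x$by_stratum[[s]]$tables[[v]], row.names = FALSE)
    }
  }
  invisible(x)
}
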