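#' Clustering configuration for lines of therapy
#'
#' Temporally proximal treatment events are aggregated into lines of therapy
#' by comparing event *start* times against a user-defined window. Two
#' window semantics are offered:
#' \describe{
#'   \item{anchor}{a line is seeded by the earliest unassigned treatment
#'     start \eqn{s_0} and absorbs every treatment starting at or before
#'     \eqn{s_0 + window}; the next unassigned start seeds the next line.
#'     This matches the common line-of-therapy convention of a fixed
#'     induction window and is the default.}
#'   \item{gap}{a treatment joins the current line if it starts within
#'     `window` days of the line's latest member start, so chains of closely
#'     spaced starts stay in one line regardless of total span.}
#' }
#' Start times alone decide membership: an ongoing long infusion interval
#' does not extend the recruitment window, because the treatment start is
#' the clinical decision point. The window boundary is inclusive.
#'
#' @param window_days Window width in days (> 0), or a string such as
#'   `"90d"` or `"3mo"` (1 month = 30.4375 days). Default 3 months.
#' @param mode `"anchor"` or `"gap"`.
#' @param categories Event categories to cluster (default `Treatment`).
#' @return A list of class `rw_cluster_config`.
#' @export
cluster_config <- function(window_days = "3mo", mode = c("anchor", "gap"),
                           categories = "Treatment") {
  window <- parse_window(window_days)
  if (!is.finite(window) || window <= 0) {
    stop("window_days must be a positive number of days", call. = FALSE)
  }
  mode <- match.arg(mode)
  bad <- setdiff(categories, event_categories())
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(window_days = window, mode = mode, categories = categories),
            class = "rw_cluster_config")
}

# Core windowed clustering over sorted start times. Returns an integer
# cluster index per element of `starts` (which must be ascending).
window_cluster <- function(starts, window, mode) {
  n <- length(starts)
  if (n == 0L) return(integer(0))
  idx <- integer(n)
  cl <- 1L
  ref <- starts[1L] # anchor: seed start; gap: latest member start
  idx[1L] <- 1L
  if (n > 1L) for (i in 2L:n) {
    if (starts[i] <= ref + window) {
      idx[i] <- cl
      if (mode == "gap") ref <- starts[i]
    } else {
      cl <- cl + 1L
      idx[i] <- cl
      ref <- starts[i]
    }
  }
  idx
}

#' Canonical regimen label
#'
#' The label of a line of therapy is the set of distinct agent names it
#' contains, lower-cased, sorted lexicographically and joined by `"+"`.
#' This canonicalization gives regimens a stable identity across patients
#' (needed, e.g., for Sankey node identity): `"Gemcitabine"` +
#' `"Cisplatin"` and `"cisplatin"` + `"gemcitabine"` both label as
#' `"cisplatin+gemcitabine"`.
#'
#' @param names Character vector of agent/event names (non-empty).
#' @return A single character label.
#' @export
regimen_label <- function(names) {
  if (!length(names)) stop("cannot label an empty set of events", call. = FALSE)
  paste(sort(unique(tolower(trimws(names)))), collapse = "+")
}

#' Cluster a patient's treatments into lines of therapy
#'
#' Partitions the Treatment-category events of one patient timeline into
#' lines of therapy (treatment summary clusters) under the window rule in
#' `config`. Every treatment event belongs to exactly one line; lines are
#' ordered by start and indexed from 1.
#'
#' @param timeline An `rw_timeline`.
#' @param config An `rw_cluster_config` (see [cluster_config()]).
#' @return A data frame of class `rw_lines` with one row per line:
#'   `patient_id`, `line_index`, `regimen_label`, `line_start`, `line_end`,
#'   `n_events`, `member_event_ids` (";"-joined), plus a list column
#'   `members` holding each line's member event rows.
#' @examples
#' ev <- data.frame(patient_id = "P1",
#'                  event_name = c("Cisplatin", "Pemetrexed", "Erlotinib"),
#'                  category = "Treatment",
#'                  start_age = c(0, 10, 200), end_age = c(60, 70, 260))
#' tl <- build_timelines(rwevents:::as_rw_events(ev))[[1]]
#' cluster_treatment_lines(tl, cluster_config(90))
#' @export
cluster_treatment_lines <- function(timeline, config = cluster_config()) {
  stopifnot(inherits(config, "rw_cluster_config"))
  cluster_category(timeline, "Treatment", config)
}

#' Aggregate a patient's events into per-category clusters
#'
#' Applies the same windowed clustering as [cluster_treatment_lines()]
#' independently to each category listed in `config$categories`, producing
#' the aggregated event summaries used for patient-level visual summaries.
#' Clusters never mix categories.
#'
#' @inheritParams cluster_treatment_lines
#' @return An `rw_lines` data frame with an additional `category` column.
#' @export
aggregate_events <- function(timeline, config = cluster_config()) {
  stopifnot(inherits(config, "rw_cluster_config"))
  parts <- lapply(config$categories, function(cat) {
    cl <- cluster_category(timeline, cat, config)
    if (nrow(cl)) cl$category <- cat
    cl
  })
  parts <- parts[vapply(parts, nrow, integer(1)) > 0L]
  if (!length(parts)) {
    out <- empty_lines()
    out$category <- character(0)
    return(out)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("rw_lines", "data.frame")
  out
}

cluster_category <- function(timeline, category, config) {
  stopifnot(inherits(timeline, "rw_timeline"))
  ev <- timeline$events
  ev <- ev[ev$category == category, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty_lines())
  # timeline events are already in canonical sorted order
  idx <- window_cluster(ev$start_age, config$window_days, config$mode)
  lines <- lapply(unique(idx), function(k) {
    sub <- ev[idx == k, , drop = FALSE]
    rownames(sub) <- NULL
    data.frame(patient_id = timeline$patient_id,
               line_index = k,
               regimen_label = regimen_label(sub$event_name),
               line_start = min(sub$start_age),
               line_end = max(sub$end_age),
               n_events = nrow(sub),
               member_event_ids = paste(sub$event_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, lines)
  out$members <- lapply(unique(idx), function(k) {
    sub <- ev[idx == k, , drop = FALSE]; rownames(sub) <- NULL; sub
  })
  rownames(out) <- NULL
  class(out) <- c("rw_lines", "data.frame")
  out
}

empty_lines <- function() {
  out <- data.frame(patient_id = character(0), line_index = integer(0),
                    regimen_label = character(0), line_start = numeric(0),
                    line_end = numeric(0), n_events = integer(0),
                    member_event_ids = character(0), stringsAsFactors = FALSE)
  out$members <- list()
  class(out) <- c("rw_lines", "data.frame")
  out
}

#' Cluster treatment lines across a cohort
#'
#' @param timelines An `rw_timelines` object.
#' @param config An `rw_cluster_config`.
#' @return An `rw_lines` data frame stacking every patient's lines.
#' @export
cluster_cohort <- function(timelines, config = cluster_config()) {
  parts <- lapply(timelines, cluster_treatment_lines, config = config)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0L]
  if (!length(parts)) return(empty_lines())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("rw_lines", "data.frame")
  out
}

#' @export
print.rw_lines <- function(x, ...) {
  cat("Treatment lines:", nrow(x), "line(s) across",
      length(unique(x$patient_id)), "patient(s)\n")
  show <- as.data.frame(x)[, setdiff(names(x), "members"), drop = FALSE]
  print(utils::head(show, 10), row.names = FALSE)
  invisible(x)
}
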