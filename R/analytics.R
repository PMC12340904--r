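#' Treatment-sequence Sankey graph
#'
#' Summarizes how patients move between regimens across line indices:
#' nodes are (line index, regimen) pairs whose size is the number of
#' patients on that regimen at that line; links count patients
#' transitioning from a line-\eqn{k} node to a line-\eqn{k+1} node; the
#' terminal count of a node is the number of its patients with no
#' subsequent line. Every node therefore satisfies
#' `patient_count == sum(outgoing links) + terminal_count`. Low-frequency
#' regimens at a line can be collapsed into an `"other"` node to keep the
#' graph readable for long-tail regimens.
#'
#' @param lines Cohort `rw_lines` (from [cluster_cohort()]).
#' @param max_lines Number of line indices to include (>= 1).
#' @param min_node_size Regimens with fewer patients than this at a line are
#'   collapsed into `"other"` (default 1 = no collapse).
#' @return An object of class `rw_sankey`: list with `nodes` (data frame
#'   `line_index`, `regimen_label`, `patient_count`, `terminal_count`) and
#'   `links` (data frame `source_line`, `source_label`, `target_label`,
#'   `patient_count`).
#' @export
build_sankey <- function(lines, max_lines = 3L, min_node_size = 1L) {
  stopifnot(max_lines >= 1L)
  if (nrow(lines) == 0L) {
    out <- list(nodes = data.frame(line_index = integer(0),
                                   regimen_label = character(0),
                                   patient_count = integer(0),
                                   terminal_count = integer(0),
                                   stringsAsFactors = FALSE),
                links = data.frame(source_line = integer(0),
                                   source_label = character(0),
                                   target_label = character(0),
                                   patient_count = integer(0),
                                   stringsAsFactors = FALSE))
    class(out) <- "rw_sankey"
    return(out)
  }
  sub <- as.data.frame(lines)[lines$line_index <= max_lines,
                              c("patient_id", "line_index", "regimen_label")]
  # collapse sparse regimens per line index
  for (k in unique(sub$line_index)) {
    at <- sub$line_index == k
    cnt <- table(sub$regimen_label[at])
    sparse <- names(cnt)[cnt < min_node_size]
    sub$regimen_label[at & sub$regimen_label %in% sparse] <- "other"
  }
  agg <- stats::aggregate(list(patient_count = sub$patient_id),
                          by = list(line_index = sub$line_index,
                                    regimen_label = sub$regimen_label),
                          FUN = function(x) length(unique(x)))
  nodes <- agg[order(agg$line_index, agg$regimen_label), , drop = FALSE]
  rownames(nodes) <- NULL

  nxt <- sub
  nxt$line_index <- nxt$line_index - 1L
  merged <- merge(sub, nxt, by = c("patient_id", "line_index"),
                  suffixes = c("_src", "_tgt"))
  if (nrow(merged)) {
    lk <- stats::aggregate(list(patient_count = merged$patient_id),
                           by = list(source_line = merged$line_index,
                                     source_label = merged$regimen_label_src,
                                     target_label = merged$regimen_label_tgt),
                           FUN = function(x) length(unique(x)))
    lk <- lk[order(lk$source_line, lk$source_label, lk$target_label), ,
             drop = FALSE]
    rownames(lk) <- NULL
  } else {
    lk <- data.frame(source_line = integer(0), source_label = character(0),
                     target_label = character(0), patient_count = integer(0),
                     stringsAsFactors = FALSE)
  }
  outgoing <- if (nrow(lk)) {
    stats::aggregate(list(out = lk$patient_count),
                     by = list(line_index = lk$source_line,
                               regimen_label = lk$source_label), FUN = sum)
  } else NULL
  nodes$terminal_count <- nodes$patient_count
  if (!is.null(outgoing)) {
    mi <- match(paste(nodes$line_index, nodes$regimen_label, sep = "\r"),
                paste(outgoing$line_index, outgoing$regimen_label, sep = "\r"))
    hit <- !is.na(mi)
    nodes$terminal_count[hit] <- nodes$patient_count[hit] - outgoing$out[mi[hit]]
  }
  out <- list(nodes = nodes, links = lk)
  class(out) <- "rw_sankey"
  out
}

#' @export
print.rw_sankey <- function(x, ...) {
  cat("Sankey graph:", nrow(x$nodes), "node(s),", nrow(x$links), "link(s)\n")
  if (nrow(x$nodes)) { cat("Nodes:\n"); print(x$nodes, row.names = FALSE) }
  if (nrow(x$links)) { cat("Links:\n"); print(x$links, row.names = FALSE) }
  invisible(x)
}

#' Treatment-by-line heatmap matrix
#'
#' Counts, for each individual agent and line index, the number of distinct
#' patients whose line at that index contains the agent; a combination line
#' `"a+b"` increments both agents. Agents are ordered by total patient
#' count, descending (ties alphabetical).
#'
#' @param lines Cohort `rw_lines`.
#' @return An object of class `rw_line_heatmap`: integer matrix
#'   (agents x line indices).
#' @export
line_heatmap <- function(lines) {
  if (nrow(lines) == 0L) {
    m <- matrix(integer(0), 0, 0)
    class(m) <- c("rw_line_heatmap", class(m))
    return(m)
  }
  expand <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
    agents <- strsplit(lines$regimen_label[i], "+", fixed = TRUE)[[1]]
    data.frame(patient_id = lines$patient_id[i],
               line_index = lines$line_index[i], agent = agents,
               stringsAsFactors = FALSE)
  }))
  expand <- unique(expand)
  ks <- sort(unique(expand$line_index))
  agents <- sort(unique(expand$agent))
  m <- matrix(0L, length(agents), length(ks),
              dimnames = list(agents, paste0("line_", ks)))
  tab <- table(expand$agent, factor(expand$line_index, levels = ks))
  m[rownames(tab), ] <- as.integer(tab)
  ord <- order(-rowSums(m), rownames(m))
  m <- m[ord, , drop = FALSE]
  class(m) <- c("rw_line_heatmap", class(m))
  m
}

#' Per-regimen treatment duration summaries
#'
#' Five-number summaries (min, Q1, median, Q3, max) of line durations
#' (`line_end - line_start`, days) per group, the data behind the duration
#' box plot.
#'
#' @param lines Cohort `rw_lines`.
#' @param by Grouping column, default `"regimen_label"`.
#' @return Data frame with one row per non-empty group: `group`, `n`,
#'   `min`, `q1`, `median`, `q3`, `max`.
#' @export
duration_stats <- function(lines, by = "regimen_label") {
  if (nrow(lines) == 0L) {
    return(data.frame(group = character(0), n = integer(0), min = numeric(0),
                      q1 = numeric(0), median = numeric(0), q3 = numeric(0),
                      max = numeric(0), stringsAsFactors = FALSE))
  }
  dur <- lines$line_end - lines$line_start
  grp <- as.character(lines[[by]])
  parts <- lapply(sort(unique(grp)), function(g) {
    x <- dur[grp == g]
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(group = g, n = length(x), min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Flag extended-duration treatment lines
#'
#' Identifies unusually long regimens: within each regimen group with at
#' least 4 lines, a line is flagged when its duration exceeds the Tukey
#' upper fence Q3 + 1.5 IQR (upper tail only — the clinically interesting
#' direction is the extended regimen). With all durations equal the IQR is
#' zero and nothing is flagged (the inequality is strict).
#'
#' @param lines Cohort `rw_lines`.
#' @param min_group Minimum group size for flagging (default 4).
#' @return Data frame of flagged lines: `patient_id`, `line_index`,
#'   `regimen_label`, `duration_days`, `group_q3`, `group_iqr`.
#' @export
flag_duration_outliers <- function(lines, min_group = 4L) {
  empty <- data.frame(patient_id = character(0), line_index = integer(0),
                      regimen_label = character(0), duration_days = numeric(0),
                      group_q3 = numeric(0), group_iqr = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(lines) == 0L) return(empty)
  dur <- lines$line_end - lines$line_start
  flags <- list()
  for (g in unique(lines$regimen_label)) {
    ix <- which(lines$regimen_label == g)
    if (length(ix) < min_group) next
    q <- stats::quantile(dur[ix], c(.25, .75), names = FALSE)
    iqr <- q[2] - q[1]
    fence <- q[2] + 1.5 * iqr
    hit <- ix[dur[ix] > fence]
    if (length(hit)) {
      flags[[length(flags) + 1L]] <- data.frame(
        patient_id = lines$patient_id[hit], line_index = lines$line_index[hit],
        regimen_label = g, duration_days = dur[hit], group_q3 = q[2],
        group_iqr = iqr, stringsAsFactors = FALSE)
    }
  }
  if (!length(flags)) return(empty)
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Swimmer-plot lanes
#'
#' Builds one lane per patient from their timeline: interval segments for
#' duration events and point markers for instantaneous ones, with a
#' deterministic lane order. Times can be re-zeroed to each patient's first
#' treatment start so that lanes align on the time origin; by default lanes
#' show absolute age, matching the age-indexed event stream.
#'
#' @param timelines An `rw_timelines` object.
#' @param sort_by `"first_treatment"` (ascending first treatment start),
#'   `"follow_up_length"` (descending last-contact minus first event), or
#'   `"stratum"` (by stratum label, then follow-up).
#' @param annotations Optional patient-level data frame (for `stratum_var`).
#' @param stratum_var Optional annotation variable labeling each lane.
#' @param rezero If `TRUE`, shift each lane so its first treatment start is
#'   time 0 (lanes without treatments shift to their first event).
#' @return An object of class `rw_swimmer`: data frame with `patient_id`,
#'   `lane` (1 = top), `start`, `end`, `category`, `label`, `is_point`,
#'   `stratum`.
#' @export
build_swimmer <- function(timelines,
                          sort_by = c("first_treatment", "follow_up_length",
                                      "stratum"),
                          annotations = NULL, stratum_var = NULL,
                          rezero = FALSE) {
  sort_by <- match.arg(sort_by)
  if (!length(timelines)) {
    out <- data.frame(patient_id = character(0), lane = integer(0),
                      start = numeric(0), end = numeric(0),
                      category = character(0), label = character(0),
                      is_point = logical(0), stratum = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("rw_swimmer", "data.frame")
    return(out)
  }
  meta <- do.call(rbind, lapply(timelines, function(tl) {
    tr <- tl$events$start_age[tl$events$category == "Treatment"]
    data.frame(patient_id = tl$patient_id,
               first_treatment = if (length(tr)) min(tr) else Inf,
               first_event = min(tl$events$start_age),
               follow_up = tl$anchors$last_contact_age - min(tl$events$start_age),
               stringsAsFactors = FALSE)
  }))
  meta$stratum <- "(all)"
  if (!is.null(stratum_var)) {
    if (is.null(annotations) || !stratum_var %in% names(annotations)) {
      stop("stratum variable '", stratum_var, "' not found in annotations",
           call. = FALSE)
    }
    s <- as.character(annotations[[stratum_var]][
      match(meta$patient_id, annotations$patient_id)])
    s[is.na(s)] <- "(missing)"
    meta$stratum <- s
  }
  ord <- switch(sort_by,
    first_treatment = order(meta$first_treatment, meta$patient_id),
    follow_up_length = order(-meta$follow_up, meta$patient_id),
    stratum = order(meta$stratum, -meta$follow_up, meta$patient_id))
  meta <- meta[ord, , drop = FALSE]
  lanes <- lapply(seq_len(nrow(meta)), function(i) {
    tl <- timelines[[meta$patient_id[i]]]
    ev <- tl$events
    off <- if (rezero) {
      if (is.finite(meta$first_treatment[i])) meta$first_treatment[i]
      else meta$first_event[i]
    } else 0
    data.frame(patient_id = tl$patient_id, lane = i,
               start = ev$start_age - off, end = ev$end_age - off,
               category = ev$category, label = ev$event_name,
               is_point = ev$start_age == ev$end_age,
               stratum = meta$stratum[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, lanes)
  rownames(out) <- NULL
  class(out) <- c("rw_swimmer", "data.frame")
  out
}

#' @export
print.rw_swimmer <- function(x, ...) {
  cat("Swimmer lanes:", length(unique(x$patient_id)), "patient(s),",
      nrow(x), "segment(s)\n")
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}

#' @export
plot.rw_swimmer <- function(x, xlab = "Days", main = "Swimmer plot", ...) {
  if (!nrow(x)) return(invisible(x))
  cats <- sort(unique(x$category))
  col <- stats::setNames(grDevices::hcl.colors(max(3L, length(cats)), "Dark 3")[
    seq_along(cats)], cats)
  nlane <- max(x$lane)
  graphics::plot(NA, xlim = range(c(x$start, x$end)),
                 ylim = c(nlane + 0.5, 0.5), xlab = xlab, ylab = "Patient",
                 yaxt = "n", main = main, ...)
  graphics::axis(2, at = seq_len(nlane),
                 labels = unique(x$patient_id[order(x$lane)]), las = 2,
                 cex.axis = 0.6)
  seg <- x[!x$is_point, , drop = FALSE]
  if (nrow(seg)) graphics::segments(seg$start, seg$lane, seg$end, seg$lane,
                                    col = col[seg$category], lwd = 3)
  pts <- x[x$is_point, , drop = FALSE]
  if (nrow(pts)) graphics::points(pts$start, pts$lane, pch = 16,
                                  col = col[pts$category], cex = 0.7)
  graphics::legend("topright", legend = cats, col = col, lwd = 3, bty = "n",
                   cex = 0.7)
  invisible(x)
}

#' Position of one event relative to another
#'
#' Classifies, per patient, where a target event (e.g. tumor sequencing)
#' falls relative to an anchor event's interval (e.g. a drug regimen):
#' `"before"` when the target ends before the anchor starts, `"after"` when
#' it starts after the anchor ends, `"concurrent"` when the closed intervals
#' overlap, or `"anchor-missing"`/`"target-missing"`. The earliest matching
#' event of each kind is used.
#'
#' @param timelines An `rw_timelines` object.
#' @param anchor,target Matchers: lists with `patterns` (case-insensitive
#'   name substrings; `NULL` matches any name) and/or `category`.
#' @return Data frame with `patient_id`, `position`, `anchor_start`,
#'   `anchor_end`, `target_start`, `target_end`.
#' @export
annotate_relative_position <- function(timelines, anchor, target) {
  first_match <- function(ev, m) {
    sel <- rep(TRUE, nrow(ev))
    if (!is.null(m$category)) sel <- sel & ev$category %in% m$category
    if (!is.null(m$patterns)) {
      nm <- tolower(ev$event_name)
      sel <- sel & Reduce(`|`, lapply(tolower(m$patterns),
                                      function(p) grepl(p, nm, fixed = TRUE)))
    }
    if (!any(sel)) return(NULL)
    ev[which(sel)[which.min(ev$start_age[sel])], , drop = FALSE]
  }
  rows <- lapply(timelines, function(tl) {
    a <- first_match(tl$events, anchor)
    t <- first_match(tl$events, target)
    pos <- if (is.null(a)) "anchor-missing"
      else if (is.null(t)) "target-missing"
      else if (t$end_age < a$start_age) "before"
      else if (t$start_age > a$end_age) "after"
      else "concurrent"
    data.frame(patient_id = tl$patient_id, position = pos,
               anchor_start = if (is.null(a)) NA_real_ else a$start_age,
               anchor_end = if (is.null(a)) NA_real_ else a$end_age,
               target_start = if (is.null(t)) NA_real_ else t$start_age,
               target_end = if (is.null(t)) NA_real_ else t$end_age,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
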