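#' Parse a parameter file describing the raw clinical tables
#'
#' The parameter file is the single piece of configuration that turns a
#' directory of heterogeneous clinical tables into a harmonized event stream.
#' One row per table declares where the table lives, which column holds the
#' event name, the event category for the whole table, and which columns hold
#' the start and (optionally) end times.
#'
#' The file is tab- or comma-delimited with a header row. Recognised columns:
#' \describe{
#'   \item{table_id}{unique identifier for the table (required)}
#'   \item{file}{path to the table, relative to the parameter file (required)}
#'   \item{event_name_col}{column holding the event name (required)}
#'   \item{category}{one of [event_categories()] (required)}
#'   \item{start_col}{column holding the event start time (required)}
#'   \item{end_col}{column holding the end time; blank for point events}
#'   \item{detail_cols}{semicolon-joined extra columns kept as details}
#'   \item{time_unit}{days (default), months, or years}
#' }
#'
#' @param path Path to the parameter file.
#' @return An object of class `rw_param_spec`: a data frame with one row per
#'   declared table, in file order, plus a `dir` attribute (the directory of
#'   the parameter file, used to resolve relative table paths).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("table_id\tfile\tevent_name_col\tcategory\tstart_col\tend_col",
#'              "meds\tmeds.tsv\tdrug\tTreatment\tstart\tstop",
#'              "imaging\timg.tsv\tfinding\tImagingAssessment\tscan_date\t"), tf)
#' parse_parameter_file(tf)
#' @export
parse_parameter_file <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- read_delimited(path)
  required <- c("table_id", "file", "event_name_col", "category", "start_col")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("parameter file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (opt in c("end_col", "detail_cols", "time_unit")) {
    if (!opt %in% names(raw)) raw[[opt]] <- ""
  }
  raw$table_id <- trimws(as.character(raw$table_id))
  if (anyDuplicated(raw$table_id)) {
    stop("duplicate table_id value(s): ",
         paste(unique(raw$table_id[duplicated(raw$table_id)]), collapse = ", "),
         call. = FALSE)
  }
  cat_norm <- normalize_category(raw$category)
  if (anyNA(cat_norm)) {
    bad <- unique(raw$category[is.na(cat_norm)])
    stop("unknown event category value(s): ", paste(bad, collapse = ", "),
         "; allowed categories are: ", paste(event_categories(), collapse = ", "),
         call. = FALSE)
  }
  unit <- trimws(as.character(raw$time_unit))
  unit[unit == ""] <- "days"
  time_unit_factor(unit) # validates

  spec <- data.frame(
    table_id = raw$table_id,
    file = trimws(as.character(raw$file)),
    event_name_col = trimws(as.character(raw$event_name_col)),
    category = cat_norm,
    start_col = trimws(as.character(raw$start_col)),
    end_col = trimws(as.character(raw$end_col)),
    detail_cols = trimws(as.character(raw$detail_cols)),
    time_unit = unit,
    stringsAsFactors = FALSE
  )
  attr(spec, "dir") <- dirname(normalizePath(path))
  class(spec) <- c("rw_param_spec", "data.frame")
  spec
}

# Split a semicolon-joined detail_cols declaration into a character vector.
split_detail_cols <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

# Read a tab- or comma-delimited text file with a header, sniffing the
# delimiter from the header line. All columns read as character so that time
# parsing and validation stay under our control.
read_delimited <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = TRUE,
                    na.strings = character(0), comment.char = "",
                    stringsAsFactors = FALSE)
}

#' @export
print.rw_param_spec <- function(x, ...) {
  cat("Parameter specification:", nrow(x), "table(s)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
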