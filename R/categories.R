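#' Event categories
#'
#' The closed set of event categories recognised by the event model.
#' `Treatment`, `Pathology`, `ClinicalResponse` and `ImagingAssessment` are
#' the categories a user assigns to uploaded tables; `Diagnosis`, `Death` and
#' `LastContact` are reserved anchor categories required by the endpoint
#' rules (survival start points and censoring); `Other` holds anything else.
#'
#' @return Character vector of the valid category names.
#' @export
event_categories <- function() {
  c("Treatment", "Pathology", "ClinicalResponse", "ImagingAssessment",
    "Diagnosis", "Death", "LastContact", "Other")
}

# Normalize user-supplied category strings: case-insensitive, whitespace/
# underscore tolerant ("Clinical Response" == "clinical_response").
# Returns NA_character_ for unknown values.
normalize_category <- function(x) {
  canon <- event_categories()
  key <- tolower(gsub("[ _-]", "", canon))
  idx <- match(tolower(gsub("[ _-]", "", trimws(x))), key)
  canon[idx]
}

# Days per declared time unit. Month and year lengths follow the civil
# averages (Gregorian year = 365.25 d, month = 365.25/12 d).
time_unit_factor <- function(unit) {
  unit <- tolower(trimws(unit))
  unit[unit == "" | is.na(unit)] <- "days"
  factors <- c(days = 1, day = 1, d = 1,
               months = 30.4375, month = 30.4375, mo = 30.4375,
               years = 365.25, year = 365.25, yr = 365.25, y = 365.25)
  out <- factors[unit]
  if (anyNA(out)) {
    stop("unknown time unit(s): ", paste(unique(unit[is.na(out)]), collapse = ", "),
         "; expected one of days, months, years", call. = FALSE)
  }
  unname(out)
}

# Parse a window specification such as 90, "90d", "3mo", "1y" into days.
parse_window <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^\\s*([0-9.]+)\\s*([a-zA-Z]*)\\s*$", x))[[1]]
  if (length(m) != 3) stop("cannot parse window: ", x, call. = FALSE)
  val <- as.numeric(m[2])
  unit <- if (m[3] == "") "days" else m[3]
  val * time_unit_factor(unit)
}
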