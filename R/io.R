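# Cohort CSV schema and readers/writers. CSVs are RFC-4180, UTF-8, "."
# decimal; missing values are empty cells. Velocities are stored in cm/s
# (the staging units); a reader flag accepts files whose LPA velocity was
# recorded in m/s, since published tables mix both conventions.

cohort_required_columns <- c(
  "infant_id", "group", "ga_weeks", "birth_weight_g", "apgar5", "cord_ph",
  "advanced_resuscitation", "td_mm", "vmax_vmin", "lpa_cms", "dao_direction",
  "la_ao", "lvo_mlkgmin", "svc_mlkgmin", "ea_ratio", "postnatal_age_h")

# mapping between exam-level measurement names (used by staging schemes and
# models) and the compact cohort CSV column names
cohort_aliases <- c(
  transductal_diameter = "td_mm",
  ductal_vmax_vmin_ratio = "vmax_vmin",
  lpa_diastolic_velocity = "lpa_cms",
  dao_flow_direction = "dao_direction",
  gestational_age_weeks = "ga_weeks")

resolve_cohort_column <- function(cohort, name) {
  if (name %in% names(cohort)) return(cohort[[name]])
  alias <- cohort_aliases[name]
  if (!is.na(alias) && alias %in% names(cohort)) return(cohort[[alias]])
  NULL
}

#' Parse gestational age given as decimal weeks or weeks+days
#'
#' Accepts `27.43`, `"27.43"` or the obstetric `"27+3"` (27 weeks 3 days)
#' notation and returns decimal weeks.
#'
#' @param x numeric or character vector.
#' @return numeric vector of gestational ages in weeks.
#' @examples
#' parse_ga_weeks(c("27+3", "26.5"))
#' @export
parse_ga_weeks <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (grepl("^\\d+\\+\\d+$", s)) {
      parts <- as.numeric(strsplit(s, "+", fixed = TRUE)[[1]])
      if (parts[2] >= 7) stop_invalid("ga", sprintf("days part of `%s` must be < 7", s))
      parts[1] + parts[2] / 7
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v) && nzchar(s)) stop_invalid("ga", sprintf("cannot parse `%s`", s))
      v
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a cohort CSV
#'
#' Validates the header against the cohort schema, normalizes categorical
#' fields (case-insensitive `forward`/`absent`/`reverse` flow directions;
#' `CM`/`IBT`/`unknown` group labels), parses gestational age given either
#' as decimal weeks or `"w+d"` text, and optionally converts an LPA
#' velocity column recorded in m/s to cm/s.
#'
#' @param path CSV file path.
#' @param lpa_units units of the `lpa_cms` column in the file: `"cms"`
#'   (default) or `"ms"` (converted to cm/s on read).
#' @return cohort data frame; extra columns are preserved untouched.
#' @export
read_cohort <- function(path, lpa_units = c("cms", "ms")) {
  lpa_units <- match.arg(lpa_units)
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(infant_id = "character"))
  missing <- setdiff(cohort_required_columns, names(raw))
  if (length(missing)) {
    stop(sprintf("cohort schema error: missing column%s %s",
                 if (length(missing) > 1L) "s" else "",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(raw$infant_id)) {
    stop("cohort schema error: infant_id values must be unique", call. = FALSE)
  }
  orig_group <- raw$group
  raw$group <- toupper(trimws(raw$group))
  bad_group <- !raw$group %in% c("CM", "IBT", "UNKNOWN")
  if (any(bad_group)) {
    stop(sprintf("row %d: unknown group `%s`", which(bad_group)[1L] + 1L,
                 orig_group[bad_group][1L]), call. = FALSE)
  }
  raw$group[raw$group == "UNKNOWN"] <- "unknown"
  raw$dao_direction <- tolower(trimws(raw$dao_direction))
  bad_dir <- !raw$dao_direction %in% c("forward", "absent", "reverse", "")
  if (any(bad_dir)) {
    stop(sprintf("row %d: unknown dao_direction `%s`",
                 which(bad_dir)[1L] + 1L, raw$dao_direction[bad_dir][1L]),
         call. = FALSE)
  }
  raw$ga_weeks <- parse_ga_weeks(raw$ga_weeks)
  if (lpa_units == "ms") raw$lpa_cms <- raw$lpa_cms * 100
  raw
}

#' Write a cohort CSV
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
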