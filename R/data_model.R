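#' Cohort selection configuration
#'
#' Thresholds controlling the procedure filter, the note-linkage date window
#' and the facility screen. Defaults reproduce the study conditions: the
#' seven spirometry-related CPT codes, notes from 1 day before to 21 days
#' after the procedure date, the 36 highest-volume facilities, and an 80%
#' FEV1-note coverage threshold.
#'
#' @param cpt_codes character vector of 5-character CPT codes to keep.
#' @param window_days closed integer interval `c(lower, upper)` of note-date
#'   offsets (days) relative to the procedure date; both endpoints inclusive.
#' @param top_n_facilities number of facilities, ranked by PFT volume, that
#'   enter the facility screen.
#' @param min_fev1_note_proportion minimum fraction of a facility's PFTs with
#'   a linked FEV1-containing note for eligibility.
#' @param proportion_comparator `">="` (default) or `">"`; how the coverage
#'   threshold is applied.
#' @param exclude_structured drop procedures whose FEV1 already exists as
#'   structured data (they need no text extraction).
#' @return an object of class `cohort_config`.
#' @examples
#' cohort_config(window_days = c(-1, 21))
#' @export
cohort_config <- function(cpt_codes = c(
                            "94010", "94375", "94060", "94726",
                            "94727", "94729", "94150"
                          ),
                          window_days = c(-1L, 21L),
                          top_n_facilities = 36L,
                          min_fev1_note_proportion = 0.80,
                          proportion_comparator = c(">=", ">"),
                          exclude_structured = TRUE) {
  proportion_comparator <- match.arg(proportion_comparator)
  cpt_codes <- as.character(cpt_codes)
  if (length(cpt_codes) == 0L) stop_pft("cpt_codes must be non-empty")
  if (!all(grepl("^\\d{5}$", cpt_codes))) {
    stop_pft("cpt_codes must be 5-digit strings")
  }
  window_days <- as.integer(window_days)
  if (length(window_days) != 2L || anyNA(window_days) ||
    window_days[1] > window_days[2]) {
    stop_pft("window_days must be c(lower, upper) with lower <= upper")
  }
  if (top_n_facilities < 1L) stop_pft("top_n_facilities must be positive")
  if (min_fev1_note_proportion < 0 || min_fev1_note_proportion > 1) {
    stop_pft("min_fev1_note_proportion must lie in [0, 1]")
  }
  structure(
    list(
      cpt_codes = cpt_codes,
      window_days = window_days,
      top_n_facilities = as.integer(top_n_facilities),
      min_fev1_note_proportion = min_fev1_note_proportion,
      proportion_comparator = proportion_comparator,
      exclude_structured = isTRUE(exclude_structured)
    ),
    class = "cohort_config"
  )
}

note_columns <- function() {
  c("note_id", "patient_id", "facility_id", "note_date", "text")
}

procedure_columns <- function() {
  c(
    "study_id", "patient_id", "facility_id", "procedure_date",
    "cpt_code", "has_structured_fev1"
  )
}

classification_columns <- function() {
  c(
    "study_id", "obstruction", "severity", "ratio_value",
    "fev1_pct_pred", "obstruction_source", "severity_source"
  )
}

read_delimited_records <- function(path, format) {
  if (!file.exists(path)) stop_pft("file not found: ", path)
  if (format == "csv") {
    utils::read.csv(path,
      colClasses = "character", check.names = FALSE,
      na.strings = character()
    )
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      return(data.frame())
    }
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
    cols <- names(recs[[1]])
    out <- lapply(cols, function(cn) {
      vapply(recs, function(r) as.character(r[[cn]] %||% NA_character_), "")
    })
    names(out) <- cols
    as.data.frame(out, check.names = FALSE)
  }
}

require_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop_pft(
      "schema error in ", what, ": missing column(s) ",
      paste(missing, collapse = ", "),
      class = "pftminer_schema_error"
    )
  }
  invisible(df)
}

#' Read clinical notes
#'
#' Reads a note table (one record per note) from CSV or JSON-lines. Required
#' columns: `note_id`, `patient_id`, `facility_id`, `note_date` (ISO-8601
#' date), `text`. Note bodies are kept byte-faithful; any normalization
#' happens later, inside snippet extraction.
#'
#' @param path file path.
#' @param format `"csv"` (RFC-4180) or `"jsonl"` (one JSON object per line).
#' @return a data.frame of notes, in file order, with `note_date` as `Date`.
#' @export
read_notes <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- read_delimited_records(path, format)
  if (nrow(df) == 0L && length(names(df)) == 0L && format == "jsonl") {
    df <- data.frame(
      note_id = character(), patient_id = character(),
      facility_id = character(), note_date = character(),
      text = character(), stringsAsFactors = FALSE
    )
  }
  require_columns(df, note_columns(), "notes")
  dates <- parse_iso_date(df$note_date)
  if (anyNA(dates)) {
    bad <- df$note_id[is.na(dates)]
    stop_pft(
      "unparseable note_date for note_id: ", paste(bad, collapse = ", "),
      class = "pftminer_record_error"
    )
  }
  out <- data.frame(
    note_id = as.character(df$note_id),
    patient_id = as.character(df$patient_id),
    facility_id = as.character(df$facility_id),
    note_date = dates,
    text = as.character(df$text),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$note_id)) {
    stop_pft(
      "duplicate note_id: ",
      paste(unique(out$note_id[duplicated(out$note_id)]), collapse = ", ")
    )
  }
  out
}

#' Read procedure records
#'
#' Reads the PFT procedure table from CSV or JSON-lines. Required columns:
#' `study_id`, `patient_id`, `facility_id`, `procedure_date` (ISO-8601),
#' `cpt_code` (5-digit string), `has_structured_fev1` (logical; records with
#' structured FEV1 results need no text extraction and are excluded by the
#' default cohort filter).
#'
#' @inheritParams read_notes
#' @return a data.frame of procedure records in file order.
#' @export
read_procedures <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- read_delimited_records(path, format)
  require_columns(df, procedure_columns(), "procedures")
  dates <- parse_iso_date(df$procedure_date)
  if (anyNA(dates)) {
    bad <- df$study_id[is.na(dates)]
    stop_pft(
      "unparseable procedure_date for study_id: ",
      paste(bad, collapse = ", "),
      class = "pftminer_record_error"
    )
  }
  cpt <- as.character(df$cpt_code)
  if (!all(grepl("^\\d{5}$", cpt))) {
    bad <- df$study_id[!grepl("^\\d{5}$", cpt)]
    stop_pft(
      "cpt_code not a 5-digit code for study_id: ",
      paste(bad, collapse = ", "),
      class = "pftminer_record_error"
    )
  }
  out <- data.frame(
    study_id = as.character(df$study_id),
    patient_id = as.character(df$patient_id),
    facility_id = as.character(df$facility_id),
    procedure_date = dates,
    cpt_code = cpt,
    has_structured_fev1 = tolower(as.character(df$has_structured_fev1)) %in%
      c("true", "t", "1", "yes"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$study_id)) {
    stop_pft(
      "duplicate study_id: ",
      paste(unique(out$study_id[duplicated(out$study_id)]), collapse = ", ")
    )
  }
  out
}

#' Validate a classification table
#'
#' Checks the structural invariants of a spirometry classification table:
#' legal category levels, value/source co-presence (`obstruction == "missing"`
#' exactly when `obstruction_source == "none"`, and likewise for severity),
#' a quantitative obstruction call always backed by a ratio value, and value
#' ranges (ratio in \[0, 1.5\], percent predicted in (0, 300)).
#'
#' @param classifications data.frame with the classification columns.
#' @return the validated data.frame, invisibly; errors on violation.
#' @export
validate_classifications <- function(classifications) {
  df <- classifications
  require_columns(df, classification_columns(), "classifications")
  chk <- function(ok, msg) {
    if (!all(ok)) {
      stop_pft(
        msg, " (study_id: ",
        paste(utils::head(df$study_id[!ok], 5L), collapse = ", "), ")",
        class = "pftminer_invariant_error"
      )
    }
  }
  chk(df$obstruction %in% obstruction_levels(), "invalid obstruction level")
  chk(df$severity %in% severity_levels(), "invalid severity level")
  chk(
    df$obstruction_source %in% source_levels(),
    "invalid obstruction_source"
  )
  chk(df$severity_source %in% source_levels(), "invalid severity_source")
  chk(
    (df$obstruction == "missing") == (df$obstruction_source == "none"),
    "obstruction 'missing' must pair with source 'none'"
  )
  chk(
    (df$severity == "missing") == (df$severity_source == "none"),
    "severity 'missing' must pair with source 'none'"
  )
  chk(
    df$obstruction_source != "quantitative" | !is.na(df$ratio_value),
    "quantitative obstruction requires a ratio value"
  )
  chk(
    is.na(df$ratio_value) | (df$ratio_value >= 0 & df$ratio_value <= 1.5),
    "ratio_value outside [0, 1.5]"
  )
  chk(
    is.na(df$fev1_pct_pred) |
      (df$fev1_pct_pred > 0 & df$fev1_pct_pred < 300),
    "fev1_pct_pred outside (0, 300)"
  )
  invisible(df)
}

#' Write a classification table to CSV
#'
#' Columns are written in the fixed canonical order; absent values become
#' empty cells. Records are validated first and violations refuse the write.
#'
#' @param classifications data.frame of classification records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_classifications()] for the inverse.
#' @export
write_classifications <- function(classifications, path) {
  validate_classifications(classifications)
  out <- classifications[, classification_columns(), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Read a classification table from CSV
#'
#' Inverse of [write_classifications()]: empty cells become `NA`.
#'
#' @param path file path.
#' @return validated classification data.frame.
#' @export
read_classifications <- function(path) {
  if (!file.exists(path)) stop_pft("file not found: ", path)
  df <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    na.strings = character()
  )
  require_columns(df, classification_columns(), "classifications")
  out <- data.frame(
    study_id = df$study_id,
    obstruction = df$obstruction,
    severity = df$severity,
    ratio_value = suppressWarnings(
      as.numeric(ifelse(df$ratio_value == "", NA, df$ratio_value))
    ),
    fev1_pct_pred = suppressWarnings(
      as.numeric(ifelse(df$fev1_pct_pred == "", NA, df$fev1_pct_pred))
    ),
    obstruction_source = df$obstruction_source,
    severity_source = df$severity_source,
    stringsAsFactors = FALSE
  )
  validate_classifications(out)
  out
}
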