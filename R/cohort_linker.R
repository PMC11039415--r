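#' Filter PFT procedures by CPT code and structured-result availability
#'
#' Keeps procedure records whose CPT code is in the configured spirometry
#' code set and, when `config$exclude_structured` is `TRUE`, whose FEV1 is
#' not already available as structured data. Input order is preserved and
#' the operation is idempotent.
#'
#' @param procedures procedure data.frame (see [read_procedures()]).
#' @param config a [cohort_config()].
#' @return the surviving subset of `procedures`, original order.
#' @export
filter_procedures <- function(procedures, config = cohort_config()) {
  keep <- procedures$cpt_code %in% config$cpt_codes
  if (config$exclude_structured) {
    keep <- keep & !procedures$has_structured_fev1
  }
  procedures[keep, , drop = FALSE]
}

#' Link candidate notes to PFT procedures by date window
#'
#' A note is linked to a procedure when the patient matches and the note
#' date falls inside the configured window relative to the procedure date
#' (default \[-1, +21\] days, both endpoints inclusive). The result is
#' ordered by `study_id`, then `note_date`, then `note_id`, so linkage is
#' invariant to input row order.
#'
#' @param procedures procedure data.frame.
#' @param notes note data.frame.
#' @param config a [cohort_config()].
#' @return data.frame with columns `study_id`, `note_id`, `facility_id`,
#'   `note_date`, `offset_days`.
#' @export
link_notes <- function(procedures, notes, config = cohort_config()) {
  empty <- data.frame(
    study_id = character(), note_id = character(),
    facility_id = character(), note_date = as.Date(character()),
    offset_days = integer(), stringsAsFactors = FALSE
  )
  if (nrow(procedures) == 0L || nrow(notes) == 0L) {
    return(empty)
  }
  pr <- procedures[, c("study_id", "patient_id", "facility_id",
    "procedure_date")]
  nt <- notes[, c("note_id", "patient_id", "note_date")]
  joined <- merge(pr, nt, by = "patient_id")
  if (nrow(joined) == 0L) {
    return(empty)
  }
  offset <- as.integer(joined$note_date - joined$procedure_date)
  keep <- offset >= config$window_days[1] & offset <= config$window_days[2]
  joined <- joined[keep, , drop = FALSE]
  offset <- offset[keep]
  ord <- order(joined$study_id, joined$note_date, joined$note_id)
  data.frame(
    study_id = joined$study_id[ord],
    note_id = joined$note_id[ord],
    facility_id = joined$facility_id[ord],
    note_date = joined$note_date[ord],
    offset_days = offset[ord],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Screen facilities by PFT volume and FEV1-note coverage
#'
#' Restricts attention to the `top_n_facilities` facilities with the most
#' PFT procedures (ties broken by facility id, lexicographically), then for
#' each computes the proportion of its PFT studies that have at least one
#' linked note containing an FEV1 token. Facilities meeting the coverage
#' threshold are flagged eligible; only eligible facilities are worth
#' template development.
#'
#' The FEV1 token is matched case-insensitively and tolerates the common
#' renderings "FEV1", "FEV-1" and "FEV 1".
#'
#' @param procedures procedure data.frame (normally already filtered).
#' @param notes note data.frame.
#' @param config a [cohort_config()].
#' @param fev1_pattern PCRE pattern defining an FEV1-containing note.
#' @return data.frame with one row per screened facility, ordered by
#'   descending PFT count: `facility_id`, `pft_count`, `fev1_note_count`,
#'   `proportion`, `eligible`.
#' @export
screen_facilities <- function(procedures, notes, config = cohort_config(),
                              fev1_pattern = "FEV[ -]?1") {
  links <- link_notes(procedures, notes, config)
  counts <- table(procedures$facility_id)
  fac <- data.frame(
    facility_id = names(counts),
    pft_count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  fac <- fac[order(-fac$pft_count, fac$facility_id), , drop = FALSE]
  if (nrow(fac) < config$top_n_facilities) {
    warning(
      sprintf(
        "only %d facilities present; screening all (top_n_facilities = %d)",
        nrow(fac), config$top_n_facilities
      ),
      call. = FALSE
    )
  }
  fac <- utils::head(fac, config$top_n_facilities)

  has_fev1 <- grepl(fev1_pattern, notes$text, perl = TRUE, ignore.case = TRUE)
  fev1_notes <- notes$note_id[has_fev1]
  # a study counts once, however many FEV1-containing notes it has
  hit_studies <- unique(links$study_id[links$note_id %in% fev1_notes])
  per_fac_hits <- table(
    procedures$facility_id[procedures$study_id %in% hit_studies]
  )
  fac$fev1_note_count <- as.integer(per_fac_hits[fac$facility_id])
  fac$fev1_note_count[is.na(fac$fev1_note_count)] <- 0L
  fac$proportion <- fac$fev1_note_count / fac$pft_count
  cmp <- if (config$proportion_comparator == ">=") `>=` else `>`
  fac$eligible <- cmp(fac$proportion, config$min_fev1_note_proportion)
  rownames(fac) <- NULL
  fac
}
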