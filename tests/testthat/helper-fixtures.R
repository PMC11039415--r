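# Small in-code fixtures shared across test files.

mini_template <- function(facility_id = "FAC_T",
                          anchor = "SPIROMETRY\\s+RESULTS:") {
  facility_template(
    facility_id = facility_id,
    anchor_pattern = anchor,
    dialect_patterns = list(
      fev1_liters = "FEV1\\s+([0-9]+(?:\\.[0-9]+)?)\\s*L\\b",
      fev1_pct_pred = "\\(([0-9.,]+)\\s*%?\\s*predicted\\)",
      ratio = "FEV1\\s*[/:]\\s*FVC:?\\s*([0-9]+(?:\\.[0-9]+)?)\\s*%?"
    ),
    pre_post_markers = "POST[- ]?(?:BRONCHODILATOR|BD)"
  )
}

mini_notes <- function(ids, dates, texts, patient = "P1", facility = "FAC_T") {
  data.frame(
    note_id = ids, patient_id = rep_len(patient, length(ids)),
    facility_id = rep_len(facility, length(ids)),
    note_date = as.Date(dates), text = texts, stringsAsFactors = FALSE
  )
}

mini_procedures <- function(ids, dates, patient = "P1", facility = "FAC_T",
                            cpt = "94010", structured = FALSE) {
  data.frame(
    study_id = ids, patient_id = rep_len(patient, length(ids)),
    facility_id = rep_len(facility, length(ids)),
    procedure_date = as.Date(dates),
    cpt_code = rep_len(cpt, length(ids)),
    has_structured_fev1 = rep_len(structured, length(ids)),
    stringsAsFactors = FALSE
  )
}

mini_classification <- function(study_id = "S1",
                                obstruction = "obstructed",
                                severity = "severe",
                                ratio_value = 0.55,
                                fev1_pct_pred = 42,
                                obstruction_source = "quantitative",
                                severity_source = "quantitative") {
  data.frame(
    study_id = study_id, obstruction = obstruction, severity = severity,
    ratio_value = ratio_value, fev1_pct_pred = fev1_pct_pred,
    obstruction_source = obstruction_source,
    severity_source = severity_source, stringsAsFactors = FALSE
  )
}

# Independent brute-force cross-tab tally used as an oracle.
brute_crosstab <- function(cls) {
  sev_levels <- c(
    "normal", "mild", "moderate", "moderately_severe", "severe",
    "very_severe", "missing"
  )
  col_levels <- c("not_obstructed", "obstructed", "missing")
  m <- matrix(0L, nrow = 7, ncol = 3,
    dimnames = list(sev_levels, col_levels))
  for (i in seq_len(nrow(cls))) {
    m[cls$severity[i], cls$obstruction[i]] <-
      m[cls$severity[i], cls$obstruction[i]] + 1L
  }
  m
}

# Independent severity banding oracle: literal transcription of the
# guideline band list.
oracle_band <- function(p) {
  if (p >= 80) "normal"
  else if (p >= 70) "mild"
  else if (p >= 60) "moderate"
  else if (p >= 50) "moderately_severe"
  else if (p >= 35) "severe"
  else "very_severe"
}
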