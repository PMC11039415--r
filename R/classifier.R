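#' Classification criteria
#'
#' Thresholds for airflow obstruction and FEV1 impairment severity.
#' Obstruction uses the fixed-ratio criterion: FEV1:FVC strictly below 0.70.
#' Severity follows the ATS/ERS 2005 bands on FEV1 percent predicted:
#' normal \[80, Inf), mild \[70, 80), moderate \[60, 70), moderately severe
#' \[50, 60), severe \[35, 50), very severe (0, 35). The printed guideline
#' ranges are integer ("70-79%"); realizing them as half-open intervals
#' recovers the integer ranges exactly while classifying non-integer values
#' (79.5) deterministically.
#'
#' @param obstruction_threshold ratio below which obstruction is present
#'   (strict inequality).
#' @param band_edges named numeric vector of lower band edges, strictly
#'   decreasing, ending above 0.
#' @return object of class `classification_criteria`.
#' @export
classification_criteria <- function(obstruction_threshold = 0.70,
                                    band_edges = c(
                                      normal = 80, mild = 70, moderate = 60,
                                      moderately_severe = 50, severe = 35,
                                      very_severe = 0
                                    )) {
  if (any(diff(band_edges) >= 0)) {
    stop_pft("band_edges must be strictly decreasing")
  }
  if (band_edges[length(band_edges)] != 0) {
    stop_pft("last band edge must be 0 (bands must cover (0, Inf))")
  }
  structure(
    list(
      obstruction_threshold = obstruction_threshold,
      band_edges = band_edges
    ),
    class = "classification_criteria"
  )
}

qual_to_obstruction <- function(q) {
  if (q == "none_found") {
    return(NULL)
  }
  if (q == "no_obstruction") "not_obstructed" else "obstructed"
}

qual_to_severity <- function(q) {
  graded <- c(
    "normal", "mild", "moderate", "moderately_severe", "severe",
    "very_severe"
  )
  if (q %in% graded) q else NULL
}

#' Classify airflow obstruction
#'
#' Quantitative values are prioritized over qualitative descriptions: when a
#' ratio is present the qualitative descriptor is ignored (even if it
#' conflicts — the conflict is reported as a discordance event). When the
#' ratio is absent, a qualitative descriptor decides: `no_obstruction` maps
#' to not obstructed; any graded or unspecified obstruction descriptor maps
#' to obstructed. With neither, the status is missing.
#'
#' @param ratio_fraction FEV1:FVC as a fraction, or `NA`.
#' @param qualitative_obstruction category from [extract_qualitative()].
#' @param criteria a [classification_criteria()].
#' @return list with `status`, `source`, and logical `discordant`.
#' @export
classify_obstruction <- function(ratio_fraction,
                                 qualitative_obstruction = "none_found",
                                 criteria = classification_criteria()) {
  if (!is.na(ratio_fraction)) {
    status <- if (ratio_fraction < criteria$obstruction_threshold) {
      "obstructed"
    } else {
      "not_obstructed"
    }
    qual_status <- qual_to_obstruction(qualitative_obstruction)
    discordant <- !is.null(qual_status) && qual_status != status
    return(list(
      status = status, source = "quantitative",
      discordant = discordant
    ))
  }
  qual_status <- qual_to_obstruction(qualitative_obstruction)
  if (!is.null(qual_status)) {
    return(list(status = qual_status, source = "qualitative",
      discordant = FALSE))
  }
  list(status = "missing", source = "none", discordant = FALSE)
}

#' Grade FEV1 impairment severity
#'
#' Quantitative percent predicted is banded by the half-open partition in
#' `criteria`; when absent, a graded qualitative FEV1 descriptor maps
#' directly to the same-named band; with neither, severity is missing.
#'
#' @param fev1_pct_pred FEV1 percent predicted, or `NA`.
#' @param qualitative_fev1 category from [extract_qualitative()].
#' @param criteria a [classification_criteria()].
#' @return list with `band` and `source`.
#' @export
grade_severity <- function(fev1_pct_pred, qualitative_fev1 = "none_found",
                           criteria = classification_criteria()) {
  if (!is.na(fev1_pct_pred) && fev1_pct_pred > 0) {
    edges <- criteria$band_edges
    band <- names(edges)[which(fev1_pct_pred >= edges)[1]]
    return(list(band = band, source = "quantitative"))
  }
  band <- qual_to_severity(qualitative_fev1)
  if (!is.null(band)) {
    return(list(band = band, source = "qualitative"))
  }
  list(band = "missing", source = "none")
}

#' Resolve an extraction into a final classification
#'
#' Composes [classify_obstruction()] and [grade_severity()] under the
#' quantitative-over-qualitative rule. When no quantitative percent
#' predicted and no qualitative FEV1 descriptor exist, a *graded*
#' qualitative obstruction descriptor ("severe obstruction") also supplies
#' the severity band; an ungraded one ("obstruction") leaves severity
#' missing. Never errors on missing data.
#'
#' @param extraction one row of [extract_values()] output (or a list with
#'   the same fields).
#' @param criteria a [classification_criteria()].
#' @return list: `obstruction`, `severity`, `ratio_value`, `fev1_pct_pred`,
#'   `obstruction_source`, `severity_source`, `discordant`.
#' @export
resolve <- function(extraction, criteria = classification_criteria()) {
  obs <- classify_obstruction(
    extraction$ratio_fraction %||% NA_real_,
    extraction$qualitative_obstruction %||% "none_found",
    criteria
  )
  qual_fev1 <- extraction$qualitative_fev1 %||% "none_found"
  sev <- grade_severity(
    extraction$fev1_pct_pred %||% NA_real_, qual_fev1, criteria
  )
  if (sev$band == "missing") {
    # fall back on a graded obstruction descriptor for severity
    band <- qual_to_severity(extraction$qualitative_obstruction %||%
      "none_found")
    if (!is.null(band)) sev <- list(band = band, source = "qualitative")
  }
  list(
    obstruction = obs$status,
    severity = sev$band,
    ratio_value = if (obs$source == "quantitative") {
      extraction$ratio_fraction
    } else {
      NA_real_
    },
    fev1_pct_pred = if (sev$source == "quantitative") {
      extraction$fev1_pct_pred
    } else {
      NA_real_
    },
    obstruction_source = obs$source,
    severity_source = sev$source,
    discordant = obs$discordant
  )
}

#' Classify a table of extractions
#'
#' Vectorized wrapper around [resolve()]. Studies present in `study_ids`
#' but absent from `extractions` (no snippet was found) classify as missing
#' on both axes.
#'
#' @param extractions data.frame from [extract_values()].
#' @param criteria a [classification_criteria()].
#' @param study_ids optional character vector of all study ids that should
#'   appear in the output (defaults to those in `extractions`).
#' @return classification data.frame (see [validate_classifications()]);
#'   attribute `discordant_ids` lists studies whose quantitative and
#'   qualitative obstruction calls disagreed.
#' @export
classify_extractions <- function(extractions,
                                 criteria = classification_criteria(),
                                 study_ids = NULL) {
  ids <- study_ids %||% extractions$study_id
  n <- length(ids)
  out <- data.frame(
    study_id = as.character(ids),
    obstruction = rep("missing", n),
    severity = rep("missing", n),
    ratio_value = rep(NA_real_, n),
    fev1_pct_pred = rep(NA_real_, n),
    obstruction_source = rep("none", n),
    severity_source = rep("none", n),
    stringsAsFactors = FALSE
  )
  discordant <- character()
  idx <- match(extractions$study_id, out$study_id)
  for (k in seq_len(nrow(extractions))) {
    i <- idx[k]
    if (is.na(i)) next
    r <- resolve(extractions[k, , drop = FALSE], criteria)
    out$obstruction[i] <- r$obstruction
    out$severity[i] <- r$severity
    out$ratio_value[i] <- r$ratio_value
    out$fev1_pct_pred[i] <- r$fev1_pct_pred
    out$obstruction_source[i] <- r$obstruction_source
    out$severity_source[i] <- r$severity_source
    if (isTRUE(r$discordant)) discordant <- c(discordant, out$study_id[i])
  }
  validate_classifications(out)
  attr(out, "discordant_ids") <- discordant
  out
}
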