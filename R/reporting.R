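crosstab_row_levels <- function() severity_levels()

crosstab_col_levels <- function() c("ratio_ge_0.7", "ratio_lt_0.7", "missing")

#' Cross-tabulate severity against obstruction
#'
#' Builds the 7 x 3 count matrix of FEV1 severity band (normal through very
#' severe, plus missing) against FEV1:FVC ratio category (at or above the
#' obstruction threshold, below it, missing), with row, column and grand
#' totals. Every classification record lands in exactly one cell.
#'
#' @param classifications validated classification data.frame.
#' @return object of class `pft_crosstab`: `cells` (matrix), `row_totals`,
#'   `col_totals`, `grand_total`.
#' @export
build_crosstab <- function(classifications) {
  validate_classifications(classifications)
  col_of <- c(
    not_obstructed = "ratio_ge_0.7", obstructed = "ratio_lt_0.7",
    missing = "missing"
  )
  rows <- factor(classifications$severity, levels = crosstab_row_levels())
  cols <- factor(col_of[classifications$obstruction],
    levels = crosstab_col_levels()
  )
  cells <- unclass(table(rows, cols))
  dimnames(cells) <- list(
    severity = crosstab_row_levels(),
    ratio = crosstab_col_levels()
  )
  structure(
    list(
      cells = cells,
      row_totals = rowSums(cells),
      col_totals = colSums(cells),
      grand_total = sum(cells)
    ),
    class = "pft_crosstab"
  )
}

#' @export
print.pft_crosstab <- function(x, ...) {
  m <- cbind(x$cells, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  rownames(m) <- c(
    "Normal", "Mild", "Moderate", "Moderately severe",
    "Severe", "Very severe", "Missing", "Total"
  )
  colnames(m) <- c(">=0.7", "<0.7", "Missing", "Total")
  cat("Cross-tabulation of FEV1:FVC ratio and FEV1 percent predicted\n")
  print(m)
  invisible(x)
}

#' Write a cross-tab as CSV (cells plus marginals)
#'
#' @param crosstab a `pft_crosstab`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(crosstab, path) {
  m <- cbind(crosstab$cells, total = crosstab$row_totals)
  m <- rbind(m, total = c(crosstab$col_totals, crosstab$grand_total))
  df <- data.frame(severity = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Headline proportions from a cross-tab
#'
#' The two summary figures reported for a spirometry extraction corpus: the
#' percentage of studies with obstruction (ratio below threshold) and the
#' percentage with a severe or very severe FEV1 reduction, both over all
#' studies in the table and rounded half-away-from-zero to one decimal on
#' the percent scale.
#'
#' @param crosstab a `pft_crosstab`.
#' @return named list: `pct_obstructed`, `pct_severe_or_worse`, plus the raw
#'   fractions `frac_obstructed`, `frac_severe_or_worse`.
#' @export
headline_proportions <- function(crosstab) {
  if (crosstab$grand_total == 0) {
    stop_pft("undefined proportions: cross-tab is empty")
  }
  frac_obs <- crosstab$col_totals[["ratio_lt_0.7"]] / crosstab$grand_total
  frac_sev <- (crosstab$row_totals[["severe"]] +
    crosstab$row_totals[["very_severe"]]) / crosstab$grand_total
  list(
    pct_obstructed = round_half_up(100 * frac_obs, 1),
    pct_severe_or_worse = round_half_up(100 * frac_sev, 1),
    frac_obstructed = frac_obs,
    frac_severe_or_worse = frac_sev
  )
}

#' Per-facility extraction yield
#'
#' For each facility: the number of PFT studies, the number with an
#' extracted ratio and an extracted percent predicted, and the corresponding
#' yields as fractions of the facility's PFTs.
#'
#' @param classifications classification data.frame.
#' @param procedures procedure data.frame supplying `study_id` ->
#'   `facility_id`.
#' @return data.frame: `facility_id`, `n_pft`, `n_ratio_extracted`,
#'   `n_fev1_extracted`, `ratio_yield`, `fev1_yield`.
#' @export
facility_yield <- function(classifications, procedures) {
  fac <- stats::setNames(procedures$facility_id, procedures$study_id)
  cls_fac <- fac[classifications$study_id]
  all_fac <- sort(unique(procedures$facility_id))
  n_pft <- table(factor(procedures$facility_id, levels = all_fac))
  n_ratio <- table(factor(
    cls_fac[!is.na(classifications$ratio_value)],
    levels = all_fac
  ))
  n_fev1 <- table(factor(
    cls_fac[!is.na(classifications$fev1_pct_pred)],
    levels = all_fac
  ))
  data.frame(
    facility_id = all_fac,
    n_pft = as.integer(n_pft),
    n_ratio_extracted = as.integer(n_ratio),
    n_fev1_extracted = as.integer(n_fev1),
    ratio_yield = as.integer(n_ratio) / as.integer(n_pft),
    fev1_yield = as.integer(n_fev1) / as.integer(n_pft),
    stringsAsFactors = FALSE
  )
}

#' Compare algorithm output with adjudicated truth
#'
#' Draws a seeded simple random sample of studies (without replacement) and
#' scores the algorithm's obstruction and severity calls against the truth
#' labels. A missing call matching a truly missing value counts as
#' agreement — correctly determining that a value is absent is part of the
#' task. Full confusion matrices and the discordant study ids are returned.
#'
#' @param predicted classification data.frame (algorithm output).
#' @param truth data.frame with `study_id`, `true_obstruction`,
#'   `true_severity` (a truth table from [generate_corpus()] works as-is).
#' @param n_sample studies to sample; capped (with a warning) at the number
#'   of shared studies.
#' @param seed RNG seed for the sample draw.
#' @return object of class `pft_validation`: `n`, `obstruction_correct`,
#'   `severity_correct`, `obstruction_accuracy`, `severity_accuracy`,
#'   `obstruction_confusion`, `severity_confusion`, `discordant_ids`,
#'   `sampled_ids`.
#' @export
validate_against_truth <- function(predicted, truth, n_sample = 100L,
                                   seed = 1L) {
  shared <- intersect(predicted$study_id, truth$study_id)
  if (length(shared) == 0L) stop_pft("no shared study_ids")
  shared <- sort(shared)
  if (n_sample > length(shared)) {
    warning(
      sprintf(
        "n_sample %d exceeds population %d; using all studies",
        n_sample, length(shared)
      ),
      call. = FALSE
    )
    n_sample <- length(shared)
  }
  sampled <- with_seed(seed, sample(shared, n_sample))
  p <- predicted[match(sampled, predicted$study_id), , drop = FALSE]
  t <- truth[match(sampled, truth$study_id), , drop = FALSE]
  obs_ok <- p$obstruction == t$true_obstruction
  sev_ok <- p$severity == t$true_severity
  structure(
    list(
      n = n_sample,
      obstruction_correct = sum(obs_ok),
      severity_correct = sum(sev_ok),
      obstruction_accuracy = mean(obs_ok),
      severity_accuracy = mean(sev_ok),
      obstruction_confusion = table(
        predicted = factor(p$obstruction, levels = obstruction_levels()),
        truth = factor(t$true_obstruction, levels = obstruction_levels())
      ),
      severity_confusion = table(
        predicted = factor(p$severity, levels = severity_levels()),
        truth = factor(t$true_severity, levels = severity_levels())
      ),
      discordant_ids = sort(sampled[!(obs_ok & sev_ok)]),
      sampled_ids = sampled
    ),
    class = "pft_validation"
  )
}

#' @export
print.pft_validation <- function(x, ...) {
  cat(sprintf(
    "Validation on %d sampled studies:\n  obstruction correct: %d/%d (%.1f%%)\n  severity correct:    %d/%d (%.1f%%)\n",
    x$n, x$obstruction_correct, x$n, 100 * x$obstruction_accuracy,
    x$severity_correct, x$n, 100 * x$severity_accuracy
  ))
  if (length(x$discordant_ids) > 0L) {
    cat(
      "  discordant:", paste(utils::head(x$discordant_ids, 10L),
        collapse = ", "
      ),
      if (length(x$discordant_ids) > 10L) "..." else "", "\n"
    )
  }
  invisible(x)
}

#' Path of the bundled reference cross-tabulation
#'
#' A reference cross-tabulation of FEV1 severity against FEV1:FVC ratio
#' category over 24,922 spirometry studies from a multi-facility VA cohort,
#' shipped as a replay fixture: expanding its cells to synthetic records and
#' rebuilding the table checks the tabulation and headline arithmetic
#' end to end.
#'
#' @return file path of the bundled CSV.
#' @export
reference_crosstab_path <- function() {
  system.file("extdata", "reference_crosstab.csv",
    package = "pftminer",
    mustWork = TRUE
  )
}

#' Read a cross-tab cell CSV
#'
#' @param path CSV with columns `severity`, `ratio_ge_0.7`, `ratio_lt_0.7`,
#'   `missing`; one row per severity level.
#' @return 7 x 3 integer matrix in canonical row/column order.
#' @export
read_crosstab_cells <- function(path = reference_crosstab_path()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(
    df, c("severity", crosstab_col_levels()), "crosstab cells"
  )
  m <- as.matrix(df[match(crosstab_row_levels(), df$severity),
    crosstab_col_levels(),
    drop = FALSE
  ])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(
    severity = crosstab_row_levels(),
    ratio = crosstab_col_levels()
  )
  m
}

#' Expand cross-tab cells into individual classification records
#'
#' Inverse of [build_crosstab()] up to study identity: emits one synthetic
#' classification record per count, with representative in-band values
#' (band midpoints for percent predicted; 0.65 / 0.75 for the two ratio
#' categories) so the records pass validation.
#'
#' @param cells 7 x 3 count matrix as from [read_crosstab_cells()].
#' @return classification data.frame with `sum(cells)` rows.
#' @export
expand_crosstab_cells <- function(cells) {
  rep_pct <- c(
    normal = 90, mild = 75, moderate = 65, moderately_severe = 55,
    severe = 42, very_severe = 25, missing = NA_real_
  )
  rep_ratio <- c(
    "ratio_ge_0.7" = 0.75, "ratio_lt_0.7" = 0.65, missing = NA_real_
  )
  obs_of <- c(
    "ratio_ge_0.7" = "not_obstructed", "ratio_lt_0.7" = "obstructed",
    missing = "missing"
  )
  rows <- list()
  k <- 0L
  for (sev in rownames(cells)) {
    for (rc in colnames(cells)) {
      n <- cells[sev, rc]
      if (n == 0L) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        study_id = sprintf("replay_%s_%s_%06d", sev, rc, seq_len(n)),
        obstruction = obs_of[[rc]],
        severity = sev,
        ratio_value = rep_ratio[[rc]],
        fev1_pct_pred = rep_pct[[sev]],
        obstruction_source = if (rc == "missing") "none" else "quantitative",
        severity_source = if (sev == "missing") "none" else "quantitative",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_classifications(out)
  out
}
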