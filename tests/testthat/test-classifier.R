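test_that("obstruction threshold is a strict 0.70 inequality", {
  expect_equal(classify_obstruction(0.69)$status, "obstructed")
  expect_equal(classify_obstruction(0.699)$status, "obstructed")
  expect_equal(classify_obstruction(0.70)$status, "not_obstructed")
  expect_equal(classify_obstruction(0.75)$status, "not_obstructed")
})

test_that("severity bands match the guideline list at every boundary", {
  cases <- list(
    list(80, "normal"), list(100, "normal"),
    list(79, "mild"), list(70, "mild"), list(79.5, "mild"),
    list(69, "moderate"), list(60, "moderate"),
    list(59, "moderately_severe"), list(50, "moderately_severe"),
    list(49, "severe"), list(35, "severe"),
    list(34, "very_severe"), list(34.9, "very_severe")
  )
  for (cs in cases) {
    expect_equal(grade_severity(cs[[1]])$band, cs[[2]],
      label = sprintf("band(%s)", cs[[1]])
    )
  }
})

test_that("severity grading equals the guideline oracle at integers 1..200", {
  for (p in 1:200) {
    expect_identical(grade_severity(p)$band, oracle_band(p),
      label = sprintf("band(%d)", p)
    )
  }
})

test_that("severity grading is monotone and exhaustive over (0, 300)", {
  ranks <- c(
    very_severe = 1, severe = 2, moderately_severe = 3, moderate = 4,
    mild = 5, normal = 6
  )
  pts <- sort(c(
    seq(0.5, 299.5, by = 0.7), 35, 50, 60, 70, 80,
    34.999, 79.999, 80.001
  ))
  bands <- vapply(pts, function(p) grade_severity(p)$band, "")
  expect_true(all(bands %in% names(ranks))) # every point maps to one band
  expect_true(all(diff(ranks[bands]) >= 0)) # never worsens as pct rises
})

test_that("every real ratio maps to exactly one status", {
  for (r in c(0.001, seq(0.05, 1.5, by = 0.05))) {
    st <- classify_obstruction(r)$status
    expect_true(st %in% c("obstructed", "not_obstructed"))
    expect_identical(st == "obstructed", r < 0.7)
  }
})

test_that("quantitative values take priority over qualitative descriptors", {
  # quantitative wins even when the descriptor conflicts
  res <- classify_obstruction(0.72, "moderate")
  expect_equal(res$status, "not_obstructed")
  expect_equal(res$source, "quantitative")
  expect_true(res$discordant)

  # qualitative fallback when the ratio is absent
  fb <- classify_obstruction(NA_real_, "mild")
  expect_equal(fb$status, "obstructed")
  expect_equal(fb$source, "qualitative")
  expect_equal(
    classify_obstruction(NA_real_, "no_obstruction")$status,
    "not_obstructed"
  )
  expect_equal(
    classify_obstruction(NA_real_, "unspecified_obstruction")$status,
    "obstructed"
  )

  # metamorphic sweep: with a ratio present, mutating the descriptor never
  # changes the outcome
  for (r in c(0.4, 0.699, 0.7, 0.9)) {
    base <- classify_obstruction(r, "none_found")$status
    for (q in c(
      "no_obstruction", "mild", "moderate", "moderately_severe",
      "severe", "very_severe", "unspecified_obstruction"
    )) {
      expect_identical(classify_obstruction(r, q)$status, base)
    }
  }
})

test_that("resolution composes obstruction and severity with provenance", {
  all_missing <- resolve(list(
    ratio_fraction = NA_real_, fev1_pct_pred = NA_real_,
    qualitative_obstruction = "none_found", qualitative_fev1 = "none_found"
  ))
  expect_equal(all_missing$obstruction, "missing")
  expect_equal(all_missing$severity, "missing")
  expect_equal(all_missing$obstruction_source, "none")
  expect_equal(all_missing$severity_source, "none")

  quant <- resolve(list(
    ratio_fraction = 0.55, fev1_pct_pred = 42,
    qualitative_obstruction = "none_found", qualitative_fev1 = "none_found"
  ))
  expect_equal(quant$obstruction, "obstructed")
  expect_equal(quant$severity, "severe")
  expect_equal(quant$obstruction_source, "quantitative")
  expect_equal(quant$severity_source, "quantitative")

  # a graded obstruction descriptor supplies the severity band too
  qual <- resolve(list(
    ratio_fraction = NA_real_, fev1_pct_pred = NA_real_,
    qualitative_obstruction = "severe", qualitative_fev1 = "none_found"
  ))
  expect_equal(qual$obstruction, "obstructed")
  expect_equal(qual$severity, "severe")
  expect_equal(qual$severity_source, "qualitative")

  # an ungraded one leaves severity missing
  ungraded <- resolve(list(
    ratio_fraction = 0.6, fev1_pct_pred = NA_real_,
    qualitative_obstruction = "unspecified_obstruction",
    qualitative_fev1 = "none_found"
  ))
  expect_equal(ungraded$obstruction, "obstructed")
  expect_equal(ungraded$severity, "missing")
})

test_that("classification of an extraction table satisfies its invariants", {
  ex <- data.frame(
    study_id = c("S1", "S2", "S3"),
    fev1_liters = c(2.1, NA, NA),
    fev1_pct_pred = c(78, NA, NA),
    ratio_raw = c(65, NA, NA),
    ratio_fraction = c(0.65, NA, NA),
    qualitative_obstruction = c("mild", "no_obstruction", "none_found"),
    qualitative_fev1 = c("none_found", "normal", "none_found"),
    stringsAsFactors = FALSE
  )
  cls <- classify_extractions(ex, study_ids = c("S1", "S2", "S3", "S4"))
  expect_silent(validate_classifications(cls))
  expect_equal(cls$obstruction, c(
    "obstructed", "not_obstructed", "missing", "missing"
  ))
  expect_equal(cls$severity, c("mild", "normal", "missing", "missing"))
  expect_equal(cls$severity_source, c(
    "quantitative", "qualitative", "none", "none"
  ))
})
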