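test_that("empty input gives an all-zero table and undefined proportions", {
  empty <- mini_classification()[0, ]
  ct <- build_crosstab(empty)
  expect_true(all(ct$cells == 0L))
  expect_equal(ct$grand_total, 0L)
  expect_error(headline_proportions(ct), "undefined")
})

test_that("cross-tab equals a brute-force tally on random records", {
  withr::with_seed(77, {
    n <- 50
    obs <- sample(c("obstructed", "not_obstructed", "missing"), n,
      replace = TRUE
    )
    sev <- sample(
      c(
        "normal", "mild", "moderate", "moderately_severe", "severe",
        "very_severe", "missing"
      ), n,
      replace = TRUE
    )
  })
  cls <- data.frame(
    study_id = sprintf("S%02d", seq_len(50)),
    obstruction = obs, severity = sev,
    ratio_value = ifelse(obs == "missing", NA,
      ifelse(obs == "obstructed", 0.6, 0.8)),
    fev1_pct_pred = ifelse(sev == "missing", NA, 70),
    obstruction_source = ifelse(obs == "missing", "none", "quantitative"),
    severity_source = ifelse(sev == "missing", "none", "qualitative"),
    stringsAsFactors = FALSE
  )
  ct <- build_crosstab(cls)
  brute <- brute_crosstab(cls)
  expect_equal(unname(ct$cells[, "ratio_ge_0.7"]),
    unname(brute[, "not_obstructed"]))
  expect_equal(unname(ct$cells[, "ratio_lt_0.7"]),
    unname(brute[, "obstructed"]))
  expect_equal(unname(ct$cells[, "missing"]), unname(brute[, "missing"]))
  # conservation of marginals
  expect_equal(sum(ct$cells), ct$grand_total)
  expect_equal(unname(rowSums(ct$cells)), unname(ct$row_totals))
  expect_equal(unname(colSums(ct$cells)), unname(ct$col_totals))
  expect_equal(sum(ct$row_totals), sum(ct$col_totals))
})

test_that("a single obstructed record gives 100% obstructed", {
  ct <- build_crosstab(mini_classification())
  hp <- headline_proportions(ct)
  expect_equal(hp$pct_obstructed, 100.0)
  expect_equal(hp$pct_severe_or_worse, 100.0)
})

test_that("percent rounding is half away from zero to one decimal", {
  expect_equal(round_half_up(70.65, 1), 70.7)
  expect_equal(round_half_up(70.64, 1), 70.6)
  expect_equal(round_half_up(35.55, 1), 35.6)
})

test_that("facility yield is extractions over PFTs per facility", {
  pr <- rbind(
    mini_procedures(sprintf("A%03d", 1:100), rep("2019-01-01", 100),
      patient = sprintf("pa%03d", 1:100), facility = "A"
    ),
    mini_procedures(sprintf("B%02d", 1:10), rep("2019-01-01", 10),
      patient = sprintf("pb%02d", 1:10), facility = "B"
    ),
    mini_procedures(sprintf("C%02d", 1:5), rep("2019-01-01", 5),
      patient = sprintf("pc%02d", 1:5), facility = "C"
    )
  )
  cls <- rbind(
    do.call(rbind, lapply(sprintf("A%03d", 1:93), mini_classification)),
    do.call(rbind, lapply(sprintf("B%02d", 1:4), function(id) {
      mini_classification(id,
        obstruction = "missing", severity = "severe",
        ratio_value = NA, fev1_pct_pred = 40,
        obstruction_source = "none"
      )
    }))
  )
  y <- facility_yield(cls, pr)
  expect_equal(y$ratio_yield[y$facility_id == "A"], 0.93)
  expect_equal(y$fev1_yield[y$facility_id == "A"], 0.93)
  expect_equal(y$ratio_yield[y$facility_id == "B"], 0)
  expect_equal(y$fev1_yield[y$facility_id == "B"], 0.4)
  expect_equal(y$ratio_yield[y$facility_id == "C"], 0)
  expect_equal(y$n_pft, c(100L, 10L, 5L))
})

test_that("validation scores agreement, counting missing-missing as a match", {
  truth <- data.frame(
    study_id = sprintf("S%03d", 1:100),
    true_obstruction = rep(c("obstructed", "missing"), 50),
    true_severity = rep(c("severe", "missing"), 50),
    stringsAsFactors = FALSE
  )
  pred <- data.frame(
    study_id = truth$study_id,
    obstruction = truth$true_obstruction,
    severity = truth$true_severity,
    stringsAsFactors = FALSE
  )
  v <- validate_against_truth(pred, truth, n_sample = 100, seed = 42)
  expect_equal(v$obstruction_correct, 100L)
  expect_equal(v$severity_correct, 100L)
  expect_length(v$discordant_ids, 0L)

  # one severity flip -> 99/100
  pred2 <- pred
  pred2$severity[pred2$study_id == "S001"] <- "mild"
  v2 <- validate_against_truth(pred2, truth, n_sample = 100, seed = 42)
  expect_equal(v2$severity_correct, 99L)
  expect_equal(v2$obstruction_correct, 100L)
  expect_identical(v2$discordant_ids, "S001")
  expect_equal(sum(v2$severity_confusion), 100)
})

test_that("validation sampling is seeded and order-invariant", {
  truth <- data.frame(
    study_id = sprintf("S%03d", 1:50),
    true_obstruction = "obstructed",
    true_severity = "severe",
    stringsAsFactors = FALSE
  )
  pred <- data.frame(
    study_id = truth$study_id, obstruction = "obstructed",
    severity = "severe", stringsAsFactors = FALSE
  )
  v1 <- validate_against_truth(pred, truth, n_sample = 20, seed = 9)
  v2 <- validate_against_truth(
    pred[rev(seq_len(50)), ], truth[sample(50), ],
    n_sample = 20, seed = 9
  )
  expect_identical(v1$sampled_ids, v2$sampled_ids)

  expect_warning(
    validate_against_truth(pred, truth, n_sample = 500, seed = 1),
    "exceeds"
  )
})

test_that("reference cross-tab replay reproduces its marginals exactly", {
  cells <- read_crosstab_cells()
  recs <- expand_crosstab_cells(cells)
  ct <- build_crosstab(recs)
  expect_identical(unname(ct$cells), unname(cells))
  expect_equal(unname(ct$col_totals), c(7245L, 17615L, 62L))
  expect_equal(ct$grand_total, 24922L)
})
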