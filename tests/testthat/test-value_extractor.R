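test_that("post-bronchodilator masking hides post values, keeps pre values", {
  tpl <- mini_template()
  txt <- "PRE: FEV1 55% POST: FEV1 68%"
  tpl2 <- facility_template("T", "PRE",
    dialect_patterns = list(fev1_pct_pred = "FEV1\\s+([0-9.]+)\\s*%"),
    pre_post_markers = "POST"
  )
  masked <- mask_post_bronchodilator(txt, tpl2)
  expect_equal(nchar(masked), nchar(txt))
  q <- extract_quantitative(masked, tpl2)
  expect_equal(q$fev1_pct_pred, 55)

  # no markers -> unchanged
  no_mark <- facility_template("T", "X")
  expect_identical(mask_post_bronchodilator(txt, no_mark), txt)

  # post-only snippet -> fully blanked -> nothing extractable
  post_only <- "POST-BRONCHODILATOR\nFEV1 70%"
  masked2 <- mask_post_bronchodilator(post_only, tpl2)
  expect_true(is.na(extract_quantitative(masked2, tpl2)$fev1_pct_pred))
})

test_that("masking runs to the next pre marker or blank line, not further", {
  tpl <- facility_template("T", "X",
    dialect_patterns = list(fev1_pct_pred = "FEV1\\s+([0-9.]+)"),
    pre_post_markers = "POST-BD"
  )
  # post segment terminated by a blank line; text after it survives
  txt <- "POST-BD FEV1 70\n\nFEV1 55 today"
  masked <- mask_post_bronchodilator(txt, tpl)
  expect_equal(extract_quantitative(masked, tpl)$fev1_pct_pred, 55)
  # newlines survive masking; offsets are stable
  expect_identical(
    which(strsplit(masked, "")[[1]] == "\n"),
    which(strsplit(txt, "")[[1]] == "\n")
  )
})

test_that("quantitative extraction pulls liters, percent and ratio", {
  tpl <- mini_template()
  q <- extract_quantitative(
    "FEV1 2.10 L (78% predicted) FEV1/FVC 65%", tpl
  )
  expect_equal(q$fev1_liters, 2.10)
  expect_equal(q$fev1_pct_pred, 78)
  expect_equal(q$ratio_raw, 65)
  expect_equal(q$ratio_fraction, 0.65)
  # provenance recorded for every present value
  expect_setequal(
    names(q$provenance), c("fev1_liters", "fev1_pct_pred", "ratio")
  )

  none <- extract_quantitative("no numerals here", tpl)
  expect_true(is.na(none$fev1_liters) && is.na(none$fev1_pct_pred) &&
    is.na(none$ratio_raw))

  colon <- extract_quantitative("FEV1/FVC: 0.65", tpl)
  expect_equal(colon$ratio_raw, 0.65)
  expect_equal(colon$ratio_fraction, 0.65)
})

test_that("first match wins within each slot", {
  tpl <- mini_template()
  q <- extract_quantitative("FEV1/FVC 65% ... FEV1/FVC 51%", tpl)
  expect_equal(q$ratio_raw, 65)
})

test_that("number parsing tolerates commas and percent signs", {
  tpl <- facility_template("T", "X",
    dialect_patterns = list(fev1_pct_pred = "pred\\s+([0-9.,]+)\\s*%?")
  )
  expect_equal(
    extract_quantitative("pred 102%", tpl)$fev1_pct_pred, 102
  )
  expect_equal(
    extract_quantitative("pred 1,02", tpl)$fev1_pct_pred, 102
  )
})

test_that("ratio normalization applies the percent heuristic", {
  expect_equal(normalize_ratio(0.65), 0.65)
  expect_equal(normalize_ratio(65), 0.65)
  expect_equal(normalize_ratio(1), 1)
  expect_true(is.na(normalize_ratio(140)))
  expect_true(is.na(normalize_ratio(NA_real_)))
})

test_that("implausible values are dropped and logged, not crashed on", {
  tpl <- facility_template("T", "X",
    dialect_patterns = list(
      fev1_liters = "vol\\s+([0-9.]+)",
      fev1_pct_pred = "pct\\s+([0-9.]+)",
      ratio = "rat\\s+([0-9.]+)"
    )
  )
  q <- extract_quantitative("vol 22.5 pct 350 rat 140", tpl)
  expect_true(is.na(q$fev1_liters))
  expect_true(is.na(q$fev1_pct_pred))
  expect_true(is.na(q$ratio_fraction))
  expect_length(q$events, 3L)
})

test_that("qualitative descriptors map through the lexicon", {
  tpl <- mini_template()
  lex <- load_lexicon()
  expect_equal(
    extract_qualitative("mild obstruction", tpl, lex)$qualitative_obstruction,
    "mild"
  )
  expect_equal(
    extract_qualitative("the FEV1 is normal", tpl, lex)$qualitative_fev1,
    "normal"
  )
  expect_equal(
    extract_qualitative(
      "no evidence of obstruction", tpl, lex
    )$qualitative_obstruction,
    "no_obstruction"
  )
  expect_equal(
    extract_qualitative("clear lungs", tpl, lex)$qualitative_obstruction,
    "none_found"
  )
})

test_that("longer descriptors shadow their substrings", {
  tpl <- mini_template()
  lex <- load_lexicon()
  expect_equal(
    extract_qualitative(
      "moderately severe obstruction", tpl, lex
    )$qualitative_obstruction,
    "moderately_severe"
  )
  expect_equal(
    extract_qualitative(
      "very severe obstruction", tpl, lex
    )$qualitative_obstruction,
    "very_severe"
  )
  expect_equal(
    extract_qualitative(
      "the FEV1 is very severely reduced", tpl, lex
    )$qualitative_fev1,
    "very_severe"
  )
  expect_equal(
    extract_qualitative("obstruction noted", tpl, lex)$qualitative_obstruction,
    "unspecified_obstruction"
  )
})

test_that("with several descriptors the one nearest the anchor wins", {
  tpl <- facility_template("T", "RESULTS:")
  lex <- load_lexicon()
  txt <- paste0(
    "prior study showed severe obstruction. RESULTS: today mild obstruction."
  )
  anchor <- find_anchor(txt, tpl)
  got <- extract_qualitative(txt, tpl, lex, anchor_offset = anchor$start)
  expect_equal(got$qualitative_obstruction, "mild")
})

test_that("extraction is deterministic and masking-length preserving", {
  corpus <- generate_corpus(corpus_config(
    n_facilities = 2, notes_per_facility = 10, seed = 5
  ))
  links <- link_notes(corpus$procedures, corpus$notes)
  snips <- extract_snippets(links, corpus$notes, corpus$registry)
  e1 <- extract_values(snips, corpus$registry)
  e2 <- extract_values(snips, corpus$registry)
  expect_identical(e1, e2)
  for (i in seq_len(nrow(snips))) {
    tpl <- template_for(snips$facility_id[i], corpus$registry)
    masked <- mask_post_bronchodilator(snips$text[i], tpl)
    expect_equal(nchar(masked), nchar(snips$text[i]))
  }
})
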