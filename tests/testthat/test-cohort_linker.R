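test_that("procedure filter keeps spirometry CPTs without structured FEV1", {
  pr <- rbind(
    mini_procedures("S1", "2019-01-01", cpt = "94010"),
    mini_procedures("S2", "2019-01-02", cpt = "94010", structured = TRUE),
    mini_procedures("S3", "2019-01-03", cpt = "99213"),
    mini_procedures("S4", "2019-01-04", cpt = "94729")
  )
  kept <- filter_procedures(pr)
  expect_identical(kept$study_id, c("S1", "S4"))
  # idempotent, and a subset of the input
  expect_identical(filter_procedures(kept), kept)
  expect_true(all(kept$study_id %in% pr$study_id))
})

test_that("procedure filter equals brute-force set membership on random input", {
  cfg <- cohort_config()
  withr::with_seed(101, {
    pr <- mini_procedures(
      sprintf("S%02d", 1:20),
      as.Date("2019-01-01") + sample(0:99, 20, replace = TRUE),
      cpt = sample(c(cfg$cpt_codes, "99213", "71020"), 20, replace = TRUE)
    )
    pr$has_structured_fev1 <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  })
  expected <- character()
  for (i in 1:20) {
    if (pr$cpt_code[i] %in% cfg$cpt_codes && !pr$has_structured_fev1[i]) {
      expected <- c(expected, pr$study_id[i])
    }
  }
  expect_identical(filter_procedures(pr, cfg)$study_id, expected)
})

test_that("date-window linkage includes both endpoints and excludes outside", {
  pr <- mini_procedures("S1", "2019-06-10")
  notes <- mini_notes(
    sprintf("N%d", 1:5),
    c("2019-06-09", "2019-06-10", "2019-07-01", "2019-07-02", "2019-06-08"),
    rep("x", 5)
  )
  links <- link_notes(pr, notes)
  # -1, 0 and +21 are in; +22 and -2 are out
  expect_setequal(links$note_id, c("N1", "N2", "N3"))
  expect_setequal(links$offset_days, c(-1L, 0L, 21L))
})

test_that("linkage equals all-pairs brute force and ignores input order", {
  withr::with_seed(202, {
    pr <- mini_procedures(
      sprintf("S%02d", 1:15),
      as.Date("2019-01-01") + sample(0:60, 15, replace = TRUE),
      patient = sample(sprintf("P%d", 1:5), 15, replace = TRUE)
    )
    notes <- mini_notes(
      sprintf("N%02d", 1:40),
      as.Date("2019-01-01") + sample(-10:80, 40, replace = TRUE),
      rep("x", 40),
      patient = sample(sprintf("P%d", 1:5), 40, replace = TRUE)
    )
  })
  links <- link_notes(pr, notes)

  brute <- character()
  for (i in seq_len(nrow(pr))) {
    for (j in seq_len(nrow(notes))) {
      off <- as.integer(notes$note_date[j] - pr$procedure_date[i])
      if (pr$patient_id[i] == notes$patient_id[j] && off >= -1 && off <= 21) {
        brute <- c(brute, paste(pr$study_id[i], notes$note_id[j]))
      }
    }
  }
  expect_setequal(paste(links$study_id, links$note_id), brute)

  shuffled <- link_notes(
    pr[sample(nrow(pr)), ], notes[sample(nrow(notes)), ]
  )
  expect_identical(shuffled, links)
})

test_that("facility screen computes coverage proportions and eligibility", {
  # facility A: 10 PFTs, 8 with an FEV1-containing linked note -> eligible
  # facility B: 4 PFTs, 1 FEV1 note -> not eligible
  # facility C: 2 PFTs, no linked notes -> proportion 0
  pr <- rbind(
    mini_procedures(sprintf("A%02d", 1:10),
      rep("2019-03-01", 10),
      patient = sprintf("pa%02d", 1:10), facility = "A"
    ),
    mini_procedures(sprintf("B%02d", 1:4),
      rep("2019-03-01", 4),
      patient = sprintf("pb%02d", 1:4), facility = "B"
    ),
    mini_procedures(sprintf("C%02d", 1:2),
      rep("2019-03-01", 2),
      patient = sprintf("pc%02d", 1:2), facility = "C"
    )
  )
  notes <- rbind(
    mini_notes(sprintf("na%02d", 1:10), rep("2019-03-02", 10),
      c(rep("Results: fev1 58%", 6), rep("FEV-1 normal", 2),
        rep("no lung data", 2)),
      patient = sprintf("pa%02d", 1:10), facility = "A"
    ),
    mini_notes("nb01", "2019-03-02", "fev 1 reported",
      patient = "pb01", facility = "B"
    )
  )
  # fewer facilities than the default top-36 -> screen them all, with warning
  expect_warning(screen_facilities(pr, notes, cohort_config()), "facilities")
  scr <- suppressWarnings(screen_facilities(pr, notes, cohort_config()))
  expect_identical(scr$facility_id, c("A", "B", "C"))
  expect_equal(scr$pft_count, c(10L, 4L, 2L))
  expect_equal(scr$fev1_note_count, c(8L, 1L, 0L))
  expect_equal(scr$proportion, c(0.8, 0.25, 0), tolerance = 1e-12)
  # 0.80 meets the inclusive threshold
  expect_identical(scr$eligible, c(TRUE, FALSE, FALSE))
  expect_true(all(scr$proportion >= 0 & scr$proportion <= 1))
  expect_lte(sum(scr$pft_count), nrow(pr))
})
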