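#' Synthetic corpus configuration
#'
#' Parameters of the seedable multi-facility note-corpus generator. The
#' default truth distribution mirrors the composition of a large
#' multi-facility extraction corpus: obstruction prevalence 0.707 and
#' severity-band weights proportional to 4535 / 3397 / 3663 / 3270 / 5547 /
#' 3317 studies (normal through very severe) with 1193 missing.
#'
#' @param n_facilities number of synthetic facilities; each is assigned a
#'   dialect from the shipped registry.
#' @param notes_per_facility studies (one note each) per facility.
#' @param seed integer seed fixing all randomness.
#' @param dialect_mix optional weights over the shipped dialects used when
#'   assigning facilities to dialects (default: uniform round-robin).
#' @param p_obstructed prevalence of true obstruction.
#' @param severity_weights named weights over severity bands incl. missing;
#'   normalized internally.
#' @param p_qualitative_only probability a templated note reports only a
#'   qualitative interpretation (no numeric values).
#' @param p_qualitative_sentence probability a quantitative note also
#'   carries an interpretation sentence.
#' @param p_post_bd_section probability a note includes a
#'   post-bronchodilator block with different (improved) values.
#' @param p_distractor_note probability a study's note is a distractor:
#'   FEV1 mentioned in prose, no templated results.
#' @param p_missing_value probability each quantitative value (ratio,
#'   percent predicted) is independently absent from the report.
#' @param p_structured fraction of procedures flagged as already having
#'   structured FEV1 results (excluded by the default cohort filter).
#' @return object of class `corpus_config`.
#' @export
corpus_config <- function(n_facilities = 4L, notes_per_facility = 50L,
                          seed = 20180101L,
                          dialect_mix = NULL,
                          p_obstructed = 0.707,
                          severity_weights = c(
                            normal = 4535, mild = 3397, moderate = 3663,
                            moderately_severe = 3270, severe = 5547,
                            very_severe = 3317, missing = 1193
                          ),
                          p_qualitative_only = 0.10,
                          p_qualitative_sentence = 0.50,
                          p_post_bd_section = 0.30,
                          p_distractor_note = 0.05,
                          p_missing_value = 0.05,
                          p_structured = 0.0) {
  probs <- c(
    p_obstructed = p_obstructed, p_qualitative_only = p_qualitative_only,
    p_qualitative_sentence = p_qualitative_sentence,
    p_post_bd_section = p_post_bd_section,
    p_distractor_note = p_distractor_note,
    p_missing_value = p_missing_value, p_structured = p_structured
  )
  if (any(probs < 0 | probs > 1)) {
    stop_pft(
      "probabilities must lie in [0, 1]: ",
      paste(names(probs)[probs < 0 | probs > 1], collapse = ", ")
    )
  }
  if (n_facilities < 1L || notes_per_facility < 1L) {
    stop_pft("n_facilities and notes_per_facility must be positive")
  }
  if (!setequal(names(severity_weights), severity_levels())) {
    stop_pft("severity_weights must name every severity band plus missing")
  }
  if (any(severity_weights < 0) || sum(severity_weights) <= 0) {
    stop_pft("severity_weights must be non-negative and sum > 0")
  }
  structure(
    list(
      n_facilities = as.integer(n_facilities),
      notes_per_facility = as.integer(notes_per_facility),
      seed = as.integer(seed),
      dialect_mix = dialect_mix,
      p_obstructed = p_obstructed,
      severity_weights = severity_weights / sum(severity_weights),
      p_qualitative_only = p_qualitative_only,
      p_qualitative_sentence = p_qualitative_sentence,
      p_post_bd_section = p_post_bd_section,
      p_distractor_note = p_distractor_note,
      p_missing_value = p_missing_value,
      p_structured = p_structured
    ),
    class = "corpus_config"
  )
}

band_pct_range <- function() {
  list(
    normal = c(80L, 120L), mild = c(70L, 79L), moderate = c(60L, 69L),
    moderately_severe = c(50L, 59L), severe = c(35L, 49L),
    very_severe = c(15L, 34L)
  )
}

obstruction_adjective <- function(severity) {
  c(
    mild = "mild", moderate = "moderate",
    moderately_severe = "moderately severe", severe = "severe",
    very_severe = "very severe"
  )[severity]
}

fev1_adverb <- function(severity) {
  c(
    mild = "mildly", moderate = "moderately",
    moderately_severe = "moderately-severely", severe = "severely",
    very_severe = "very severely"
  )[severity]
}

# Interpretation sentence consistent with the drawn classes; returns "" when
# there is nothing to say.
interpretation_sentence <- function(obstructed, severity) {
  parts <- character()
  if (obstructed) {
    adj <- obstruction_adjective(severity)
    parts <- c(parts, if (is.na(adj)) {
      "There is obstruction."
    } else {
      sprintf("There is %s obstruction.", adj)
    })
  } else {
    parts <- c(parts, "No evidence of obstruction.")
  }
  if (severity == "normal") {
    parts <- c(parts, "The FEV1 is normal.")
  } else if (severity != "missing") {
    parts <- c(parts, sprintf("The FEV1 is %s reduced.", fev1_adverb(severity)))
  }
  paste(parts, collapse = " ")
}

# Render the pre-BD results block, optional post-BD block and interpretation
# in one of the four shipped dialect styles. Values may be NA (omitted).
render_results <- function(style, liters, pct, ratio_pct, post,
                           interp) {
  frac <- function(rp) sprintf("%.2f", rp / 100)
  pre <- switch(style,
    block = paste0(
      "SPIROMETRY RESULTS:\n",
      if (!is.na(liters) && !is.na(pct)) {
        sprintf("  FEV1: %.2f L (%d%% predicted)\n", liters, pct)
      } else if (!is.na(liters)) {
        sprintf("  FEV1: %.2f L\n", liters)
      } else {
        ""
      },
      sprintf("  FVC: %.2f L\n", if (is.na(liters)) 3.1 else liters + 1.2),
      if (!is.na(ratio_pct)) sprintf("  FEV1/FVC: %d%%\n", ratio_pct) else ""
    ),
    tabular = paste0(
      "PFT REPORT - LUNG FUNCTION LABORATORY\n\nPRE-BRONCHODILATOR\n",
      if (!is.na(liters)) sprintf("FEV1 (L): %.2f\n", liters) else "",
      if (!is.na(pct)) sprintf("FEV1 %% Predicted: %d\n", pct) else "",
      if (!is.na(ratio_pct)) {
        sprintf("FEV1/FVC Ratio: %s\n", frac(ratio_pct))
      } else {
        ""
      }
    ),
    narrative = paste0(
      "Spirometry reveals",
      if (!is.na(liters) && !is.na(pct)) {
        sprintf(
          " an FEV1 of %.2f liters which is %d percent of predicted.",
          liters, pct
        )
      } else if (!is.na(liters)) {
        sprintf(" an FEV1 of %.2f liters.", liters)
      } else if (!is.na(pct)) {
        sprintf(
          " an FEV1 which is %d percent of predicted.", pct
        )
      } else {
        " the following."
      },
      if (!is.na(ratio_pct)) {
        sprintf(" The FEV1/FVC ratio is %d percent.", ratio_pct)
      } else {
        ""
      },
      "\n"
    ),
    compact = paste0(
      "LUNG FUNCTION SUMMARY\n",
      if (!is.na(liters) && !is.na(pct)) {
        sprintf("FEV1 = %.2f L / %d%%pred\n", liters, pct)
      } else if (!is.na(liters)) {
        sprintf("FEV1 = %.2f L\n", liters)
      } else if (!is.na(pct)) {
        sprintf("FEV1 pct = %d%%pred\n", pct)
      } else {
        ""
      },
      if (!is.na(ratio_pct)) {
        sprintf("FEV1:FVC = %s\n", frac(ratio_pct))
      } else {
        ""
      }
    )
  )
  post_block <- ""
  if (!is.null(post)) {
    post_block <- switch(style,
      block = sprintf(
        "POST-BRONCHODILATOR:\n  FEV1: %.2f L (%d%% predicted)\n  FEV1/FVC: %d%%\n",
        post$liters, post$pct, post$ratio_pct
      ),
      tabular = sprintf(
        "POST-BRONCHODILATOR\nFEV1 (L): %.2f\nFEV1 %% Predicted: %d\nFEV1/FVC Ratio: %s\n",
        post$liters, post$pct, frac(post$ratio_pct)
      ),
      narrative = sprintf(
        "Post-bronchodilator testing shows an FEV1 of %.2f liters which is %d percent of predicted.\n",
        post$liters, post$pct
      ),
      compact = sprintf(
        "POST-BD: FEV1 = %.2f L / %d%%pred\n",
        post$liters, post$pct
      )
    )
  }
  interp_block <- ""
  if (nzchar(interp)) {
    label <- switch(style,
      block = "Interpretation: ",
      tabular = "IMPRESSION: ",
      narrative = "",
      compact = "Impression: "
    )
    interp_block <- paste0("\n", label, interp, "\n")
  }
  paste0(pre, post_block, interp_block)
}

#' Generate a synthetic multi-facility note corpus with ground truth
#'
#' For each synthetic study the generator draws an obstruction status and a
#' severity band from the configured truth distribution, draws consistent
#' integer-percent values (ratio 40-69% when obstructed, 70-90% when not;
#' percent predicted uniform within the drawn band), renders a note in the
#' facility's dialect — templated anchor phrase, optional
#' post-bronchodilator block with improved values, optional interpretation
#' sentence, or a distractor note mentioning FEV1 in prose with no template
#' — and emits a matching procedure record plus a note dated within the
#' linkage window. The truth table records the drawn values and the
#' classification labels implied by what the note actually reports (derived
#' with [resolve()], so stored truth and classifier criteria can never
#' disagree).
#'
#' @param config a [corpus_config()].
#' @param registry_path dialect registry YAML (defaults to the shipped
#'   synthetic registry; entries must carry a `render_style` the generator
#'   knows: block, tabular, narrative, compact).
#' @return list of class `pft_corpus`: `notes`, `procedures`, `truth`
#'   (columns `study_id`, `true_ratio`, `true_pct_pred`, `true_obstruction`,
#'   `true_severity`, `note_kind`), `registry` (templates re-keyed to the
#'   generated facilities), `config`.
#' @export
generate_corpus <- function(config = corpus_config(),
                            registry_path = default_registry_path()) {
  raw <- yaml::read_yaml(registry_path)
  shipped <- load_registry(registry_path)
  styles <- vapply(raw$facilities, function(e) e$render_style %||% "block", "")
  names(styles) <- vapply(raw$facilities, function(e) e$facility_id, "")

  with_seed(config$seed, {
    n_dialects <- length(shipped)
    mix <- config$dialect_mix %||% rep(1, n_dialects)
    if (length(mix) != n_dialects) {
      stop_pft("dialect_mix must have one weight per shipped dialect")
    }
    fac_ids <- sprintf("F%02d", seq_len(config$n_facilities))
    fac_dialect <- if (is.null(config$dialect_mix)) {
      rep(seq_len(n_dialects), length.out = config$n_facilities)
    } else {
      sample(seq_len(n_dialects), config$n_facilities,
        replace = TRUE, prob = mix / sum(mix)
      )
    }

    registry <- lapply(seq_along(fac_ids), function(i) {
      tpl <- shipped[[fac_dialect[i]]]
      tpl$facility_id <- fac_ids[i]
      tpl
    })
    names(registry) <- fac_ids
    class(registry) <- "template_registry"

    n <- config$n_facilities * config$notes_per_facility
    study_fac <- rep(fac_ids, each = config$notes_per_facility)
    study_id <- sprintf("S%06d", seq_len(n))
    patient_id <- sprintf("P%06d", seq_len(n))
    note_id <- sprintf("N%06d", seq_len(n))
    proc_date <- as.Date("2018-01-01") +
      sample.int(as.integer(as.Date("2022-12-31") - as.Date("2018-01-01")) +
        1L, n, replace = TRUE) - 1L
    note_offset <- sample(-1:21, n, replace = TRUE)
    cpt <- sample(cohort_config()$cpt_codes, n, replace = TRUE)
    structured <- stats::runif(n) < config$p_structured

    bands <- names(config$severity_weights)
    sev <- sample(bands, n, replace = TRUE, prob = config$severity_weights)
    obstructed <- stats::runif(n) < config$p_obstructed
    kind_draw <- stats::runif(n)
    kind <- ifelse(kind_draw < config$p_distractor_note, "distractor",
      ifelse(kind_draw < config$p_distractor_note +
        config$p_qualitative_only, "qualitative_only", "templated")
    )

    ranges <- band_pct_range()
    texts <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      style <- styles[[names(shipped)[fac_dialect[match(
        study_fac[i], fac_ids
      )]]]]
      header <- sprintf(
        "PULMONARY CLINIC NOTE\nPatient: %s\nVisit date: %s\n\n",
        patient_id[i], format(proc_date[i] + note_offset[i])
      )
      if (kind[i] == "distractor") {
        texts[i] <- paste0(
          header,
          "Follow-up for chronic dyspnea. Home peak-flow and FEV1 trends ",
          "discussed; formal testing deferred to a later visit.\n"
        )
        truth[[i]] <- data.frame(
          study_id = study_id[i], true_ratio = NA_real_,
          true_pct_pred = NA_real_, true_obstruction = "missing",
          true_severity = "missing", note_kind = kind[i],
          stringsAsFactors = FALSE
        )
        next
      }

      ratio_pct <- if (obstructed[i]) {
        sample(40:69, 1L)
      } else {
        sample(70:90, 1L)
      }
      pct <- if (sev[i] == "missing") {
        NA_integer_
      } else {
        r <- ranges[[sev[i]]]
        sample(r[1]:r[2], 1L)
      }
      miss_ratio <- stats::runif(1) < config$p_missing_value
      miss_pct <- stats::runif(1) < config$p_missing_value

      if (kind[i] == "qualitative_only") {
        rendered_ratio <- NA_integer_
        rendered_pct <- NA_integer_
        interp <- interpretation_sentence(obstructed[i], sev[i])
      } else {
        rendered_ratio <- if (miss_ratio) NA_integer_ else ratio_pct
        rendered_pct <- if (miss_pct) NA_integer_ else pct
        interp <- if (stats::runif(1) < config$p_qualitative_sentence) {
          interpretation_sentence(obstructed[i], sev[i])
        } else {
          ""
        }
      }
      liters <- if (is.na(rendered_pct)) {
        if (kind[i] == "qualitative_only") NA_real_ else 2.4
      } else {
        round(max(0.5, min(5.9, rendered_pct / 100 * 3.2)), 2)
      }
      post <- NULL
      if (stats::runif(1) < config$p_post_bd_section &&
        kind[i] == "templated") {
        bump <- sample(3:12, 1L)
        post <- list(
          liters = round(min(6, (if (is.na(liters)) 2.4 else liters) * 1.08), 2),
          pct = min(150L, (if (is.na(rendered_pct)) 60L else rendered_pct) +
            bump),
          ratio_pct = min(95L, (if (is.na(rendered_ratio)) 60L else
            rendered_ratio) + bump)
        )
      }
      texts[i] <- paste0(
        header,
        render_results(
          style,
          liters = liters, pct = rendered_pct, ratio_pct = rendered_ratio,
          post = post, interp = interp
        )
      )

      # truth labels follow from what the note actually reports
      qual_obs <- "none_found"
      qual_fev <- "none_found"
      if (nzchar(interp)) {
        qual_obs <- if (!obstructed[i]) {
          "no_obstruction"
        } else if (sev[i] %in% c(
          "mild", "moderate", "moderately_severe", "severe", "very_severe"
        )) {
          sev[i]
        } else {
          "unspecified_obstruction"
        }
        qual_fev <- if (sev[i] == "missing") "none_found" else sev[i]
      }
      lab <- resolve(list(
        ratio_fraction = if (is.na(rendered_ratio)) {
          NA_real_
        } else {
          rendered_ratio / 100
        },
        fev1_pct_pred = if (is.na(rendered_pct)) {
          NA_real_
        } else {
          as.numeric(rendered_pct)
        },
        qualitative_obstruction = qual_obs,
        qualitative_fev1 = qual_fev
      ))
      truth[[i]] <- data.frame(
        study_id = study_id[i],
        true_ratio = if (is.na(rendered_ratio)) {
          NA_real_
        } else {
          rendered_ratio / 100
        },
        true_pct_pred = if (is.na(rendered_pct)) {
          NA_real_
        } else {
          as.numeric(rendered_pct)
        },
        true_obstruction = lab$obstruction,
        true_severity = lab$severity,
        note_kind = kind[i],
        stringsAsFactors = FALSE
      )
    }

    notes <- data.frame(
      note_id = note_id, patient_id = patient_id, facility_id = study_fac,
      note_date = proc_date + note_offset, text = texts,
      stringsAsFactors = FALSE
    )
    procedures <- data.frame(
      study_id = study_id, patient_id = patient_id,
      facility_id = study_fac, procedure_date = proc_date,
      cpt_code = cpt, has_structured_fev1 = structured,
      stringsAsFactors = FALSE
    )
    structure(
      list(
        notes = notes, procedures = procedures,
        truth = do.call(rbind, truth), registry = registry, config = config
      ),
      class = "pft_corpus"
    )
  })
}

#' Apply deterministic robustness perturbations to note texts
#'
#' Produces a noisy copy of the corpus notes for robustness testing: the
#' ground truth is unchanged, so extraction accuracy can be compared between
#' the clean and perturbed runs. Available perturbations: `whitespace_jitter`
#' (random doubling of spaces), `synonym_swap` ("FEV1/FVC" and "FEV1:FVC"
#' exchanged), `comma_separators` (thousands commas inserted into runs of 4+
#' digits), `percent_dropout` (percent signs replaced by spaces).
#'
#' @param notes note data.frame.
#' @param noise_config named logical list enabling perturbations; empty
#'   means identity.
#' @param seed RNG seed for the randomized perturbations.
#' @return note data.frame with perturbed `text`.
#' @export
perturb_corpus <- function(notes, noise_config = list(), seed = 1L) {
  txt <- notes$text
  with_seed(seed, {
    if (isTRUE(noise_config$synonym_swap)) {
      txt <- gsub("FEV1/FVC", "\u0001", txt, fixed = TRUE)
      txt <- gsub("FEV1:FVC", "FEV1/FVC", txt, fixed = TRUE)
      txt <- gsub("\u0001", "FEV1:FVC", txt, fixed = TRUE)
    }
    if (isTRUE(noise_config$percent_dropout)) {
      txt <- gsub("%", " ", txt, fixed = TRUE)
    }
    if (isTRUE(noise_config$comma_separators)) {
      txt <- vapply(txt, function(s) {
        gsub("(?<!\\d)(\\d{1,3})(\\d{3})(?!\\d)", "\\1,\\2", s, perl = TRUE)
      }, "", USE.NAMES = FALSE)
    }
    if (isTRUE(noise_config$whitespace_jitter)) {
      txt <- vapply(txt, function(s) {
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        dbl <- chars == " " & stats::runif(length(chars)) < 0.3
        chars[dbl] <- "  "
        paste(chars, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    notes$text <- txt
    notes
  })
}
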