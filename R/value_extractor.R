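default_pre_marker <- function() {
  "\\bPRE\\b[-: ]?(BRONCHODILATOR|BD)?"
}

#' Blank post-bronchodilator segments in a snippet
#'
#' Only pre-bronchodilator values are extracted. From each occurrence of a
#' post-bronchodilator marker, characters are replaced by spaces up to the
#' next pre-bronchodilator marker, the next blank line, or the end of the
#' snippet — whichever comes first. Newlines are preserved and text length
#' is unchanged, so every downstream offset still indexes the original
#' snippet.
#'
#' @param snippet_text snippet text.
#' @param template a [facility_template()]; its `pre_post_markers` define
#'   the post-bronchodilator markers (an empty list disables masking).
#' @param pre_marker pattern recognizing the return to pre-bronchodilator
#'   content.
#' @return the masked text, same length as the input.
#' @export
mask_post_bronchodilator <- function(snippet_text, template,
                                     pre_marker = default_pre_marker()) {
  markers <- template$pre_post_markers
  if (length(markers) == 0L) {
    return(snippet_text)
  }
  txt <- snippet_text
  n <- nchar(txt)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  post_starts <- integer()
  for (p in markers) {
    post_starts <- c(post_starts, all_matches(p, txt)$start)
  }
  if (length(post_starts) == 0L) {
    return(snippet_text)
  }
  pre_starts <- all_matches(pre_marker, txt)$start
  blank_lines <- all_matches("\\n[ \\t]*\\n", txt)$start
  for (s in sort(unique(post_starts))) {
    stops <- c(
      pre_starts[pre_starts > s],
      blank_lines[blank_lines > s],
      n
    )
    e <- min(stops) # 0-based start of the terminator (exclusive end of mask)
    idx <- seq.int(s + 1L, e) # 1-based character positions to blank
    keep_nl <- chars[idx] == "\n"
    chars[idx][!keep_nl] <- " "
  }
  paste(chars, collapse = "")
}

parse_reported_number <- function(s) {
  s <- gsub(",", "", s, fixed = TRUE)
  s <- gsub("%", "", s, fixed = TRUE)
  suppressWarnings(as.numeric(trimws(s)))
}

plausibility_ranges <- function() {
  list(
    fev1_liters = c(0.2, 10), # exclusive bounds
    fev1_pct_pred = c(5, 200),
    ratio_fraction = c(0.1, 1.5)
  )
}

#' Normalize a raw FEV1:FVC ratio to a fraction
#'
#' Report dialects print the ratio either as a fraction ("0.65") or as a
#' percent ("65" / "65%"). Values at most 1 are taken as fractions; values
#' in (1, 120\] are divided by 100; anything larger is implausible and
#' dropped (returned as `NA`).
#'
#' @param ratio_raw numeric ratio as printed.
#' @return fraction, or `NA_real_` when implausible.
#' @export
normalize_ratio <- function(ratio_raw) {
  if (is.na(ratio_raw)) {
    return(NA_real_)
  }
  if (ratio_raw <= 1) {
    return(ratio_raw)
  }
  if (ratio_raw <= 120) {
    return(ratio_raw / 100)
  }
  NA_real_
}

#' Extract quantitative spirometry values from a masked snippet
#'
#' Applies the dialect's value patterns to the (post-bronchodilator-masked)
#' snippet text. For each slot the first match wins; the captured number is
#' parsed tolerating comma thousands separators and a trailing percent sign.
#' Implausible values are dropped and recorded as events: FEV1 outside
#' (0.2, 10) liters, percent predicted outside (5, 200), and ratio outside
#' (0.1, 1.5) after percent normalization.
#'
#' @param masked_text snippet text after [mask_post_bronchodilator()].
#' @param template a [facility_template()].
#' @return list with `fev1_liters`, `fev1_pct_pred`, `ratio_raw`,
#'   `ratio_fraction` (each `NA` when absent), `provenance` (per-slot match
#'   text and 0-based snippet offset), and `events` (dropped-value log).
#' @export
extract_quantitative <- function(masked_text, template) {
  pats <- template$dialect_patterns
  out <- list(
    fev1_liters = NA_real_, fev1_pct_pred = NA_real_,
    ratio_raw = NA_real_, ratio_fraction = NA_real_,
    provenance = list(), events = character()
  )
  ranges <- plausibility_ranges()
  grab <- function(slot) {
    if (is.null(pats[[slot]])) {
      return(NULL)
    }
    m <- first_match(pats[[slot]], masked_text)
    if (is.null(m) || is.null(m$capture)) {
      return(NULL)
    }
    val <- parse_reported_number(m$capture)
    if (is.na(val)) {
      return(NULL)
    }
    list(value = val, match = m$text, offset = m$start)
  }

  h <- grab("fev1_liters")
  if (!is.null(h)) {
    r <- ranges$fev1_liters
    if (h$value > r[1] && h$value < r[2]) {
      out$fev1_liters <- h$value
      out$provenance$fev1_liters <- list(
        slot = "fev1_liters", match = h$match, offset = h$offset
      )
    } else {
      out$events <- c(out$events, sprintf(
        "fev1_liters value %g implausible, dropped", h$value
      ))
    }
  }

  h <- grab("fev1_pct_pred")
  if (!is.null(h)) {
    r <- ranges$fev1_pct_pred
    if (h$value > r[1] && h$value < r[2]) {
      out$fev1_pct_pred <- h$value
      out$provenance$fev1_pct_pred <- list(
        slot = "fev1_pct_pred", match = h$match, offset = h$offset
      )
    } else {
      out$events <- c(out$events, sprintf(
        "fev1_pct_pred value %g implausible, dropped", h$value
      ))
    }
  }

  h <- grab("ratio")
  if (!is.null(h)) {
    frac <- normalize_ratio(h$value)
    r <- ranges$ratio_fraction
    if (!is.na(frac) && frac > r[1] && frac < r[2]) {
      out$ratio_raw <- h$value
      out$ratio_fraction <- frac
      out$provenance$ratio <- list(
        slot = "ratio", match = h$match, offset = h$offset
      )
    } else {
      out$events <- c(out$events, sprintf(
        "ratio value %g implausible, dropped", h$value
      ))
    }
  }
  out
}

#' Path of the bundled qualitative descriptor lexicon
#' @return file path of the lexicon YAML shipped with the package.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "qualitative_lexicon.yml",
    package = "pftminer",
    mustWork = TRUE
  )
}

#' Load a qualitative descriptor lexicon
#'
#' The lexicon is an ordered list of `(pattern, category, applies_to)`
#' entries mapping descriptor phrases ("mild obstruction", "the FEV1 is
#' normal", "no evidence of obstruction") to the enumerated obstruction and
#' FEV1-severity categories. Order encodes precedence: longer, more specific
#' phrases ("moderately severe obstruction") must precede the phrases they
#' contain ("severe obstruction", "obstruction"); a match overlapping an
#' earlier entry's match is discarded. Negated phrasings are ordinary
#' entries mapping to `no_obstruction`, listed before the affirmative forms.
#'
#' @param path lexicon file (YAML); defaults to the bundled lexicon.
#' @return data.frame with columns `pattern`, `category`, `applies_to`, of
#'   class `pft_lexicon`.
#' @export
load_lexicon <- function(path = default_lexicon_path()) {
  raw <- yaml::read_yaml(path)
  entries <- raw$entries %||% raw
  df <- do.call(rbind, lapply(entries, function(e) {
    data.frame(
      pattern = e$pattern, category = e$category,
      applies_to = e$applies_to, stringsAsFactors = FALSE
    )
  }))
  ok_obs <- df$applies_to == "obstruction" &
    df$category %in% qual_obstruction_levels()
  ok_fev <- df$applies_to == "fev1" & df$category %in% qual_fev1_levels()
  if (!all(ok_obs | ok_fev)) {
    stop_pft(
      "invalid lexicon entry: ",
      df$pattern[which(!(ok_obs | ok_fev))[1]]
    )
  }
  for (p in df$pattern) {
    check <- pattern_compiles(p)
    if (!isTRUE(check)) {
      stop_pft("lexicon pattern does not compile: ", p, ": ", check)
    }
  }
  structure(df, class = c("pft_lexicon", "data.frame"))
}

# Collect all lexicon matches in `text`, honoring precedence: a match that
# overlaps a match of an earlier lexicon entry is dropped.
lexicon_matches <- function(text, lexicon) {
  hits <- list()
  taken <- data.frame(start = integer(), end = integer())
  for (i in seq_len(nrow(lexicon))) {
    mm <- all_matches(lexicon$pattern[i], text)
    if (nrow(mm) == 0L) next
    for (j in seq_len(nrow(mm))) {
      overlaps <- any(mm$start[j] < taken$end & mm$end[j] > taken$start)
      if (overlaps) next
      taken <- rbind(taken, mm[j, , drop = FALSE])
      hits[[length(hits) + 1L]] <- data.frame(
        entry = i,
        category = lexicon$category[i],
        applies_to = lexicon$applies_to[i],
        start = mm$start[j], end = mm$end[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(
      entry = integer(), category = character(),
      applies_to = character(), start = integer(), end = integer(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, hits)
}

#' Extract qualitative descriptors from a masked snippet
#'
#' Matches the lexicon against the snippet (optionally restricted to the
#' region from the dialect's `qualitative_section` pattern onward). Within
#' each target (`obstruction`, `fev1`) the descriptor whose match offset is
#' nearest the anchor wins; ties go to the earlier lexicon entry.
#'
#' @param masked_text snippet text after masking.
#' @param template a [facility_template()].
#' @param lexicon a [load_lexicon()] result.
#' @param anchor_offset 0-based offset of the anchor within the snippet.
#' @return list with `qualitative_obstruction`, `qualitative_fev1`
#'   (category strings; `"none_found"` when absent) and `provenance`.
#' @export
extract_qualitative <- function(masked_text, template,
                                lexicon = load_lexicon(),
                                anchor_offset = 0L) {
  region_start <- 0L
  qs <- template$dialect_patterns$qualitative_section
  if (!is.null(qs)) {
    m <- first_match(qs, masked_text)
    if (!is.null(m)) region_start <- m$start
  }
  region <- substr(masked_text, region_start + 1L, nchar(masked_text))
  hits <- lexicon_matches(region, lexicon)
  out <- list(
    qualitative_obstruction = "none_found",
    qualitative_fev1 = "none_found",
    provenance = list()
  )
  if (nrow(hits) == 0L) {
    return(out)
  }
  hits$start <- hits$start + region_start
  hits$end <- hits$end + region_start
  pick <- function(target) {
    h <- hits[hits$applies_to == target, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(NULL)
    }
    d <- abs(h$start - anchor_offset)
    h <- h[order(d, h$entry), , drop = FALSE]
    h[1, , drop = FALSE]
  }
  obs <- pick("obstruction")
  if (!is.null(obs)) {
    out$qualitative_obstruction <- obs$category
    out$provenance$qualitative_obstruction <- list(
      slot = "qualitative", match = substr(
        masked_text, obs$start + 1L, obs$end
      ),
      offset = obs$start
    )
  }
  fev <- pick("fev1")
  if (!is.null(fev)) {
    out$qualitative_fev1 <- fev$category
    out$provenance$qualitative_fev1 <- list(
      slot = "qualitative", match = substr(
        masked_text, fev$start + 1L, fev$end
      ),
      offset = fev$start
    )
  }
  out
}

#' Run the full value extraction over a snippet table
#'
#' For each snippet: masks post-bronchodilator segments, extracts
#' quantitative values and qualitative descriptors. Deterministic and pure —
#' identical snippets and templates give identical extractions.
#'
#' @param snippets data.frame from [extract_snippets()].
#' @param registry a `template_registry`.
#' @param lexicon a [load_lexicon()] result.
#' @return data.frame with one row per snippet: `study_id`, `fev1_liters`,
#'   `fev1_pct_pred`, `ratio_raw`, `ratio_fraction`,
#'   `qualitative_obstruction`, `qualitative_fev1`; attribute `events`
#'   collects dropped-value messages.
#' @export
extract_values <- function(snippets, registry, lexicon = load_lexicon()) {
  n <- nrow(snippets)
  out <- data.frame(
    study_id = character(n), fev1_liters = numeric(n),
    fev1_pct_pred = numeric(n), ratio_raw = numeric(n),
    ratio_fraction = numeric(n),
    qualitative_obstruction = character(n), qualitative_fev1 = character(n),
    stringsAsFactors = FALSE
  )
  events <- character()
  for (i in seq_len(n)) {
    tpl <- template_for(snippets$facility_id[i], registry)
    masked <- mask_post_bronchodilator(snippets$text[i], tpl)
    quant <- extract_quantitative(masked, tpl)
    qual <- extract_qualitative(masked, tpl, lexicon,
      anchor_offset = snippets$anchor_offset[i]
    )
    out$study_id[i] <- snippets$study_id[i]
    out$fev1_liters[i] <- quant$fev1_liters
    out$fev1_pct_pred[i] <- quant$fev1_pct_pred
    out$ratio_raw[i] <- quant$ratio_raw
    out$ratio_fraction[i] <- quant$ratio_fraction
    out$qualitative_obstruction[i] <- qual$qualitative_obstruction
    out$qualitative_fev1[i] <- qual$qualitative_fev1
    if (length(quant$events) > 0L) {
      events <- c(events, paste0(snippets$study_id[i], ": ", quant$events))
    }
  }
  attr(out, "events") <- events
  out
}
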