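#' Normalize note text for pattern matching
#'
#' Applies Unicode NFC normalization, converts CR/LF and bare CR line
#' endings to LF, and replaces non-breaking spaces with ordinary spaces.
#' Idempotent; all snippet offsets refer to the normalized text.
#'
#' @param raw character vector of note bodies.
#' @return normalized character vector.
#' @export
normalize_text <- function(raw) {
  x <- stringi::stri_trans_nfc(enc2utf8(raw))
  x <- gsub("\r\n", "\n", x, fixed = TRUE)
  x <- gsub("\r", "\n", x, fixed = TRUE)
  gsub("\u00a0", " ", x, fixed = TRUE)
}

#' Find the anchor phrase in a note
#'
#' Returns the span of the first match of the template's anchor pattern in
#' the (already normalized) note text, or `NULL` when the note is not a
#' templated PFT report. Only the first match is used: a snippet is one
#' window per note, so multiple studies listed in one note fall inside a
#' single window (a known limitation of the character-window approach).
#'
#' @param note_text normalized note text (single string).
#' @param template a [facility_template()].
#' @return list with 0-based half-open `start`/`end` offsets, or `NULL`.
#' @export
find_anchor <- function(note_text, template) {
  m <- first_match(template$anchor_pattern, note_text)
  if (is.null(m)) {
    return(NULL)
  }
  list(start = m$start, end = m$end)
}

#' Cut the character window around an anchor match
#'
#' Returns the snippet `note_text[max(0, start - before) : min(len, end +
#' after)]` in 0-based half-open coordinates: up to `before_chars` characters
#' of context before the match start and up to `after_chars` after the match
#' end, truncated at the note boundaries. The anchor match itself is always
#' fully contained in the snippet.
#'
#' @param note_text normalized note text.
#' @param span anchor span from [find_anchor()].
#' @param template a [facility_template()].
#' @return list of class `pft_snippet`: `text`, `snippet_start`,
#'   `snippet_end`, `anchor_start`, `anchor_end` (offsets into the
#'   normalized note), and `anchor_offset` (anchor start relative to the
#'   snippet).
#' @export
extract_snippet <- function(note_text, span, template) {
  n <- nchar(note_text)
  if (is.null(span) || span$start < 0L || span$end > n ||
    span$start >= span$end) {
    stop_pft("invalid anchor span")
  }
  s0 <- max(0L, span$start - template$before_chars)
  e0 <- min(n, span$end + template$after_chars)
  structure(
    list(
      text = substr(note_text, s0 + 1L, e0),
      snippet_start = s0,
      snippet_end = e0,
      anchor_start = span$start,
      anchor_end = span$end,
      anchor_offset = span$start - s0
    ),
    class = "pft_snippet"
  )
}

#' Cut snippets for all linked notes
#'
#' For each (study, note) link: looks up the facility's template (notes from
#' unregistered facilities are skipped and counted, never guessed),
#' normalizes the note body, finds the anchor, and cuts the window. One
#' snippet per study at most: when several linked notes of a study contain
#' an anchor, the earliest note (then lowest note id) wins.
#'
#' @param links linkage table from [link_notes()].
#' @param notes note data.frame.
#' @param registry a `template_registry`.
#' @return data.frame with columns `study_id`, `note_id`, `facility_id`,
#'   `text`, `anchor_start`, `anchor_end`, `anchor_offset`; attribute
#'   `counts` records `n_links`, `n_no_template`, `n_no_anchor`,
#'   `n_snippets`.
#' @export
extract_snippets <- function(links, notes, registry) {
  note_text <- stats::setNames(notes$text, notes$note_id)
  rows <- vector("list", nrow(links))
  n_no_template <- 0L
  n_no_anchor <- 0L
  if (nrow(links) > 0L) {
    for (i in seq_len(nrow(links))) {
      tpl <- template_for(links$facility_id[i], registry)
      if (is.null(tpl)) {
        n_no_template <- n_no_template + 1L
        next
      }
      txt <- normalize_text(note_text[[links$note_id[i]]])
      span <- find_anchor(txt, tpl)
      if (is.null(span)) {
        n_no_anchor <- n_no_anchor + 1L
        next
      }
      snip <- extract_snippet(txt, span, tpl)
      rows[[i]] <- data.frame(
        study_id = links$study_id[i],
        note_id = links$note_id[i],
        facility_id = links$facility_id[i],
        text = snip$text,
        anchor_start = snip$anchor_start,
        anchor_end = snip$anchor_end,
        anchor_offset = snip$anchor_offset,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(
      study_id = character(), note_id = character(),
      facility_id = character(), text = character(),
      anchor_start = integer(), anchor_end = integer(),
      anchor_offset = integer(), stringsAsFactors = FALSE
    )
  }
  # links arrive ordered by study, note_date, note_id: first hit wins
  out <- out[!duplicated(out$study_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(
    n_links = nrow(links),
    n_no_template = n_no_template,
    n_no_anchor = n_no_anchor,
    n_snippets = nrow(out)
  )
  out
}

#' Dump snippets as JSON-lines for audit
#'
#' @param snippets data.frame from [extract_snippets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snippets <- function(snippets, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(snippets))) {
    writeLines(
      jsonlite::toJSON(as.list(snippets[i, , drop = FALSE]),
        auto_unbox = TRUE
      ),
      con
    )
  }
  invisible(path)
}
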