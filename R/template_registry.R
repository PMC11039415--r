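dialect_slots <- function() {
  c("fev1_liters", "fev1_pct_pred", "ratio", "qualitative_section")
}

#' Construct a facility template
#'
#' A facility template is the data-driven form of a facility's PFT report
#' dialect: the anchor pattern that delineates the start of results, the
#' snippet window sizes, the named extraction patterns, and the markers that
#' flag post-bronchodilator segments. All patterns are compiled (checked)
#' eagerly so a bad pattern fails at construction, not mid-corpus.
#'
#' @param facility_id facility identifier.
#' @param anchor_pattern PCRE source string locating the start of results.
#' @param before_chars characters of context kept before the anchor match
#'   (default 150).
#' @param after_chars characters kept after the anchor match (default 1000).
#' @param dialect_patterns named list of PCRE source strings; allowed names:
#'   `fev1_liters`, `fev1_pct_pred`, `ratio`, `qualitative_section`. Value
#'   patterns must expose the numeric field as capture group 1.
#' @param pre_post_markers character vector of patterns flagging the start
#'   of a post-bronchodilator segment.
#' @return an object of class `facility_template`.
#' @export
facility_template <- function(facility_id, anchor_pattern,
                              before_chars = 150L, after_chars = 1000L,
                              dialect_patterns = list(),
                              pre_post_markers = character()) {
  if (before_chars < 0L || after_chars < 0L) {
    stop_pft("before_chars and after_chars must be non-negative")
  }
  check <- pattern_compiles(anchor_pattern)
  if (!isTRUE(check)) {
    stop_pft(
      "facility ", facility_id, ": anchor_pattern does not compile: ", check,
      class = "pftminer_template_error"
    )
  }
  extra <- setdiff(names(dialect_patterns), dialect_slots())
  if (length(extra) > 0L) {
    stop_pft(
      "facility ", facility_id, ": unknown dialect slot(s) ",
      paste(extra, collapse = ", "),
      class = "pftminer_template_error"
    )
  }
  for (slot in names(dialect_patterns)) {
    check <- pattern_compiles(dialect_patterns[[slot]])
    if (!isTRUE(check)) {
      stop_pft(
        "facility ", facility_id, ": pattern for slot '", slot,
        "' does not compile: ", check,
        class = "pftminer_template_error"
      )
    }
  }
  for (p in pre_post_markers) {
    check <- pattern_compiles(p)
    if (!isTRUE(check)) {
      stop_pft(
        "facility ", facility_id, ": pre_post_marker does not compile: ",
        check,
        class = "pftminer_template_error"
      )
    }
  }
  structure(
    list(
      facility_id = as.character(facility_id),
      anchor_pattern = anchor_pattern,
      before_chars = as.integer(before_chars),
      after_chars = as.integer(after_chars),
      dialect_patterns = dialect_patterns,
      pre_post_markers = as.character(pre_post_markers)
    ),
    class = "facility_template"
  )
}

#' Load a facility template registry
#'
#' Reads a YAML (or JSON) registry of facility dialects. Each entry under
#' `facilities:` supplies `facility_id`, `anchor_pattern`, optional
#' `before_chars`/`after_chars` (default 150/1000), `dialect_patterns`, and
#' `pre_post_markers`. All patterns compile at load time; an invalid pattern
#' is reported with its facility and slot. Duplicate facility entries are a
#' hard error — silent override would be an audit hazard.
#'
#' @param path path to the registry file.
#' @return named list of [facility_template()] objects, keyed by facility id,
#'   with class `template_registry`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop_pft("registry file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- raw$facilities %||% raw
  if (length(entries) == 0L) stop_pft("registry contains no facilities")
  templates <- lapply(entries, function(e) {
    if (is.null(e$facility_id) || is.null(e$anchor_pattern)) {
      stop_pft(
        "registry entry missing facility_id or anchor_pattern",
        class = "pftminer_template_error"
      )
    }
    facility_template(
      facility_id = e$facility_id,
      anchor_pattern = e$anchor_pattern,
      before_chars = e$before_chars %||% 150L,
      after_chars = e$after_chars %||% 1000L,
      dialect_patterns = e$dialect_patterns %||% list(),
      pre_post_markers = unlist(e$pre_post_markers) %||% character()
    )
  })
  ids <- vapply(templates, function(t) t$facility_id, "")
  if (anyDuplicated(ids)) {
    stop_pft(
      "duplicate facility entries in registry: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      class = "pftminer_template_error"
    )
  }
  names(templates) <- ids
  structure(templates, class = "template_registry")
}

#' Look up a facility's template
#'
#' Exact facility-id lookup. Facilities without a registered template return
#' `NULL`; their notes are skipped (and counted) downstream, never guessed at
#' with another facility's dialect.
#'
#' @param facility_id facility identifier.
#' @param registry a loaded [load_registry()] result.
#' @return a `facility_template` or `NULL`.
#' @export
template_for <- function(facility_id, registry) {
  registry[[as.character(facility_id)]]
}

#' Write a template registry back to YAML
#'
#' Inverse of [load_registry()]: serializes the templates so a generated or
#' edited registry can be shipped alongside a corpus.
#'
#' @param registry a `template_registry`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  entries <- lapply(unname(registry), function(t) {
    list(
      facility_id = t$facility_id,
      anchor_pattern = t$anchor_pattern,
      before_chars = t$before_chars,
      after_chars = t$after_chars,
      dialect_patterns = t$dialect_patterns,
      pre_post_markers = as.list(t$pre_post_markers)
    )
  })
  yaml::write_yaml(list(facilities = entries), path)
  invisible(path)
}

#' Path of the synthetic example registry shipped with the package
#'
#' The shipped registry holds synthetic reconstructions of several plausible
#' facility report dialects (no real facility's template is reproduced); the
#' synthetic corpus generator renders notes in these dialects.
#'
#' @return file path of the bundled registry YAML.
#' @export
default_registry_path <- function() {
  system.file("extdata", "synthetic_templates.yml",
    package = "pftminer",
    mustWork = TRUE
  )
}

#' Load the bundled synthetic dialect registry
#' @return a `template_registry`.
#' @export
default_registry <- function() load_registry(default_registry_path())
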