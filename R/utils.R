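#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed report percentages use the
#' conventional half-away-from-zero rule, so headline proportions go through
#' this helper to keep reported one-decimal values stable.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under `seed` without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stop_pft <- function(..., class = "pftminer_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Validate that a regex source string compiles under PCRE; returns TRUE or
# the compilation error message.
pattern_compiles <- function(pattern) {
  res <- tryCatch(
    {
      regexpr(pattern, "", perl = TRUE)
      TRUE
    },
    error = function(e) conditionMessage(e),
    warning = function(w) conditionMessage(w)
  )
  res
}

# First PCRE match of `pattern` in `text`; NULL if none.
# Returns 0-based half-open [start, end) plus the first capture group when
# the pattern has one.
first_match <- function(pattern, text, ignore_case = TRUE) {
  m <- regexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)
  if (m[1] == -1L) {
    return(NULL)
  }
  out <- list(
    start = m[1] - 1L,
    end = m[1] - 1L + attr(m, "match.length"),
    text = substr(text, m[1], m[1] + attr(m, "match.length") - 1L)
  )
  cs <- attr(m, "capture.start")
  if (!is.null(cs) && ncol(cs) >= 1L && cs[1, 1] > 0L) {
    cl <- attr(m, "capture.length")
    out$capture <- substr(text, cs[1, 1], cs[1, 1] + cl[1, 1] - 1L)
  }
  out
}

# All PCRE matches as a data.frame of 0-based half-open spans.
all_matches <- function(pattern, text, ignore_case = TRUE) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length")
  )
}

# Parse an ISO-8601 date column strictly; returns Date with NA where invalid.
parse_iso_date <- function(x) {
  x <- as.character(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  # as.Date() silently wraps some impossible dates on certain platforms;
  # round-trip to be strict.
  bad <- !is.na(d) & format(d, "%Y-%m-%d") != x
  d[bad] <- as.Date(NA)
  d
}

obstruction_levels <- function() c("obstructed", "not_obstructed", "missing")

severity_levels <- function() {
  c(
    "normal", "mild", "moderate", "moderately_severe",
    "severe", "very_severe", "missing"
  )
}

source_levels <- function() c("quantitative", "qualitative", "none")

qual_obstruction_levels <- function() {
  c(
    "none_found", "no_obstruction", "mild", "moderate", "moderately_severe",
    "severe", "very_severe", "unspecified_obstruction"
  )
}

qual_fev1_levels <- function() {
  c(
    "none_found", "normal", "mild", "moderate", "moderately_severe",
    "severe", "very_severe"
  )
}
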