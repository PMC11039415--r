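---
title: "Extracting spirometry results from templated clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting spirometry results from templated clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pftminer)
```

## The extraction model

`pftminer` treats PFT report extraction as a deterministic, rule-based
pipeline rather than a statistical NLP problem. The underlying assumption
is that within one facility, PFT results are pasted into notes by the same
laboratory system and therefore follow a stable template: a recognizable
phrase opens the results section, and the values appear in a fixed local
syntax. Under that assumption, per-facility regular expressions applied to
a bounded character window around the anchor phrase are both more precise
and more auditable than corpus-trained models — every extracted value can
be traced to the exact matched text and offset, which the package records
as provenance.

The pipeline stages and the parameters that matter:

* **Procedure filter.** Spirometry-related CPT codes
  (94010, 94375, 94060, 94726, 94727, 94729, 94150) select PFT studies;
  studies whose FEV1 already exists as structured data are excluded
  (`exclude_structured = TRUE`) because they need no text extraction.
* **Note linkage.** Notes within a closed window of −1 to +21 days around
  the procedure date are candidates. Both endpoints are inclusive: a
  window phrased in whole days most naturally includes its bounds, and the
  −1 day accommodates notes timestamped the evening before an early-morning
  test.
* **Facility screen.** Among the `top_n_facilities` (default 36) by PFT
  volume, a facility is worth template development when at least 80% of
  its PFTs have a linked note containing an FEV1 token. The threshold is
  applied inclusively (≥ 0.80) and the comparator is configurable, since
  either convention is defensible; the token match is case-insensitive and
  tolerates "FEV-1"/"FEV 1". Ranking ties break lexicographically by
  facility id so the screen is deterministic.
* **Snippet window.** Up to 150 characters before the anchor match start
  and 1000 after the match end, truncated at note boundaries. Measuring
  "after" from the match *end* guarantees the anchor itself is always
  inside the snippet. Only the first anchor match produces a snippet: the
  pipeline deliberately does not partition multiple dated studies inside
  one window (a known limitation of the character-window design), so a
  single window per note is the reproducible choice. Offsets are 0-based
  and half-open throughout, and always refer to the normalized text
  (NFC, LF line endings, no-break spaces collapsed); raw note bodies are
  never modified, so the stored notes stay byte-faithful for audit.
* **Post-bronchodilator masking.** Only pre-bronchodilator values are
  wanted. From each post-bronchodilator marker, characters are blanked to
  the next pre-bronchodilator marker, blank line, or snippet end; newlines
  and total length are preserved so all offsets remain valid.
* **Value extraction.** Within each pattern slot the first match wins,
  consistent with the single-window design. Number parsing tolerates comma
  separators and percent signs. Implausible captures are dropped and
  logged rather than propagated: FEV1 outside (0.2, 10) liters, percent
  predicted outside (5, 200), ratio outside (0.1, 1.5) after
  normalization. These ranges are this package's own guards against loose
  patterns capturing page numbers or dates; they are configurable in
  spirit (stored in one internal table) and generous enough that no
  physiologic value is rejected.
* **Ratio normalization.** Reports print the FEV1:FVC ratio either as a
  fraction ("0.65") or as a percent ("65%"). Values ≤ 1 are taken as
  fractions; values in (1, 120] are divided by 100; larger values are
  implausible. The plausibility gate is applied after this normalization —
  applying it to the raw value would wrongly reject the percent form.
* **Qualitative lexicon.** Descriptor phrases are data, not code: an
  ordered YAML lexicon maps phrase patterns to obstruction and
  FEV1-severity categories. Order encodes longest-match precedence
  ("moderately severe obstruction" must never degrade to "severe
  obstruction"), implemented by discarding any match that overlaps an
  earlier entry's match. Negation is handled the same way: "no evidence of
  obstruction" is an ordinary entry mapping to `no_obstruction`, listed
  before the affirmative forms. When several descriptors survive, the one
  nearest the anchor wins — the phrase adjacent to the results block is
  the one describing this study.
* **Classification.** Obstruction is a strict FEV1:FVC < 0.70; severity
  follows the ATS/ERS 2005 percent-predicted bands. The guideline prints
  integer ranges ("70–79%"), which under-determine the real line; the
  bands are realized as half-open intervals \[80, ∞), \[70, 80), \[60, 70),
  \[50, 60), \[35, 50), (0, 35), which recover the printed integer ranges
  exactly and classify non-integer values (79.5 → mild) deterministically.
  Quantitative values always take priority over qualitative descriptors;
  a conflicting descriptor is recorded as a discordance event but never
  changes the call. When no quantitative value exists the descriptor
  decides, and a *graded* obstruction descriptor ("severe obstruction")
  also supplies the severity band — a bare "obstruction" leaves severity
  missing, since grading it would invent information.

## The synthetic corpus

Because no real note corpus can ship with the package, the generator in
`generate_corpus()` is a first-class module that emulates the features the
pipeline must handle: multiple facilities with different report dialects
(a block template, a tabular pre/post layout, a narrative style and a
compact summary style), post-bronchodilator blocks with different values,
interpretation sentences, qualitative-only reports, distractor notes that
mention FEV1 in prose without a templated report, and per-value
missingness.

Default truth distribution: obstruction prevalence 0.707 and
severity-band weights proportional to 4535 / 3397 / 3663 / 3270 / 5547 /
3317 with 1193 missing — the composition of a large multi-facility
extraction corpus, so the generated class mix is realistic rather than
uniform. True values are drawn as integer percents uniformly within the
drawn class (ratio 40–69% when obstructed, 70–90% when not; percent
predicted uniform within its band, with 80–120 for normal and 15–34 for
very severe), which keeps rendered text and stored truth exactly equal and
avoids boundary ambiguity from rounding. Rates the generator needs but
that have no canonical value are package choices, documented here:
10% qualitative-only notes, 50% of quantitative notes carry an
interpretation sentence, 30% post-bronchodilator blocks, 5% distractor
notes, 5% per-value missingness. The stored truth labels are derived by
applying the package's own classification rules to what each note
actually reports (`resolve()`), which makes truth and criteria consistent
by construction; the test suite additionally re-derives the labels from
the stored values as an internal-consistency check.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: OCR noise and typos, template drift over
time within a facility, multiple dated studies pasted into one note,
copy-forwarded stale results, and genuinely novel dialects. On real notes
the pipeline's accuracy is bounded by how well the registry's patterns
describe each facility; the synthetic corpus shows the *machinery* is
exact when the patterns match, not that any fixed pattern set covers an
unseen hospital. The perturbation harness (`perturb_corpus()`:
whitespace jitter, "FEV1/FVC"↔"FEV1:FVC" swaps, thousands commas,
percent-sign dropout) probes robustness only to variation the shipped
patterns were written to absorb.

## Numerical and design choices

* Percent rounding for reported proportions is half-away-from-zero to one
  decimal (`round_half_up()`), matching how report percentages are
  conventionally printed and keeping replay comparisons stable; base R's
  round-half-even would turn 70.65 into 70.6.
* Degenerate inputs are defined, not errors: an empty classification
  table tabulates to all zeros (proportions are then an explicit error),
  a facility with no linked notes has coverage 0, a note without an
  anchor yields no snippet, and a study without a usable snippet
  classifies as missing on both axes.
* Facilities without a registered template are skipped and counted, never
  guessed at with another facility's dialect.
* Duplicate facility entries in a registry are a hard load error; silent
  override would be an audit hazard.
* The validation sampler draws a simple random sample (seeded, without
  replacement); stratification by facility was considered and not adopted
  because the agreement statistic is corpus-level. Missing-vs-missing
  counts as agreement: correctly determining that a value is absent is
  part of the task.
* All randomness flows through explicit seeds (`corpus_config(seed=)`,
  `perturb_corpus(seed=)`, `validate_against_truth(seed=)`), and seeded
  code restores the caller's RNG state.

## Problem sizes

The shipped test suite exercises the oracle comparisons on fixtures of a
few dozen to a few hundred records (e.g. 40 procedures × 120 notes for the
all-pairs linkage oracle, 200 records for the tabulation oracle) and runs
the end-to-end recovery check on a 2,000-study, 5-facility corpus — large
enough that every dialect, note kind and fallback path appears hundreds of
times, while keeping a full test run under a minute. The acceptance script
uses the same 2,000-study scale.

## Known limitations

* One snippet per note: sequential studies in a single note are not
  partitioned; the first anchor wins.
* No extraction of FVC in liters, DLCO, lung volumes, or bronchodilator
  response; the registry schema's four slots are deliberately minimal.
* The fixed 0.70 ratio threshold and ATS/ERS bands are the only
  interpretation scheme; lower-limit-of-normal or z-score interpretation
  is out of scope (the threshold value itself is configurable).
* Qualitative severity mapping trusts the report's own wording; a
  facility that grades severity by different cutoffs than the bands above
  would introduce label noise the pipeline cannot detect.
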