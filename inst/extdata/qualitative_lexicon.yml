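# Qualitative descriptor lexicon.
#
# Ordered: longer/more specific phrases and negated phrasings come first;
# a match overlapping an earlier entry's match is discarded, which gives
# longest-match precedence ("moderately severe obstruction" never degrades
# to "severe obstruction", "no evidence of obstruction" never degrades to
# "obstruction").
entries:
  # --- negated / normal obstruction phrasings ---
  - pattern: "no\\s+(?:evidence\\s+of\\s+)?(?:airflow\\s+)?obstruct(?:ion|ive)"
    category: no_obstruction
    applies_to: obstruction
  - pattern: "without\\s+(?:evidence\\s+of\\s+)?(?:airflow\\s+)?obstruction"
    category: no_obstruction
    applies_to: obstruction
  - pattern: "normal\\s+spirometry"
    category: no_obstruction
    applies_to: obstruction
  - pattern: "spirometry\\s+is\\s+normal"
    category: no_obstruction
    applies_to: obstruction
  # --- graded obstruction, longest first ---
  - pattern: "(?:moderately[- ]severe|moderate[- ]to[- ]severe)\\s+(?:airflow\\s+)?obstruct(?:ion|ive)"
    category: moderately_severe
    applies_to: obstruction
  - pattern: "very\\s+severe\\s+(?:airflow\\s+)?obstruct(?:ion|ive)"
    category: very_severe
    applies_to: obstruction
  - pattern: "severe\\s+(?:airflow\\s+)?obstruct(?:ion|ive)"
    category: severe
    applies_to: obstruction
  - pattern: "moderate\\s+(?:airflow\\s+)?obstruct(?:ion|ive)"
    category: moderate
    applies_to: obstruction
  - pattern: "mild\\s+(?:airflow\\s+)?obstruct(?:ion|ive)"
    category: mild
    applies_to: obstruction
  - pattern: "obstruct(?:ion|ive)(?:\\s+(?:airway|ventilatory)\\s+defect)?"
    category: unspecified_obstruction
    applies_to: obstruction
  # --- FEV1 severity descriptors, longest first ---
  - pattern: "FEV[ -]?1\\s+is\\s+(?:normal|within\\s+normal\\s+limits)"
    category: normal
    applies_to: fev1
  - pattern: "FEV[ -]?1\\s+is\\s+moderately[- ]severely\\s+(?:reduced|decreased)"
    category: moderately_severe
    applies_to: fev1
  - pattern: "FEV[ -]?1\\s+is\\s+very\\s+severely\\s+(?:reduced|decreased)"
    category: very_severe
    applies_to: fev1
  - pattern: "FEV[ -]?1\\s+is\\s+severely\\s+(?:reduced|decreased)"
    category: severe
    applies_to: fev1
  - pattern: "FEV[ -]?1\\s+is\\s+moderately\\s+(?:reduced|decreased)"
    category: moderate
    applies_to: fev1
  - pattern: "FEV[ -]?1\\s+is\\s+mildly\\s+(?:reduced|decreased)"
    category: mild
    applies_to: fev1
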