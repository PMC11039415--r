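# Synthetic facility dialect registry.
#
# These dialects are plausible reconstructions of templated PFT report
# styles; no real facility's note template is reproduced here. The
# synthetic corpus generator renders notes in these dialects, keyed by the
# render_style field (ignored by the registry loader's template fields).
#
# Value patterns expose the numeric field as capture group 1. Literal
# whitespace is written \s+ so whitespace jitter does not break matching;
# percent signs are optional so percent-sign dropout does not either.
facilities:
  - facility_id: FAC_A
    render_style: block
    anchor_pattern: "SPIROMETRY\\s+RESULTS:"
    before_chars: 150
    after_chars: 1000
    dialect_patterns:
      fev1_liters: "FEV[ -]?1:\\s*([0-9]+(?:\\.[0-9]+)?)\\s*L\\b"
      fev1_pct_pred: "FEV[ -]?1:[^\\n]*?\\(\\s*([0-9]+(?:\\.[0-9]+)?)\\s*%?\\s*predicted\\s*\\)"
      ratio: "FEV[ -]?1\\s*[/:]\\s*FVC:?\\s*([0-9]+(?:\\.[0-9]+)?)\\s*%?"
      qualitative_section: "Interpretation:"
    pre_post_markers:
      - "POST[- ]?(?:BRONCHODILATOR|BD)"
  - facility_id: FAC_B
    render_style: tabular
    anchor_pattern: "PFT\\s+REPORT\\s+-\\s+LUNG\\s+FUNCTION\\s+LABORATORY"
    dialect_patterns:
      fev1_liters: "FEV[ -]?1\\s+\\(L\\):\\s*([0-9]+(?:\\.[0-9]+)?)"
      fev1_pct_pred: "FEV[ -]?1\\s+%?\\s*Predicted:\\s*([0-9]+(?:\\.[0-9]+)?)"
      ratio: "FEV[ -]?1\\s*[/:]\\s*FVC\\s+Ratio:\\s*([0-9]+(?:\\.[0-9]+)?)"
      qualitative_section: "IMPRESSION:"
    pre_post_markers:
      - "POST[- ]?(?:BRONCHODILATOR|BD)"
  - facility_id: FAC_C
    render_style: narrative
    anchor_pattern: "Spirometry\\s+(?:reveals|shows|demonstrates)"
    dialect_patterns:
      fev1_liters: "FEV[ -]?1\\s+of\\s+([0-9]+(?:[.,][0-9]+)?)\\s*liters?"
      fev1_pct_pred: "which\\s+is\\s+([0-9]+(?:\\.[0-9]+)?)\\s*(?:%|percent)?\\s+of\\s+(?:the\\s+)?predicted"
      ratio: "FEV[ -]?1\\s*[/:]\\s*FVC\\s+ratio\\s+(?:is|of)\\s+([0-9]+(?:\\.[0-9]+)?)\\s*(?:%|percent)?"
    pre_post_markers:
      - "Post[- ]?bronchodilator"
  - facility_id: FAC_D
    render_style: compact
    anchor_pattern: "LUNG\\s+FUNCTION\\s+SUMMARY"
    dialect_patterns:
      fev1_liters: "FEV[ -]?1\\s*=\\s*([0-9]+(?:\\.[0-9]+)?)\\s*L\\b"
      fev1_pct_pred: "([0-9]+(?:\\.[0-9]+)?)\\s*%?\\s*pred\\b"
      ratio: "FEV[ -]?1\\s*[:/]\\s*FVC\\s*=\\s*([0-9]+(?:\\.[0-9]+)?)"
      qualitative_section: "Impression:"
    pre_post_markers:
      - "POST[- ]?BD"
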