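# AACE/ACE-AME 2016 (Gharib et al., Endocr Pract 2016). Three classes:
# high requires at least one high-risk feature; low covers cystic/spongiform
# patterns; everything else is intermediate.
system: AACE
version: "2016.1"
kind: pattern
suspicious_features: [microcalcifications, taller_than_wide, irregular_margins, marked_hypoechogenicity, extrathyroidal_extension]
rules:
  - {when: {suspicious: true}, class: high}
  - {when: {composition: [cystic, spongiform]}, class: low}
  - {when: {}, class: intermediate}
classes: [low, intermediate, high]
ordinal_rank: {low: 1, intermediate: 2, high: 3}
fna_threshold:
  low: {rule: gt, mm: 20}
  intermediate: {rule: gt, mm: 20}
  high: {rule: ge, mm: 10}
macro_risk: {low: low, intermediate: intermediate, high: high}
sparing_excluded_classes: []
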