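# K-TIRADS (Korean Society of Thyroid Radiology, Shin et al. 2016).
# Pattern lattice over composition x solid-portion echogenicity x suspicious features.
# Class 1 (no nodule) is not representable; classes as used for actual nodules.
system: KTIRADS
version: "2016.1"
kind: pattern
suspicious_features: [microcalcifications, taller_than_wide, irregular_margins, extrathyroidal_extension]
rules:   # first match wins
  - {when: {composition: [cystic, spongiform], suspicious: false}, class: "2"}
  - {when: {composition: [solid], echogenicity: [slightly_hypoechoic, hypoechoic, markedly_hypoechoic], suspicious: true}, class: "5"}
  - {when: {composition: [solid], suspicious: true}, class: "4"}
  - {when: {composition: [solid], echogenicity: [slightly_hypoechoic, hypoechoic, markedly_hypoechoic]}, class: "4"}
  - {when: {composition: [solid]}, class: "3"}
  - {when: {suspicious: true}, class: "4"}   # partially cystic (or calcified cystic pattern)
  - {when: {}, class: "3"}                   # partially cystic, no suspicious feature
classes: ["2", "3", "4", "5"]
ordinal_rank: {"2": 1, "3": 2, "4": 3, "5": 4}
fna_threshold:
  "2": {rule: ge, mm: 20}
  "3": {rule: ge, mm: 15}
  "4": {rule: ge, mm: 10}
  "5": {rule: ge, mm: 10}
# class 4 pooled with the high-risk macro group: its expected-malignancy band
# (15-50%) straddles the 20% macro cut and is treated as high risk
macro_risk: {"2": low, "3": intermediate, "4": high, "5": high}
sparing_excluded_classes: []
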