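# EU-TIRADS (European Thyroid Association, Russ et al. 2017).
# Any high-risk feature puts the nodule in class 5 regardless of composition;
# class 1 (no nodule) is not representable.
system: EUTIRADS
version: "2017.1"
kind: pattern
suspicious_features: [microcalcifications, taller_than_wide, irregular_margins, marked_hypoechogenicity, extrathyroidal_extension]
rules:
  - {when: {composition: [cystic, spongiform], suspicious: false}, class: "2"}
  - {when: {suspicious: true}, class: "5"}
  - {when: {echogenicity: [slightly_hypoechoic, hypoechoic]}, class: "4"}
  - {when: {}, class: "3"}
classes: ["2", "3", "4", "5"]
ordinal_rank: {"2": 1, "3": 2, "4": 3, "5": 4}
fna_threshold:
  "2": {rule: never}
  "3": {rule: gt, mm: 20}
  "4": {rule: gt, mm: 15}
  "5": {rule: gt, mm: 10}
macro_risk: {"2": low, "3": low, "4": intermediate, "5": high}
sparing_excluded_classes: []
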