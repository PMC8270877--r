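# ATA 2015 sonographic patterns (Haugen et al., Thyroid 2016).
# Not a total function: bundles outside the published patterns (e.g. iso/hyperechoic
# nodules with microcalcifications or irregular margins; mixed nodules whose solid
# portion eccentricity is doubtful) return the UNCLASSIFIABLE sentinel.
system: ATA
version: "2015.1"
kind: pattern
suspicious_features: [microcalcifications, taller_than_wide, irregular_margins, extrathyroidal_extension, rim_calcification]
rules:
  - {when: {composition: [cystic], suspicious: false}, class: benign}
  - {when: {composition: [spongiform], suspicious: false}, class: very_low}
  - {when: {composition: [mixed], eccentric: [na]}, class: UNCLASSIFIABLE}
  - {when: {composition: [solid, mixed], echogenicity: [slightly_hypoechoic, hypoechoic, markedly_hypoechoic], suspicious: true}, class: high}
  - {when: {composition: [solid], echogenicity: [slightly_hypoechoic, hypoechoic, markedly_hypoechoic], suspicious: false}, class: intermediate}
  - {when: {composition: [solid], echogenicity: [isoechoic, hyperechoic], suspicious: false}, class: low}
  - {when: {composition: [mixed], suspicious: false, eccentric: ["true"]}, class: low}
  - {when: {composition: [mixed], suspicious: false, eccentric: ["false"]}, class: very_low}
  - {when: {}, class: UNCLASSIFIABLE}
classes: [benign, very_low, low, intermediate, high]
ordinal_rank: {benign: 1, very_low: 2, low: 3, intermediate: 4, high: 5}
fna_threshold:
  benign: {rule: never}
  very_low: {rule: ge, mm: 20}
  low: {rule: ge, mm: 15}
  intermediate: {rule: ge, mm: 10}
  high: {rule: ge, mm: 10}
macro_risk: {benign: low, very_low: low, low: intermediate, intermediate: intermediate, high: high}
sparing_excluded_classes: [benign]
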