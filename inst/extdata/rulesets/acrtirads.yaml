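# ACR TI-RADS (American College of Radiology, Tessler et al. 2017).
# Additive point system: one value per feature category, echogenic foci additive.
system: ACRTIRADS
version: "2017.1"
kind: points
points:
  composition:
    cystic: 0
    spongiform: 0
    mixed: 1
    solid: 2
  echogenicity:
    anechoic: 0
    hyperechoic: 1
    isoechoic: 1
    slightly_hypoechoic: 2
    hypoechoic: 2
    markedly_hypoechoic: 3
  shape:
    wider_than_tall: 0
    taller_than_wide: 3
  margins:
    smooth: 0
    irregular_or_blurred: 2
    lobulated: 2
    extrathyroidal_extension: 3
  echogenic_foci:            # additive across all foci present
    none: 0
    hyperechoic_spot_comet: 0
    macrocalcification: 1
    rim_calcification_with_extrusion: 2
    microcalcification_punctate: 3
bands:                       # total points -> class; 1 point is unreachable under
  - {class: TR1, min_points: 0, max_points: 1}   # the canonical table but maps to TR1
  - {class: TR2, min_points: 2, max_points: 2}
  - {class: TR3, min_points: 3, max_points: 3}
  - {class: TR4, min_points: 4, max_points: 6}
  - {class: TR5, min_points: 7, max_points: 999}
classes: [TR1, TR2, TR3, TR4, TR5]
ordinal_rank: {TR1: 1, TR2: 2, TR3: 3, TR4: 4, TR5: 5}
fna_threshold:
  TR1: {rule: never}
  TR2: {rule: never}
  TR3: {rule: ge, mm: 25}
  TR4: {rule: ge, mm: 15}
  TR5: {rule: ge, mm: 10}
macro_risk: {TR1: low, TR2: low, TR3: intermediate, TR4: intermediate, TR5: high}
sparing_excluded_classes: []
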