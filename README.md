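# nustriage

Rule-based thyroid nodule ultrasound risk scores and FNA triage evaluation.

Thyroid nodules are common, mostly benign, and heavily over-investigated:
the incidental detection of small differentiated thyroid cancers has risen
sharply while mortality has not. Nodule ultrasound scores (NUS, generically
"TIRADS") map sonographic features — composition, echogenicity, margins,
shape, echogenic foci — plus size to a malignancy-risk class and a
recommendation on whether fine-needle aspiration (FNA) cytology is
indicated. `nustriage` implements five published systems on one harmonized
feature lexicon and quantifies how each would triage a cohort of nodules
that all actually underwent FNA: how many cytologies each score would have
*spared*, and at what diagnostic cost.

It is intended for endocrinologists, radiologists and biostatisticians
auditing score performance on retrospective FNA cohorts, and for method
developers who need a reproducible rule engine plus the standard diagnostic
statistics around it.

## What it implements

* **Five classifiers** driven by versioned, checksummed rule tables (YAML
  data, not code): K-TIRADS (classes 2–5), ATA 2015 (benign … high
  suspicion, with an explicit `UNCLASSIFIABLE` sentinel for bundles outside
  the published patterns), AACE/ACE-AME (low/intermediate/high), EU-TIRADS
  (2–5), and ACR TI-RADS (additive 0–14 points banded into TR1–TR5).
* **FNA indication**: per-class size thresholds with the exact strictness
  each guideline prints (e.g. K-TIRADS 3 at ≥ 15 mm, EU-TIRADS 3 strictly
  > 20 mm, ACR TR1–TR2 never).
* **Cytology dichotomization**: positive = TIR3B/TIR4/TIR5 (or pre-2014
  Thy3/Thy4/Thy5 under the British scheme); negative = TIR2 or two
  consecutive TIR3A; single unconfirmed TIR3A is `unresolved`; TIR1/Thy1
  only is `nondiagnostic`. Eligibility filtering (≥ 10 mm, complete
  description, diagnostic cytology) and a post-2014 SIAPEC-only sub-cohort
  mode are included.
* **Metrics**: per-class malignancy rates; expected/observed/spared FNA
  accounting; sensitivity, specificity, PPV, NPV with Wald intervals
  (p ± z·√(p(1−p)/n)); ordinal ROC/AUC by the rank concordance estimator
  (ties ½) with Hanley–McNeil intervals; unweighted Cohen's κ with
  Landis–Koch bands; Pearson χ²; low/intermediate/high macro-risk pooling.
* **Synthetic cohorts**: a seeded archetype-based generator calibrated to
  published class shares and per-class positive-cytology rates, plus
  packaged count fixtures that reproduce the published summary-table
  arithmetic exactly.

## Worked example

```r
library(nustriage)

nod <- nodule_record(
  nodule_id = "N001", composition = "solid", echogenicity = "hypoechoic",
  margins = "smooth", taller_than_wide = FALSE,
  echogenic_foci = "microcalcification_punctate",
  diameters_mm = c(18, 13, 11), cytology = c("TIR3A", "TIR3A"))
ann <- classify_nodules(add_cytology_outcome(nod))
ann[, c("KTIRADS_class", "ATA_class", "AACE_class", "EUTIRADS_class",
        "ACRTIRADS_class", "acr_points", "cytology_outcome")]
#>   KTIRADS_class ATA_class AACE_class EUTIRADS_class ACRTIRADS_class acr_points cytology_outcome
#> 1             5      high       high              5             TR5          7         negative
```

An 18 mm solid hypoechoic nodule with punctate microcalcifications lands in
the top class of every system (ACR points: solid 2 + hypoechoic 2 +
punctate foci 3 = 7 → TR5), and every system indicates FNA at 18 mm; its
twice-confirmed TIR3A cytology dichotomizes to negative — a "true
false-positive" of the scores.

Cohort-level accounting on the packaged fixture:

```r
fx <- table_fixture()
sparing_report(fixture_view(fx, "KTIRADS"), "KTIRADS")
#> FNA sparing under KTIRADS: 665 spared of 6474 observed (10.3%)
#>  class_label n_observed n_expected n_spared spared_negative spared_positive included
#>            2        365        234      131             121              10     TRUE
#>            3       2827       2293      534             505              29     TRUE
#>            4       2704       2704        0               0               0     TRUE
#>            5        578        578        0               0               0     TRUE

diagnostic_metrics(fna_triage_confusion(fixture_view(fx, "KTIRADS"), "KTIRADS"))
#>        metric value ci_low ci_high    n
#> 1 sensitivity 0.945  0.928   0.962  709
#> 2 specificity 0.109  0.101   0.117 5765
#> 3         ppv 0.115  0.107   0.124 5809
#> 4         npv 0.941  0.923   0.959  665
```

Applied retrospectively, K-TIRADS would have spared 665 of 6474 FNAs
(10.3%) at 94.5% sensitivity for positive cytology; only 39 score-negative
nodules had positive cytology.

A shell entry point wrapping the same functions ships at
`inst/cli/nus-triage` (subcommands `classify`, `evaluate`, `simulate`,
`agreement`, `reproduce-tables`).

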