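---
title: "Methods: ultrasound risk scores, cytology dichotomization and FNA triage evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultrasound risk scores, cytology dichotomization and FNA triage evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nustriage)
```

## The problem and the model

A nodule ultrasound score (NUS) is a deterministic map from a sonographic
description to a malignancy-risk class, paired with a per-class size
threshold above which fine-needle aspiration (FNA) is recommended. Applied
retrospectively to a cohort in which *every* nodule underwent FNA, a score
partitions the performed cytologies into *expected* (the score would have
indicated them) and *spared* (it would not). The evaluation questions are:
how much cytology would each score save, and how many positive cytologies
would the saving miss?

`nustriage` treats this as a triage test: test-positive means "FNA
indicated by the score" (class plus size rule), outcome-positive means
"positive cytology". From that 2×2 table we report sensitivity
tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp) and NPV tn/(tn+fn).
This operational dichotomy is a deliberate design choice: published
cohort summaries are not all mutually consistent under any single
reconstruction we tried, and this definition is the one that exactly
reproduces the reference K-TIRADS row (sensitivity, PPV and its interval).
Remaining discrepancies in other systems' summary rows are surfaced in the
package documentation rather than chased; the corresponding cells are
covered by property-based tests (conservation, scale invariance, oracle
equivalence), not asserted numerically.

## Feature lexicon and domain rules

All five classifiers consume one harmonized lexicon: composition
(cystic/spongiform/mixed/solid), solid-portion eccentricity for mixed
nodules (true/false/doubtful), echogenicity (six levels, anechoic through
markedly hypoechoic), halo, margins (smooth, irregular or blurred,
lobulated, extrathyroidal extension), taller-than-wide shape, a *set* of
echogenic foci (comet-tail spot, macro-, punctate micro-, rim
calcification), vascularization, and three diameters in mm. Halo and
vascularization are recorded but scored by none of the five systems; they
remain available to the simulator and to future rule tables.

Structural invariants are enforced at parse time (positive diameters,
anechoic only for cystic/mixed, eccentricity only for mixed, `none` foci
exclusive); violations land in a rejects report with row numbers rather
than being silently dropped.

*Eligibility* mirrors the study-cohort construction: maximum diameter
≥ 10 mm (exactly 10.0 mm is eligible — the exclusion is a strict "below
10 mm"), complete ultrasound description, and a diagnostic cytology
history. The maximum of the three diameters is the size used against every
threshold; the cited guidelines use the largest diameter and the source
cohort description does not say otherwise. When several exclusion reasons
apply, one primary reason is assigned in the fixed order subcentimeter →
incomplete description → nondiagnostic cytology.

*Cytology dichotomization.* Positive: any TIR3B/TIR4/TIR5, or Thy3/Thy4/
Thy5 under the pre-2014 British scheme (Thy3 was referred to surgery, hence
positive). Negative: any TIR2/Thy2, or two *consecutive* TIR3A. A single
unconfirmed TIR3A is `unresolved` (kept in the cohort, excluded from
metric denominators); TIR1/Thy1-only histories are `nondiagnostic`. Two
readings here are genuinely open and we fixed them as package defaults:

* a **single TIR2 counts as negative** — the "two consecutive samples"
  confirmation is required only for TIR3A. The alternative reading (two
  consecutive TIR2 as well) would push every once-sampled benign nodule
  out of the negative pool, which matches neither clinical practice nor
  the published cohort sizes.
* era is carried per cytology result; a nodule with **mixed-era** history
  is classified by its most severe result and is excluded from the
  post-2014 sub-cohort (`post2014_subset()`), whose
  `exclude_indeterminate` mode additionally drops TIR3A/TIR3B carriers.

## The five rule tables

Rule tables are *data*, not code: one YAML file per system under
`inst/extdata/rulesets/`, carrying the pattern rows (ordered, first match
wins) or the ACR point table, the FNA thresholds with per-entry strictness,
the ordinal ranks used for ROC (1–3 AACE, 1–4 K-TIRADS/EU-TIRADS, 1–5
ATA/ACR), and the macro-risk map. Files are versioned and checksummed into
every run manifest, so a transcription correction never touches logic. The
tables transcribe the canonical published criteria of each guideline; any
idiosyncratic simplifications a particular study team may have used on top
of them are not recoverable from printed summaries and are not modelled.

Numerical/tie-break choices worth stating:

* **Strictness follows the printed symbols**: ties at a strict (">")
  threshold do not indicate FNA (a 20.0 mm EU-TIRADS 3 nodule is not
  indicated; a 15.0 mm K-TIRADS 3 nodule is).
* **ACR points are additive**, including across multiple foci. A 1-point
  total is unreachable under the canonical table but maps to TR1 so the
  banding is total. Exotic multi-foci bundles can sum past the
  instrument's 14-point scale; `acr_points()` caps at 14 (the published
  scale and the continuous ROC variable run 0–14, and the TR5 band starts
  at 7, so the cap can never change a class).
* **ATA is not total.** Bundles outside the published patterns —
  iso-/hyperechoic nodules with suspicious features, mixed nodules with a
  doubtful (unrecorded) eccentric solid portion — return the
  `UNCLASSIFIABLE` sentinel, a first-class value. The doubtful-eccentric
  rule fires before the high-suspicion pattern, so *all* doubtful mixed
  nodules abstain, including hypoechoic suspicious ones a looser reading
  could call high. Unclassifiable nodules are excluded from ATA per-class
  statistics and sparing (reported as a pseudo-class), and a
  sensitivity-analysis mode (`drop_ata_unclassifiable`) removes them from
  all five systems' analyses.
* A purely cystic or spongiform bundle carrying suspicious foci is
  internally contradictory for the ATA patterns (a cyst with
  microcalcifications is not a simple cyst) and abstains; K-TIRADS routes
  such bundles through its partially-cystic rules (≥ class 4 when
  suspicious). Consequently no system ever assigns *low* macro-risk to a
  bundle containing microcalcifications, taller-than-wide shape or
  extrathyroidal extension — an invariant audited by exhaustive
  enumeration of the coherent feature lattice
  (`enumerate_feature_lattice()`, 3 200 bundles).
* **Macro-risk grouping** pools classes into expected-malignancy bands
  < 5% / 5–20% / > 20%. K-TIRADS 4 goes to the *high* group: its published
  expected-malignancy band (15–50%) straddles the 20% cut. The published
  macro-group summary row could not be reconstructed from printed counts
  under either pooling mode we provide (`per_system`, `pooled_pairs`), so
  neither is asserted against it; `macro_metrics()` documents its own
  threshold convention (test-positive = macro group at or above the row's
  group).

## Metrics

Wald intervals (z = 1.96 at the default level, no continuity correction)
are used for all proportions — validated against the reference PPV
half-width (0.8 points at p = 670/5809). AUC uses the rank concordance
(Mann–Whitney) estimator with midranks, so ties count ½, and the
Hanley–McNeil variance for its interval; the estimator is tested for exact
equality against a brute-force pairwise oracle and against an independent
ROC implementation. Cohen's κ is the unweighted statistic with the
standard large-sample standard error and Landis–Koch interpretation bands.
χ² is Pearson's without continuity correction. No multiplicity adjustment
is applied anywhere (none is in scope). Percentages are rounded to one
decimal and κ/AUC to three only at render time; machine-readable outputs
are unrounded.

*Sparing accounting.* Per class, expected + spared = observed is an
enforced invariant. Classes that never indicate FNA still accrue observed
FNAs (real-world indications outside the score); their sparing is counted,
with one exception mirroring the reference accounting: the ATA *benign*
class is excluded from sparing totals by default
(`include_benign_class = FALSE`) while remaining in the observed
denominator.

## Packaged fixtures

`table_fixture()` ships the printed per-class counts of the reference
cohort (expected/observed/spared FNA with cytology composition for all five
systems, plus the histology table), and `fixture_view()` expands them into
per-nodule (class, outcome, FNA-indicated) tuples — the exact input shape
of the metrics module — so the whole summary-table arithmetic is a
regression test (`reproduce_tables()`). Three printed cells are
inconsistent with their own row totals (a spared-count cell printing 8
where 49 is conserved; a spared total printing 667 against a 621 + 56
breakdown; a 1856/193 split against a 2227 row total whose printed
percentages imply 371). These are stored verbatim with flags; the expansion
uses `total − negative` for flagged rows so that row sums are conserved,
and no test asserts the typo cells. Two histology share cells differ from
their own counts by one rounding unit and are compared at the table's
printed granularity (± 0.1 pp).

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not any patient's data:

* **Archetypes.** Four feature bundles chosen to map deterministically to
  K-TIRADS classes 2–5 (pure cyst; bland partially-cystic with eccentric
  solid portion; solid hypoechoic; solid hypoechoic with punctate
  microcalcifications). Archetype weights default to the reference
  cohort's observed K-TIRADS class shares (5.6/43.7/41.8/8.9%). Because
  the archetype→class map is deterministic, those marginals are matched
  analytically up to multinomial noise — the ± 2-point calibration
  contract needs no search. Only one system is a calibration target;
  the other four systems' marginals are emergent, which honestly mirrors
  the real data-generating process (one nodule, five different class
  assignments).
* **Malignancy and cytology noise.** Truth is Bernoulli per archetype;
  cytology is positive with probability 0.90 given malignant and 0.02
  given benign. Archetype malignancy probabilities are back-solved from
  the target per-class positive-cytology rates (4.7/7.8/11.9/25.8%) under
  that noise model. Positive cytologies are high-risk-indeterminate
  (TIR3B, or Thy3 before 2014) with probability 0.53, otherwise TIR4/TIR5
  at 0.648/0.352 — the reference flow-chart's category mix. Benign
  results are TIR2, or twice-confirmed TIR3A with probability 0.064
  (emitting two consecutive TIR3A honors the confirmation rule, so every
  generated nodule has a resolved outcome). The era mix defaults to 40%
  pre-2014, the approximate share of pre-2014 positives in the reference
  flow chart.
* **Sizes** are log-normal per archetype (medians 16–24 mm, σ_log 0.4),
  truncated at 10 mm by resampling, so every generated nodule is
  eligible by construction. Histology labels are drawn from the published
  mix (46.8% classic papillary, etc.) for malignant nodules with positive
  cytology (the surgery-referred stratum).
* **Reproducibility.** One integer seed; each sampling stage draws from
  its own numbered sub-stream (`seed → stage sub-seed`), so adding a stage
  never perturbs earlier draws, and identical configs give byte-identical
  CSVs.

What the simulator does *not* emulate: operator-level feature noise (kappa
studies use an explicit label-perturbation in the tests instead),
correlations between features beyond the archetype bundles, within-patient
clustering of multiple nodules, and the exclusion stages upstream of
eligibility (their category counts are not fully enumerable from the
reference). Passing calibration tests therefore show that the pipeline
recovers known parameters under the assumed structure — not that real
cohorts satisfy that structure.

## Problem sizes and budgets

The test suite generates cohorts of 500–20 000 nodules (parameter-recovery
checks use n = 10 000–20 000 with binomial 3-SE envelopes), enumerates the
full 3 200-bundle feature lattice for the classifier audits, and samples
10⁵ histology draws; the whole suite runs in well under a minute on one
CPU, and `classify` + `evaluate` on a 6 474-nodule cohort takes about a
second. The acceptance script re-derives every reported quantity at run
time from the packaged counts, a fresh 6 474-nodule simulation and a 10⁵
histology sample.

## Known limitations

* Rule-table fidelity is to the published guidelines; study-specific
  adaptations summarized only in unavailable supplements cannot be
  captured.
* Table rows other than the reproducible reference cells are checked by
  properties, not values (see above).
* Wald intervals degrade near 0/1 proportions and small n; they are kept
  because they are the reference's method, not because they are optimal.
* The generator's four archetypes cannot produce ATA-unclassifiable or
  taller-than-wide nodules; audits of those paths use the exhaustive
  lattice instead.
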