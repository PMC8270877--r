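test_that("ACR point totals and bands match hand-summed examples", {
  cyst <- nodule_record(composition = "cystic", echogenicity = "anechoic")
  expect_equal(acr_points(cyst), 0L)
  expect_equal(classify_acr(cyst), "TR1")

  worst <- nodule_record(composition = "solid",
                         echogenicity = "markedly_hypoechoic",
                         taller_than_wide = TRUE,
                         margins = "extrathyroidal_extension",
                         echogenic_foci = "microcalcification_punctate")
  expect_equal(acr_points(worst), 14L)    # maximum attainable total
  expect_equal(classify_acr(worst), "TR5")

  # solid(2) + iso(1) + wider(0) + smooth(0) + macrocalcification(1) = 4
  mid <- nodule_record(composition = "solid", echogenicity = "isoechoic",
                       echogenic_foci = "macrocalcification")
  expect_equal(acr_points(mid), 4L)
  expect_equal(classify_acr(mid), "TR4")

  # foci points are additive across foci present
  multi <- nodule_record(composition = "solid", echogenicity = "isoechoic",
                         echogenic_foci = c("macrocalcification",
                                            "microcalcification_punctate"))
  expect_equal(acr_points(multi), 7L)
  expect_equal(classify_acr(multi), "TR5")
})

test_that("pattern classifiers reproduce the published pattern examples", {
  cyst <- nodule_record(composition = "cystic", echogenicity = "anechoic")
  spong <- nodule_record(composition = "spongiform")
  expect_equal(classify_ata(cyst), "benign")
  expect_equal(classify_ata(spong), "very_low")
  expect_equal(classify_ata(nodule_record(echogenicity = "hypoechoic",
                                          margins = "irregular_or_blurred")),
               "high")
  # patterns the ATA table cannot allocate
  expect_equal(classify_ata(nodule_record(
    echogenic_foci = "microcalcification_punctate")), UNCLASSIFIABLE)
  expect_equal(classify_ata(nodule_record(
    margins = "irregular_or_blurred")), UNCLASSIFIABLE)
  expect_equal(classify_ata(nodule_record(
    composition = "mixed", solid_portion_eccentric = NA)), UNCLASSIFIABLE)

  expect_equal(classify_aace(spong), "low")
  expect_equal(classify_aace(nodule_record()), "intermediate")
  expect_equal(classify_aace(nodule_record(
    echogenic_foci = "microcalcification_punctate")), "high")

  expect_equal(classify_eutirads(cyst), "2")
  expect_equal(classify_eutirads(nodule_record()), "3")
  expect_equal(classify_eutirads(nodule_record(
    echogenicity = "hypoechoic", taller_than_wide = TRUE)), "5")
  expect_equal(classify_eutirads(nodule_record(
    echogenicity = "slightly_hypoechoic")), "4")

  expect_equal(classify_ktirads(spong), "2")
  expect_equal(classify_ktirads(nodule_record(
    composition = "mixed", solid_portion_eccentric = TRUE)), "3")
  expect_equal(classify_ktirads(nodule_record(
    echogenicity = "hypoechoic",
    echogenic_foci = "microcalcification_punctate")), "5")
  expect_equal(classify_ktirads(nodule_record(echogenicity = "hypoechoic")), "4")
})

test_that("FNA size thresholds honor per-entry strictness", {
  expect_true(fna_indicated("KTIRADS", "3", 15))
  expect_false(fna_indicated("KTIRADS", "3", 14.9))
  expect_false(fna_indicated("ACRTIRADS", "TR3", 24))
  expect_true(fna_indicated("ACRTIRADS", "TR3", 25))
  expect_false(fna_indicated("EUTIRADS", "2", 50))      # benign: never
  expect_false(fna_indicated("EUTIRADS", "3", 20))      # strict >20: tie fails
  expect_true(fna_indicated("EUTIRADS", "3", 20.1))
  expect_false(fna_indicated("AACE", "intermediate", 20))
  expect_true(fna_indicated("AACE", "high", 10))
  expect_false(fna_indicated("ATA", "benign", 60))
  expect_true(fna_indicated("ATA", "very_low", 20))
  expect_error(fna_indicated("ATA", UNCLASSIFIABLE, 20), "UNCLASSIFIABLE")
})

test_that("FNA indication is monotone in diameter and in class rank", {
  for (sys in nus_systems()) {
    classes <- as.character(load_ruleset(sys)$classes)
    for (cl in classes) {
      ind <- fna_indicated(sys, cl, seq(5, 40, by = 0.5))
      expect_true(all(diff(ind) >= 0), info = paste(sys, cl))
    }
    # at >= 25 mm, a riskier class never loses an indication
    ind25 <- fna_indicated(sys, classes, rep(25, length(classes)))
    expect_true(all(diff(ind25) >= 0), info = sys)
    ind40 <- fna_indicated(sys, classes, rep(40, length(classes)))
    expect_true(all(diff(ind40) >= 0), info = sys)
  }
})

test_that("ordinal ranks span the documented ranges and increase with risk", {
  expect_equal(ordinal_rank("AACE", c("low", "intermediate", "high")), 1:3)
  expect_equal(ordinal_rank("KTIRADS", c("2", "3", "4", "5")), 1:4)
  expect_equal(ordinal_rank("EUTIRADS", c("2", "3", "4", "5")), 1:4)
  expect_equal(ordinal_rank("ATA", c("benign", "very_low", "low",
                                     "intermediate", "high")), 1:5)
  expect_equal(ordinal_rank("ACRTIRADS", paste0("TR", 1:5)), 1:5)
  expect_error(ordinal_rank("ATA", UNCLASSIFIABLE), "UNCLASSIFIABLE")
})

test_that("macro-risk grouping pools the documented classes", {
  expect_equal(macro_group("KTIRADS", "4"), "high")   # pooled with high risk
  expect_equal(macro_group("EUTIRADS", "3"), "low")
  expect_equal(macro_group("ACRTIRADS", "TR4"), "intermediate")
  expect_equal(macro_group("ATA", c("benign", "very_low")), c("low", "low"))
  expect_equal(macro_group("AACE", "intermediate"), "intermediate")
  expect_error(macro_group("ATA", UNCLASSIFIABLE), "UNCLASSIFIABLE")
})

test_that("every coherent feature bundle is classified; only ATA may abstain", {
  lat <- annotated_lattice()
  for (sys in c("KTIRADS", "AACE", "EUTIRADS", "ACRTIRADS")) {
    cls <- lat[[paste0(sys, "_class")]]
    expect_false(anyNA(cls), info = sys)
    expect_true(all(cls %in% as.character(load_ruleset(sys)$classes)), info = sys)
  }
  ata <- lat$ATA_class
  expect_false(anyNA(ata))
  expect_true(all(ata %in% c(load_ruleset("ATA")$classes, UNCLASSIFIABLE)))
  # the unallocatable patterns reported by users of the ATA table are abstained on
  uncl <- lat$ATA_class == UNCLASSIFIABLE
  iso_micro <- lat$composition == "solid" & lat$echogenicity == "isoechoic" &
    foci_has(lat$echogenic_foci, "microcalcification_punctate")
  doubtful_mixed <- lat$composition == "mixed" & is.na(lat$solid_portion_eccentric)
  expect_true(all(uncl[iso_micro]))
  expect_true(all(uncl[doubtful_mixed]))
  expect_true(any(uncl))
})

test_that("ACR points are monotone under single-feature escalation and bands step up", {
  lat <- annotated_lattice()
  pts <- lat$acr_points
  expect_true(all(pts >= 0 & pts <= 14))
  # class is a monotone step function of points
  ord <- order(pts)
  rank_by_pts <- ordinal_rank("ACRTIRADS", lat$ACRTIRADS_class)[ord]
  expect_true(all(tapply(rank_by_pts, pts[ord], function(x) length(unique(x))) == 1))
  expect_true(all(diff(tapply(rank_by_pts, pts[ord], unique)) >= 0))

  escalate <- function(records, col, to) { records[[col]] <- to; records }
  solid <- lat[lat$composition == "solid", ]
  # echogenicity escalation on solid nodules
  echo_order <- c("hyperechoic", "isoechoic", "slightly_hypoechoic",
                  "hypoechoic", "markedly_hypoechoic")
  for (i in seq_len(length(echo_order) - 1)) {
    a <- escalate(solid, "echogenicity", echo_order[i])
    b <- escalate(solid, "echogenicity", echo_order[i + 1])
    expect_true(all(acr_points(b) >= acr_points(a)))
  }
  # shape, margin and focus escalation on the whole lattice
  expect_true(all(acr_points(escalate(lat, "taller_than_wide", TRUE)) >=
                    acr_points(escalate(lat, "taller_than_wide", FALSE))))
  expect_true(all(acr_points(escalate(lat, "margins", "irregular_or_blurred")) >=
                    acr_points(escalate(lat, "margins", "smooth"))))
  no_micro <- lat[!foci_has(lat$echogenic_foci, "microcalcification_punctate"), ]
  with_micro <- no_micro
  with_micro$echogenic_foci <- ifelse(
    no_micro$echogenic_foci == "none", "microcalcification_punctate",
    paste0(no_micro$echogenic_foci, ";microcalcification_punctate"))
  expect_true(all(acr_points(with_micro) >= acr_points(no_micro)))
})

test_that("no system assigns low macro risk to hard suspicious features", {
  lat <- annotated_lattice()
  hard <- has_hard_suspicious(lat)
  for (sys in nus_systems()) {
    macro <- lat[[paste0(sys, "_macro")]]
    expect_false(any(macro[hard] == "low", na.rm = TRUE), info = sys)
  }
})

test_that("classify_nodules annotates ranks, FNA and macro consistently", {
  recs <- rbind(
    nodule_record("a", composition = "cystic", echogenicity = "anechoic",
                  diameters_mm = c(30, 20, 20)),
    nodule_record("b", echogenicity = "hypoechoic", diameters_mm = c(12, 9, 8)),
    nodule_record("c", echogenic_foci = "microcalcification_punctate",
                  diameters_mm = c(18, 12, 10))
  )
  ann <- classify_nodules(recs)
  expect_equal(ann$max_diameter_mm, c(30, 12, 18))
  expect_equal(ann$KTIRADS_class, c("2", "4", "4"))
  expect_equal(ann$KTIRADS_fna, c(TRUE, TRUE, TRUE))
  expect_equal(ann$ATA_class, c("benign", "intermediate", UNCLASSIFIABLE))
  expect_true(is.na(ann$ATA_rank[3]) && is.na(ann$ATA_fna[3]) &&
                is.na(ann$ATA_macro[3]))
  expect_equal(ann$acr_points, acr_points(recs))
})
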