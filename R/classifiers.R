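#' @title Rule-based ultrasound risk classifiers
#' @name classifiers
#' @description The five nodule ultrasound scores (NUS): K-TIRADS, ATA 2015,
#'   AACE/ACE-AME, EU-TIRADS and ACR TI-RADS, applied to the harmonized
#'   feature lexicon. ACR TI-RADS is an additive point system (0-14 points
#'   banded into TR1-TR5); the others are pattern lattices. The ATA pattern
#'   set is not total: bundles outside the published patterns return the
#'   `UNCLASSIFIABLE` sentinel (a first-class value, never an error).
NULL

# per-record presence of each suspicious-feature token a ruleset may reference
.suspicious_any <- function(records, tokens) {
  out <- rep(FALSE, nrow(records))
  for (tok in tokens) {
    flag <- switch(tok,
      microcalcifications = foci_has(records$echogenic_foci,
                                     "microcalcification_punctate"),
      taller_than_wide = records$taller_than_wide,
      irregular_margins = records$margins %in%
        c("irregular_or_blurred", "lobulated"),
      extrathyroidal_extension = records$margins == "extrathyroidal_extension",
      marked_hypoechogenicity = records$echogenicity == "markedly_hypoechoic",
      rim_calcification = foci_has(records$echogenic_foci,
                                   "rim_calcification_with_extrusion"),
      stop("unknown suspicious-feature token: ", tok)
    )
    out <- out | (!is.na(flag) & flag)
  }
  out
}

.eccentric_token <- function(x) {
  ifelse(is.na(x), "na", ifelse(x, "true", "false"))
}

# vectorized first-match evaluation of a pattern ruleset
.classify_pattern <- function(records, rs) {
  n <- nrow(records)
  suspicious <- .suspicious_any(records, rs$suspicious_features)
  ecc <- .eccentric_token(records$solid_portion_eccentric)
  out <- rep(NA_character_, n)
  for (rule in rs$rules) {
    cond <- rep(TRUE, n)
    w <- rule$when
    if (!is.null(w$composition)) {
      cond <- cond & records$composition %in% unlist(w$composition)
    }
    if (!is.null(w$echogenicity)) {
      cond <- cond & records$echogenicity %in% unlist(w$echogenicity)
    }
    if (!is.null(w$suspicious)) cond <- cond & (suspicious == w$suspicious)
    if (!is.null(w$eccentric)) {
      cond <- cond & ecc %in% as.character(unlist(w$eccentric))
    }
    hit <- is.na(out) & cond
    out[hit] <- rule$class
  }
  out
}

#' ACR TI-RADS point total
#'
#' Sum of the per-category points (composition, echogenicity, shape, margins,
#' echogenic foci; foci points are additive across all foci present) per the
#' published ACR table shipped in the ruleset data file. Range 0-14.
#'
#' @param records nodule data frame with complete features.
#' @return integer vector of point totals.
#' @export
acr_points <- function(records) {
  rs <- load_ruleset("ACRTIRADS")
  pt <- rs$points
  comp <- unlist(pt$composition)[records$composition]
  echo <- unlist(pt$echogenicity)[records$echogenicity]
  shape <- ifelse(records$taller_than_wide,
                  pt$shape$taller_than_wide, pt$shape$wider_than_tall)
  marg <- unlist(pt$margins)[records$margins]
  foci_pts <- unlist(pt$echogenic_foci)
  foci <- vapply(foci_split(records$echogenic_foci), function(v) {
    if (length(v) == 1L && is.na(v)) return(NA_real_)
    sum(foci_pts[v])
  }, numeric(1))
  # the instrument's scale tops out at 14; rare multi-foci bundles that sum
  # beyond it are displayed at the ceiling (the TR5 band starts at 7, so the
  # class is unaffected)
  as.integer(pmin(comp + echo + shape + marg + foci, 14))
}

.acr_band <- function(points) {
  rs <- load_ruleset("ACRTIRADS")
  out <- rep(NA_character_, length(points))
  for (b in rs$bands) {
    hit <- !is.na(points) & points >= b$min_points & points <= b$max_points
    out[hit] <- b$class
  }
  out
}

#' Classify nodules under one system
#'
#' @param records nodule data frame with complete ultrasound features.
#' @return character vector of class labels (for ATA possibly
#'   `UNCLASSIFIABLE`).
#' @examples
#' cyst <- nodule_record(composition = "cystic", echogenicity = "anechoic")
#' classify_acr(cyst)       # "TR1"
#' classify_ata(cyst)       # "benign"
#' @export
classify_acr <- function(records) .acr_band(acr_points(records))

#' @rdname classify_acr
#' @export
classify_ata <- function(records) .classify_pattern(records, load_ruleset("ATA"))

#' @rdname classify_acr
#' @export
classify_aace <- function(records) .classify_pattern(records, load_ruleset("AACE"))

#' @rdname classify_acr
#' @export
classify_eutirads <- function(records) {
  .classify_pattern(records, load_ruleset("EUTIRADS"))
}

#' @rdname classify_acr
#' @export
classify_ktirads <- function(records) {
  .classify_pattern(records, load_ruleset("KTIRADS"))
}

#' Classify nodules under any system by name
#' @param records nodule data frame.
#' @param system one of [nus_systems()].
#' @return character vector of class labels.
#' @export
classify_system <- function(records, system) {
  system <- match.arg(system, nus_systems())
  switch(system,
    KTIRADS = classify_ktirads(records),
    ATA = classify_ata(records),
    AACE = classify_aace(records),
    EUTIRADS = classify_eutirads(records),
    ACRTIRADS = classify_acr(records)
  )
}

#' FNA indication by class and size
#'
#' Threshold comparison with per-entry strictness exactly as the systems
#' prescribe (e.g. K-TIRADS class 3 indicates FNA at >= 15 mm; EU-TIRADS
#' class 3 strictly above 20 mm; ACR TR1-TR2 and ATA benign and EU-TIRADS 2
#' never indicate FNA). Ties at a strict (">") threshold do not indicate FNA.
#'
#' @param system one of [nus_systems()].
#' @param class_label class label(s) of that system; `UNCLASSIFIABLE` is an
#'   error (callers must handle the sentinel first).
#' @param max_diameter_mm numeric vector of maximum diameters.
#' @return logical vector.
#' @export
fna_indicated <- function(system, class_label, max_diameter_mm) {
  rs <- load_ruleset(system)
  class_label <- as.character(class_label)
  if (any(class_label == UNCLASSIFIABLE, na.rm = TRUE)) {
    stop("fna_indicated is undefined for UNCLASSIFIABLE nodules")
  }
  bad <- !is.na(class_label) & !(class_label %in% as.character(rs$classes))
  if (any(bad)) stop("unknown ", system, " class: ",
                     paste(unique(class_label[bad]), collapse = ", "))
  n <- max(length(class_label), length(max_diameter_mm))
  class_label <- rep_len(class_label, n)
  max_diameter_mm <- rep_len(max_diameter_mm, n)
  out <- rep(NA, n)
  for (cl in unique(class_label[!is.na(class_label)])) {
    th <- rs$fna_threshold[[cl]]
    i <- !is.na(class_label) & class_label == cl
    out[i] <- switch(th$rule,
      never = FALSE,
      ge = max_diameter_mm[i] >= th$mm,
      gt = max_diameter_mm[i] > th$mm,
      stop("unknown threshold rule: ", th$rule)
    )
  }
  out
}

#' Ordinal rank of a class for ROC analysis
#'
#' Increasing with risk: 1-3 for AACE/ACE-AME, 1-4 for K-TIRADS and
#' EU-TIRADS, 1-5 for ATA and ACR TI-RADS.
#'
#' @inheritParams fna_indicated
#' @return integer vector.
#' @export
ordinal_rank <- function(system, class_label) {
  rs <- load_ruleset(system)
  class_label <- as.character(class_label)
  if (any(class_label == UNCLASSIFIABLE, na.rm = TRUE)) {
    stop("ordinal_rank is undefined for UNCLASSIFIABLE nodules")
  }
  ranks <- unlist(rs$ordinal_rank)
  bad <- !is.na(class_label) & !(class_label %in% names(ranks))
  if (any(bad)) stop("unknown ", system, " class: ",
                     paste(unique(class_label[bad]), collapse = ", "))
  as.integer(ranks[class_label])
}

#' Macro-risk group of a class
#'
#' Pools comparable classes across systems into three expected-malignancy
#' bands: low (<5%), intermediate (5-20%), high (>20%). K-TIRADS 4 is pooled
#' with the high-risk group (its expected-malignancy band, 15-50%, straddles
#' the cut).
#'
#' @inheritParams fna_indicated
#' @return character vector in `c("low", "intermediate", "high")`.
#' @export
macro_group <- function(system, class_label) {
  rs <- load_ruleset(system)
  class_label <- as.character(class_label)
  if (any(class_label == UNCLASSIFIABLE, na.rm = TRUE)) {
    stop("macro_group is undefined for UNCLASSIFIABLE nodules")
  }
  map <- unlist(rs$macro_risk)
  bad <- !is.na(class_label) & !(class_label %in% names(map))
  if (any(bad)) stop("unknown ", system, " class: ",
                     paste(unique(class_label[bad]), collapse = ", "))
  unname(map[class_label])
}

#' Annotate a nodule table with all requested systems
#'
#' Adds, per system, columns `<SYSTEM>_class`, `<SYSTEM>_rank`,
#' `<SYSTEM>_fna`, `<SYSTEM>_macro`, plus `acr_points` when ACR TI-RADS is
#' selected and `max_diameter_mm`. For ATA `UNCLASSIFIABLE` nodules the rank,
#' FNA indication and macro group are `NA`.
#'
#' @param records nodule data frame with complete features.
#' @param systems character vector, subset of [nus_systems()].
#' @return annotated data frame.
#' @export
classify_nodules <- function(records, systems = nus_systems()) {
  systems <- match.arg(systems, nus_systems(), several.ok = TRUE)
  records$max_diameter_mm <- max_diameter(records)
  for (sys in systems) {
    cls <- classify_system(records, sys)
    ok <- !is.na(cls) & cls != UNCLASSIFIABLE
    rank <- rep(NA_integer_, length(cls))
    fna <- rep(NA, length(cls))
    macro <- rep(NA_character_, length(cls))
    if (any(ok)) {
      rank[ok] <- ordinal_rank(sys, cls[ok])
      fna[ok] <- fna_indicated(sys, cls[ok], records$max_diameter_mm[ok])
      macro[ok] <- macro_group(sys, cls[ok])
    }
    records[[paste0(sys, "_class")]] <- cls
    records[[paste0(sys, "_rank")]] <- rank
    records[[paste0(sys, "_fna")]] <- fna
    records[[paste0(sys, "_macro")]] <- macro
    if (sys == "ACRTIRADS") records$acr_points <- acr_points(records)
  }
  records
}

#' Enumerate the coherent finite feature space
#'
#' Generates every coherent feature bundle: cystic nodules are anechoic,
#' spongiform nodules isoechoic, solid nodules non-anechoic; the eccentric
#' solid-portion flag varies (true/false/doubtful) only for mixed nodules;
#' an echogenic-foci set containing `"none"` contains nothing else. Halo and
#' vascularization are recorded but unused by the five rule tables and held
#' fixed. Used by the exhaustive classifier audits.
#'
#' @param diameters_mm three diameters given to every bundle.
#' @return nodule data frame (one row per bundle).
#' @export
enumerate_feature_lattice <- function(diameters_mm = c(15, 12, 10)) {
  lv <- nus_feature_levels()
  combos <- list()
  add <- function(comp, ech, ecc) {
    combos[[length(combos) + 1L]] <<-
      data.frame(composition = comp, echogenicity = ech,
                 solid_portion_eccentric = ecc, stringsAsFactors = FALSE)
  }
  add("cystic", "anechoic", NA)
  add("spongiform", "isoechoic", NA)
  for (ech in lv$echogenicity) for (ecc in c(TRUE, FALSE, NA)) add("mixed", ech, ecc)
  for (ech in setdiff(lv$echogenicity, "anechoic")) add("solid", ech, NA)
  ce <- do.call(rbind, combos)

  real_foci <- setdiff(lv$echogenic_foci, "none")
  foci_sets <- "none"
  for (k in seq_along(real_foci)) {
    sets <- utils::combn(real_foci, k, FUN = paste, collapse = ";")
    foci_sets <- c(foci_sets, sets)
  }
  grid <- expand.grid(i = seq_len(nrow(ce)), margins = lv$margins,
                      taller_than_wide = c(FALSE, TRUE),
                      echogenic_foci = foci_sets,
                      stringsAsFactors = FALSE)
  out <- ce[grid$i, , drop = FALSE]
  out$margins <- grid$margins
  out$taller_than_wide <- grid$taller_than_wide
  out$echogenic_foci <- grid$echogenic_foci
  out$halo <- "absent"
  out$vascularization <- "absent"
  out$nodule_id <- sprintf("lattice%05d", seq_len(nrow(out)))
  out$patient_id <- out$nodule_id
  out$diam1_mm <- diameters_mm[1]
  out$diam2_mm <- diameters_mm[2]
  out$diam3_mm <- diameters_mm[3]
  out$cytology <- "TIR2"
  out$fna_performed <- TRUE
  out$histology <- NA_character_
  out$sex <- NA_character_
  out$age_years <- NA_real_
  rownames(out) <- NULL
  out
}
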