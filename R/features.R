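#' Sonographic feature lexicon
#'
#' Controlled vocabularies for the harmonized per-nodule ultrasound description
#' consumed by all five risk-stratification systems. Tokens are exact lowercase
#' strings; `echogenic_foci` is a set, serialized as a semicolon-joined string
#' in the CSV schema.
#'
#' @return Named list of character vectors, one per categorical feature.
#' @export
nus_feature_levels <- function() {
  list(
    composition = c("cystic", "spongiform", "mixed", "solid"),
    echogenicity = c("anechoic", "hyperechoic", "isoechoic",
                     "slightly_hypoechoic", "hypoechoic", "markedly_hypoechoic"),
    halo = c("present", "absent", "discontinuous_or_thick"),
    margins = c("smooth", "irregular_or_blurred", "lobulated",
                "extrathyroidal_extension"),
    echogenic_foci = c("none", "hyperechoic_spot_comet", "macrocalcification",
                       "microcalcification_punctate",
                       "rim_calcification_with_extrusion"),
    vascularization = c("absent", "perinodular_slight_intranodular",
                        "marked_intranodular_or_mixed")
  )
}

# feature columns that must be non-missing for a "complete" US description
.feature_cols <- c("composition", "echogenicity", "halo", "margins",
                   "taller_than_wide", "echogenic_foci", "vascularization",
                   "diam1_mm", "diam2_mm", "diam3_mm")

#' Split a semicolon-joined echogenic-foci string into tokens
#' @param x character vector of semicolon-joined foci sets.
#' @return list of character vectors (one per element of `x`).
#' @export
foci_split <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";", fixed = TRUE)
  lapply(out, function(v) if (length(v) == 1L && is.na(v)) NA_character_ else trimws(v))
}

#' Does a foci set contain a given focus?
#' @param foci character vector of semicolon-joined foci sets.
#' @param token one focus token.
#' @return logical vector (NA where the set is missing).
#' @export
foci_has <- function(foci, token) {
  vapply(foci_split(foci), function(v) {
    if (length(v) == 1L && is.na(v)) return(NA)
    token %in% v
  }, logical(1))
}

#' Construct a one-row nodule record
#'
#' Convenience constructor used in examples and tests; returns a one-row
#' data frame in the standard nodule schema (see [parse_nodule_table()]).
#'
#' @param nodule_id,patient_id identifiers.
#' @param composition,echogenicity,halo,margins,vascularization lexicon tokens.
#' @param solid_portion_eccentric logical; only meaningful for mixed nodules.
#' @param taller_than_wide logical shape flag.
#' @param echogenic_foci character vector of foci tokens (or `"none"`).
#' @param diameters_mm numeric vector of three diameters in millimetres.
#' @param cytology character vector of cytology categories in chronological
#'   order (e.g. `c("TIR3A", "TIR3A")`), or `"system:category:era"` triples.
#' @param fna_performed logical.
#' @param histology,sex,age_years optional.
#' @return one-row data frame.
#' @export
nodule_record <- function(nodule_id = "n1", patient_id = "p1",
                          composition = "solid", echogenicity = "isoechoic",
                          halo = "absent", margins = "smooth",
                          solid_portion_eccentric = NA,
                          taller_than_wide = FALSE,
                          echogenic_foci = "none",
                          vascularization = "absent",
                          diameters_mm = c(15, 12, 10),
                          cytology = "TIR2",
                          fna_performed = TRUE,
                          histology = NA_character_,
                          sex = NA_character_, age_years = NA_real_) {
  stopifnot(length(diameters_mm) == 3L)
  data.frame(
    nodule_id = nodule_id, patient_id = patient_id,
    composition = composition,
    solid_portion_eccentric = as.logical(solid_portion_eccentric),
    echogenicity = echogenicity, halo = halo, margins = margins,
    taller_than_wide = taller_than_wide,
    echogenic_foci = paste(echogenic_foci, collapse = ";"),
    vascularization = vascularization,
    diam1_mm = diameters_mm[1], diam2_mm = diameters_mm[2],
    diam3_mm = diameters_mm[3],
    cytology = paste(cytology, collapse = ";"),
    fna_performed = fna_performed, histology = histology,
    sex = sex, age_years = age_years,
    stringsAsFactors = FALSE
  )
}

#' Maximum nodule diameter
#'
#' The size compared against every FNA threshold is the maximum of the three
#' recorded diameters (the convention of the underlying guidelines).
#'
#' @param records nodule data frame.
#' @return numeric vector of maximum diameters (mm).
#' @export
max_diameter <- function(records) {
  pmax(records$diam1_mm, records$diam2_mm, records$diam3_mm, na.rm = FALSE)
}

# First structural problem with a feature row, or NA if none. Missing values
# are not flagged here (they are an eligibility matter, not a parse error).
.feature_issue <- function(records) {
  lv <- nus_feature_levels()
  n <- nrow(records)
  issue <- rep(NA_character_, n)
  set_issue <- function(bad, msg) {
    bad <- !is.na(bad) & bad & is.na(issue)
    issue[bad] <<- msg
  }
  bad_token <- function(x, vocab) !is.na(x) & !(x %in% vocab)
  set_issue(bad_token(records$composition, lv$composition), "invalid composition")
  set_issue(bad_token(records$echogenicity, lv$echogenicity), "invalid echogenicity")
  set_issue(bad_token(records$halo, lv$halo), "invalid halo")
  set_issue(bad_token(records$margins, lv$margins), "invalid margins")
  set_issue(bad_token(records$vascularization, lv$vascularization),
            "invalid vascularization")
  foci <- foci_split(records$echogenic_foci)
  bad_foci <- vapply(foci, function(v) {
    if (length(v) == 1L && is.na(v)) return(FALSE)
    if (!all(v %in% lv$echogenic_foci)) return(TRUE)
    "none" %in% v && length(v) > 1L   # "none" is exclusive
  }, logical(1))
  set_issue(bad_foci, "invalid echogenic_foci")
  for (d in c("diam1_mm", "diam2_mm", "diam3_mm")) {
    set_issue(!is.na(records[[d]]) & records[[d]] <= 0, "non-positive diameter")
  }
  set_issue(!is.na(records$solid_portion_eccentric) &
              !is.na(records$composition) & records$composition != "mixed",
            "solid_portion_eccentric set for non-mixed nodule")
  set_issue(!is.na(records$echogenicity) & records$echogenicity == "anechoic" &
              !is.na(records$composition) &
              !(records$composition %in% c("cystic", "mixed")),
            "anechoic echogenicity requires cystic or mixed composition")
  issue
}

# complete ultrasound description (no missing feature fields)
.features_complete <- function(records) {
  ok <- rep(TRUE, nrow(records))
  for (col in .feature_cols) ok <- ok & !is.na(records[[col]])
  ok
}
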