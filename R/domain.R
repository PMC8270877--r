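#' @title Nodule cohort data model and study eligibility rules
#' @name domain
#' @description Parsing of the nodule CSV schema, cytology dichotomization
#'   under the two reporting schemes used over the study period (British
#'   Thyroid Association "Thy" categories until May 2014, SIAPEC-IAP "TIR"
#'   categories afterwards), cohort eligibility filtering, and the post-2014
#'   sub-cohort selection.
NULL

.bta_categories <- c("Thy1", "Thy2", "Thy3", "Thy4", "Thy5")
.siapec_categories <- c("TIR1", "TIR2", "TIR3A", "TIR3B", "TIR4", "TIR5")

# categories counted as positive cytology (surgical referral). Thy3 responses
# are counted positive: under the BTA scheme the indeterminate class was
# referred to surgery.
.positive_categories <- c("TIR3B", "TIR4", "TIR5", "Thy3", "Thy4", "Thy5")
.negative_categories <- c("TIR2", "Thy2")
.nondiagnostic_categories <- c("TIR1", "Thy1")

#' Parse a cytology history string
#'
#' Accepts semicolon-joined entries, each either a bare category
#' (`"TIR3A"`, era inferred from the scheme) or a full
#' `"system:category:era"` triple (e.g. `"SIAPEC:TIR2:post2014"`).
#'
#' @param x character vector of cytology strings (one per nodule).
#' @return list of data frames with columns `system`, `category`, `era`,
#'   in chronological order. Invalid entries yield an `"error"` attribute-free
#'   `NULL` element; use [parse_nodule_table()] for collected diagnostics.
#' @export
parse_cytology <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(system = character(), category = character(),
                        era = character(), stringsAsFactors = FALSE))
    }
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    rows <- lapply(parts, function(p) {
      f <- strsplit(p, ":", fixed = TRUE)[[1]]
      if (length(f) == 1L) {
        cat <- f[1]
        if (cat %in% .bta_categories) {
          c("BTA", cat, "pre2014")
        } else if (cat %in% .siapec_categories) {
          c("SIAPEC", cat, "post2014")
        } else {
          return(NULL)
        }
      } else if (length(f) == 3L) {
        f
      } else {
        NULL
      }
    })
    if (any(vapply(rows, is.null, logical(1)))) return(NULL)
    out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(out) <- c("system", "category", "era")
    ok <- all(out$system %in% c("BTA", "SIAPEC")) &&
      all(out$era %in% c("pre2014", "post2014")) &&
      all(out$category[out$system == "BTA"] %in% .bta_categories) &&
      all(out$category[out$system == "SIAPEC"] %in% .siapec_categories) &&
      all((out$system == "BTA") == (out$era == "pre2014"))
    if (!ok) return(NULL)
    out
  })
}

#' Dichotomize a cytology history
#'
#' Applies the study rule: positive if any result is TIR3B/TIR4/TIR5 (or
#' pre-2014 Thy3/Thy4/Thy5); negative if the history contains a TIR2 (or Thy2;
#' a single benign result suffices) or two consecutive TIR3A results and
#' nothing positive; `unresolved` when the only informative result is a single
#' unconfirmed TIR3A; `nondiagnostic` when every result is TIR1/Thy1.
#'
#' @param history character vector of categories in chronological order, or a
#'   data frame as returned by [parse_cytology()].
#' @return one of `"positive"`, `"negative"`, `"unresolved"`, `"nondiagnostic"`.
#' @examples
#' dichotomize_cytology(c("TIR3A", "TIR3A"))  # "negative"
#' dichotomize_cytology("Thy3")               # "positive"
#' dichotomize_cytology("TIR3A")              # "unresolved"
#' @export
dichotomize_cytology <- function(history) {
  cats <- if (is.data.frame(history)) history$category else as.character(history)
  if (length(cats) == 0L) stop("empty cytology history")
  known <- c(.bta_categories, .siapec_categories)
  if (!all(cats %in% known)) {
    stop("unknown cytology category: ", paste(setdiff(cats, known), collapse = ", "))
  }
  if (any(cats %in% .positive_categories)) return("positive")
  if (any(cats %in% .negative_categories)) return("negative")
  if (any(cats == "TIR3A")) {
    consec <- length(cats) >= 2L &&
      any(cats[-length(cats)] == "TIR3A" & cats[-1L] == "TIR3A")
    return(if (consec) "negative" else "unresolved")
  }
  "nondiagnostic"
}

#' Add the dichotomized cytology outcome to a nodule table
#' @param records nodule data frame with a `cytology` column.
#' @return `records` with an added `cytology_outcome` column (`NA` where the
#'   history is empty or unparseable).
#' @export
add_cytology_outcome <- function(records) {
  hist <- parse_cytology(records$cytology)
  records$cytology_outcome <- vapply(hist, function(h) {
    if (is.null(h) || nrow(h) == 0L) return(NA_character_)
    dichotomize_cytology(h)
  }, character(1))
  records
}

.mandatory_cols <- c("nodule_id", "patient_id", "composition",
                     "solid_portion_eccentric", "echogenicity", "halo",
                     "margins", "taller_than_wide", "echogenic_foci",
                     "vascularization", "diam1_mm", "diam2_mm", "diam3_mm",
                     "cytology", "fna_performed")
.optional_cols <- c("histology", "sex", "age_years")

.parse_logical <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read and validate a nodule CSV
#'
#' Reads the documented nodule schema (comma-separated, UTF-8, mandatory
#' header). Rows violating the schema (unknown enum tokens, non-positive
#' diameters, structural invariants, unparseable cytology) are collected into
#' a rejects report rather than silently dropped; valid rows are returned
#' typed and losslessly.
#'
#' @param source path or connection to a CSV file.
#' @return list with elements `records` (typed data frame of valid rows) and
#'   `rejects` (data frame of `row`, `reason`; `row` is the data row number).
#' @export
parse_nodule_table <- function(source) {
  raw <- utils::read.csv(source, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(.mandatory_cols, names(raw))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  for (col in .optional_cols) if (!col %in% names(raw)) raw[[col]] <- NA_character_
  if (nrow(raw) == 0L) {
    rec <- raw[, c(.mandatory_cols, .optional_cols)]
    return(list(records = .type_records(rec),
                rejects = data.frame(row = integer(), reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  blank_na <- function(x) ifelse(is.na(x) | trimws(x) == "", NA_character_, trimws(x))
  for (col in names(raw)) raw[[col]] <- blank_na(raw[[col]])
  rec <- .type_records(raw)

  reason <- rep(NA_character_, nrow(rec))
  num_src <- c("diam1_mm", "diam2_mm", "diam3_mm", "age_years")
  for (col in num_src) {
    bad <- !is.na(raw[[col]]) & is.na(rec[[col]])
    reason[bad & is.na(reason)] <- paste0("unparseable ", col)
  }
  for (col in c("solid_portion_eccentric", "taller_than_wide", "fna_performed")) {
    bad <- !is.na(raw[[col]]) & is.na(rec[[col]])
    reason[bad & is.na(reason)] <- paste0("unparseable ", col)
  }
  fi <- .feature_issue(rec)
  idx <- is.na(reason) & !is.na(fi)
  reason[idx] <- fi[idx]
  cyt <- parse_cytology(rec$cytology)
  bad_cyt <- vapply(cyt, is.null, logical(1))
  reason[is.na(reason) & bad_cyt] <- "unparseable cytology"
  n_cyt <- vapply(cyt, function(h) if (is.null(h)) 0L else nrow(h), integer(1))
  empty_cyt <- !bad_cyt & n_cyt == 0L &
    !is.na(rec$fna_performed) & rec$fna_performed
  reason[is.na(reason) & empty_cyt] <- "fna_performed without cytology history"

  keep <- is.na(reason)
  list(
    records = rec[keep, , drop = FALSE],
    rejects = data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  )
}

.type_records <- function(raw) {
  rec <- raw[, c(.mandatory_cols, .optional_cols), drop = FALSE]
  for (col in c("diam1_mm", "diam2_mm", "diam3_mm", "age_years")) {
    rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))
  }
  for (col in c("solid_portion_eccentric", "taller_than_wide", "fna_performed")) {
    rec[[col]] <- if (is.character(rec[[col]])) .parse_logical(rec[[col]]) else as.logical(rec[[col]])
  }
  rownames(rec) <- NULL
  rec
}

#' Write a nodule table in the standard CSV schema
#' @param records nodule data frame.
#' @param path output file path.
#' @export
write_nodule_table <- function(records, path) {
  utils::write.csv(records[, c(.mandatory_cols, .optional_cols)], path,
                   row.names = FALSE, na = "")
}

#' Study eligibility filter
#'
#' Partitions parsed records into eligible and excluded, mirroring the study
#' flowchart: nodules under 10 mm (maximum diameter; exactly 10.0 mm is
#' eligible), incomplete ultrasound descriptions, and nodules whose entire
#' cytology history is nondiagnostic (Thy1/TIR1) are excluded. Each exclusion
#' carries one primary reason, assigned in that order of precedence.
#'
#' @param records nodule data frame.
#' @return list with `eligible` (data frame) and `excluded` (data frame with
#'   an added `exclusion_reason` column).
#' @export
eligibility_filter <- function(records) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  dmax <- max_diameter(records)
  reason[!is.na(dmax) & dmax < 10] <- "subcentimeter"
  complete <- .features_complete(records)
  reason[is.na(reason) & !complete] <- "incomplete_features"
  outcome <- add_cytology_outcome(records)$cytology_outcome
  reason[is.na(reason) & (is.na(outcome) | outcome == "nondiagnostic")] <-
    "nondiagnostic_cytology"
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded) > 0L) excluded$exclusion_reason <- reason[!is.na(reason)]
  else excluded$exclusion_reason <- character(0)
  list(eligible = records[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' Restrict to the post-May-2014 (SIAPEC-only) sub-cohort
#'
#' Keeps records whose entire cytology history was reported under the
#' SIAPEC-IAP scheme (post-2014). Nodules with mixed-era histories are
#' dropped. With `exclude_indeterminate = TRUE`, records containing any
#' indeterminate result (TIR3A or TIR3B) are additionally dropped, mirroring
#' the study's uniformity sub-analysis.
#'
#' @param records nodule data frame.
#' @param exclude_indeterminate logical.
#' @return the filtered data frame (idempotent).
#' @export
post2014_subset <- function(records, exclude_indeterminate = FALSE) {
  hist <- parse_cytology(records$cytology)
  keep <- vapply(hist, function(h) {
    if (is.null(h) || nrow(h) == 0L) return(FALSE)
    if (!all(h$era == "post2014")) return(FALSE)
    if (exclude_indeterminate && any(h$category %in% c("TIR3A", "TIR3B"))) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  records[keep, , drop = FALSE]
}
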