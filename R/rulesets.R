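#' The five supported ultrasound risk-stratification systems
#' @return character vector of system names.
#' @export
nus_systems <- function() c("KTIRADS", "ATA", "AACE", "EUTIRADS", "ACRTIRADS")

#' Sentinel class for nodules outside the ATA pattern set
#' @export
UNCLASSIFIABLE <- "UNCLASSIFIABLE"

.ruleset_file <- function(system) {
  file <- switch(system,
    KTIRADS = "ktirads.yaml", ATA = "ata.yaml", AACE = "aace.yaml",
    EUTIRADS = "eutirads.yaml", ACRTIRADS = "acrtirads.yaml",
    stop("unknown system: ", system)
  )
  path <- system.file("extdata", "rulesets", file, package = "nustriage")
  if (!nzchar(path)) stop("ruleset file not found for ", system)
  path
}

.ruleset_cache <- new.env(parent = emptyenv())

#' Load a system's rule table
#'
#' Rule tables (pattern rows, ACR point table, FNA size thresholds with
#' per-entry strictness, ordinal ranks, macro-risk map) are shipped as
#' versioned YAML data files and cached after first load.
#'
#' @param system one of [nus_systems()].
#' @return list with the parsed ruleset plus `checksum` (md5 of the file).
#' @export
load_ruleset <- function(system) {
  system <- match.arg(system, nus_systems())
  if (!is.null(.ruleset_cache[[system]])) return(.ruleset_cache[[system]])
  path <- .ruleset_file(system)
  rs <- yaml::read_yaml(path)
  rs$checksum <- unname(tools::md5sum(path))
  rs$path <- path
  stopifnot(
    identical(sort(names(rs$ordinal_rank)), sort(as.character(rs$classes))),
    identical(sort(names(rs$fna_threshold)), sort(as.character(rs$classes))),
    identical(sort(names(rs$macro_risk)), sort(as.character(rs$classes)))
  )
  .ruleset_cache[[system]] <- rs
  rs
}

#' Ruleset versions and checksums (for run manifests)
#' @return data frame with `system`, `version`, `checksum`.
#' @export
ruleset_checksums <- function() {
  do.call(rbind, lapply(nus_systems(), function(s) {
    rs <- load_ruleset(s)
    data.frame(system = s, version = rs$version, checksum = rs$checksum,
               stringsAsFactors = FALSE)
  }))
}
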