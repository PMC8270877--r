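# shared helpers: oracles and cached lattice annotation

# brute-force pairwise AUC oracle: mean over all positive-negative pairs of
# 1 / 0.5 / 0 for win / tie / loss
brute_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

.lattice_env <- new.env(parent = emptyenv())

# full coherent feature lattice annotated by all five systems (cached)
annotated_lattice <- function() {
  if (is.null(.lattice_env$lat)) {
    .lattice_env$lat <- classify_nodules(enumerate_feature_lattice())
  }
  .lattice_env$lat
}

# does a lattice row carry one of the three universally suspicious features
has_hard_suspicious <- function(records) {
  foci_has(records$echogenic_foci, "microcalcification_punctate") |
    records$taller_than_wide |
    records$margins == "extrathyroidal_extension"
}

# write a nodule CSV from text lines (header implied by write_nodule_table)
tmp_nodule_csv <- function(records) {
  path <- tempfile(fileext = ".csv")
  write_nodule_table(records, path)
  path
}
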