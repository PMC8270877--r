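#' @title Seeded synthetic cohort generator
#' @name synthcohort
#' @description Generates nodule cohorts with the statistical structure the
#'   analysis assumes: archetype feature bundles, class-conditional
#'   malignancy probabilities, truncated log-normal sizes (support >= 10 mm),
#'   a two-layer cytology noise model (Bernoulli malignancy, then category
#'   conditional on truth and reporting era), and histology labels drawn from
#'   the published mix. Every generated nodule passes [eligibility_filter()]
#'   by construction. Reproducible from a single integer seed via documented
#'   per-stage sub-streams, so adding a sampling stage never perturbs earlier
#'   draws.
NULL

#' Default histology mix (published shares)
#' @return named numeric simplex over the seven histology labels.
#' @export
histology_mix <- function() {
  hist <- .fixture_csv("table1_histology.csv")
  stats::setNames(hist$n / sum(hist$n), hist$label)
}

#' Draw histology labels
#' @param n number of draws (uses the caller's RNG state).
#' @param mix named simplex over histology labels.
#' @return character vector of labels.
#' @export
histology_sampler <- function(n, mix = histology_mix()) {
  .check_simplex(mix, "histology mix")
  sample(names(mix), n, replace = TRUE, prob = mix)
}

.check_simplex <- function(w, what) {
  if (any(is.na(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop(what, " must be a simplex (non-negative, summing to 1)")
  }
  invisible(TRUE)
}

#' Default feature archetypes
#'
#' Four bundles chosen so each maps deterministically to one K-TIRADS class
#' (the calibration target system): a pure cyst (class 2), a bland
#' partially-cystic nodule with an eccentric solid portion (class 3), a solid
#' hypoechoic nodule without suspicious features (class 4), and a solid
#' hypoechoic nodule with punctate microcalcifications (class 5).
#'
#' @return data frame of archetype templates with `malignancy_prob` and
#'   log-normal size parameters (mm, truncated at >= 10).
#' @export
default_archetypes <- function() {
  data.frame(
    name = c("benign_cyst", "mixed_bland", "solid_hypoechoic",
             "solid_hypoechoic_microcalc"),
    composition = c("cystic", "mixed", "solid", "solid"),
    solid_portion_eccentric = c(NA, TRUE, NA, NA),
    echogenicity = c("anechoic", "isoechoic", "hypoechoic", "hypoechoic"),
    halo = c("absent", "present", "absent", "absent"),
    margins = "smooth",
    taller_than_wide = FALSE,
    echogenic_foci = c("none", "none", "none", "microcalcification_punctate"),
    vascularization = c("absent", "perinodular_slight_intranodular",
                        "perinodular_slight_intranodular",
                        "marked_intranodular_or_mixed"),
    # malignancy probabilities back-solved from the target class-conditional
    # positive-cytology rates (4.7/7.8/11.9/25.8%) under the default cytology
    # noise model: r = m * p(pos|mal) + (1 - m) * p(pos|benign)
    malignancy_prob = c(0.0307, 0.0659, 0.1125, 0.2705),
    size_meanlog = log(c(24, 19, 17, 16)),
    size_sdlog = c(0.40, 0.40, 0.40, 0.40),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param n_nodules cohort size.
#' @param seed integer seed (single source of randomness for the run).
#' @param archetypes archetype table (see [default_archetypes()]).
#' @param archetype_weights simplex over archetypes.
#' @param p_pos_given_malignant probability a malignant nodule yields
#'   positive cytology (TIR3B/TIR4/TIR5 or pre-2014 Thy3/Thy4/Thy5).
#' @param p_pos_given_benign probability a benign nodule yields positive
#'   cytology (the false-positive layer, realized as a high-risk
#'   indeterminate category).
#' @param indeterminate_given_positive share of positive cytologies reported
#'   as high-risk indeterminate (TIR3B, or Thy3 before 2014).
#' @param tir4_given_noninterminate share of the remaining positives reported
#'   as TIR4/Thy4 (rest TIR5/Thy5).
#' @param indeterminate_given_benign share of negative cytologies reported as
#'   twice-confirmed TIR3A rather than TIR2 (post-2014 only; the confirmation
#'   rule is honored by emitting two consecutive TIR3A results).
#' @param era_mix proportion of nodules whose cytology predates May 2014
#'   (BTA scheme).
#' @param histology_mix named simplex over the seven histology labels,
#'   assigned to malignant nodules with positive cytology (the
#'   surgery-referred stratum).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_nodules = 6474,
                              seed = 20210218,
                              archetypes = default_archetypes(),
                              archetype_weights = c(0.05638, 0.43667,
                                                    0.41767, 0.08928),
                              p_pos_given_malignant = 0.90,
                              p_pos_given_benign = 0.02,
                              indeterminate_given_positive = 0.53,
                              tir4_given_noninterminate = 0.648,
                              indeterminate_given_benign = 0.064,
                              era_mix = 0.40,
                              histology_mix = nustriage::histology_mix()) {
  stopifnot(n_nodules >= 0, length(archetype_weights) == nrow(archetypes))
  archetype_weights <- archetype_weights / 1  # keep numeric
  .check_simplex(archetype_weights, "archetype weights")
  .check_simplex(histology_mix, "histology mix")
  probs <- c(p_pos_given_malignant, p_pos_given_benign,
             indeterminate_given_positive, tir4_given_noninterminate,
             indeterminate_given_benign, era_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(archetypes$malignancy_prob < 0 | archetypes$malignancy_prob > 1)) {
    stop("archetype malignancy probabilities must lie in [0, 1]")
  }
  out <- list(n_nodules = as.integer(n_nodules), seed = as.integer(seed),
              archetypes = archetypes, archetype_weights = archetype_weights,
              p_pos_given_malignant = p_pos_given_malignant,
              p_pos_given_benign = p_pos_given_benign,
              indeterminate_given_positive = indeterminate_given_positive,
              tir4_given_noninterminate = tir4_given_noninterminate,
              indeterminate_given_benign = indeterminate_given_benign,
              era_mix = era_mix, histology_mix = histology_mix)
  class(out) <- "simulation_config"
  out
}

#' Default calibrated configuration
#'
#' Archetype weights equal the calibration target system's (K-TIRADS)
#' observed class shares and the archetype malignancy probabilities are
#' back-solved from its per-class positive-cytology rates; because each
#' archetype maps deterministically to one K-TIRADS class, the generated
#' cohort's K-TIRADS marginals match the targets up to multinomial noise.
#' Other systems' marginals are emergent, not forced.
#'
#' @param n_nodules cohort size.
#' @param seed integer seed.
#' @return a `simulation_config`.
#' @export
default_calibration <- function(n_nodules = 6474, seed = 20210218) {
  simulation_config(n_nodules = n_nodules, seed = seed)
}

# per-stage sub-seed: stage k of run seed s. Stages are numbered once and
# never reordered, so adding stage k+1 cannot perturb draws of stages <= k.
.stage_seed <- function(seed, stage) (abs(seed) %% 100000L) * 10000L + stage

# truncated log-normal: resample until all draws are >= lower
.rlnorm_trunc <- function(n, meanlog, sdlog, lower = 10) {
  out <- stats::rlnorm(n, meanlog, sdlog)
  while (any(bad <- out < lower)) {
    out[bad] <- stats::rlnorm(sum(bad), meanlog[bad], sdlog[bad])
  }
  out
}

#' Generate a synthetic nodule cohort
#'
#' @param config a [simulation_config()].
#' @return nodule data frame in the standard CSV schema, with auxiliary
#'   columns `archetype` and `malignant` (the simulation truth).
#' @export
generate_cohort <- function(config = default_calibration()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_nodules
  arch <- config$archetypes
  empty <- nodule_record()[0, ]
  empty$archetype <- character(0); empty$malignant <- logical(0)
  if (n == 0L) return(empty)

  set.seed(.stage_seed(config$seed, 1L))
  a_idx <- sample.int(nrow(arch), n, replace = TRUE,
                      prob = config$archetype_weights)

  set.seed(.stage_seed(config$seed, 2L))
  d1 <- .rlnorm_trunc(n, arch$size_meanlog[a_idx], arch$size_sdlog[a_idx])
  d2 <- d1 * stats::runif(n, 0.60, 0.95)
  d3 <- d2 * stats::runif(n, 0.60, 0.95)

  set.seed(.stage_seed(config$seed, 3L))
  malignant <- stats::rbinom(n, 1L, arch$malignancy_prob[a_idx]) == 1L

  set.seed(.stage_seed(config$seed, 4L))
  pre2014 <- stats::runif(n) < config$era_mix

  set.seed(.stage_seed(config$seed, 5L))
  p_pos <- ifelse(malignant, config$p_pos_given_malignant,
                  config$p_pos_given_benign)
  cyt_pos <- stats::runif(n) < p_pos

  set.seed(.stage_seed(config$seed, 6L))
  u_ind <- stats::runif(n)
  u_45 <- stats::runif(n)
  u_3a <- stats::runif(n)
  category <- character(n)
  indet <- u_ind < config$indeterminate_given_positive
  tir4 <- u_45 < config$tir4_given_noninterminate
  category[cyt_pos & indet] <- ifelse(pre2014[cyt_pos & indet], "Thy3", "TIR3B")
  category[cyt_pos & !indet & tir4] <-
    ifelse(pre2014[cyt_pos & !indet & tir4], "Thy4", "TIR4")
  category[cyt_pos & !indet & !tir4] <-
    ifelse(pre2014[cyt_pos & !indet & !tir4], "Thy5", "TIR5")
  conf3a <- !pre2014 & u_3a < config$indeterminate_given_benign
  category[!cyt_pos] <- ifelse(pre2014[!cyt_pos], "Thy2",
                               ifelse(conf3a[!cyt_pos], "TIR3A;TIR3A", "TIR2"))

  set.seed(.stage_seed(config$seed, 7L))
  histology <- rep(NA_character_, n)
  referred <- malignant & cyt_pos
  if (any(referred)) {
    histology[referred] <- histology_sampler(sum(referred),
                                             config$histology_mix)
  }

  set.seed(.stage_seed(config$seed, 8L))
  sex <- ifelse(stats::runif(n) < 0.78, "F", "M")
  age <- pmin(pmax(round(stats::rnorm(n, 55, 14)), 18), 90)

  out <- data.frame(
    nodule_id = sprintf("syn%06d", seq_len(n)),
    patient_id = sprintf("pat%06d", seq_len(n)),
    composition = arch$composition[a_idx],
    solid_portion_eccentric = arch$solid_portion_eccentric[a_idx],
    echogenicity = arch$echogenicity[a_idx],
    halo = arch$halo[a_idx],
    margins = arch$margins[a_idx],
    taller_than_wide = arch$taller_than_wide[a_idx],
    echogenic_foci = arch$echogenic_foci[a_idx],
    vascularization = arch$vascularization[a_idx],
    diam1_mm = round(d1, 1), diam2_mm = round(d2, 1), diam3_mm = round(d3, 1),
    cytology = category,
    fna_performed = TRUE,
    histology = histology,
    sex = sex, age_years = as.numeric(age),
    archetype = arch$name[a_idx],
    malignant = malignant,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
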