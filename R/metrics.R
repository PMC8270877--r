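#' @title Diagnostic performance metrics and FNA-sparing accounting
#' @name metrics
#' @description Contingency construction from the FNA-indication dichotomy
#'   (test-positive = the score indicates FNA at the nodule's class and size;
#'   outcome-positive = positive cytology), per-class malignancy rates,
#'   expected/observed/spared FNA accounting, sensitivity/specificity/PPV/NPV
#'   with Wald confidence intervals, ordinal ROC/AUC (rank concordance
#'   estimator, Hanley-McNeil interval), Cohen's kappa with Landis-Koch
#'   bands, and Pearson's chi-squared test.
NULL

# Normalize input to the standard evaluation view: one row per (nodule,
# system) with class_label, outcome ("negative"/"positive"), fna_indicated.
# Accepts either a table annotated by classify_nodules() (+ cytology outcome)
# or a ready-made view (as produced by fixture_view()). Unresolved and
# unclassifiable records are dropped with counts kept as attributes.
.as_view <- function(data, system) {
  if (paste0(system, "_class") %in% names(data)) {
    if (!"cytology_outcome" %in% names(data)) data <- add_cytology_outcome(data)
    view <- data.frame(class_label = as.character(data[[paste0(system, "_class")]]),
                       outcome = data$cytology_outcome,
                       fna_indicated = data[[paste0(system, "_fna")]],
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("class_label", "outcome", "fna_indicated") %in% names(data)))
    view <- data[, c("class_label", "outcome", "fna_indicated")]
    view$class_label <- as.character(view$class_label)
  }
  resolved <- !is.na(view$outcome) & view$outcome %in% c("negative", "positive")
  n_unresolved <- sum(!resolved)
  view <- view[resolved, , drop = FALSE]
  uncl <- is.na(view$class_label) | view$class_label == UNCLASSIFIABLE
  out <- view[!uncl, , drop = FALSE]
  attr(out, "n_unresolved") <- n_unresolved
  attr(out, "n_unclassifiable") <- sum(uncl)
  attr(out, "unclassifiable_positive") <- sum(view$outcome[uncl] == "positive")
  out
}

#' Per-class cytology composition
#'
#' Counts and positive-cytology rate per risk class of one system. For ATA a
#' pseudo-class row reports the nodules outside the published patterns
#' (`UNCLASSIFIABLE`) and their positive rate; they are excluded from the
#' per-class statistics proper.
#'
#' @param data annotated nodule table (see [classify_nodules()]) or a
#'   standard evaluation view with columns `class_label`, `outcome`,
#'   `fna_indicated`.
#' @param system one of [nus_systems()].
#' @return data frame with `class_label`, `n_negative`, `n_positive`,
#'   `n_total`, `positive_rate` (proportion; `NA` for empty classes).
#' @export
class_summary <- function(data, system) {
  system <- match.arg(system, nus_systems())
  view <- .as_view(data, system)
  if (nrow(view) + attr(view, "n_unclassifiable") == 0L) {
    stop("no records with a resolved cytology outcome")
  }
  classes <- as.character(load_ruleset(system)$classes)
  rows <- lapply(classes, function(cl) {
    sub <- view[view$class_label == cl, , drop = FALSE]
    n_neg <- sum(sub$outcome == "negative")
    n_pos <- sum(sub$outcome == "positive")
    data.frame(class_label = cl, n_negative = n_neg, n_positive = n_pos,
               n_total = n_neg + n_pos,
               positive_rate = if (n_neg + n_pos > 0) n_pos / (n_neg + n_pos) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_uncl <- attr(view, "n_unclassifiable")
  if (n_uncl > 0L) {
    pos <- attr(view, "unclassifiable_positive")
    out <- rbind(out, data.frame(
      class_label = UNCLASSIFIABLE, n_negative = n_uncl - pos,
      n_positive = pos, n_total = n_uncl, positive_rate = pos / n_uncl,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Expected vs observed vs spared FNA
#'
#' Every nodule in the cohort underwent FNA (observed). The expected FNAs are
#' those the score would have indicated at the nodule's class and size; the
#' spared FNAs are the difference. Classes that never indicate FNA but whose
#' sparing the study did not count (the ATA benign class) are excluded from
#' the sparing totals unless `include_benign_class = TRUE`; the spared
#' fraction uses all observed FNAs as denominator.
#'
#' @inheritParams class_summary
#' @param include_benign_class include classes listed as sparing-excluded in
#'   the ruleset (ATA benign) in the sparing totals.
#' @return object of class `sparing_report`: list with `system`, `per_class`
#'   data frame (`class_label`, `n_observed`, `n_expected`, `n_spared`,
#'   `spared_negative`, `spared_positive`, `included`), `n_observed_total`,
#'   `n_expected_total`, `n_spared_total`, `spared_fraction`,
#'   `n_unclassifiable`.
#' @export
sparing_report <- function(data, system, include_benign_class = FALSE) {
  system <- match.arg(system, nus_systems())
  rs <- load_ruleset(system)
  view <- .as_view(data, system)
  if (attr(view, "n_unclassifiable") > 0L) {
    message(attr(view, "n_unclassifiable"),
            " unclassifiable record(s) excluded from ", system, " sparing")
  }
  excluded_classes <- if (include_benign_class) character(0) else
    as.character(unlist(rs$sparing_excluded_classes))
  classes <- as.character(rs$classes)
  rows <- lapply(classes, function(cl) {
    sub <- view[view$class_label == cl, , drop = FALSE]
    spared <- sub[!sub$fna_indicated, , drop = FALSE]
    data.frame(class_label = cl,
               n_observed = nrow(sub),
               n_expected = sum(sub$fna_indicated),
               n_spared = nrow(spared),
               spared_negative = sum(spared$outcome == "negative"),
               spared_positive = sum(spared$outcome == "positive"),
               included = !(cl %in% excluded_classes),
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  inc <- per_class[per_class$included, , drop = FALSE]
  n_obs_total <- sum(per_class$n_observed)
  out <- list(system = system, per_class = per_class,
              n_observed_total = n_obs_total,
              n_expected_total = sum(inc$n_expected),
              n_spared_total = sum(inc$n_spared),
              spared_negative_total = sum(inc$spared_negative),
              spared_positive_total = sum(inc$spared_positive),
              spared_fraction = if (n_obs_total > 0)
                sum(inc$n_spared) / n_obs_total else NA_real_,
              n_unclassifiable = attr(view, "n_unclassifiable"))
  class(out) <- "sparing_report"
  out
}

#' @export
print.sparing_report <- function(x, ...) {
  cat(sprintf("FNA sparing under %s: %d spared of %d observed (%.1f%%)\n",
              x$system, x$n_spared_total, x$n_observed_total,
              100 * x$spared_fraction))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' 2x2 contingency table constructor
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return object of class `contingency`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(as.list(counts), class = "contingency")
}

#' FNA-triage confusion matrix
#'
#' Test-positive means the score indicates FNA (class plus size threshold);
#' outcome-positive means positive cytology.
#'
#' @inheritParams class_summary
#' @return object of class `contingency` with counts `tp` (indicated,
#'   positive), `fp` (indicated, negative), `fn` (not indicated, positive),
#'   `tn` (not indicated, negative).
#' @export
fna_triage_confusion <- function(data, system) {
  view <- .as_view(data, match.arg(system, nus_systems()))
  pos <- view$outcome == "positive"
  contingency_table(
    tp = sum(view$fna_indicated & pos),
    fp = sum(view$fna_indicated & !pos),
    fn = sum(!view$fna_indicated & pos),
    tn = sum(!view$fna_indicated & !pos)
  )
}

.wald_ci <- function(p, n, conf_level) {
  if (is.na(p) || n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - hw), min(1, p + hw))
}

#' Sensitivity, specificity, PPV and NPV with Wald intervals
#'
#' Point estimates from a 2x2 contingency; confidence intervals by the normal
#' approximation p +/- z * sqrt(p(1-p)/n) without continuity correction,
#' where n is the metric's own denominator. Metrics with a zero denominator
#' are reported as `NA`.
#'
#' @param t a `contingency` object (see [contingency_table()]).
#' @param conf_level confidence level (default 0.95, z = 1.96).
#' @return data frame with `metric`, `value` (proportion), `ci_low`,
#'   `ci_high`, `n`.
#' @export
diagnostic_metrics <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency"))
  dens <- list(sensitivity = t$tp + t$fn, specificity = t$tn + t$fp,
               ppv = t$tp + t$fp, npv = t$tn + t$fn)
  nums <- list(sensitivity = t$tp, specificity = t$tn, ppv = t$tp, npv = t$tn)
  rows <- lapply(names(dens), function(m) {
    n <- dens[[m]]
    p <- if (n > 0) nums[[m]] / n else NA_real_
    ci <- .wald_ci(p, n, conf_level)
    data.frame(metric = m, value = p, ci_low = ci[1], ci_high = ci[2], n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' AUC for an ordinal (or point) score
#'
#' Rank-sum (concordance) estimator: the probability that a random positive
#' outscores a random negative, ties counted one half. Confidence interval by
#' the Hanley-McNeil variance formula.
#'
#' @param scores numeric vector (ordinal ranks 1-3/1-4/1-5 or ACR points
#'   0-14).
#' @param outcomes binary vector (`0`/`1`, logical, or
#'   `"negative"`/`"positive"`).
#' @param conf_level confidence level.
#' @return list with `value`, `ci_low`, `ci_high`, `n_positive`,
#'   `n_negative`.
#' @export
auc_ordinal <- function(scores, outcomes, conf_level = 0.95) {
  if (is.character(outcomes) || is.factor(outcomes)) {
    outcomes <- as.character(outcomes) == "positive"
  }
  outcomes <- as.logical(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auc_ordinal requires both outcome classes")
  }
  r <- rank(scores)   # midranks handle ties as 1/2
  auc <- (sum(r[outcomes]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(max(v, 0))
  list(value = auc, ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se), n_positive = n_pos, n_negative = n_neg)
}

#' Landis-Koch agreement band for a kappa value
#' @param kappa numeric.
#' @return character band label.
#' @export
kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa < 0) return("poor")
  if (kappa <= 0.20) return("slight")
  if (kappa <= 0.40) return("fair")
  if (kappa <= 0.60) return("moderate")
  if (kappa <= 0.80) return("substantial")
  "almost perfect"
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement between two raters assigning the same nodules
#' to score classes, with the Landis-Koch interpretation band and a normal
#' approximation confidence interval.
#'
#' @param ratings_a,ratings_b equal-length vectors of class labels.
#' @param conf_level confidence level.
#' @return list with `value`, `ci_low`, `ci_high`, `n`, `band`. When expected
#'   agreement is 1 the kappa is undefined and reported as `NA`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b, conf_level = 0.95) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length")
  }
  n <- length(ratings_a)
  if (n < 2L) stop("need at least two paired ratings")
  ratings_a <- as.character(ratings_a); ratings_b <- as.character(ratings_b)
  labels <- sort(unique(c(ratings_a, ratings_b)))
  pa <- table(factor(ratings_a, levels = labels)) / n
  pb <- table(factor(ratings_b, levels = labels)) / n
  p_o <- mean(ratings_a == ratings_b)
  p_e <- sum(as.numeric(pa) * as.numeric(pb))
  if (p_e >= 1) {
    return(list(value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = n, band = NA_character_))
  }
  k <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(value = k, ci_low = max(-1, k - z * se), ci_high = min(1, k + z * se),
       n = n, band = kappa_band(k))
}

#' Metrics over the three macro-risk groups
#'
#' Maps classes to the low/intermediate/high macro-risk groups and summarises
#' cytology composition per group, with threshold metrics (test-positive =
#' macro group at or above the row's group). Two pooling modes: `per_system`
#' analyses one system's assignments; `pooled_pairs` stacks every
#' (nodule, system) assignment across the requested systems, so a nodule
#' classifiable by all five systems contributes five observations.
#'
#' @param data annotated nodule table (see [classify_nodules()]).
#' @param pooling `"per_system"` or `"pooled_pairs"`.
#' @param systems systems to pool (`pooled_pairs`) or the single system
#'   (`per_system`).
#' @return data frame with one row per macro group: counts, positive rate and
#'   sensitivity/specificity/ppv/npv at that group's threshold.
#' @export
macro_metrics <- function(data, pooling = c("per_system", "pooled_pairs"),
                          systems = nus_systems()) {
  pooling <- match.arg(pooling)
  systems <- match.arg(systems, nus_systems(), several.ok = TRUE)
  if (pooling == "per_system" && length(systems) != 1L) {
    stop("per_system pooling requires exactly one system")
  }
  if (!"cytology_outcome" %in% names(data)) data <- add_cytology_outcome(data)
  pieces <- lapply(systems, function(sys) {
    macro <- data[[paste0(sys, "_macro")]]
    if (is.null(macro)) stop("records are not annotated for ", sys,
                             "; run classify_nodules() first")
    data.frame(macro = macro, outcome = data$cytology_outcome,
               stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, pieces)
  obs <- obs[!is.na(obs$macro) & obs$outcome %in% c("negative", "positive"), ]
  if (nrow(obs) == 0L) stop("no resolvable macro-group observations")
  groups <- c("low", "intermediate", "high")
  rank <- match(obs$macro, groups)
  pos <- obs$outcome == "positive"
  rows <- lapply(seq_along(groups), function(g) {
    in_g <- rank == g
    test_pos <- rank >= g
    t <- contingency_table(tp = sum(test_pos & pos), fp = sum(test_pos & !pos),
                           fn = sum(!test_pos & pos), tn = sum(!test_pos & !pos))
    dm <- diagnostic_metrics(t)
    data.frame(group = groups[g],
               n_negative = sum(in_g & !pos), n_positive = sum(in_g & pos),
               n_total = sum(in_g),
               positive_rate = if (sum(in_g) > 0) sum(in_g & pos) / sum(in_g) else NA_real_,
               sensitivity = dm$value[dm$metric == "sensitivity"],
               specificity = dm$value[dm$metric == "specificity"],
               ppv = dm$value[dm$metric == "ppv"],
               npv = dm$value[dm$metric == "npv"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson's chi-squared test of independence
#'
#' Without continuity correction, degrees of freedom (r-1)(c-1).
#'
#' @param table matrix of non-negative counts (r x c).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_squared_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-squared test undefined with a zero margin")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}
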