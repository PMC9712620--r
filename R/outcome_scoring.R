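#' Classify a patient by their good:poor outcome-site ratio
#'
#' Patients are divided on the ratio of good-outcome to poor-outcome
#' sites among their peaks: ratio above `hi` is `good`, below `lo` is
#' `poor`, anything else (including values exactly at a threshold, which
#' the strict inequalities leave unassigned) is `mixed`. With zero
#' poor-outcome sites and at least one good the ratio is infinite and the
#' class is `good`; with both counts zero the class is `NA`.
#'
#' @param n_good,n_poor Nonnegative counts (vectorized).
#' @param hi,lo Ratio thresholds, `hi > lo` (defaults 1.2 and 0.8).
#' @return Data frame with columns `n_good, n_poor, ratio, klass`.
#' @export
outcome_ratio_class <- function(n_good, n_poor, hi = 1.2, lo = 0.8) {
  stopifnot(length(n_good) == length(n_poor))
  if (any(n_good < 0) || any(n_poor < 0)) stop("counts must be >= 0")
  if (hi <= lo) stop("need hi > lo")
  ratio <- ifelse(n_poor > 0, n_good / n_poor,
                  ifelse(n_good > 0, Inf, NA_real_))
  klass <- ifelse(is.na(ratio), NA_character_,
                  ifelse(ratio > hi, "good",
                         ifelse(ratio < lo, "poor", "mixed")))
  data.frame(n_good = n_good, n_poor = n_poor, ratio = ratio,
             klass = klass, stringsAsFactors = FALSE)
}

#' Exact test of outcome-class composition between patient groups
#'
#' Fisher's exact test on the labels x classes contingency table (the
#' Freeman-Halton extension for tables wider than 2x2), two-sided by
#' probability ordering of all tables with the observed margins.
#'
#' @param table_2x3 Integer matrix, rows = patient groups (e.g.
#'   case/control), columns = outcome classes.
#' @return The exact p-value.
#' @export
group_class_fisher <- function(table_2x3) {
  tab <- as.matrix(table_2x3)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integers")
  if (sum(tab) == 0) stop("all-zero table")
  # all-zero rows/columns carry no information for the conditional test
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  stats::fisher.test(tab)$p.value
}

#' Per-patient annotation counts split by outcome group
#'
#' Counts, for each patient, the universe sites they carry that bear the
#' annotation, optionally restricted to the least prevalent fraction of
#' the ranking (`stratum_fraction = 0.10` keeps the bottom decile of
#' ranks), and compares the case vs control count distributions with a
#' two-sided Kolmogorov-Smirnov test.
#'
#' @param universe A ranked `site_universe`.
#' @param flags Logical per-site annotation flags ([annotate_overlap()]).
#' @param labels Named character vector patient id -> group label; must
#'   cover all patients and contain exactly two groups.
#' @param stratum_fraction Optional fraction in (0, 1]: restrict to the
#'   bottom `stratum_fraction` of ranks (least prevalent sites). `NULL`
#'   (default) uses all sites.
#' @return List with `counts` (data frame `patient_id, label, count`),
#'   `ks_statistic`, `ks_p`.
#' @export
annotation_count_histograms <- function(universe, flags, labels,
                                        stratum_fraction = NULL) {
  stopifnot(inherits(universe, "site_universe"))
  patients <- rownames(universe$presence)
  if (!all(patients %in% names(labels)))
    stop("labels must cover all patients; missing: ",
         paste(setdiff(patients, names(labels)), collapse = ", "))
  labels <- labels[patients]
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("need exactly two outcome groups, got ",
                                length(groups))
  if (length(flags) != length(universe$sites))
    stop("flags length must equal the number of sites")
  keep <- flags
  if (!is.null(stratum_fraction)) {
    if (anyNA(universe$sites$rank))
      stop("universe has no ranks; run rank_and_bin() first")
    if (stratum_fraction <= 0 || stratum_fraction > 1)
      stop("stratum_fraction must be in (0, 1]")
    cut <- ceiling((1 - stratum_fraction) * length(universe$sites))
    keep <- keep & universe$sites$rank > cut
  }
  counts <- as.integer(universe$presence[, keep, drop = FALSE] %*%
                         rep(1L, sum(keep)))
  df <- data.frame(patient_id = patients, label = unname(labels),
                   count = counts, stringsAsFactors = FALSE)
  if (any(table(factor(labels, levels = groups)) == 0))
    stop("a group has zero patients")
  ks <- compare_samples(df$count[df$label == groups[1]],
                        df$count[df$label == groups[2]], method = "ks")
  list(counts = df, ks_statistic = ks$statistic, ks_p = ks$p_value)
}

#' Score every patient on good/poor outcome sites and test group contrast
#'
#' Convenience wrapper: counts each patient's universe sites flagged as
#' good-outcome and poor-outcome, classifies the good:poor ratio with
#' [outcome_ratio_class()], tabulates classes by outcome group, and runs
#' the exact test of [group_class_fisher()].
#'
#' @param universe A `site_universe`.
#' @param good_flags,poor_flags Logical per-site flags.
#' @param labels Named patient id -> group label vector (two groups).
#' @param hi,lo Ratio thresholds passed to [outcome_ratio_class()].
#' @return List with `scores` (per-patient table incl. label and class),
#'   `class_table` (groups x classes), `fisher_p`.
#' @export
score_patient_outcomes <- function(universe, good_flags, poor_flags,
                                   labels, hi = 1.2, lo = 0.8) {
  stopifnot(inherits(universe, "site_universe"))
  patients <- rownames(universe$presence)
  if (!all(patients %in% names(labels)))
    stop("labels must cover all patients")
  n_good <- as.integer(universe$presence[, good_flags, drop = FALSE] %*%
                         rep(1L, sum(good_flags)))
  n_poor <- as.integer(universe$presence[, poor_flags, drop = FALSE] %*%
                         rep(1L, sum(poor_flags)))
  sc <- outcome_ratio_class(n_good, n_poor, hi = hi, lo = lo)
  sc <- cbind(data.frame(patient_id = patients,
                         label = unname(labels[patients]),
                         stringsAsFactors = FALSE), sc)
  tab <- table(sc$label, factor(sc$klass,
                                levels = c("good", "mixed", "poor")))
  list(scores = sc, class_table = unclass(tab),
       fisher_p = group_class_fisher(as.matrix(tab)))
}
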