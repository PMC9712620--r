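#' Flag universe sites overlapping an annotation set
#'
#' A site is flagged when it shares at least one base pair with any
#' interval of the annotation (point annotations such as SNVs or risk SNPs
#' are width-1 intervals).
#'
#' @param universe A `site_universe`.
#' @param annotation A `GRanges` of annotation intervals.
#' @return List with `flags` (logical, one per site in current site order,
#'   named by site id) and `fraction` (flagged / total sites).
#' @export
annotate_overlap <- function(universe, annotation) {
  stopifnot(inherits(universe, "site_universe"),
            methods::is(annotation, "GRanges"))
  flags <- IRanges::overlapsAny(universe$sites, annotation,
                                ignore.strand = TRUE)
  names(flags) <- universe$sites$site_id
  list(flags = flags, fraction = mean(flags))
}

#' Hypergeometric enrichment of an annotation within prevalence bins
#'
#' For each bin, tests whether the annotated sites concentrate there. With
#' N universe sites of which K are annotated, and a bin of n sites of
#' which x are annotated, the reported p-value is the strict upper tail
#' P(X > x) under Hypergeometric(N, K, n); set `inclusive = TRUE` for
#' P(X >= x).
#'
#' @param universe A `site_universe` that has been through [rank_and_bin()].
#' @param flags Logical per-site flags from [annotate_overlap()].
#' @param inclusive Use the inclusive tail P(X >= x) instead of the strict
#'   P(X > x).
#' @return Data frame with one row per bin: `bin, N, K, n, x, expected,
#'   direction, p_value`.
#' @export
hypergeom_bin_enrichment <- function(universe, flags, inclusive = FALSE) {
  stopifnot(inherits(universe, "site_universe"))
  if (anyNA(universe$sites$bin))
    stop("universe has no bins; run rank_and_bin() first")
  if (length(flags) != length(universe$sites))
    stop("flags length must equal the number of sites")
  N <- length(universe$sites)
  K <- sum(flags)
  bins <- factor(universe$sites$bin, levels = c("SH", "PS", "UN"))
  out <- lapply(levels(bins), function(b) {
    idx <- bins == b
    n <- sum(idx)
    if (n == 0L) return(NULL)
    x <- sum(flags[idx])
    p <- hypergeom_tail_p(N, K, n, x, inclusive = inclusive)
    data.frame(bin = b, N = N, K = K, n = n, x = x,
               expected = n * K / N,
               direction = ifelse(x >= n * K / N, "enriched", "depleted"),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X > x)` (strict, the default) or `P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)`: x annotated among n drawn from a
#' universe of N with K annotated.
#'
#' @param N Universe size. @param K Annotated in universe.
#' @param n Drawn (bin size). @param x Annotated among drawn.
#' @param inclusive Include the observed value in the tail.
#' @return The tail probability.
#' @export
hypergeom_tail_p <- function(N, K, n, x, inclusive = FALSE) {
  if (n > N || K > N) stop("need n <= N and K <= N")
  if (x > min(K, n)) stop("x cannot exceed min(K, n)")
  q <- if (inclusive) x - 1 else x
  stats::phyper(q, K, N - K, n, lower.tail = FALSE)
}

#' Observed-over-expected mutation rate with Fisher's exact test
#'
#' Compares the per-bp mutation rate inside a region class with the
#' genome-wide rate. O/E = (mut_in / bp_in) / (mut_total / genome_bp). The
#' two-sided Fisher test treats every bp as a Bernoulli mutation trial:
#' the 2x2 table is mutated/unmutated bp inside vs outside the regions.
#'
#' @param mutations `GRanges` of mutation positions (width-1).
#' @param regions `GRanges` of the region class (e.g. one prevalence bin).
#' @param genome_bp Total genome size in bp; must be at least the region
#'   footprint.
#' @return List with `o_e`, `p_value`, and the underlying counts
#'   (`mut_in`, `mut_total`, `bp_in`, `bp_total`). With zero mutations
#'   overall, `o_e` is `NA` and `p_value` 1.
#' @export
mutation_rate_fisher <- function(mutations, regions, genome_bp) {
  stopifnot(methods::is(mutations, "GRanges"),
            methods::is(regions, "GRanges"))
  bp_in <- sum(GenomicRanges::width(GenomicRanges::reduce(
    regions, ignore.strand = TRUE)))
  if (bp_in == 0) stop("regions have zero footprint")
  if (genome_bp < bp_in)
    stop("genome_bp is smaller than the region footprint")
  mut_total <- length(mutations)
  mut_in <- sum(IRanges::overlapsAny(mutations, regions,
                                     ignore.strand = TRUE))
  if (mut_total == 0L)
    return(list(o_e = NA_real_, p_value = 1,
                mut_in = 0L, mut_total = 0L,
                bp_in = bp_in, bp_total = genome_bp))
  o_e <- (mut_in / bp_in) / (mut_total / genome_bp)
  tab <- matrix(c(mut_in, bp_in - mut_in,
                  mut_total - mut_in, (genome_bp - bp_in) -
                    (mut_total - mut_in)), nrow = 2)
  p <- stats::fisher.test(tab)$p.value
  list(o_e = o_e, p_value = p, mut_in = mut_in, mut_total = mut_total,
       bp_in = bp_in, bp_total = genome_bp)
}

#' Permutation test of equality of two density estimates
#'
#' Estimates Gaussian-kernel densities of the two samples on a common
#' `ngrid`-point grid using a single shared bandwidth (normal-reference
#' rule on the pooled sample), takes the integrated squared difference as
#' the statistic, and permutes group labels to obtain an empirical
#' p-value `(1 + #\{perm >= obs\}) / (1 + n_perm)`.
#'
#' @param values_a,values_b Numeric samples (each of size >= 2).
#' @param n_perm Number of label permutations (default 1000).
#' @param ngrid Number of grid points for the density estimates.
#' @param seed Optional RNG seed for the permutations.
#' @return List with `statistic`, `p_value`, `bandwidth`, `grid`.
#' @export
density_equality_permutation <- function(values_a, values_b,
                                         n_perm = 1000L, ngrid = 100L,
                                         seed = NULL) {
  stopifnot(is.numeric(values_a), is.numeric(values_b),
            length(values_a) >= 2, length(values_b) >= 2)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  na <- length(values_a); nb <- length(values_b)
  pooled <- c(values_a, values_b)
  h <- stats::bw.nrd(pooled)
  if (!is.finite(h) || h <= 0) h <- max(stats::sd(pooled), 1e-8)
  grid <- seq(min(pooled) - 3 * h, max(pooled) + 3 * h,
              length.out = ngrid)
  dx <- grid[2L] - grid[1L]
  # kernel matrix grid x observations, reused across permutations
  D <- stats::dnorm(outer(grid, pooled, "-"), sd = h)
  stat_for <- function(ia) {
    fa <- rowMeans(D[, ia, drop = FALSE])
    fb <- rowMeans(D[, -ia, drop = FALSE])
    sum((fa - fb)^2) * dx
  }
  obs <- stat_for(seq_len(na))
  perm <- vapply(seq_len(n_perm), function(i)
    stat_for(sample.int(na + nb, na)), numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       bandwidth = h, grid = grid)
}

#' Two-sample comparison: pooled-variance t test or Kolmogorov-Smirnov
#'
#' `method = "t"` is the classical two-tailed Student's t-test of means
#' with pooled variance; `method = "ks"` is the two-sided
#' Kolmogorov-Smirnov test with asymptotic p-value. With zero pooled
#' variance and equal means the t statistic is undefined and both fields
#' are `NA`; with zero pooled variance and different means the statistic
#' is infinite and p is 0.
#'
#' @param a,b Numeric samples.
#' @param method `"t"` or `"ks"`.
#' @return List with `statistic` and `p_value`.
#' @export
compare_samples <- function(a, b, method = c("t", "ks")) {
  method <- match.arg(method)
  stopifnot(is.numeric(a), is.numeric(b))
  if (method == "t") {
    if (length(a) < 2 || length(b) < 2)
      stop("t-test needs at least 2 values per sample")
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    d <- mean(a) - mean(b)
    if (sp2 == 0) {
      if (d == 0) return(list(statistic = NA_real_, p_value = NA_real_))
      return(list(statistic = sign(d) * Inf, p_value = 0))
    }
    tt <- d / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(abs(tt), df = na + nb - 2, lower.tail = FALSE)
    return(list(statistic = tt, p_value = p))
  }
  if (length(a) < 1 || length(b) < 1)
    stop("ks needs at least 1 value per sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
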