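# Independent brute-force oracles used across the suite. These are
# deliberately naive (enumeration, O(n^2) scans) and share no code with
# the package's implementations.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr <- function(chrom, start, end, score = NULL, name = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(score)) g$score <- score
  if (!is.null(name)) g$name <- name
  g
}

# single-linkage components of the pairwise >=1 bp overlap graph,
# via union-find on an explicit O(n^2) overlap scan
bf_components <- function(chrom, start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        start[i] <= end[j] && start[j] <= end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx)
    data.frame(chrom = chrom[idx[1]], start = min(start[idx]),
               end = max(end[idx]), stringsAsFactors = FALSE)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# hypergeometric tail by explicit choose() summation
hyper_tail_oracle <- function(N, K, n, x, inclusive = FALSE) {
  lo <- if (inclusive) x else x + 1
  hi <- min(K, n)
  if (lo > hi) return(0)
  ks <- lo:hi
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# two-sided 2x2 Fisher by probability-ordered enumeration
fisher2x2_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- exp(lchoose(c1, ks) + lchoose(N - c1, r1 - ks) - lchoose(N, r1))
  obs <- pr[ks == tab[1, 1]]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# two-sided Freeman-Halton for a 2x3 table: enumerate all tables with the
# observed margins, probability ordering
freeman_halton_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); cs <- colSums(tab); N <- sum(tab)
  logp <- function(a, b, c)
    lchoose(cs[1], a) + lchoose(cs[2], b) + lchoose(cs[3], c) -
    lchoose(N, r1)
  obs <- logp(tab[1, 1], tab[1, 2], tab[1, 3])
  tot <- 0
  for (a in 0:min(r1, cs[1])) for (b in 0:min(r1 - a, cs[2])) {
    c <- r1 - a - b
    if (c > cs[3]) next
    lp <- logp(a, b, c)
    if (lp <= obs + 1e-7) tot <- tot + exp(lp)
  }
  tot
}

# two-sample KS D by direct ECDF comparison at every data point
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t),
                 numeric(1))))
}

# beta-binomial moments for prevalence = 1 + BB(m, a, b)
bb_mean <- function(m, a, b) 1 + m * a / (a + b)
bb_var <- function(m, a, b) {
  p <- a / (a + b)
  m * p * (1 - p) * (a + b + m) / (a + b + 1)
}
bb_pmf <- function(k, m, a, b)
  exp(lchoose(m, k) + lbeta(k + a, m - k + b) - lbeta(a, b))

# minimal consistent site_universe for unit tests that only need
# prevalence bookkeeping (sites spaced apart on one chromosome)
mock_universe <- function(prevalences, n_patients) {
  n <- length(prevalences)
  sites <- gr("chr1", seq_len(n) * 1000L, seq_len(n) * 1000L + 200L)
  sites$site_id <- sprintf("site_%05d", seq_len(n))
  sites$prevalence <- as.integer(prevalences)
  sites$rank <- NA_integer_
  sites$bin <- NA_character_
  patients <- sprintf("P%03d", seq_len(n_patients))
  pres <- matrix(FALSE, n_patients, n,
                 dimnames = list(patients, sites$site_id))
  for (i in seq_len(n)) pres[seq_len(prevalences[i]), i] <- TRUE
  occ <- pres * 1.0
  structure(list(sites = sites, n_patients = n_patients,
                 sh_fraction = NA_real_, sh_min_patients = NA_integer_,
                 occurrence = occ, presence = pres),
            class = "site_universe")
}

# small cohorts shared by the acceptance blocks, built once per run
.acc_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function() {
  if (is.null(.acc_cache$cohort)) {
    spec <- cohort_spec(n_patients = 88L, n_sites = 5000L, seed = 20260101L)
    .acc_cache$cohort <- generate_cohort(spec)
    .acc_cache$spec <- spec
  }
  list(cohort = .acc_cache$cohort, spec = .acc_cache$spec)
}
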