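#' Specification of a synthetic patient cohort
#'
#' Bundles all parameters of the synthetic-cohort generator. The defaults
#' describe the study conditions the package is validated against: an
#' 88-patient cohort whose site prevalences follow a heavy-tailed
#' beta-binomial (most sites present in very few patients), peak-caller
#' scores positively correlated with prevalence, several enhancers looped
#' to each gene promoter, expression linearly driven by causal enhancers'
#' log scores, somatic mutation rates elevated in shared sites, and a
#' case/control outcome with an excess of metastasis-associated sites in
#' cases.
#'
#' @param n_patients Number of patients (>= 2).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp of
#'   the synthetic genome.
#' @param n_sites Number of ground-truth binding sites.
#' @param prevalence_dist Either `"betabinom"` (prevalence = 1 +
#'   BetaBinomial(n_patients - 1, shape1, shape2)) or `"fixed"` (all sites
#'   at `prevalence_value`).
#' @param prevalence_shape1,prevalence_shape2 Beta-binomial shape
#'   parameters; the defaults (0.3, 2) put most mass near prevalence 1.
#' @param prevalence_value Prevalence used when `prevalence_dist = "fixed"`.
#' @param peak_width_mean,peak_width_sd Peak width sampling distribution
#'   (normal, truncated at 150 bp).
#' @param score_base,score_slope,score_sd Score model: the mean log score of
#'   a site is `score_base + score_slope * prevalence / n_patients`, and
#'   individual scores are log-normal around it with sd `score_sd`. A
#'   positive slope reproduces the positive peak-strength/prevalence
#'   correlation seen in patient cistromes.
#' @param n_genes Number of genes with promoters and loops.
#' @param enhancers_per_gene_lambda Poisson mean of the number of enhancers
#'   looped to each promoter (at least one is always linked).
#' @param causal_fraction Fraction of linked enhancers with nonzero effect
#'   on expression.
#' @param causal_per_gene Optional integer: exactly this many causal
#'   enhancers per gene (capped at the landscape size); overrides
#'   `causal_fraction` when set.
#' @param effect_size Regression coefficient of a causal enhancer's
#'   `log(score + 1)` on expression.
#' @param noise_sd Expression residual standard deviation.
#' @param mutation_rate_bg Background somatic mutation rate per bp.
#' @param mutation_rr Named relative-rate multipliers for the SH/PS/UN bins.
#' @param case_fraction Fraction of patients labelled case.
#' @param met_fraction Fraction of sites carrying the metastasis-associated
#'   annotation (sampled preferentially from low-prevalence sites).
#' @param good_fraction,poor_fraction Fractions of sites carrying the
#'   good-/poor-outcome annotations (good skews to high, poor to low
#'   prevalence).
#' @param met_site_excess Extra probability that each case patient carries
#'   a met-annotated site, on top of the base prevalence draw.
#' @param sh_fraction Cohort fraction defining a shared site in the truth
#'   binning (matches the analysis default).
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 88L,
                        chrom_sizes = c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7),
                        n_sites = 5000L,
                        prevalence_dist = c("betabinom", "fixed"),
                        prevalence_shape1 = 0.3,
                        prevalence_shape2 = 2.0,
                        prevalence_value = 1L,
                        peak_width_mean = 300,
                        peak_width_sd = 75,
                        score_base = 3.0,
                        score_slope = 2.0,
                        score_sd = 0.5,
                        n_genes = 100L,
                        enhancers_per_gene_lambda = 4,
                        causal_fraction = 0.25,
                        causal_per_gene = NULL,
                        effect_size = 1.5,
                        noise_sd = 0.5,
                        mutation_rate_bg = 4e-4,
                        mutation_rr = c(SH = 5, PS = 2, UN = 1),
                        case_fraction = 0.5,
                        met_fraction = 0.10,
                        good_fraction = 0.05,
                        poor_fraction = 0.05,
                        met_site_excess = 0.15,
                        sh_fraction = 0.68,
                        seed = 1L) {
  prevalence_dist <- match.arg(prevalence_dist)
  chk <- function(cond, msg) if (!cond) stop("invalid cohort_spec: ", msg)
  chk(length(n_patients) == 1 && n_patients >= 2, "n_patients must be >= 2")
  chk(is.numeric(chrom_sizes) && length(chrom_sizes) >= 1 &&
        !is.null(names(chrom_sizes)) && all(chrom_sizes > 0),
      "chrom_sizes must be a named positive vector")
  chk(n_sites >= 1, "n_sites must be >= 1")
  chk(prevalence_shape1 > 0 && prevalence_shape2 > 0,
      "beta-binomial shapes must be positive")
  chk(prevalence_value >= 1 && prevalence_value <= n_patients,
      "prevalence_value must lie in [1, n_patients]")
  chk(peak_width_mean >= 150, "peak_width_mean must be >= 150 bp")
  chk(score_sd >= 0 && noise_sd >= 0, "sds must be nonnegative")
  chk(causal_fraction >= 0 && causal_fraction <= 1,
      "causal_fraction must be in [0, 1]")
  chk(is.null(causal_per_gene) || causal_per_gene >= 0,
      "causal_per_gene must be nonnegative")
  chk(mutation_rate_bg >= 0, "mutation_rate_bg must be >= 0")
  chk(all(c("SH", "PS", "UN") %in% names(mutation_rr)) &&
        all(mutation_rr >= 0), "mutation_rr needs SH/PS/UN rates >= 0")
  chk(case_fraction > 0 && case_fraction < 1,
      "case_fraction must be in (0, 1)")
  chk(met_site_excess >= 0 && met_site_excess <= 1,
      "met_site_excess must be in [0, 1]")
  chk(sh_fraction > 0 && sh_fraction <= 1, "sh_fraction must be in (0, 1]")
  chk(length(seed) == 1 && is.finite(seed) && abs(seed) < 2^31 - 16,
      "seed must be a single 32-bit integer")
  # capacity check: placement needs room for sites + promoters with gaps
  need <- n_sites * (peak_width_mean + 2500) + n_genes * 4500
  chk(need < 0.5 * sum(chrom_sizes),
      "genome too small for requested n_sites/n_genes")
  structure(list(
    n_patients = as.integer(n_patients), chrom_sizes = chrom_sizes,
    n_sites = as.integer(n_sites), prevalence_dist = prevalence_dist,
    prevalence_shape1 = prevalence_shape1,
    prevalence_shape2 = prevalence_shape2,
    prevalence_value = as.integer(prevalence_value),
    peak_width_mean = peak_width_mean, peak_width_sd = peak_width_sd,
    score_base = score_base, score_slope = score_slope, score_sd = score_sd,
    n_genes = as.integer(n_genes),
    enhancers_per_gene_lambda = enhancers_per_gene_lambda,
    causal_fraction = causal_fraction, causal_per_gene = causal_per_gene,
    effect_size = effect_size, noise_sd = noise_sd,
    mutation_rate_bg = mutation_rate_bg, mutation_rr = mutation_rr,
    case_fraction = case_fraction, met_fraction = met_fraction,
    good_fraction = good_fraction, poor_fraction = poor_fraction,
    met_site_excess = met_site_excess, sh_fraction = sh_fraction,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# uniform placement with rejection: non-overlapping intervals, pairwise
# separated by > min_gap bp
.place_intervals <- function(n, width_fun, chrom_sizes, min_gap = 200L) {
  chroms <- names(chrom_sizes)
  acc_chr <- character(0); acc_start <- integer(0); acc_end <- integer(0)
  guard <- 0L
  while (length(acc_start) < n) {
    guard <- guard + 1L
    if (guard > 50L) stop("could not place intervals; genome too crowded")
    m <- 2L * (n - length(acc_start)) + 10L
    w <- width_fun(m)
    ci <- sample.int(length(chroms), m, replace = TRUE,
                     prob = chrom_sizes / sum(chrom_sizes))
    s <- floor(stats::runif(m, 1, chrom_sizes[ci] - w)) |> as.integer()
    cand_chr <- c(acc_chr, chroms[ci])
    cand_start <- c(acc_start, s)
    cand_end <- c(acc_end, s + as.integer(w) - 1L)
    fixed <- c(rep(TRUE, length(acc_start)), rep(FALSE, m))
    ord <- order(cand_chr, cand_start)
    cand_chr <- cand_chr[ord]; cand_start <- cand_start[ord]
    cand_end <- cand_end[ord]; fixed <- fixed[ord]
    keep <- logical(length(ord))
    last_chr <- ""; last_end <- -Inf
    for (i in seq_along(ord)) {
      if (fixed[i]) {           # previously accepted: always stays
        keep[i] <- TRUE
        last_chr <- cand_chr[i]; last_end <- cand_end[i]
      } else if (cand_chr[i] != last_chr ||
                 cand_start[i] > last_end + min_gap) {
        keep[i] <- TRUE
        last_chr <- cand_chr[i]; last_end <- cand_end[i]
      }
    }
    acc_chr <- cand_chr[keep]; acc_start <- cand_start[keep]
    acc_end <- cand_end[keep]
  }
  take <- sort(sample.int(length(acc_start), n))
  gr <- GenomicRanges::GRanges(
    factor(acc_chr[take], levels = chroms),
    IRanges::IRanges(acc_start[take], acc_end[take])
  )
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.bin_label <- function(prevalence, n_patients, sh_fraction) {
  sh_min <- ceiling(sh_fraction * n_patients)
  ifelse(prevalence == 1L, "UN",
         ifelse(prevalence >= sh_min, "SH", "PS"))
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Places non-overlapping ground-truth sites and gene promoters on a
#' synthetic genome, draws each site's prevalence from the configured
#' distribution, assigns carrier patients (with a case-biased excess for
#' metastasis-annotated sites), draws log-normal peak scores whose mean
#' increases with prevalence, jitters each carrier's peak around the site,
#' links enhancers to promoters through loops, and simulates expression,
#' somatic mutations, copy-number segments, and case/control labels.
#' Every component is reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `spec`, `peak_sets` (patient-named list of scored `GRanges`), `truth`
#'   (`GRanges` of true sites with `site_id`, `prevalence`, `bin`),
#'   `carriers` (per-site patient index list), `promoters`, `loops`,
#'   `expression`, `causal_map`, `mutations`, `cna`, `outcome`,
#'   `annotations` (named list of `GRanges`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_pat <- spec$n_patients
  patients <- sprintf("P%03d", seq_len(n_pat))

  width_fun <- function(k)
    pmax(150, round(stats::rnorm(k, spec$peak_width_mean,
                                 spec$peak_width_sd)))
  placed <- .place_intervals(spec$n_sites + spec$n_genes,
                             function(k) {
                               w <- width_fun(k)
                               # promoters drawn separately below
                               w
                             },
                             spec$chrom_sizes, min_gap = 2400L)
  # promoters take n_genes random slots, widened to the 2001-bp TSS window
  prom_idx <- sort(sample.int(length(placed), spec$n_genes))
  promoters <- placed[prom_idx]
  mid <- (GenomicRanges::start(promoters) +
            GenomicRanges::end(promoters)) %/% 2L
  promoters <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(promoters),
    IRanges::IRanges(mid - 1000L, mid + 1000L)
  )
  GenomeInfoDb::seqlengths(promoters) <- spec$chrom_sizes
  S4Vectors::mcols(promoters)$gene_id <-
    sprintf("gene_%04d", seq_len(spec$n_genes))
  site_tmpl <- placed[-prom_idx]

  # prevalence per site
  prev <- switch(spec$prevalence_dist,
    betabinom = 1L + stats::rbinom(
      spec$n_sites, n_pat - 1L,
      stats::rbeta(spec$n_sites, spec$prevalence_shape1,
                   spec$prevalence_shape2)),
    fixed = rep(spec$prevalence_value, spec$n_sites)
  )

  # outcome labels
  n_case <- max(1L, min(n_pat - 1L, round(spec$case_fraction * n_pat)))
  case_idx <- sort(sample.int(n_pat, n_case))
  labels <- ifelse(seq_len(n_pat) %in% case_idx, "case", "control")

  # annotation site-id subsets (met skews low-prevalence, good skews high)
  n_met <- round(spec$met_fraction * spec$n_sites)
  n_good <- round(spec$good_fraction * spec$n_sites)
  n_poor <- round(spec$poor_fraction * spec$n_sites)
  met_sites <- if (n_met > 0)
    sample.int(spec$n_sites, n_met, prob = 1 / prev) else integer(0)
  # good/poor outcome sets are sampled uniformly so per-patient
  # good:poor counts straddle the ratio thresholds
  good_sites <- if (n_good > 0)
    sample.int(spec$n_sites, n_good) else integer(0)
  pool <- setdiff(seq_len(spec$n_sites), good_sites)
  poor_sites <- if (n_poor > 0)
    pool[sample.int(length(pool), min(n_poor, length(pool)))]
  else integer(0)

  # carriers: uniform subset of the drawn prevalence size, then a
  # case-biased excess for met-annotated sites
  carriers <- lapply(seq_len(spec$n_sites), function(i)
    sort(sample.int(n_pat, prev[i])))
  if (spec$met_site_excess > 0 && length(met_sites) > 0) {
    for (i in met_sites) {
      extra <- case_idx[stats::runif(length(case_idx)) <
                          spec$met_site_excess]
      carriers[[i]] <- sort(union(carriers[[i]], extra))
    }
  }
  prev_real <- lengths(carriers)

  # scores: log-normal around a prevalence-dependent mean log score
  site_chr <- as.character(GenomicRanges::seqnames(site_tmpl))
  s0 <- GenomicRanges::start(site_tmpl)
  e0 <- GenomicRanges::end(site_tmpl)
  half <- (e0 - s0 + 1L) %/% 2L
  site_rep <- rep.int(seq_len(spec$n_sites), prev_real)
  carr_vec <- unlist(carriers)
  total <- length(carr_vec)
  mu <- spec$score_base + spec$score_slope * prev_real / n_pat
  sc <- exp(stats::rnorm(total, mu[site_rep], spec$score_sd))
  ds <- pmin(70L, pmax(-70L, as.integer(round(stats::rnorm(total, 0, 25)))))
  de <- pmin(70L, pmax(-70L, as.integer(round(stats::rnorm(total, 0, 25)))))
  # every carrier peak contains the site midpoint, so single-linkage
  # merging reconstructs exactly one universe site per truth site
  half_rep <- half[site_rep]
  ds <- pmin(ds, half_rep - 5L)
  de <- pmax(de, -(half_rep - 5L))
  pk <- data.frame(patient = carr_vec, chrom = site_chr[site_rep],
                   start = s0[site_rep] + ds, end = e0[site_rep] + de,
                   score = sc, site = site_rep)
  peak_sets <- lapply(seq_len(n_pat), function(p) {
    rows <- pk[pk$patient == p, , drop = FALSE]
    rows <- rows[order(rows$chrom, rows$start), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      factor(rows$chrom, levels = names(spec$chrom_sizes)),
      IRanges::IRanges(rows$start, rows$end), score = rows$score)
    GenomeInfoDb::seqlengths(gr) <- spec$chrom_sizes
    gr
  })
  names(peak_sets) <- patients

  # truth universe: merged extent of the carrier peaks of each site
  tr_start <- tapply(pk$start, pk$site, min)
  tr_end <- tapply(pk$end, pk$site, max)
  truth <- GenomicRanges::GRanges(
    factor(site_chr, levels = names(spec$chrom_sizes)),
    IRanges::IRanges(as.integer(tr_start[as.character(seq_len(spec$n_sites))]),
                     as.integer(tr_end[as.character(seq_len(spec$n_sites))])),
    prevalence = as.integer(prev_real),
    bin = .bin_label(prev_real, n_pat, spec$sh_fraction)
  )
  GenomeInfoDb::seqlengths(truth) <- spec$chrom_sizes
  ord <- order(as.character(GenomicRanges::seqnames(truth)),
               GenomicRanges::start(truth), GenomicRanges::end(truth))
  truth <- truth[ord]
  carriers <- carriers[ord]
  site_of_rank <- order(ord)            # original index -> sorted position
  S4Vectors::mcols(truth)$site_id <-
    sprintf("site_%05d", seq_along(truth))

  # loops: each gene linked to >= 1 enhancer site
  k_g <- pmax(1L, stats::rpois(spec$n_genes,
                               spec$enhancers_per_gene_lambda))
  k_g <- pmin(k_g, spec$n_sites)
  loop_gene <- rep(promoters$gene_id, k_g)
  loop_site <- unlist(lapply(k_g, function(k)
    sample.int(spec$n_sites, k)))
  loop_site_sorted <- site_of_rank[loop_site]
  anchor1 <- rep(GenomicRanges::granges(promoters), k_g)
  anchor2 <- GenomicRanges::granges(truth)[loop_site_sorted]
  loops <- loop_set(anchor1, anchor2, name = loop_gene)

  ann <- list(
    met = GenomicRanges::granges(truth)[sort(site_of_rank[met_sites])],
    good_outcome = GenomicRanges::granges(truth)[sort(site_of_rank[good_sites])],
    poor_outcome = GenomicRanges::granges(truth)[sort(site_of_rank[poor_sites])]
  )

  cohort <- structure(list(
    spec = spec, patients = patients, peak_sets = peak_sets,
    truth = truth, carriers = carriers, promoters = promoters,
    loops = loops,
    loop_table = data.frame(gene_id = loop_gene,
                            site_id = truth$site_id[loop_site_sorted],
                            stringsAsFactors = FALSE),
    expression = NULL, causal_map = NULL, mutations = NULL,
    cna = NULL,
    outcome = data.frame(patient_id = patients, label = labels,
                         stringsAsFactors = FALSE),
    annotations = ann
  ), class = "synthetic_cohort")

  cohort <- generate_expression(cohort, spec)
  cohort <- generate_mutations(cohort, spec)
  cohort$cna <- .generate_cna(cohort, spec)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$truth), "truth sites,",
      length(x$patients), "patients,", x$spec$n_genes, "genes\n")
  invisible(x)
}

#' Simulate expression driven by causal enhancers
#'
#' For each gene g and patient p,
#' `expr[g, p] = intercept_g + sum_j beta_j * x_jp + eps`, where `x_jp` is
#' `log(score + 1)` of the patient's peak at linked enhancer j (0 when the
#' patient carries no peak there) and `eps ~ N(0, noise_sd)`. Causal
#' enhancers are drawn per gene from the linked set (a
#' `causal_fraction`-binomial draw, or exactly `causal_per_gene` when set);
#' all other linked enhancers have zero effect. Genes with no causal
#' enhancer are intercept plus noise. Deterministic given `spec$seed`.
#'
#' @param cohort A `synthetic_cohort` with loops already generated.
#' @param spec The [cohort_spec()] used to generate it.
#' @return The cohort with `expression` (genes x patients matrix) and
#'   `causal_map` (data frame gene_id, site_id, beta) filled in.
#' @export
generate_expression <- function(cohort, spec) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 1L)
  n_pat <- length(cohort$patients)
  gene_ids <- cohort$promoters$gene_id
  # occupancy design values straight from the generator's ground truth
  xs <- matrix(0, nrow = length(cohort$truth), ncol = n_pat,
               dimnames = list(cohort$truth$site_id, cohort$patients))
  # fill occupancy from peak sets against truth sites (exact by design)
  for (p in seq_len(n_pat)) {
    gr <- cohort$peak_sets[[p]]
    if (length(gr) == 0) next
    hits <- GenomicRanges::findOverlaps(cohort$truth, gr,
                                        ignore.strand = TRUE)
    si <- S4Vectors::queryHits(hits)
    sc <- gr$score[S4Vectors::subjectHits(hits)]
    mx <- tapply(sc, si, max)
    xs[as.integer(names(mx)), p] <- log1p(as.numeric(mx))
  }

  lt <- cohort$loop_table
  intercepts <- stats::rnorm(length(gene_ids), 8, 1)
  expr <- matrix(NA_real_, nrow = length(gene_ids), ncol = n_pat,
                 dimnames = list(gene_ids, cohort$patients))
  causal <- vector("list", length(gene_ids))
  for (g in seq_along(gene_ids)) {
    sites <- unique(lt$site_id[lt$gene_id == gene_ids[g]])
    m <- length(sites)
    n_causal <- if (!is.null(spec$causal_per_gene))
      min(m, spec$causal_per_gene)
    else if (m > 0) stats::rbinom(1L, m, spec$causal_fraction) else 0L
    cs <- if (n_causal > 0) sites[sample.int(m, n_causal)] else character(0)
    mu <- intercepts[g]
    if (length(cs) > 0)
      mu <- mu + spec$effect_size *
        colSums(xs[cs, , drop = FALSE])
    expr[g, ] <- mu + stats::rnorm(n_pat, 0, spec$noise_sd)
    if (length(cs) > 0)
      causal[[g]] <- data.frame(gene_id = gene_ids[g], site_id = cs,
                                beta = spec$effect_size,
                                stringsAsFactors = FALSE)
  }
  cohort$expression <- expr
  cohort$causal_map <- if (any(!vapply(causal, is.null, logical(1))))
    do.call(rbind, causal)
  else
    data.frame(gene_id = character(0), site_id = character(0),
               beta = numeric(0))
  cohort
}

#' Simulate somatic point mutations with bin-dependent rates
#'
#' Mutation counts per truth site are Poisson with rate
#' `mutation_rate_bg * rr(bin) * width`; the rest of the genome receives
#' background draws at `mutation_rate_bg` per bp. Positions are uniform
#' within their region. Deterministic given `spec$seed`.
#'
#' @inheritParams generate_expression
#' @return The cohort with `mutations` (a width-1 `GRanges`) filled in.
#' @export
generate_mutations <- function(cohort, spec) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 2L)
  if (spec$mutation_rate_bg == 0) {
    cohort$mutations <- GenomicRanges::GRanges(seqlengths = spec$chrom_sizes)
    return(cohort)
  }
  truth <- cohort$truth
  w <- GenomicRanges::width(truth)
  rr <- spec$mutation_rr[truth$bin]
  lam <- spec$mutation_rate_bg * rr * w
  counts <- stats::rpois(length(truth), lam)
  chr <- as.character(GenomicRanges::seqnames(truth))
  pos_in <- unlist(lapply(which(counts > 0), function(i)
    floor(stats::runif(counts[i], GenomicRanges::start(truth)[i],
                       GenomicRanges::end(truth)[i] + 1))))
  chr_in <- rep(chr[counts > 0], counts[counts > 0])

  genome_bp <- sum(spec$chrom_sizes)
  bg_bp <- genome_bp - sum(w)
  n_bg <- stats::rpois(1L, spec$mutation_rate_bg * bg_bp)
  chr_bg <- character(0); pos_bg <- numeric(0)
  while (n_bg > 0) {
    m <- ceiling(n_bg * 1.2) + 10
    ci <- sample.int(length(spec$chrom_sizes), m, replace = TRUE,
                     prob = spec$chrom_sizes / genome_bp)
    ps <- floor(stats::runif(m, 1, spec$chrom_sizes[ci] + 1))
    cand <- GenomicRanges::GRanges(
      factor(names(spec$chrom_sizes)[ci], levels = names(spec$chrom_sizes)),
      IRanges::IRanges(ps, width = 1))
    out <- !IRanges::overlapsAny(cand, truth, ignore.strand = TRUE)
    take <- which(out)[seq_len(min(n_bg, sum(out)))]
    chr_bg <- c(chr_bg, names(spec$chrom_sizes)[ci[take]])
    pos_bg <- c(pos_bg, ps[take])
    n_bg <- n_bg - length(take)
  }
  mut <- GenomicRanges::GRanges(
    factor(c(chr_in, chr_bg), levels = names(spec$chrom_sizes)),
    IRanges::IRanges(as.integer(c(pos_in, pos_bg)), width = 1))
  GenomeInfoDb::seqlengths(mut) <- spec$chrom_sizes
  cohort$mutations <- GenomicRanges::sort(mut, ignore.strand = TRUE)
  cohort
}

# a few gain/loss segments per patient, placed uniformly
.generate_cna <- function(cohort, spec) {
  set.seed(spec$seed + 3L)
  chroms <- names(spec$chrom_sizes)
  lapply(stats::setNames(nm = cohort$patients), function(p) {
    k <- stats::rpois(1L, 3)
    if (k == 0)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), call = character(0),
                        stringsAsFactors = FALSE))
    ci <- sample.int(length(chroms), k, replace = TRUE,
                     prob = spec$chrom_sizes / sum(spec$chrom_sizes))
    w <- round(stats::runif(k, 5e4, 5e5))
    s <- floor(stats::runif(k, 1, spec$chrom_sizes[ci] - w))
    data.frame(chrom = chroms[ci], start = as.integer(s),
               end = as.integer(s + w - 1),
               call = sample(c("gain", "loss"), k, replace = TRUE),
               stringsAsFactors = FALSE)[order(chroms[ci], s), ,
                                         drop = FALSE]
  })
}
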