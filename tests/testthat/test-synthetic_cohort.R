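test_that("a point-mass prevalence forces every patient to carry the site", {
  spec <- cohort_spec(n_patients = 3, n_sites = 1, n_genes = 2,
                      prevalence_dist = "fixed", prevalence_value = 3,
                      met_fraction = 0, seed = 7)
  co <- generate_cohort(spec)
  expect_true(all(lengths(co$peak_sets) == 1L))
  expect_equal(co$truth$prevalence, 3L)
  # the three peaks mutually overlap (they all contain the site midpoint)
  u <- build_universe(co$peak_sets)
  expect_length(u$sites, 1L)
  expect_equal(u$sites$prevalence, 3L)
})

test_that("identical seeds give identical cohorts and fixtures", {
  spec <- cohort_spec(n_patients = 6, n_sites = 80, n_genes = 8, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  expect_identical(a$peak_sets, b$peak_sets)
  expect_identical(a$mutations, b$mutations)
  d1 <- file.path(tempdir(), "fx_a"); d2 <- file.path(tempdir(), "fx_b")
  write_fixtures(a, d1); write_fixtures(b, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("realized prevalences match the beta-binomial distribution", {
  spec <- cohort_spec(n_patients = 88, n_sites = 10000, n_genes = 20,
                      prevalence_shape1 = 0.3, prevalence_shape2 = 2.0,
                      met_site_excess = 0,   # no outcome distortion here
                      chrom_sizes = c(chr1 = 4e7, chr2 = 4e7, chr3 = 4e7),
                      seed = 101)
  co <- generate_cohort(spec)
  prev <- co$truth$prevalence
  mean_an <- bb_mean(87, 0.3, 2.0)
  se <- sqrt(bb_var(87, 0.3, 2.0) / length(prev))
  expect_lt(abs(mean(prev) - mean_an), 3 * se)

  # chi-square goodness of fit against the analytic pmf, alpha = 0.01
  pmf <- bb_pmf(0:87, 87, 0.3, 2.0)
  expected <- length(prev) * pmf
  # pool the thin upper tail so expected counts stay above 5
  cutoff <- max(which(cumsum(rev(expected)) < 5))
  last <- 88 - cutoff
  obs <- tabulate(prev, nbins = 88)
  obs_b <- c(obs[1:(last - 1)], sum(obs[last:88]))
  exp_b <- c(expected[1:(last - 1)], sum(expected[last:88]))
  stat <- sum((obs_b - exp_b)^2 / exp_b)
  p <- pchisq(stat, df = length(obs_b) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)

  # score-prevalence correlation sign matches the positive slope
  occ <- build_universe(co$peak_sets)
  sc <- occ$occurrence[occ$presence]
  pv <- rep(occ$sites$prevalence, each = nrow(occ$occurrence))[
    as.vector(occ$presence)]
  expect_gt(cor(sc, pv), 0)
})

test_that("invalid generator parameters are configuration errors", {
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(cohort_spec(prevalence_shape1 = -1), "shape")
  expect_error(cohort_spec(mutation_rate_bg = -1), "mutation_rate_bg")
  expect_error(cohort_spec(n_sites = 1e6,
                           chrom_sizes = c(chr1 = 1e6)), "genome")
})

test_that("noiseless expression is an exact linear function of occupancy", {
  spec <- cohort_spec(n_patients = 12, n_sites = 60, n_genes = 10,
                      causal_per_gene = 1, effect_size = 2,
                      noise_sd = 0, seed = 33)
  co <- generate_cohort(spec)
  u <- build_universe(co$peak_sets)
  for (i in seq_len(nrow(co$causal_map))) {
    g <- co$causal_map$gene_id[i]
    s <- co$causal_map$site_id[i]
    x <- u$occurrence[, s]
    y <- co$expression[g, rownames(u$occurrence)]
    fit <- lm(y ~ x)
    expect_equal(unname(coef(fit)["x"]), 2, tolerance = 1e-8)
    expect_lt(max(abs(residuals(fit))), 1e-8)
    # carrier vs non-carrier difference is exactly beta * x
    carr <- x > 0
    if (any(carr) && any(!carr))
      expect_equal(y[carr] - mean(y[!carr]), 2 * x[carr],
                   tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("with no causal enhancers expression is independent of occupancy", {
  spec <- cohort_spec(n_patients = 40, n_sites = 400, n_genes = 100,
                      causal_fraction = 0, seed = 55)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$causal_map), 0L)
  u <- build_universe(co$peak_sets)
  slopes <- vapply(seq_len(spec$n_genes), function(g) {
    sites <- co$loop_table$site_id[co$loop_table$gene_id ==
                                     rownames(co$expression)[g]]
    x <- u$occurrence[, sites[1]]
    if (max(x) == min(x)) return(NA_real_)
    unname(coef(lm(co$expression[g, rownames(u$occurrence)] ~ x))[2])
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  # mean slope consistent with zero at 3 standard errors
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("OLS recovers the causal effect across repeated expression draws", {
  spec <- cohort_spec(n_patients = 88, n_sites = 300, n_genes = 10,
                      causal_per_gene = 1, effect_size = 1,
                      noise_sd = 0.5, seed = 77)
  co <- generate_cohort(spec)
  u <- build_universe(co$peak_sets)
  pat <- rownames(u$occurrence)
  slopes <- c()
  for (k in 1:20) {
    spec_k <- spec; spec_k$seed <- spec$seed + 100L + k
    co_k <- generate_expression(co, spec_k)
    for (i in seq_len(nrow(co_k$causal_map))) {
      x <- u$occurrence[, co_k$causal_map$site_id[i]]
      y <- co_k$expression[co_k$causal_map$gene_id[i], pat]
      if (max(x) > min(x)) slopes <- c(slopes, unname(coef(lm(y ~ x))[2]))
    }
  }
  expect_gt(length(slopes), 100)
  expect_lt(abs(mean(slopes) - 1), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("mutation rates follow the configured relative rates", {
  # elevated background rate keeps per-bin counts informative at this
  # reduced problem size
  base <- list(n_patients = 20, n_sites = 800, n_genes = 10, seed = 9,
               mutation_rate_bg = 2e-3)
  # null: identical rates everywhere, O/E close to 1 in every bin
  spec1 <- do.call(cohort_spec, c(base, list(
    mutation_rr = c(SH = 1, PS = 1, UN = 1))))
  co1 <- generate_cohort(spec1)
  for (b in c("PS", "UN")) {
    reg <- co1$truth[co1$truth$bin == b]
    r <- mutation_rate_fisher(co1$mutations, reg,
                              sum(spec1$chrom_sizes))
    expect_lt(abs(r$o_e - 1), 3 / sqrt(r$mut_in))
  }
  # elevated shared-site rate recovered within sampling error
  spec2 <- do.call(cohort_spec, utils::modifyList(base, list(seed = 10)))
  co2 <- generate_cohort(spec2)
  sh <- co2$truth[co2$truth$bin == "SH"]
  r2 <- mutation_rate_fisher(co2$mutations, sh, sum(spec2$chrom_sizes))
  expect_gt(r2$mut_in, 10)
  expect_lt(abs(r2$o_e - 5), 3 * 5 / sqrt(r2$mut_in))
  # zero rate: no mutations at all
  spec3 <- do.call(cohort_spec,
                   utils::modifyList(base, list(mutation_rate_bg = 0)))
  co3 <- generate_cohort(spec3)
  expect_length(co3$mutations, 0L)
})

test_that("fixtures round-trip losslessly and have the expected inventory", {
  spec <- cohort_spec(n_patients = 3, n_sites = 40, n_genes = 5,
                      good_fraction = 0, seed = 19)
  co <- generate_cohort(spec)
  d <- file.path(tempdir(), "fx_rt")
  write_fixtures(co, d)
  expect_length(list.files(file.path(d, "peaks")), 3L)
  expect_length(list.files(file.path(d, "cna")), 3L)
  expect_true(all(file.exists(file.path(
    d, c("loops.bedpe", "expression.tsv", "mutations.bed",
         "outcome.tsv", "truth.json")))))
  # empty annotation set still produces a (zero-line) BED file
  gb <- file.path(d, "annotations", "good_outcome.bed")
  expect_true(file.exists(gb))
  expect_length(readLines(gb), 0L)

  fx <- read_cohort_fixtures(d)
  for (p in names(co$peak_sets)) {
    expect_equal(start(fx$peak_sets[[p]]), start(co$peak_sets[[p]]))
    expect_equal(end(fx$peak_sets[[p]]), end(co$peak_sets[[p]]))
    expect_equal(fx$peak_sets[[p]]$score, co$peak_sets[[p]]$score)
  }
  expect_equal(fx$expression, co$expression)
  expect_equal(start(fx$mutations), start(co$mutations))
  expect_equal(fx$outcome,
               setNames(co$outcome$label, co$outcome$patient_id))
  expect_equal(start(fx$truth), start(co$truth))
  expect_equal(fx$truth$prevalence, co$truth$prevalence)
  expect_equal(fx$truth$bin, co$truth$bin)
  expect_equal(fx$loops$name, co$loops$name)
  expect_equal(start(fx$loops$anchor2), start(co$loops$anchor2))
  unlink(d, recursive = TRUE)
})
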