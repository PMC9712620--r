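test_that("annotation overlap flags match a pairwise brute force", {
  u <- mock_universe(c(3, 2, 2, 1), 4)   # sites at 1000..1200, 2000.., ...
  ann <- gr("chr1", c(1100, 2100), c(1150, 2105))
  res <- annotate_overlap(u, ann)
  expect_equal(unname(res$flags), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$fraction, 0.5)
  expect_equal(annotate_overlap(u, GenomicRanges::GRanges())$fraction, 0)

  set.seed(11)
  u2 <- mock_universe(sample.int(5, 20, replace = TRUE), 5)
  s <- sample.int(25000, 7)
  ann2 <- gr("chr1", s, s + sample.int(400, 7))
  flags <- annotate_overlap(u2, ann2)$flags
  oracle <- vapply(seq_along(u2$sites), function(i)
    any(start(u2$sites)[i] <= end(ann2) &
          start(ann2) <= end(u2$sites)[i]), logical(1))
  expect_equal(unname(flags), oracle)
})

test_that("hypergeometric tails equal explicit enumeration", {
  # N=10, K=5, n=5, x=2: P(X > 2) = (100 + 25 + 1) / 252 = 0.5
  expect_equal(hypergeom_tail_p(10, 5, 5, 2), 0.5)
  # no outcome above the maximum
  expect_equal(hypergeom_tail_p(10, 5, 5, 5), 0)
  expect_error(hypergeom_tail_p(10, 12, 5, 2), "K <= N")

  for (N in c(5, 11, 18, 25)) {
    for (K in 0:N) for (n in c(0, 1, N %/% 2, N)) {
      for (x in 0:min(K, n)) {
        expect_equal(hypergeom_tail_p(N, K, n, x),
                     hyper_tail_oracle(N, K, n, x), tolerance = 1e-12)
        expect_equal(hypergeom_tail_p(N, K, n, x, inclusive = TRUE),
                     hyper_tail_oracle(N, K, n, x, inclusive = TRUE),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("bin enrichment table is consistent and directions flip on complement", {
  set.seed(3)
  u <- rank_and_bin(mock_universe(c(20, 19, 10, 8, 5, 1, 1, 1), 20))
  flags <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  names(flags) <- u$sites$site_id
  e <- hypergeom_bin_enrichment(u, flags)
  expect_equal(e$N, rep(8L, 3))
  expect_equal(sum(e$n), 8L)
  expect_equal(sum(e$x), sum(flags))
  for (i in seq_len(nrow(e)))
    expect_equal(e$p_value[i],
                 hyper_tail_oracle(e$N[i], e$K[i], e$n[i], e$x[i]))
  ec <- hypergeom_bin_enrichment(u, !flags)
  strict <- e$x != e$expected & ec$x != ec$expected
  expect_true(all(e$direction[strict] != ec$direction[strict]))
})

test_that("mutation O/E arithmetic and Fisher p match the oracles", {
  # equal rates inside and out (10/1000 vs 90/9000): O/E = 1, p ~ 1
  reg <- gr("chr1", 1, 1000)
  pos_in <- round(seq(1, 991, length.out = 10))
  mut_in <- gr("chr1", pos_in, pos_in)
  pos_out <- round(seq(2000, 9950, length.out = 90))
  mut_out <- gr("chr1", pos_out, pos_out)
  r <- mutation_rate_fisher(c(mut_in, mut_out), reg, 1e4)
  expect_equal(r$o_e, 1)
  expect_gt(r$p_value, 0.99)

  # 10 of 100 mutations in 1 kb of a 100 kb genome: O/E = 10
  expect_equal(r$mut_in, 10L)
  r2 <- mutation_rate_fisher(c(mut_in, mut_out), reg, 1e5)
  expect_equal(r2$o_e, 10)
  tab <- matrix(c(10, 990, 90, 1e5 - 1000 - 90), nrow = 2)
  expect_equal(r2$p_value, fisher2x2_oracle(tab), tolerance = 1e-8)

  # degenerate inputs
  r3 <- mutation_rate_fisher(GenomicRanges::GRanges(), reg, 1e5)
  expect_true(is.na(r3$o_e))
  expect_equal(r3$p_value, 1)
  expect_error(mutation_rate_fisher(mut_in, GenomicRanges::GRanges(), 1e5),
               "footprint")
  expect_error(mutation_rate_fisher(mut_in, reg, 10), "smaller")
})

test_that("density-equality permutation test separates and calibrates", {
  x <- rnorm(50, 0, 1)
  same <- density_equality_permutation(x, x, n_perm = 99, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(5)
  a <- rnorm(200); b <- rnorm(200, 3)
  sep <- density_equality_permutation(a, b, n_perm = 199, seed = 2)
  expect_lte(sep$p_value, 0.01)

  # under the null the rejection rate at alpha = 0.05 stays inside a
  # 99% binomial interval; data are generated up front so the
  # permutation seeds cannot feed back into the samples
  set.seed(6)
  nrun <- 300
  dat <- replicate(nrun, list(a = rnorm(30), b = rnorm(30)),
                   simplify = FALSE)
  rej <- vapply(seq_len(nrun), function(i) {
    p <- density_equality_permutation(dat[[i]]$a, dat[[i]]$b,
                                      n_perm = 99, seed = 1000 + i)$p_value
    p <= 0.05
  }, logical(1))
  ci <- 2.576 * sqrt(0.05 * 0.95 / nrun)
  expect_lt(abs(mean(rej) - 0.05), ci + 1e-9)
})

test_that("two-sample comparisons match closed forms and ECDF oracle", {
  idt <- compare_samples(c(1, 2, 3), c(1, 2, 3), method = "t")
  expect_equal(idt$statistic, 0)
  expect_equal(idt$p_value, 1)
  idk <- compare_samples(c(1, 2), c(1, 2), method = "ks")
  expect_equal(idk$statistic, 0)
  expect_equal(idk$p_value, 1)

  # hand-worked pooled t for (1,2,3) vs (4,5,6): sp^2 = 1,
  # t = -3 / sqrt(2/3)
  tt <- compare_samples(c(1, 2, 3), c(4, 5, 6), method = "t")
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$p_value, 2 * pt(-abs(tt$statistic), df = 4),
               tolerance = 1e-12)

  # degenerate variance cases
  expect_true(is.na(compare_samples(c(1, 1), c(1, 1),
                                    method = "t")$statistic))
  zv <- compare_samples(c(2, 2), c(1, 1), method = "t")
  expect_equal(zv$p_value, 0)

  set.seed(8)
  for (rep in 1:15) {
    a <- sample(rnorm(50), sample(3:50, 1))
    b <- sample(rnorm(50, 0.5), sample(3:50, 1))
    expect_equal(compare_samples(a, b, method = "ks")$statistic,
                 ks_D_oracle(a, b), tolerance = 1e-12)
  }
})
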