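test_that("TSS exclusion removes peaks within the window and keeps the rest", {
  # 0-based spec coordinates: TSS at 1000, window [0, 2000)
  tss <- gr("chr1", 1001, 1001)
  peaks <- gr("chr1", c(501, 2501), c(700, 2700), score = c(1, 1))
  out <- exclude_tss(peaks, tss, window_bp = 1000)
  expect_equal(start(out), 2501)
  # boundary: a peak starting exactly at the window edge survives
  edge <- gr("chr1", c(2001, 2000), c(2100, 2100), score = c(1, 1))
  out2 <- exclude_tss(edge, tss, window_bp = 1000)
  expect_equal(start(out2), 2001)
})

test_that("TSS exclusion matches a brute-force pairwise check", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 40
    pstart <- sample.int(20000, n)
    peaks <- gr("chr1", pstart, pstart + sample.int(300, n), score = runif(n))
    tpos <- sample.int(20000, 4)
    tss <- gr("chr1", tpos, tpos)
    w <- 500
    out <- exclude_tss(peaks, tss, window_bp = w)
    keep_oracle <- vapply(seq_len(n), function(i) {
      !any(start(peaks)[i] <= tpos + w - 1 & end(peaks)[i] >= tpos - w)
    }, logical(1))
    expect_equal(start(out), start(peaks)[keep_oracle])
  }
})

test_that("universe merging follows single linkage with per-patient counting", {
  # 0-based: A {[100,200),[300,400)}, B {[150,250)}, C {[150,160)}
  ps <- list(
    A = gr("chr1", c(101, 301), c(200, 400), score = c(5, 7)),
    B = gr("chr1", 151, 250, score = 3),
    C = gr("chr1", 151, 160, score = 2)
  )
  u <- build_universe(ps)
  expect_equal(start(u$sites), c(101, 301))
  expect_equal(end(u$sites), c(250, 400))
  expect_equal(u$sites$prevalence, c(3L, 1L))
  # occurrence holds log1p of the per-patient max score
  expect_equal(unname(u$occurrence["A", ]), c(log1p(5), log1p(7)))
  expect_equal(unname(u$occurrence["C", 2]), 0)
})

test_that("a single patient's universe is its own merged peak set", {
  ps <- list(A = gr("chr1", c(1, 50, 500), c(60, 100, 600),
                    score = c(1, 2, 3)))
  u <- build_universe(ps)
  expect_equal(length(u$sites), 2L)
  expect_true(all(u$sites$prevalence == 1L))
})

test_that("universe equals brute-force overlap-graph components", {
  set.seed(7)
  for (rep in 1:8) {
    n_pat <- sample(2:4, 1)
    ps <- lapply(seq_len(n_pat), function(p) {
      k <- sample(10:60, 1)
      s <- sample.int(5000, k)
      GenomicRanges::sort(gr(sample(c("chr1", "chr2"), k, replace = TRUE),
                             s, s + sample.int(200, k),
                             score = runif(k)))
    })
    names(ps) <- paste0("P", seq_len(n_pat))
    all_chr <- unlist(lapply(ps, function(g) as.character(seqnames(g))))
    all_s <- unlist(lapply(ps, start))
    all_e <- unlist(lapply(ps, end))
    oracle <- bf_components(all_chr, all_s, all_e)
    u <- build_universe(ps)
    expect_equal(as.character(seqnames(u$sites)), oracle$chrom)
    expect_equal(start(u$sites), oracle$start)
    expect_equal(end(u$sites), oracle$end)
    # prevalence equals the per-patient brute-force overlap count
    prev_oracle <- vapply(seq_len(nrow(oracle)), function(i)
      sum(vapply(ps, function(g)
        any(as.character(seqnames(g)) == oracle$chrom[i] &
              start(g) <= oracle$end[i] & end(g) >= oracle$start[i]),
        logical(1))), integer(1))
    expect_equal(u$sites$prevalence, prev_oracle)
    # matrix row presence count per site equals stored prevalence
    expect_equal(unname(colSums(u$presence)), unname(u$sites$prevalence))
  }
})

test_that("invalid peak-set input is rejected", {
  expect_error(build_universe(list()), "non-empty")
  expect_error(build_universe(list(A = gr("chr1", 1, 10))), "score")
})

test_that("binning reproduces the 88-patient thresholds", {
  u <- mock_universe(c(88, 60, 59, 45, 2, 1), 88)
  u <- rank_and_bin(u, sh_fraction = 0.68)
  expect_equal(u$sh_min_patients, 60L)
  got <- setNames(u$sites$bin, u$sites$prevalence)
  expect_equal(unname(got[c("88", "60", "59", "45", "2", "1")]),
               c("SH", "SH", "PS", "PS", "PS", "UN"))
  expect_equal(u$sites$rank, 1:6)
  expect_true(all(diff(u$sites$prevalence) <= 0))
})

test_that("changing sh_fraction moves only the SH/PS boundary, never UN", {
  set.seed(1)
  for (rep in 1:10) {
    n_pat <- sample(5:90, 1)
    u <- mock_universe(sample.int(n_pat, 30, replace = TRUE), n_pat)
    bins <- lapply(c(0.3, 0.68, 1), function(f)
      rank_and_bin(u, sh_fraction = f)$sites$bin)
    un_sets <- lapply(bins, function(b) which(b == "UN"))
    expect_equal(un_sets[[1]], un_sets[[2]])
    expect_equal(un_sets[[2]], un_sets[[3]])
    # binning is always a partition
    for (b in bins) expect_true(all(b %in% c("SH", "PS", "UN")))
  }
  expect_error(rank_and_bin(mock_universe(1, 5), sh_fraction = 0),
               "sh_fraction")
  expect_error(rank_and_bin(mock_universe(1, 5), sh_fraction = 1.2),
               "sh_fraction")
})

test_that("prevalence consensus partitions the universe across levels", {
  ps <- list(
    A = gr("chr1", c(101, 301, 901), c(200, 400, 950), score = c(1, 1, 1)),
    B = gr("chr1", c(151, 301), c(250, 400), score = c(1, 1)),
    C = gr("chr1", 301, 400, score = 1)
  )
  u <- rank_and_bin(build_universe(ps))
  expect_length(prevalence_consensus(u, 3), 1L)   # [301,400]
  levels_gr <- lapply(1:3, prevalence_consensus, universe = u)
  all_gr <- do.call(c, levels_gr)
  # pairwise disjoint and jointly covering the universe
  expect_equal(sum(countOverlaps(all_gr, all_gr)), length(all_gr))
  expect_equal(sum(width(all_gr)), sum(width(u$sites)))
  expect_length(prevalence_consensus(u, 2), 1L)
  # beyond the max observed prevalence: empty set
  ps1 <- list(A = gr("chr1", 1, 100, score = 1),
              B = gr("chr1", 1, 100, score = 1))
  u1 <- build_universe(ps1)
  expect_length(prevalence_consensus(u1, 1), 0L)
})

test_that("consensus at a lower level excludes higher-level regions", {
  # hand-worked nested case: overlapping site list injected directly
  u <- mock_universe(c(3, 2, 2, 1), 3)
  u$sites <- gr("chr1", c(101, 151, 501, 481),
                c(200, 250, 600, 700))
  u$sites$site_id <- sprintf("site_%05d", 1:4)
  u$sites$prevalence <- c(3L, 2L, 2L, 1L)
  u$sites$rank <- NA_integer_; u$sites$bin <- NA_character_
  lvl2 <- prevalence_consensus(u, 2)
  expect_equal(start(lvl2), c(201, 501))   # [151,250] minus [101,200]
  expect_equal(end(lvl2), c(250, 600))
  lvl1 <- prevalence_consensus(u, 1)
  expect_equal(start(lvl1), c(481, 601))   # [481,700] minus [501,600]
  expect_equal(end(lvl1), c(500, 700))
})

test_that("normalized prevalence is the cohort fraction", {
  u <- rank_and_bin(mock_universe(c(60, 88), 88))
  f <- normalize_prevalence(u)
  expect_equal(unname(f), c(1, 60 / 88))
  # proportional prevalences in cohorts of different size normalize equally
  u1 <- mock_universe(c(4, 8, 20), 20)
  u2 <- mock_universe(c(1, 2, 5), 5)
  expect_equal(unname(normalize_prevalence(u1)),
               unname(normalize_prevalence(u2)))
})
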