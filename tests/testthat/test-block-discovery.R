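test_that("pairwise r2 matches hand computation on 2x2 tables", {
  perfect <- haplotype_records(rep("chr1", 2), c(1L, 1L), c("11", "00"),
                               c(5L, 5L))
  expect_equal(pairwise_r2(perfect, 1L, 2L, min_pairs = 2)$r2, 1)
  indep <- haplotype_records(rep("chr1", 4), rep(1L, 4),
                             c("11", "10", "01", "00"), rep(2L, 4))
  expect_equal(pairwise_r2(indep, 1L, 2L, min_pairs = 2)$r2, 0)
  skew <- haplotype_records(rep("chr1", 4), rep(1L, 4),
                            c("11", "10", "01", "00"), c(4L, 1L, 1L, 4L))
  expect_equal(pairwise_r2(skew, 1L, 2L, min_pairs = 2)$r2, 0.36)
})

test_that("r2 is undefined for constant margins or too few co-covering reads", {
  const <- haplotype_records(rep("chr1", 2), c(1L, 1L), c("10", "11"),
                             c(5L, 5L))
  expect_true(is.na(pairwise_r2(const, 1L, 2L, min_pairs = 2)$r2))
  few <- haplotype_records(rep("chr1", 2), c(1L, 1L), c("11", "00"),
                           c(1L, 1L))
  res <- pairwise_r2(few, 1L, 2L, min_pairs = 10)
  expect_true(is.na(res$r2))
  expect_equal(res$n_pairs, 2)
  expect_error(pairwise_r2(const, 1L, 3L), "adjacent")
})

test_that("r2 matches Pearson correlation on count-expanded read lists", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    haps <- vapply(seq_len(n), function(i)
      paste(sample(c("0", "1", "?"), 2, TRUE, c(.45, .45, .1)),
            collapse = ""), "")
    counts <- sample.int(6L, n, replace = TRUE)
    recs <- haplotype_records(rep("chr1", n), rep(1L, n), haps, counts)
    got <- pairwise_r2(recs, 1L, 2L, min_pairs = 1L)$r2
    a <- substr(haps, 1, 1); b <- substr(haps, 2, 2)
    ok <- a != "?" & b != "?"
    expected <- oracle_r2(as.integer(a[ok] == "1"), as.integer(b[ok] == "1"),
                          counts[ok])
    if (is.na(expected)) expect_true(is.na(got))
    else expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("partition_blocks splits at weak pairs and drops singletons", {
  sites <- cpg_index(list(chr1 = (0:3) * 30L))
  recs <- make_pair_records(c(1, 1, 0))
  reg <- partition_blocks(recs, sites, min_pairs = 10L)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$first_site, 1L)
  expect_equal(reg$n_sites, 3L)
  expect_equal(reg$start, 0L)
  expect_equal(reg$end, 62L)
  # all pairs weak: nothing survives
  none <- partition_blocks(make_pair_records(c(0, 0, 0)), sites)
  expect_equal(nrow(none), 0L)
})

test_that("linkage exactly at the threshold does not form a block", {
  sites <- cpg_index(list(chr1 = c(0L, 30L)))
  # 2x2 counts (11 = 2, 01 = 1, 00 = 3) give r2 = 36/72 = 0.5 exactly
  recs <- haplotype_records(rep("chr1", 3), rep(1L, 3),
                            c("11", "01", "00"), c(2L, 1L, 3L))
  expect_identical(pairwise_r2(recs, 1L, 2L, min_pairs = 1)$r2, 0.5)
  expect_equal(nrow(partition_blocks(recs, sites, min_pairs = 1L)), 0L)
})

test_that("a genomic gap above max_gap breaks the chain", {
  sites <- cpg_index(list(chr1 = c(0L, 30L, 900L, 930L)))
  recs <- make_pair_records(c(1, 1, 1))
  reg <- partition_blocks(recs, sites, min_pairs = 10L, max_gap = 500L)
  expect_equal(reg$first_site, c(1L, 3L))
  expect_equal(reg$n_sites, c(2L, 2L))
  all_one <- partition_blocks(recs, sites, min_pairs = 10L, max_gap = Inf)
  expect_equal(nrow(all_one), 1L)
})

test_that("partitioning equals the exhaustive maximal-run scan on random instances", {
  set.seed(77)
  for (rep in 1:20) {
    n_sites <- sample(20:100, 1)
    sites <- cpg_index(list(chr1 = (seq_len(n_sites) - 1L) * 30L))
    linked_target <- runif(n_sites - 1L) < 0.55
    recs <- make_pair_records(as.numeric(linked_target))
    reg <- partition_blocks(recs, sites, min_pairs = 10L)
    # recompute linkage exactly as the oracle sees it
    linked <- vapply(seq_len(n_sites - 1L), function(i) {
      r2 <- pairwise_r2(recs, i, i + 1L, min_pairs = 10L)$r2
      !is.na(r2) && r2 > 0.5
    }, TRUE)
    runs <- oracle_runs(linked)
    expect_equal(nrow(reg), length(runs))
    if (length(runs)) {
      expect_equal(reg$first_site, vapply(runs, `[[`, 1L, "first"))
      expect_equal(reg$first_site + reg$n_sites - 1L,
                   vapply(runs, `[[`, 1L, "last"))
    }
  }
})

test_that("blocks are invariant to read order and count splitting", {
  set.seed(5)
  sites <- cpg_index(list(chr1 = (0:9) * 30L))
  n <- 120L
  len <- sample(2:4, n, replace = TRUE)
  recs <- haplotype_records(
    rep("chr1", n),
    vapply(len, function(l) sample.int(10L - l + 1L, 1), 1L),
    vapply(len, function(l)
      paste(sample(c("0", "1"), l, TRUE), collapse = ""), ""),
    sample.int(4L, n, replace = TRUE))
  base <- partition_blocks(recs, sites, min_pairs = 5L)
  shuffled <- recs[sample.int(n), ]
  expect_equal(as.data.frame(partition_blocks(shuffled, sites, min_pairs = 5L)),
               as.data.frame(base))
  split_recs <- haplotype_records(
    rep("chr1", sum(recs$count)), rep(recs$site_start, recs$count),
    rep(recs$hap, recs$count), rep(1L, sum(recs$count)))
  expect_equal(as.data.frame(partition_blocks(split_recs, sites, min_pairs = 5L)),
               as.data.frame(base))
})

test_that("raising the r2 threshold only refines blocks", {
  set.seed(31)
  sites <- cpg_index(list(chr1 = (0:29) * 30L))
  n <- 600L
  len <- sample(2:5, n, replace = TRUE)
  recs <- haplotype_records(
    rep("chr1", n),
    vapply(len, function(l) sample.int(30L - l + 1L, 1), 1L),
    vapply(len, function(l) {
      calls <- integer(l)
      calls[1] <- stats::rbinom(1, 1, 0.5)
      for (j in seq_len(l - 1))
        calls[j + 1] <- if (runif(1) < 0.25) 1L - calls[j] else calls[j]
      paste(calls, collapse = "")
    }, ""),
    rep(1L, n))
  for (pair in list(c(0.2, 0.5), c(0.5, 0.8))) {
    coarse <- partition_blocks(recs, sites, r2_threshold = pair[1],
                               min_pairs = 5L)
    fine <- partition_blocks(recs, sites, r2_threshold = pair[2],
                             min_pairs = 5L)
    # every fine block lies inside some coarse block
    for (i in seq_len(nrow(fine))) {
      lo <- fine$first_site[i]
      hi <- lo + fine$n_sites[i] - 1L
      inside <- any(coarse$first_site <= lo &
                      coarse$first_site + coarse$n_sites - 1L >= hi)
      expect_true(inside)
    }
  }
})
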