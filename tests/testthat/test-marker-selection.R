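test_that("sample detection filter keeps exactly the samples at the floor", {
  mat <- matrix(NA_real_, 3, 6, dimnames = list(c("a", "b", "c"),
                                                paste0("m", 1:6)))
  mat[1, 1:4] <- 0.5
  mat[2, 1:5] <- 0.5
  mat[3, 1:6] <- 0.5
  expect_equal(filter_samples(mat, 5), c("b", "c"))
  expect_equal(filter_samples(mat, 0), c("a", "b", "c"))
  expect_error(filter_samples(mat, 7), "detection floor")
})

test_that("block filter applies inclusive detection and variability thresholds", {
  mat <- cbind(
    sparse = c(0.5, NA, NA),              # detected in 1/3 < 2/3
    constant = c(0.4, 0.4, 0.4),          # SD 0
    boundary = c(0.10, 0.12, 0.14),       # SD exactly 0.02
    strong = c(0.1, 0.5, 0.9))
  rownames(mat) <- c("a", "b", "c")
  expect_equal(sd(mat[, "boundary"]), 0.02)
  kept <- filter_blocks(mat, 2 / 3, 0.02)
  expect_equal(kept, c("boundary", "strong"))
})

test_that("rank-sum p-values match exact enumeration on worked examples", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r$p, 1 / 20)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "two_sided")$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(), c(1, 2)), "empty")
})

test_that("rank-sum p-values match full permutation enumeration on random data", {
  set.seed(8)
  for (alt in c("greater", "less", "two_sided")) {
    for (rep in 1:10) {
      x <- runif(5); y <- runif(5)
      expect_equal(wilcoxon_rank_sum(x, y, alt)$p,
                   oracle_rank_sum_p(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("signed-rank p-values match sign-flip enumeration", {
  # all-positive distinct differences, n = 5, one-sided
  r <- wilcoxon_signed_rank(c(2, 4, 7, 11, 16), c(1, 2, 3, 4, 5), "greater")
  expect_equal(r$p, 1 / 32)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "nonzero")
  set.seed(9)
  for (alt in c("greater", "less", "two_sided")) {
    for (rep in 1:10) {
      x <- runif(8); y <- runif(8)
      expect_equal(wilcoxon_signed_rank(x, y, alt)$p,
                   oracle_signed_rank_p(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # monotone in raw p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("marker selection recovers spiked tumor blocks with direction tags", {
  co <- tiny_cohort()
  mat <- score_cohort(co$records, co$regions)
  cfg <- filter_config(min_detected_per_sample = 30L,
                       test = "signed_rank", alternative = "both",
                       fdr_threshold = 0.05)
  mk <- select_markers(mat, co$metadata, cfg, "tumor_vs_normal")
  expect_s3_class(mk, "marker_set")
  expect_true(all(mk$fdr_q < 0.05))
  expect_true(all(mk$fdr_q >= mk$raw_p))
  spiked <- co$truth[co$truth$type == "tumor_diff", ]
  expect_gte(sum(spiked$id %in% mk$id), nrow(spiked) - 3L)
  # directions agree with the simulated shift for true discoveries
  hit <- mk[mk$id %in% spiked$id, ]
  expect_true(all(hit$direction ==
                    spiked$direction[match(hit$id, spiked$id)]))
})

test_that("one-sided selection in a single direction never returns the other", {
  co <- tiny_cohort()
  mat <- score_cohort(co$records, co$regions)
  cfg <- filter_config(min_detected_per_sample = 30L,
                       test = "signed_rank", alternative = "greater",
                       fdr_threshold = 0.05)
  mk <- select_markers(mat, co$metadata, cfg, "tumor_vs_normal")
  expect_true(all(mk$direction == "hyper"))
  hypo <- co$truth$id[co$truth$type == "tumor_diff" &
                        co$truth$direction == "hypo"]
  expect_false(any(hypo %in% mk$id))
})

test_that("MVI contrast combines MHL and UMHL marker sets with kind tags", {
  co <- tiny_cohort()
  mats <- list(MHL = score_cohort(co$records, co$regions, score_kind = "MHL"),
               UMHL = score_cohort(co$records, co$regions,
                                   score_kind = "UMHL"))
  cfg <- filter_config(min_detected_per_sample = 30L, test = "rank_sum",
                       alternative = "both", fdr_threshold = 0.05)
  mk <- select_markers(mats, co$metadata, cfg, "mvi")
  expect_true(all(mk$score_kind %in% c("MHL", "UMHL")))
  spiked <- co$truth$id[co$truth$type == "mvi_diff"]
  expect_gte(sum(unique(mk$id) %in% spiked), 3L)
  # tumor-differential blocks are not MVI markers
  tum <- co$truth$id[co$truth$type == "tumor_diff"]
  expect_lte(sum(unique(mk$id) %in% tum), 1L)
})

test_that("null cohorts yield near-nominal selection rates", {
  spec <- cohort_spec(n_normal = 12, n_mvi_neg = 6, n_mvi_pos = 6,
                      n_healthy_plasma = 0, patient_plasma = FALSE,
                      n_blocks = 200, n_diff_tumor = 0, n_diff_mvi = 0,
                      seed = 404)
  co <- simulate_cohort(spec)
  mat <- score_cohort(co$records, co$regions)
  cfg <- filter_config(min_detected_per_sample = 20L, test = "signed_rank",
                       alternative = "both", fdr_threshold = 0.05)
  mk <- select_markers(mat, co$metadata, cfg, "tumor_vs_normal")
  # with no signal anywhere, BH keeps the expected selection count tiny
  expect_lte(nrow(mk), 3L)
  # per-test type-I control at alpha: two-sided p-values are uniform
  tum <- co$metadata$sample_id[co$metadata$tumor_status == "tumor" &
                                 co$metadata$specimen == "tissue"]
  nor <- co$metadata$sample_id[co$metadata$tumor_status == "normal"]
  pvals <- vapply(colnames(mat), function(id)
    tryCatch(wilcoxon_rank_sum(mat[tum, id], mat[nor, id], "two_sided")$p,
             error = function(e) NA_real_), 1)
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!is.na(pvals))) +
              0.02)
})

test_that("filter cascade equals the joint application of its predicates", {
  co <- tiny_cohort()
  mat <- score_cohort(co$records, co$regions)
  kept_samples <- filter_samples(mat, 30L)
  sub <- mat[kept_samples, ]
  staged <- filter_blocks(sub, 2 / 3, 0.02)
  joint <- colnames(sub)[colMeans(!is.na(sub)) >= 2 / 3 &
                           apply(sub, 2, sd, na.rm = TRUE) >= 0.02]
  expect_identical(staged, joint)
})
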