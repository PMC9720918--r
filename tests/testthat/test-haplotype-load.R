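test_that("haplotype load matches hand-computed values on worked examples", {
  # fully methylated read: all fractions 1 at every length
  r <- haplotype_records("chr1", 1L, "111", 1L)
  sf <- substring_fractions(r, 1L, 3L)
  expect_equal(sf$frac_meth, c(1, 1, 1))
  expect_equal(mhl(r, 1L, 3L), 1)
  # "10": one methylated and one unmethylated length-1 window, no length-2
  r <- haplotype_records("chr1", 1L, "10", 1L)
  sf <- substring_fractions(r, 1L, 2L)
  expect_equal(sf$frac_meth, c(0.5, 0))
  expect_equal(sf$frac_unmeth, c(0.5, 0))
  expect_equal(mhl(r, 1L, 2L), (1 * 0.5 + 8 * 0) / 9)
  expect_equal(umhl(r, 1L, 2L), (1 * 0.5 + 8 * 0) / 9)
  # missing call splits the read into two length-1 segments
  r <- haplotype_records("chr1", 1L, "1?1", 1L)
  sf <- substring_fractions(r, 1L, 3L)
  expect_equal(sf$n_windows, c(2, 0, 0))
  expect_equal(sf$frac_meth[1], 1)
  expect_equal(mhl(r, 1L, 3L), 1)   # only length 1 evaluable
  # {11, 00}: P(MH) = (0.5, 0.5) so cubic weights cancel to 0.5
  r <- haplotype_records(c("chr1", "chr1"), c(1L, 1L), c("11", "00"),
                         c(1L, 1L))
  expect_equal(mhl(r, 1L, 2L), 0.5)
  expect_equal(umhl(r, 1L, 2L), 0.5)
})

test_that("undetected blocks and all-missing reads score as missing", {
  r <- haplotype_records("chr1", 10L, "11", 1L)
  expect_true(is.na(mhl(r, 1L, 3L)))           # no overlap
  r <- haplotype_records("chr1", 1L, "??", 1L)
  expect_true(is.na(mhl(r, 1L, 2L)))           # nothing evaluable
})

test_that("MHL/UMHL agree with the brute-force window enumerator", {
  set.seed(42)
  for (rep in 1:300) {
    l <- sample(2:6, 1)
    b <- random_block(l, 20)
    recs <- haplotype_records(rep("chr1", length(b$haps)), b$starts, b$haps,
                              b$counts)
    # oracle works on in-block strings: pad reads to block coordinates
    padded <- vapply(seq_along(b$haps), function(i)
      paste0(strrep("?", b$starts[i] - 1L), b$haps[i]), "")
    expect_equal(mhl(recs, 1L, l), oracle_load(padded, b$counts, l, 3, "meth"),
                 tolerance = 1e-12)
    expect_equal(umhl(recs, 1L, l),
                 oracle_load(padded, b$counts, l, 3, "unmeth"),
                 tolerance = 1e-12)
  }
})

test_that("UMHL equals MHL of the complemented records exactly", {
  set.seed(11)
  for (rep in 1:100) {
    l <- sample(2:6, 1)
    b <- random_block(l, 15)
    recs <- haplotype_records(rep("chr1", length(b$haps)), b$starts, b$haps,
                              b$counts)
    expect_identical(umhl(recs, 1L, l), mhl(complement_calls(recs), 1L, l))
  }
})

test_that("load statistics are bounded, count-scale invariant, and reduce to the beta value at l = 1 windows", {
  set.seed(3)
  for (rep in 1:50) {
    l <- sample(2:5, 1)
    b <- random_block(l, 10)
    recs <- haplotype_records(rep("chr1", length(b$haps)), b$starts, b$haps,
                              b$counts)
    v <- mhl(recs, 1L, l)
    if (!is.na(v)) expect_true(v >= 0 && v <= 1)
    # duplicating every read leaves the statistic unchanged
    dup <- recs
    dup$count <- dup$count * 3L
    expect_equal(mhl(dup, 1L, l), v, tolerance = 1e-12)
    # splitting a count-c record into c count-1 records too
    split_recs <- haplotype_records(
      rep("chr1", sum(b$counts)), rep(b$starts, b$counts),
      rep(b$haps, b$counts), rep(1L, sum(b$counts)))
    expect_equal(mhl(split_recs, 1L, l), v, tolerance = 1e-12)
  }
  # degenerate single-CpG block: MHL = methylation frequency
  r <- haplotype_records(rep("chr1", 2), c(1L, 1L), c("1", "0"), c(3L, 1L))
  expect_equal(mhl(r, 1L, 1L), 0.75)
})

test_that("linear weighting is one parameter away", {
  r <- haplotype_records("chr1", 1L, "10", 1L)
  expect_equal(mhl(r, 1L, 2L, load_params(weight_exponent = 1)),
               (1 * 0.5 + 2 * 0) / 3)
})

test_that("score_cohort fills cells, marks undetected blocks, and matches per-cell recomputation", {
  regions <- data.frame(id = c("b1", "b2"), chrom = "chr1",
                        start = c(0L, 100L), end = c(62L, 162L),
                        first_site = c(1L, 4L), n_sites = c(3L, 3L))
  samples <- list(
    s1 = haplotype_records(rep("chr1", 2), c(1L, 4L), c("11", "010"),
                           c(10L, 2L)),
    s2 = haplotype_records("chr1", 1L, "111", 5L))
  mat <- score_cohort(samples, regions)
  expect_equal(dim(mat), c(2L, 2L))
  expect_true(is.na(mat["s2", "b2"]))
  expect_equal(mat["s1", "b1"], mhl(samples$s1, 1L, 3L))
  expect_equal(mat["s1", "b2"], mhl(samples$s1, 4L, 3L))
  expect_equal(mat["s2", "b1"], 1)
  umat <- score_cohort(samples, regions, score_kind = "UMHL")
  expect_equal(umat["s1", "b2"], umhl(samples$s1, 4L, 3L))
})

test_that("cohort score matrix equals brute-force recomputation per cell", {
  co <- simulate_cohort(cohort_spec(n_normal = 3, n_mvi_neg = 2,
                                    n_mvi_pos = 2, n_healthy_plasma = 2,
                                    n_blocks = 25, n_diff_tumor = 3,
                                    n_diff_mvi = 2, seed = 9))
  mat <- score_cohort(co$records, co$regions)
  for (s in names(co$records)) {
    recs <- co$records[[s]]
    for (j in sample.int(nrow(co$regions), 8)) {
      fs <- co$regions$first_site[j]
      ns <- co$regions$n_sites[j]
      sel <- recs$site_start + nchar(recs$hap) - 1L >= fs &
        recs$site_start <= fs + ns - 1L
      expected <- if (!any(sel)) NA_real_ else {
        padded <- vapply(which(sel), function(i)
          substr(paste0(strrep("?", recs$site_start[i] - 1L), recs$hap[i]),
                 fs, fs + ns - 1L), "")
        oracle_load(padded, recs$count[sel], ns, 3, "meth")
      }
      expect_equal(mat[s, co$regions$id[j]], expected, tolerance = 1e-12)
    }
  }
})

test_that("reads crossing block boundaries contribute only in-block windows", {
  regions <- data.frame(id = c("b1", "b2"), chrom = "chr1",
                        start = c(0L, 60L), end = c(32L, 92L),
                        first_site = c(1L, 3L), n_sites = c(2L, 2L))
  # one read spanning both blocks: "1101" over sites 1..4
  samples <- list(s = haplotype_records("chr1", 1L, "1101", 1L))
  mat <- score_cohort(samples, regions)
  expect_equal(mat["s", "b1"], 1)                       # "11"
  expect_equal(mat["s", "b2"], mhl(
    haplotype_records("chr1", 1L, "01", 1L), 1L, 2L))   # "01"
})
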