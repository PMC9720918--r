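#' Pairwise methylation linkage disequilibrium
#'
#' Computes r-squared — the squared Pearson correlation of the two binary
#' call vectors — between two adjacent CpG sites, over reads covering both
#' sites with non-missing calls at both, weighted by record counts.
#' r-squared is undefined (NA) when fewer than `min_pairs` reads co-cover
#' the sites or when either site's calls are constant among them.
#'
#' @param records A [haplotype_records()] data.frame (one chromosome).
#' @param left_site,right_site Adjacent CpG ordinals (`right = left + 1`).
#' @param min_pairs Minimum co-covering read count for a defined value.
#' @return A one-row data.frame: `left_site`, `right_site`, `r2`, `n_pairs`.
#' @examples
#' recs <- haplotype_records(rep("chr1", 2), c(1L, 1L), c("11", "00"),
#'                           c(5L, 5L))
#' pairwise_r2(recs, 1L, 2L, min_pairs = 2)
#' @export
pairwise_r2 <- function(records, left_site, right_site, min_pairs = 10L) {
  if (right_site != left_site + 1L)
    stop("pairwise_r2 is defined for adjacent sites only")
  if (length(unique(records$chrom)) > 1L)
    stop("records must come from a single chromosome")
  off <- left_site - records$site_start + 1L
  len <- nchar(records$hap)
  cover <- off >= 1L & off + 1L <= len
  a <- substr(records$hap[cover], off[cover], off[cover])
  b <- substr(records$hap[cover], off[cover] + 1L, off[cover] + 1L)
  ok <- a != "?" & b != "?"
  cnt <- records$count[cover][ok]
  r2_from_counts(as.integer(a[ok] == "1"), as.integer(b[ok] == "1"),
                 cnt, left_site, right_site, min_pairs)
}

r2_from_counts <- function(a, b, cnt, left_site, right_site, min_pairs) {
  cnt <- as.numeric(cnt)
  n <- sum(cnt)
  out <- data.frame(left_site = left_site, right_site = right_site,
                    r2 = NA_real_, n_pairs = n)
  if (n < min_pairs) return(out)
  n11 <- sum(cnt[a == 1L & b == 1L])
  nL <- sum(cnt[a == 1L])
  nR <- sum(cnt[b == 1L])
  denom <- nL * (n - nL) * nR * (n - nR)
  if (denom == 0) return(out)          # constant margin: undefined
  out$r2 <- (n * n11 - nL * nR)^2 / denom
  out
}

# adjacent-pair LD table for one chromosome, count-weighted over all records
adjacent_pair_ld <- function(records, n_sites, min_pairs = 10L) {
  len <- nchar(records$hap)
  multi <- which(len >= 2L)
  if (length(multi)) {
    reps <- len[multi] - 1L
    row <- rep(multi, reps)
    offs <- sequence(reps)
    pair <- records$site_start[row] + offs - 1L
    a <- substr(records$hap[row], offs, offs)
    b <- substr(records$hap[row], offs + 1L, offs + 1L)
    ok <- a != "?" & b != "?"
    dt <- data.table::data.table(pair = pair[ok],
                                 a = as.integer(a[ok] == "1"),
                                 b = as.integer(b[ok] == "1"),
                                 cnt = as.numeric(records$count[row][ok]))
    agg <- dt[, list(n = sum(cnt), n11 = sum(cnt[a == 1L & b == 1L]),
                     nL = sum(cnt[a == 1L]), nR = sum(cnt[b == 1L])),
              by = "pair"]
  } else {
    agg <- data.table::data.table(pair = integer(), n = numeric(),
                                  n11 = numeric(), nL = numeric(),
                                  nR = numeric())
  }
  out <- data.frame(left_site = seq_len(n_sites - 1L),
                    right_site = seq_len(n_sites - 1L) + 1L,
                    r2 = NA_real_, n_pairs = 0)
  m <- match(agg$pair, out$left_site)
  out$n_pairs[m] <- agg$n
  denom <- agg$nL * (agg$n - agg$nL) * agg$nR * (agg$n - agg$nR)
  out$r2[m] <- ifelse(denom > 0 & agg$n >= min_pairs,
                      (agg$n * agg$n11 - agg$nL * agg$nR)^2 / denom,
                      NA_real_)
  out
}

#' Partition CpG sites into methylation haplotype blocks
#'
#' Chains adjacent CpG pairs whose methylation r-squared exceeds the
#' threshold: maximal runs of consecutive CpGs in which every adjacent
#' pair has a defined r-squared strictly greater than `r2_threshold`
#' become one block; singleton runs are discarded (a block needs at least
#' two sites). An undefined r-squared (too few co-covering reads or a
#' constant margin) breaks the chain, as does a genomic gap larger than
#' `max_gap` between the pair's positions.
#'
#' @param records A [haplotype_records()] data.frame, pooled over the
#'   reference samples.
#' @param sites A [cpg_index()].
#' @param r2_threshold Linkage threshold; pairs with r-squared exactly at
#'   the threshold are excluded.
#' @param min_pairs Minimum co-covering reads for a defined r-squared.
#' @param max_gap Maximum genomic distance (bp) between adjacent CpGs for
#'   them to be linkable; `Inf` disables the gap rule.
#' @return An `mhb_regions` data.frame (`id`, `chrom`, `start`, `end`,
#'   `first_site`, `n_sites`), sorted and non-overlapping.
#' @export
partition_blocks <- function(records, sites, r2_threshold = 0.5,
                             min_pairs = 10L, max_gap = 500L) {
  stopifnot(inherits(sites, "cpg_index"))
  per_chrom <- list()
  for (ch in names(sites)) {
    pos <- sites[[ch]]
    n <- length(pos)
    if (n < 2L) next
    recs <- records[records$chrom == ch, , drop = FALSE]
    ld <- adjacent_pair_ld(recs, n, min_pairs)
    gap_ok <- diff(pos) <= max_gap
    linked <- !is.na(ld$r2) & ld$r2 > r2_threshold & gap_ok
    runs <- rle(linked)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values
    if (!any(keep)) next
    first <- starts[keep]              # first linked pair -> first site
    last <- ends[keep] + 1L            # last site of the run
    per_chrom[[ch]] <- data.frame(
      chrom = ch, start = pos[first], end = pos[last] + 2L,
      first_site = first, n_sites = last - first + 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(per_chrom)) {
    out <- data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      first_site = integer(), n_sites = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, per_chrom)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    out$id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
    out <- out[c("id", "chrom", "start", "end", "first_site", "n_sites")]
    rownames(out) <- NULL
  }
  class(out) <- c("mhb_regions", "data.frame")
  out
}

#' Pool records across samples
#'
#' Concatenates per-sample record sets (e.g. for pooled block discovery).
#'
#' @param record_list Named list of [haplotype_records()].
#' @return A single `haplotype_records` data.frame.
#' @export
pool_records <- function(record_list) {
  df <- do.call(rbind, lapply(unname(record_list), as.data.frame))
  if (is.null(df)) return(haplotype_records())
  validate_haplotype_records(df)
}
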