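#' Haplotype load scoring parameters
#'
#' @param weight_exponent Positive exponent of the length weights
#'   `w_i = i^weight_exponent`. The default cubic weighting emphasises long
#'   consecutive runs; `weight_exponent = 1` recovers linear weighting.
#' @param min_reads_detect Minimum reads overlapping a block for it to
#'   count as detected; undetected blocks score as missing.
#' @param count_weighted Logical; count each record's windows `count`
#'   times (default) rather than once per distinct haplotype string.
#' @return An object of class `load_params`.
#' @export
load_params <- function(weight_exponent = 3, min_reads_detect = 1L,
                        count_weighted = TRUE) {
  stopifnot(weight_exponent > 0, min_reads_detect >= 1L)
  structure(list(weight_exponent = weight_exponent,
                 min_reads_detect = as.integer(min_reads_detect),
                 count_weighted = isTRUE(count_weighted)),
            class = "load_params")
}

# clip records to a block's ordinal span; returns in-block call strings
# and counts (empty when nothing overlaps)
clip_to_block <- function(records, first_site, n_sites,
                          count_weighted = TRUE) {
  last_site <- first_site + n_sites - 1L
  len <- nchar(records$hap)
  s <- records$site_start
  lo <- pmax(s, first_site)
  hi <- pmin(s + len - 1L, last_site)
  keep <- which(lo <= hi)
  list(hap = substr(records$hap[keep], lo[keep] - s[keep] + 1L,
                    hi[keep] - s[keep] + 1L),
       count = if (count_weighted) as.numeric(records$count[keep])
               else rep(1, length(keep)))
}

#' Per-length consecutive substring fractions
#'
#' For each window length `i` from 1 to the block length, the fraction of
#' contiguous length-`i` call windows that are fully methylated and fully
#' un-methylated, over all reads intersecting the block. Reads are clipped
#' to the block and segmented at missing calls before windows are
#' enumerated, so no window spans a missing call; a count-`c` record
#' contributes `c` copies of each of its windows.
#'
#' @param records A [haplotype_records()] data.frame.
#' @param first_site,n_sites The block's first CpG ordinal and length.
#' @param params A [load_params()].
#' @return A data.frame with one row per length: `length`, `n_windows`,
#'   `frac_meth`, `frac_unmeth` (fractions `NA` where no window of that
#'   length is evaluable).
#' @export
substring_fractions <- function(records, first_site, n_sites,
                                params = load_params()) {
  cl <- clip_to_block(records, first_site, n_sites, params$count_weighted)
  counts <- hap_window_counts(cl$hap, cl$count, as.integer(n_sites))
  data.frame(length = seq_len(n_sites),
             n_windows = counts[, 1L],
             frac_meth = ifelse(counts[, 1L] > 0,
                                counts[, 2L] / counts[, 1L], NA_real_),
             frac_unmeth = ifelse(counts[, 1L] > 0,
                                  counts[, 3L] / counts[, 1L], NA_real_))
}

load_from_counts <- function(counts, exponent, col) {
  evaluable <- counts[, 1L] > 0
  if (!any(evaluable)) return(NA_real_)
  w <- seq_len(nrow(counts))^exponent
  sum(w[evaluable] * counts[evaluable, col] / counts[evaluable, 1L]) /
    sum(w[evaluable])
}

#' Methylated and un-methylated haplotype load
#'
#' MHL is the weighted average, over window lengths `i = 1..l`, of the
#' fraction of length-`i` contiguous call windows that are fully
#' methylated, with weights `w_i = i^weight_exponent`; it rewards long
#' consecutive methylated runs. UMHL is the mirror statistic for
#' un-methylated runs. Lengths with no evaluable window are dropped from
#' both sums; a block with fewer than `min_reads_detect` overlapping reads
#' (or no evaluable window at any length) scores `NA` (undetected).
#'
#' @inheritParams substring_fractions
#' @return A single value in `[0, 1]`, or `NA` when undetected.
#' @examples
#' r <- haplotype_records("chr1", 1L, "10", 1L)
#' mhl(r, 1L, 2L)   # (1 * 0.5 + 8 * 0) / 9
#' @export
mhl <- function(records, first_site, n_sites, params = load_params()) {
  block_load(records, first_site, n_sites, params, 2L)
}

#' @rdname mhl
#' @export
umhl <- function(records, first_site, n_sites, params = load_params()) {
  block_load(records, first_site, n_sites, params, 3L)
}

block_load <- function(records, first_site, n_sites, params, col) {
  stopifnot(inherits(params, "load_params"))
  cl <- clip_to_block(records, first_site, n_sites, params$count_weighted)
  if (length(cl$hap) == 0L || sum(cl$count) < params$min_reads_detect)
    return(NA_real_)
  counts <- hap_window_counts(cl$hap, cl$count, as.integer(n_sites))
  load_from_counts(counts, params$weight_exponent, col)
}

#' Score a cohort of samples over a region set
#'
#' Computes the MHL (or UMHL) of every sample x block cell; cells where
#' the block is undetected in a sample are missing.
#'
#' @param samples Either a named list of [haplotype_records()] or a named
#'   character vector of haplotype TSV paths (then `sites` is required).
#' @param regions An `mhb_regions` data.frame carrying `first_site` and
#'   `n_sites` (see [read_regions()] / [partition_blocks()]).
#' @param params A [load_params()].
#' @param score_kind `"MHL"` or `"UMHL"`.
#' @param sites A [cpg_index()], needed when `samples` are file paths.
#' @return A samples x blocks numeric matrix with `score_kind` attribute;
#'   `NA` marks undetected cells.
#' @export
score_cohort <- function(samples, regions, params = load_params(),
                         score_kind = c("MHL", "UMHL"), sites = NULL) {
  score_kind <- match.arg(score_kind)
  col <- if (score_kind == "MHL") 2L else 3L
  stopifnot(is.data.frame(regions),
            all(c("id", "chrom", "first_site", "n_sites") %in% names(regions)))
  if (is.character(samples)) {
    if (is.null(sites))
      stop("scoring from files requires a CpG site index")
    paths <- samples
    samples <- lapply(names(paths), function(s) {
      tryCatch(read_haplotypes(paths[[s]], sites),
               error = function(e) stop("sample '", s, "': ",
                                        conditionMessage(e), call. = FALSE))
    })
    names(samples) <- names(paths)
  }
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be named")
  mat <- matrix(NA_real_, nrow = length(samples), ncol = nrow(regions),
                dimnames = list(names(samples), regions$id))
  for (s in seq_along(samples)) {
    recs <- samples[[s]]
    for (ch in unique(regions$chrom)) {
      in_ch <- regions$chrom == ch
      reg <- regions[in_ch, , drop = FALSE]
      sel <- recs$chrom == ch
      if (!any(sel) || nrow(reg) == 0L) next
      mat[s, in_ch] <- score_chrom(recs$site_start[sel], recs$hap[sel],
                                   recs$count[sel], reg, params, col)
    }
  }
  attr(mat, "score_kind") <- score_kind
  mat
}

# score every region of one chromosome for one sample; plain-vector hot path
score_chrom <- function(site_start, hap, count, reg, params, col) {
  out <- rep(NA_real_, nrow(reg))
  reg_end <- reg$first_site + reg$n_sites - 1L
  read_len <- nchar(hap)
  read_last <- site_start + read_len - 1L
  if (!params$count_weighted) count <- rep(1, length(count))
  # regions are sorted and non-overlapping in ordinals, so the regions a
  # read intersects form a contiguous index range
  hi <- findInterval(read_last, reg$first_site)
  lo <- findInterval(site_start - 1L, reg_end) + 1L
  ok <- which(lo <= hi & hi >= 1L)
  if (!length(ok)) return(out)
  lo_ok <- pmax(lo[ok], 1L)
  reads <- rep(ok, hi[ok] - lo_ok + 1L)
  regs <- unlist(lapply(seq_along(ok), function(i) lo_ok[i]:hi[ok[i]]))
  o <- order(regs)
  reads <- reads[o]
  regs <- regs[o]
  bounds <- c(0L, cumsum(rle(regs)$lengths))
  uregs <- regs[bounds[-1L]]
  for (g in seq_along(uregs)) {
    j <- uregs[g]
    idx <- reads[(bounds[g] + 1L):bounds[g + 1L]]
    clip_lo <- pmax(site_start[idx], reg$first_site[j])
    clip_hi <- pmin(read_last[idx], reg_end[j])
    haps <- substr(hap[idx], clip_lo - site_start[idx] + 1L,
                   clip_hi - site_start[idx] + 1L)
    cnt <- as.numeric(count[idx])
    if (sum(cnt) < params$min_reads_detect) next
    counts <- hap_window_counts(haps, cnt, reg$n_sites[j])
    out[j] <- load_from_counts(counts, params$weight_exponent, col)
  }
  out
}
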