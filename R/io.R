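#' Read and write haplotype TSV files
#'
#' The haplotype dialect is a minimal mHap-style tab-separated format with
#' columns `chrom`, `start`, `end`, `hap`, `count`, `strand`; header lines
#' are `#`-prefixed; `start` is the 0-based genomic position of the first
#' covered CpG cytosine and `end` is the position of the last covered CpG
#' plus 2 (half-open, covering the CG dinucleotide). Calls are `1`
#' (methylated), `0` (unmethylated), `?` (missing). The `strand` column is
#' accepted and ignored.
#'
#' On read, every record's coordinates must resolve to consecutive CpG
#' ordinals in `sites`; records that do not align are rejected with a
#' diagnostic naming the offending line numbers.
#'
#' @param path File path.
#' @param sites A [cpg_index()] giving the reference CpG positions.
#' @param records A [haplotype_records()] data.frame.
#' @return `read_haplotypes` returns a `haplotype_records` data.frame with
#'   multiplicities preserved; `write_haplotypes` returns `path` invisibly.
#' @export
read_haplotypes <- function(path, sites) {
  stopifnot(inherits(sites, "cpg_index"))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (!any(keep))
    return(haplotype_records())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("malformed haplotype line(s) ", paste(lineno[nf < 5L], collapse = ", "),
         " in ", path, ": fewer than 5 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  hap <- vapply(fields, `[[`, "", 4L)
  count <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  bad <- is.na(start) | is.na(end) | is.na(count) | !grepl("^[01?]+$", hap) |
    count < 1L
  if (any(bad))
    stop("malformed haplotype line(s) ", paste(lineno[bad], collapse = ", "),
         " in ", path)
  ord <- site_ordinal(sites, chrom, start)
  len <- nchar(hap)
  aligned <- !is.na(ord)
  if (any(aligned)) {
    last_ok <- rep(FALSE, length(ord))
    for (ch in unique(chrom[aligned])) {
      sel <- which(aligned & chrom == ch)
      pos <- sites[[ch]]
      last_idx <- ord[sel] + len[sel] - 1L
      in_range <- last_idx <= length(pos)
      last_ok[sel[in_range]] <-
        pos[last_idx[in_range]] + 2L == end[sel[in_range]]
    }
    aligned <- aligned & last_ok
  }
  if (any(!aligned))
    stop("haplotype line(s) ", paste(lineno[!aligned], collapse = ", "),
         " in ", path, " do not align to consecutive reference CpGs")
  haplotype_records(chrom, ord, hap, count)
}

#' @rdname read_haplotypes
#' @export
write_haplotypes <- function(records, path, sites) {
  records <- validate_haplotype_records(records)
  stopifnot(inherits(sites, "cpg_index"))
  writeLines("#chrom\tstart\tend\that\tcount\tstrand", path)
  if (nrow(records)) {
    len <- nchar(records$hap)
    start <- integer(nrow(records))
    end <- integer(nrow(records))
    for (ch in unique(records$chrom)) {
      sel <- records$chrom == ch
      pos <- sites[[ch]]
      if (is.null(pos)) stop("chromosome '", ch, "' absent from site index")
      last_idx <- records$site_start[sel] + len[sel] - 1L
      if (any(last_idx > length(pos)))
        stop("record extends past the CpG index on '", ch, "'")
      start[sel] <- pos[records$site_start[sel]]
      end[sel] <- pos[last_idx] + 2L
    }
    dt <- data.table::data.table(chrom = records$chrom, start = start,
                                 end = end, hap = records$hap,
                                 count = records$count, strand = ".")
    data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' Read and write MHB region files (BED)
#'
#' Regions are 4-column BED: `chrom`, `start`, `end`, `name`
#' (0-based, half-open). When a [cpg_index()] is supplied on read, member
#' CpG ordinals are recovered: the member sites of a region are the
#' reference CpGs whose position lies in `[start, end - 2]`.
#'
#' @param path File path.
#' @param sites Optional [cpg_index()]; required by scoring.
#' @param regions A regions data.frame as returned by `read_regions` or
#'   [partition_blocks()].
#' @return A data.frame of class `mhb_regions` with columns `id`, `chrom`,
#'   `start`, `end` and (when `sites` is given) `first_site`, `n_sites`.
#' @export
read_regions <- function(path, sites = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L) stop("regions BED needs at least 3 columns: ", path)
  df <- data.frame(chrom = as.character(dt[[1L]]),
                   start = as.integer(dt[[2L]]),
                   end = as.integer(dt[[3L]]),
                   stringsAsFactors = FALSE)
  df$id <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else
    sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  if (any(df$end <= df$start)) stop("region with end <= start in ", path)
  df <- df[c("id", "chrom", "start", "end")]
  if (!is.null(sites)) df <- attach_site_ordinals(df, sites)
  class(df) <- c("mhb_regions", "data.frame")
  df
}

attach_site_ordinals <- function(df, sites) {
  stopifnot(inherits(sites, "cpg_index"))
  df$first_site <- NA_integer_
  df$n_sites <- NA_integer_
  for (ch in unique(df$chrom)) {
    pos <- sites[[ch]]
    if (is.null(pos)) stop("chromosome '", ch, "' absent from site index")
    sel <- which(df$chrom == ch)
    lo <- findInterval(df$start[sel] - 1L, pos) + 1L
    hi <- findInterval(df$end[sel] - 2L, pos)
    df$first_site[sel] <- lo
    df$n_sites[sel] <- hi - lo + 1L
  }
  if (any(df$n_sites < 2L))
    stop("region(s) with fewer than 2 member CpGs: ",
         paste(df$id[df$n_sites < 2L], collapse = ", "))
  df
}

#' @rdname read_regions
#' @export
write_regions <- function(regions, path) {
  stopifnot(is.data.frame(regions),
            all(c("id", "chrom", "start", "end") %in% names(regions)))
  dt <- data.table::data.table(chrom = regions$chrom, start = regions$start,
                               end = regions$end, name = regions$id)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and write score matrices
#'
#' Samples x MHBs matrices of MHL or UMHL values in `[0, 1]`, tab-separated
#' with a header row, first column `sample_id`, missing cells written as
#' `NA` (a missing cell means the block was undetected in that sample).
#' The score kind travels in a `# score_kind:` comment line and as the
#' matrix's `score_kind` attribute.
#'
#' @param path File path.
#' @param mat Numeric matrix with sample row names and MHB column names.
#' @param score_kind `"MHL"` or `"UMHL"`.
#' @return `read_matrix` returns the numeric matrix (attribute
#'   `score_kind` set when present in the file).
#' @export
write_matrix <- function(mat, path, score_kind = attr(mat, "score_kind")) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  rng <- range(mat, na.rm = TRUE)
  if (!all(is.na(mat)) && (rng[1] < 0 || rng[2] > 1))
    stop("score values must lie in [0, 1]")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(score_kind))
    writeLines(paste0("# score_kind: ", score_kind), con)
  writeLines(paste(c("sample_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(v)
    paste(ifelse(is.na(v), "NA", format(v, digits = 17, scientific = FALSE,
                                        trim = TRUE)), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, n = 5L)
  kind <- NULL
  m <- regmatches(lines, regexec("^#\\s*score_kind:\\s*(\\S+)", lines))
  hits <- m[lengths(m) == 2L]
  if (length(hits)) kind <- hits[[1L]][2L]
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          skip = if (is.null(kind)) 0L else 1L)
  if (names(dt)[1L] != "sample_id")
    stop("score matrix must have first column 'sample_id': ", path)
  mat <- as.matrix(dt[, -1L])
  rownames(mat) <- as.character(dt[[1L]])
  storage.mode(mat) <- "double"
  if (!is.null(kind)) attr(mat, "score_kind") <- kind
  mat
}

#' Read and write cohort metadata tables
#'
#' Per-sample labels: `sample_id`, `specimen` (`tissue`/`plasma`),
#' `tumor_status` (`tumor`/`normal`/`healthy`), `mvi_status`
#' (`positive`/`negative`/`not_applicable`), `pair_id` (links a tumor
#' tissue to its matched peritumoral normal; `NA` when unpaired),
#' `surv_time` (months) and `surv_event` (`event`/`censored`/`unknown`).
#' Tab-separated with header, `NA` missing token.
#'
#' @param path File path.
#' @param meta Metadata data.frame.
#' @return `read_metadata` returns the validated data.frame.
#' @export
read_metadata <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = "sample_id"))
  validate_metadata(as.data.frame(dt))
}

#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  data.table::fwrite(meta, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "specimen", "tumor_status", "mvi_status", "pair_id",
            "surv_time", "surv_event")
  stopifnot(is.data.frame(meta), all(need %in% names(meta)))
  meta <- meta[need]
  meta$sample_id <- as.character(meta$sample_id)
  meta$pair_id <- as.character(meta$pair_id)
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id")
  chk <- function(col, allowed)
    if (!all(meta[[col]] %in% allowed))
      stop("invalid value in metadata column '", col, "'")
  chk("specimen", c("tissue", "plasma"))
  chk("tumor_status", c("tumor", "normal", "healthy"))
  chk("mvi_status", c("positive", "negative", "not_applicable"))
  chk("surv_event", c("event", "censored", "unknown", NA))
  if (any(meta$mvi_status != "not_applicable" & meta$tumor_status != "tumor"))
    stop("mvi_status other than 'not_applicable' requires tumor_status 'tumor'")
  if (any(!is.na(meta$surv_time) & meta$surv_time < 0))
    stop("negative survival time")
  paired <- meta[!is.na(meta$pair_id) & meta$specimen == "tissue", ]
  if (nrow(paired)) {
    tab <- table(paired$pair_id, paired$tumor_status)
    ok <- all(tab[, colnames(tab) %in% "tumor"] == 1L) &&
      all(tab[, colnames(tab) %in% "normal"] == 1L) &&
      all(rowSums(tab) == 2L)
    if (!ok)
      stop("each pair_id must appear on exactly one tumor and one normal tissue sample")
  }
  class(meta) <- "data.frame"
  meta
}
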