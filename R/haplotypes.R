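#' Read-level methylation haplotype records
#'
#' A haplotype record is one read-level observation: a run of binary CpG
#' methylation calls over consecutive CpG ordinals on one chromosome, with a
#' positive multiplicity. Calls are encoded as a string over `1`
#' (methylated), `0` (unmethylated) and `?` (missing).
#'
#' @param chrom Character vector of chromosome names.
#' @param site_start Integer vector: 1-based ordinal of the first covered
#'   CpG within the chromosome's sorted CpG list.
#' @param hap Character vector of call strings over `[01?]`.
#' @param count Positive integer multiplicities.
#' @return A data.frame of class `haplotype_records` with columns `chrom`,
#'   `site_start`, `hap`, `count` and `high_missing` (flag set when more
#'   than half of a record's calls are missing; records are kept and the
#'   scoring layer decides what to do with them).
#' @examples
#' haplotype_records("chr1", c(1L, 2L), c("110", "0?1"), c(3L, 1L))
#' @export
haplotype_records <- function(chrom = character(), site_start = integer(),
                              hap = character(), count = integer()) {
  df <- data.frame(chrom = as.character(chrom),
                   site_start = as.integer(site_start),
                   hap = as.character(hap),
                   count = as.integer(count),
                   stringsAsFactors = FALSE)
  validate_haplotype_records(df)
}

validate_haplotype_records <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "site_start", "hap", "count") %in% names(df)))
  if (nrow(df)) {
    if (any(is.na(df$hap)) || any(!grepl("^[01?]+$", df$hap)))
      stop("haplotype strings must be non-empty over {0,1,?}")
    if (any(is.na(df$count)) || any(df$count < 1L))
      stop("record counts must be positive integers")
    if (any(is.na(df$site_start)) || any(df$site_start < 1L))
      stop("site_start ordinals must be >= 1")
  }
  n_miss <- nchar(df$hap) - nchar(gsub("?", "", df$hap, fixed = TRUE))
  df$high_missing <- n_miss > nchar(df$hap) / 2
  class(df) <- c("haplotype_records", "data.frame")
  df
}

#' Complement methylation calls
#'
#' Swaps methylated and unmethylated calls in every record (missing calls
#' unchanged). UMHL of a record set equals MHL of its complement.
#'
#' @param records A [haplotype_records()] data.frame.
#' @return The complemented records.
#' @export
complement_calls <- function(records) {
  records$hap <- chartr("01", "10", records$hap)
  records
}
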