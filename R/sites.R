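#' CpG reference index
#'
#' Builds the per-chromosome index of CpG cytosine positions that anchors
#' haplotype records and block regions. Internally every record refers to
#' CpGs by their 1-based ordinal within the chromosome's sorted position
#' vector; genomic coordinates (0-based) appear only at file boundaries.
#'
#' @param x Either a named list mapping chromosome names to integer vectors
#'   of 0-based CpG positions, or a data.frame with columns `chrom` and
#'   `pos`.
#' @return An object of class `cpg_index`: a named list of strictly
#'   increasing integer position vectors.
#' @examples
#' idx <- cpg_index(list(chr1 = c(100L, 130L, 160L)))
#' @export
cpg_index <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "pos") %in% names(x)))
    x <- split(as.integer(x$pos), as.character(x$chrom))
  }
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    stop("cpg_index needs a named list of position vectors")
  x <- lapply(x, function(p) as.integer(sort(p)))
  for (chrom in names(x)) {
    p <- x[[chrom]]
    if (length(p) == 0L) stop("chromosome '", chrom, "' has no CpG sites")
    if (any(p < 0L)) stop("negative CpG position on '", chrom, "'")
    if (anyDuplicated(p)) stop("duplicated CpG position on '", chrom, "'")
  }
  structure(x, class = "cpg_index")
}

#' @export
print.cpg_index <- function(x, ...) {
  cat("<cpg_index> ", length(x), " chromosome(s), ",
      sum(vapply(x, length, 1L)), " CpG sites\n", sep = "")
  invisible(x)
}

#' Write / read a CpG index as TSV
#'
#' Two columns (`chrom`, `pos`, 0-based), tab-separated, `#`-prefixed header.
#'
#' @param sites A [cpg_index()].
#' @param path File path.
#' @return `read_sites` returns a `cpg_index`; `write_sites` returns `path`
#'   invisibly.
#' @export
write_sites <- function(sites, path) {
  stopifnot(inherits(sites, "cpg_index"))
  df <- data.table::data.table(
    chrom = rep(names(sites), vapply(sites, length, 1L)),
    pos = unlist(sites, use.names = FALSE))
  writeLines("#chrom\tpos", path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty CpG index file: ", path)
  dt <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos"),
                          colClasses = list(character = 1L, integer = 2L))
  cpg_index(as.data.frame(dt))
}

# position -> ordinal lookup; errors carry the offending lines
site_ordinal <- function(sites, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (!ch %in% names(sites)) next
    out[sel] <- match(pos[sel], sites[[ch]])
  }
  out
}
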