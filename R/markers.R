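#' Marker selection filter configuration
#'
#' The filter cascade applied before per-block testing: samples must have
#' at least `min_detected_per_sample` detected blocks (the full-genome
#' default of 25,000 corresponds to a catalog of a few hundred thousand
#' regions and should be scaled with the region set); candidate blocks
#' must be detected in at least `min_detection_fraction` of retained
#' samples and show a score standard deviation of at least `min_sd` (both
#' thresholds inclusive). Surviving blocks are tested per block and
#' selected at `fdr_threshold` after Benjamini-Hochberg adjustment.
#'
#' @param min_detected_per_sample Detection floor per sample.
#' @param min_detection_fraction Minimum non-missing fraction per block.
#' @param min_sd Minimum per-block standard deviation (n-1 denominator).
#' @param fdr_threshold FDR cutoff for selection.
#' @param test `"rank_sum"` (unpaired) or `"signed_rank"` (paired).
#' @param alternative `"greater"`, `"less"`, `"two_sided"`, or `"both"`
#'   (one-sided tests run separately in each direction, BH-adjusted within
#'   each direction, and combined — the per-marker direction is never
#'   picked from the data first).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_detected_per_sample = 25000L,
                          min_detection_fraction = 2 / 3,
                          min_sd = 0.02, fdr_threshold = 0.05,
                          test = c("rank_sum", "signed_rank"),
                          alternative = c("both", "greater", "less",
                                          "two_sided")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  stopifnot(min_detection_fraction > 0, min_detection_fraction <= 1,
            fdr_threshold > 0, fdr_threshold < 1, min_sd >= 0,
            min_detected_per_sample >= 0)
  structure(list(min_detected_per_sample = as.integer(min_detected_per_sample),
                 min_detection_fraction = min_detection_fraction,
                 min_sd = min_sd, fdr_threshold = fdr_threshold,
                 test = test, alternative = alternative),
            class = "filter_config")
}

#' Sample detection filter
#'
#' Keeps samples with at least `min_detected` non-missing block scores.
#'
#' @param mat Samples x blocks score matrix.
#' @param min_detected Detection floor.
#' @return Character vector of retained sample ids.
#' @export
filter_samples <- function(mat, min_detected) {
  detected <- rowSums(!is.na(mat))
  keep <- rownames(mat)[detected >= min_detected]
  if (length(keep) == 0L)
    stop("no sample reaches the detection floor of ", min_detected,
         " blocks")
  keep
}

#' Block detection and variability filter
#'
#' Keeps blocks detected in at least `min_detection_fraction` of the
#' samples and whose non-missing scores have standard deviation at least
#' `min_sd` (inclusive thresholds, n-1 denominator).
#'
#' @param mat Samples x blocks score matrix (after sample filtering).
#' @param min_detection_fraction Minimum non-missing fraction.
#' @param min_sd Minimum standard deviation.
#' @return Character vector of retained block ids.
#' @export
filter_blocks <- function(mat, min_detection_fraction = 2 / 3,
                          min_sd = 0.02) {
  frac <- colMeans(!is.na(mat))
  sds <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  colnames(mat)[frac >= min_detection_fraction & sds >= min_sd]
}

#' Wilcoxon rank-sum test (unpaired)
#'
#' Mid-ranks for ties; exact p-value for small untied samples, normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param case,control Numeric vectors (missing values dropped).
#' @param alternative `"greater"`, `"less"` or `"two_sided"`, stated for
#'   the case group relative to control.
#' @return A list with `statistic` (rank-sum W) and `p`.
#' @export
wilcoxon_rank_sum <- function(case, control,
                              alternative = c("two_sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (length(case) == 0L || length(control) == 0L)
    stop("rank-sum test undefined: a group is empty")
  ht <- suppressWarnings(stats::wilcox.test(
    case, control, alternative = sub("_sided", ".sided", alternative),
    exact = NULL, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Wilcoxon signed-rank test (paired)
#'
#' Zero differences dropped; exact p-value for small untied samples,
#' normal approximation with corrections otherwise.
#'
#' @param case,control Paired numeric vectors (pairs with a missing member
#'   dropped).
#' @inheritParams wilcoxon_rank_sum
#' @return A list with `statistic` (signed-rank V) and `p`.
#' @export
wilcoxon_signed_rank <- function(case, control,
                                 alternative = c("two_sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(case) == length(control))
  ok <- !is.na(case) & !is.na(control)
  d <- case[ok] - control[ok]
  if (length(d) == 0L || all(d == 0))
    stop("signed-rank test undefined: no nonzero paired difference")
  ht <- suppressWarnings(stats::wilcox.test(
    case[ok], control[ok], paired = TRUE,
    alternative = sub("_sided", ".sided", alternative),
    exact = NULL, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_i = min_{j >= rank(i)} m p_(j) / j`, capped
#' at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differential methylation markers
#'
#' Runs the filter cascade and the configured per-block test on one or two
#' score matrices (e.g. MHL and UMHL), BH-adjusts within each score kind
#' (and, for `alternative = "both"`, within each direction), and returns
#' markers with `fdr_q` below the configured threshold, tagged by score
#' kind and direction.
#'
#' @param matrices A single score matrix or a named list of them (names
#'   are score kinds, e.g. `list(MHL = m1, UMHL = m2)`).
#' @param metadata A cohort metadata data.frame (see [read_metadata()]).
#' @param config A [filter_config()].
#' @param contrast `"tumor_vs_normal"` (tissue samples; with
#'   `test = "signed_rank"` only matched `pair_id` samples are used) or
#'   `"mvi"` (tumor tissue, MVI positive vs negative).
#' @return A data.frame of class `marker_set`: `id`, `score_kind`,
#'   `direction` (`hyper`/`hypo` in the case group), `statistic`, `raw_p`,
#'   `fdr_q`.
#' @export
select_markers <- function(matrices, metadata, config = filter_config(),
                           contrast = c("tumor_vs_normal", "mvi")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(config, "filter_config"))
  if (is.matrix(matrices)) {
    kind <- attr(matrices, "score_kind")
    matrices <- stats::setNames(list(matrices),
                                if (is.null(kind)) "MHL" else kind)
  }
  groups <- contrast_groups(metadata, contrast, config$test)
  out <- list()
  for (kind in names(matrices)) {
    mat <- matrices[[kind]]
    sub <- mat[intersect(rownames(mat), c(groups$case, groups$control)), ,
               drop = FALSE]
    kept_samples <- filter_samples(sub, config$min_detected_per_sample)
    sub <- sub[kept_samples, , drop = FALSE]
    case_ids <- intersect(groups$case, kept_samples)
    ctrl_ids <- intersect(groups$control, kept_samples)
    if (config$test == "signed_rank") {
      pair_ok <- groups$pair_case %in% case_ids &
        groups$pair_control %in% ctrl_ids
      case_ids <- groups$pair_case[pair_ok]
      ctrl_ids <- groups$pair_control[pair_ok]
      if (length(case_ids) == 0L)
        stop("no complete pairs available for the signed-rank contrast")
    }
    if (length(case_ids) == 0L || length(ctrl_ids) == 0L)
      stop("a contrast group is empty after filtering")
    blocks <- filter_blocks(sub, config$min_detection_fraction,
                            config$min_sd)
    alts <- switch(config$alternative,
                   both = c("greater", "less"),
                   config$alternative)
    for (alt in alts) {
      res <- test_blocks(sub, blocks, case_ids, ctrl_ids, config$test, alt)
      if (is.null(res)) next
      res$fdr_q <- benjamini_hochberg(res$raw_p)
      res <- res[res$fdr_q < config$fdr_threshold, , drop = FALSE]
      if (nrow(res)) {
        res$score_kind <- kind
        res$direction <- switch(alt, greater = "hyper", less = "hypo",
                                two_sided = NA_character_)
        out[[length(out) + 1L]] <- res
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), statistic = numeric(), raw_p = numeric(),
               fdr_q = numeric(), score_kind = character(),
               direction = character(), stringsAsFactors = FALSE)
  res <- res[c("id", "score_kind", "direction", "statistic", "raw_p",
               "fdr_q")]
  res <- res[order(res$score_kind, res$fdr_q, res$raw_p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("marker_set", "data.frame")
  res
}

test_blocks <- function(mat, blocks, case_ids, ctrl_ids, test, alt) {
  if (length(blocks) == 0L) return(NULL)
  stat <- raw_p <- rep(NA_real_, length(blocks))
  for (i in seq_along(blocks)) {
    x <- mat[case_ids, blocks[i]]
    y <- mat[ctrl_ids, blocks[i]]
    r <- tryCatch({
      if (test == "signed_rank") wilcoxon_signed_rank(x, y, alt)
      else wilcoxon_rank_sum(x, y, alt)
    }, error = function(e) NULL)
    if (!is.null(r)) {
      stat[i] <- r$statistic
      raw_p[i] <- r$p
    }
  }
  ok <- !is.na(raw_p)
  if (!any(ok)) return(NULL)
  data.frame(id = blocks[ok], statistic = stat[ok], raw_p = raw_p[ok],
             stringsAsFactors = FALSE)
}

contrast_groups <- function(metadata, contrast, test) {
  metadata <- validate_metadata(metadata)
  tis <- metadata[metadata$specimen == "tissue", , drop = FALSE]
  if (contrast == "tumor_vs_normal") {
    case <- tis$sample_id[tis$tumor_status == "tumor"]
    control <- tis$sample_id[tis$tumor_status == "normal"]
    pairs <- tis[!is.na(tis$pair_id), , drop = FALSE]
    pid <- sort(unique(pairs$pair_id))
    pc <- vapply(pid, function(p)
      pairs$sample_id[pairs$pair_id == p & pairs$tumor_status == "tumor"], "")
    pn <- vapply(pid, function(p)
      pairs$sample_id[pairs$pair_id == p & pairs$tumor_status == "normal"], "")
    list(case = case, control = control, pair_case = unname(pc),
         pair_control = unname(pn))
  } else {
    tum <- tis[tis$tumor_status == "tumor", , drop = FALSE]
    if (test == "signed_rank")
      stop("the MVI contrast is unpaired; use test = 'rank_sum'")
    list(case = tum$sample_id[tum$mvi_status == "positive"],
         control = tum$sample_id[tum$mvi_status == "negative"],
         pair_case = character(), pair_control = character())
  }
}
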