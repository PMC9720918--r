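#' Block generation parameters
#'
#' Parameters of the two-state Markov-chain read generator for one block.
#' Each simulated read starts methylated with probability `theta` (for its
#' group) and toggles state with probability `switch_rate` at each of the
#' `n_cpgs - 1` steps, so `switch_rate` tunes the consecutiveness of
#' methylated runs — the property the haplotype load statistics measure.
#' Read depth is Poisson(`mean_depth`); with probability `1 - detect_prob`
#' the block yields no reads at all in a sample.
#'
#' @param n_cpgs Number of CpG sites in the block (>= 2).
#' @param theta Probability that a read starts in the methylated state;
#'   either a single value or a named vector keyed by group.
#' @param switch_rate Per-step probability of toggling methylation state.
#' @param mean_depth Expected number of reads per sample.
#' @param detect_prob Per-sample probability the block is observed at all.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(n_cpgs = 5L, theta = 0.5, switch_rate = 0.1,
                       mean_depth = 30, detect_prob = 0.9) {
  stopifnot(n_cpgs >= 2L, all(theta >= 0 & theta <= 1),
            switch_rate >= 0, switch_rate <= 1,
            detect_prob >= 0, detect_prob <= 1, mean_depth > 0)
  structure(list(n_cpgs = as.integer(n_cpgs), theta = theta,
                 switch_rate = switch_rate, mean_depth = mean_depth,
                 detect_prob = detect_prob), class = "block_spec")
}

#' Binary haplotype pattern table
#'
#' All `2^n_cpgs` call patterns for a block, as strings; pattern `p`
#' (0-based) has call `(p >> (j-1)) & 1` at CpG `j`.
#'
#' @param n_cpgs Block length.
#' @return Character vector of length `2^n_cpgs`.
#' @export
pattern_strings <- function(n_cpgs) {
  bits <- pattern_bits(n_cpgs)
  apply(bits, 1L, paste, collapse = "")
}

pattern_bits <- function(n_cpgs) {
  p <- 0:(2^n_cpgs - 1L)
  sapply(seq_len(n_cpgs), function(j) bitwAnd(bitwShiftR(p, j - 1L), 1L))
}

#' Markov-chain pattern probabilities
#'
#' Probability of each full-length call pattern under the two-state chain:
#' initial state methylated with probability `theta`, per-step toggle
#' probability `switch_rate`. Vectorised over `theta` (one row per value).
#'
#' @param n_cpgs Block length.
#' @param theta Initial methylation probability (vector allowed).
#' @param switch_rate Per-step toggle probability.
#' @return A `length(theta) x 2^n_cpgs` matrix of probabilities; each row
#'   sums to 1. Columns follow [pattern_strings()] order.
#' @export
markov_pattern_probs <- function(n_cpgs, theta, switch_rate) {
  bits <- pattern_bits(n_cpgs)
  toggles <- rowSums(abs(bits[, -1L, drop = FALSE] -
                           bits[, -n_cpgs, drop = FALSE]))
  w <- switch_rate^toggles * (1 - switch_rate)^(n_cpgs - 1L - toggles)
  first <- bits[, 1L]
  # P(pattern) = P(first call) * switch_rate^toggles * (1-s)^stays
  out <- outer(theta, first, function(th, b) th * b + (1 - th) * (1 - b)) *
    matrix(w, nrow = length(theta), ncol = length(w), byrow = TRUE)
  out
}

#' Simulate reads for one sample x block
#'
#' Draws Poisson read depth, applies detection dropout, and samples read
#' patterns from the Markov-chain pattern distribution (equivalent, by
#' Poisson thinning, to drawing each read's chain independently).
#'
#' @param spec A [block_spec()].
#' @param group Optional group name selecting an element of `spec$theta`.
#' @param chrom,site_start Anchoring of the block in a CpG index.
#' @return A [haplotype_records()] data.frame (possibly empty).
#' @export
simulate_block_reads <- function(spec, group = NULL, chrom = "chr1",
                                 site_start = 1L) {
  stopifnot(inherits(spec, "block_spec"))
  theta <- if (is.null(group)) spec$theta[[1L]] else {
    if (!group %in% names(spec$theta))
      stop("group '", group, "' not named in spec$theta")
    spec$theta[[group]]
  }
  if (stats::runif(1) > spec$detect_prob) return(haplotype_records())
  n <- stats::rpois(1L, spec$mean_depth)
  if (n == 0L) return(haplotype_records())
  probs <- markov_pattern_probs(spec$n_cpgs, theta, spec$switch_rate)[1L, ]
  counts <- as.integer(stats::rmultinom(1L, n, probs))
  keep <- counts > 0L
  haplotype_records(chrom = rep(chrom, sum(keep)),
                    site_start = rep(as.integer(site_start), sum(keep)),
                    hap = pattern_strings(spec$n_cpgs)[keep],
                    count = counts[keep])
}

#' Synthetic cohort specification
#'
#' Defines the study conditions the generator emulates: group sizes
#' mirroring a matched tumor/normal tissue cohort with patient and healthy
#' plasma, a block-structured genome, spiked tumor-differential and
#' MVI-differential blocks with stated methylation shifts, plasma as a
#' per-read tumor/background mixture, per-sample detection dropout, and
#' exponential survival whose hazard depends on MVI status.
#'
#' @param n_normal Matched peritumoral normal tissue samples.
#' @param n_mvi_neg,n_mvi_pos Tumor tissue samples by MVI status.
#' @param n_healthy_plasma Healthy-control plasma samples.
#' @param patient_plasma Logical; simulate one plasma sample per patient.
#' @param n_blocks,n_cpgs Genome size: number of blocks and CpGs per block.
#' @param cpg_spacing,block_gap Within-block CpG spacing and gap between
#'   blocks (bp); blocks are far enough apart that adjacent-pair linkage
#'   never bridges them.
#' @param mean_depth,plasma_depth Expected reads per block for tissue and
#'   plasma samples.
#' @param switch_rate Per-step toggle probability (within-block LD).
#' @param detect_prob Per-sample block detection probability.
#' @param n_diff_tumor,tumor_shift Number of tumor-differential blocks and
#'   the shift applied to their tumor-group theta.
#' @param n_diff_mvi,mvi_shift Number of MVI-differential blocks and the
#'   shift applied in MVI-positive tumors only.
#' @param frac_hyper Fraction of spiked blocks shifted up (the rest down).
#' @param tumor_fraction Per-read probability that a patient-plasma read
#'   derives from the matched tumor's distribution.
#' @param hazard_mvi_neg,hazard_mvi_pos Exponential event hazards
#'   (per month) by MVI status.
#' @param censor_rate Exponential censoring hazard (per month).
#' @param followup_max Administrative censoring time (months).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 25L, n_mvi_neg = 17L, n_mvi_pos = 18L,
                        n_healthy_plasma = 24L, patient_plasma = TRUE,
                        n_blocks = 2000L, n_cpgs = 5L, cpg_spacing = 30L,
                        block_gap = 1000L, mean_depth = 30, plasma_depth = 30,
                        switch_rate = 0.1, detect_prob = 0.9,
                        n_diff_tumor = 20L, tumor_shift = 0.4,
                        n_diff_mvi = 8L, mvi_shift = 0.3, frac_hyper = 0.5,
                        tumor_fraction = 0.3,
                        hazard_mvi_neg = 0.02, hazard_mvi_pos = 0.08,
                        censor_rate = 0.01, followup_max = 60,
                        seed = 1L) {
  spec <- list(n_normal = as.integer(n_normal),
               n_mvi_neg = as.integer(n_mvi_neg),
               n_mvi_pos = as.integer(n_mvi_pos),
               n_healthy_plasma = as.integer(n_healthy_plasma),
               patient_plasma = isTRUE(patient_plasma),
               n_blocks = as.integer(n_blocks), n_cpgs = as.integer(n_cpgs),
               cpg_spacing = as.integer(cpg_spacing),
               block_gap = as.integer(block_gap),
               mean_depth = mean_depth, plasma_depth = plasma_depth,
               switch_rate = switch_rate, detect_prob = detect_prob,
               n_diff_tumor = as.integer(n_diff_tumor),
               tumor_shift = tumor_shift,
               n_diff_mvi = as.integer(n_diff_mvi), mvi_shift = mvi_shift,
               frac_hyper = frac_hyper, tumor_fraction = tumor_fraction,
               hazard_mvi_neg = hazard_mvi_neg,
               hazard_mvi_pos = hazard_mvi_pos, censor_rate = censor_rate,
               followup_max = followup_max, seed = as.integer(seed))
  stopifnot(spec$n_blocks >= 1L, spec$n_cpgs >= 2L,
            spec$n_diff_tumor + spec$n_diff_mvi <= spec$n_blocks,
            spec$n_mvi_neg + spec$n_mvi_pos >= 1L, spec$n_normal >= 1L,
            spec$tumor_fraction >= 0, spec$tumor_fraction <= 1,
            spec$tumor_shift >= 0, spec$mvi_shift >= 0,
            spec$detect_prob >= 0, spec$detect_prob <= 1,
            spec$hazard_mvi_neg > 0, spec$hazard_mvi_pos > 0)
  structure(spec, class = "cohort_spec")
}

#' Simulate a full synthetic cohort
#'
#' Generates read-level haplotypes for every sample, the block region set,
#' sample metadata (with survival for tumor patients) and a truth table of
#' spiked differential blocks. Tumor-differential blocks use a shifted
#' theta in all tumors; MVI-differential blocks shift theta in MVI-positive
#' tumors only; each patient-plasma read comes from the matched tumor's
#' distribution with probability `tumor_fraction`, otherwise from the
#' normal distribution.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `mhb_cohort` with elements `sites`
#'   ([cpg_index()]), `regions` (true block definitions), `records` (named
#'   list of [haplotype_records()] per sample), `metadata`, `truth`
#'   (per-block type, direction and thetas) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  k <- spec$n_cpgs
  nb <- spec$n_blocks

  # genome: evenly spaced blocks on one chromosome
  stride <- (k - 1L) * spec$cpg_spacing + spec$block_gap
  offsets <- (seq_len(nb) - 1L) * stride
  pos <- as.integer(rep(offsets, each = k) +
                      rep((0:(k - 1L)) * spec$cpg_spacing, nb))
  sites <- cpg_index(list(chr1 = pos))
  regions <- data.frame(
    id = sprintf("mhb_%05d", seq_len(nb)), chrom = "chr1",
    start = pos[(seq_len(nb) - 1L) * k + 1L],
    end = pos[seq_len(nb) * k] + 2L,
    first_site = (seq_len(nb) - 1L) * k + 1L, n_sites = k,
    stringsAsFactors = FALSE)
  class(regions) <- c("mhb_regions", "data.frame")

  # per-block thetas: background uniform; spiked blocks shifted per group
  th_normal <- stats::runif(nb, 0.1, 0.9)
  type <- rep("background", nb)
  direction <- rep("none", nb)
  spiked <- sample.int(nb, spec$n_diff_tumor + spec$n_diff_mvi)
  idx_tumor <- spiked[seq_len(spec$n_diff_tumor)]
  idx_mvi <- spiked[seq_len(spec$n_diff_mvi) + spec$n_diff_tumor]
  type[idx_tumor] <- "tumor_diff"
  type[idx_mvi] <- "mvi_diff"
  th_tumor <- th_normal
  spike <- function(idx, shift) {
    n <- length(idx)
    if (n == 0L) return(list(idx = idx, base = numeric(), shifted = numeric(),
                             dir = character()))
    n_up <- round(spec$frac_hyper * n)
    dir <- c(rep("hyper", n_up), rep("hypo", n - n_up))
    base <- ifelse(dir == "hyper", stats::runif(n, 0.05, 0.95 - shift),
                   stats::runif(n, 0.05 + shift, 0.95))
    shifted <- base + ifelse(dir == "hyper", shift, -shift)
    list(idx = idx, base = base, shifted = shifted, dir = dir)
  }
  st <- spike(idx_tumor, spec$tumor_shift)
  th_normal[st$idx] <- st$base
  th_tumor[st$idx] <- st$shifted
  direction[st$idx] <- st$dir
  sm <- spike(idx_mvi, spec$mvi_shift)
  th_normal[sm$idx] <- sm$base
  th_tumor[sm$idx] <- sm$base         # MVI blocks not tumor-differential
  th_mvi_pos <- th_tumor
  th_mvi_pos[sm$idx] <- sm$shifted
  direction[sm$idx] <- sm$dir

  truth <- data.frame(id = regions$id, type = type, direction = direction,
                      theta_normal = th_normal, theta_tumor = th_tumor,
                      theta_mvi_pos = th_mvi_pos, stringsAsFactors = FALSE)

  # pattern probability profiles (blocks x patterns)
  pat <- pattern_strings(k)
  P_normal <- markov_pattern_probs(k, th_normal, spec$switch_rate)
  P_tum_neg <- markov_pattern_probs(k, th_tumor, spec$switch_rate)
  P_tum_pos <- markov_pattern_probs(k, th_mvi_pos, spec$switch_rate)

  draw_sample <- function(P, depth) {
    lam <- depth * P * stats::rbinom(nb, 1L, spec$detect_prob)
    counts <- matrix(stats::rpois(length(lam), lam), nrow = nb)
    nz <- which(counts > 0L, arr.ind = TRUE)
    nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
    haplotype_records(chrom = rep("chr1", nrow(nz)),
                      site_start = (nz[, 1L] - 1L) * k + 1L,
                      hap = pat[nz[, 2L]],
                      count = counts[nz])
  }

  n_tumor <- spec$n_mvi_neg + spec$n_mvi_pos
  mvi <- sample(rep(c("negative", "positive"),
                    c(spec$n_mvi_neg, spec$n_mvi_pos)))
  ids_normal <- sprintf("N%02d", seq_len(spec$n_normal))
  ids_tumor <- sprintf("T%02d", seq_len(n_tumor))
  ids_hp <- sprintf("PH%02d", seq_len(spec$n_healthy_plasma))
  ids_pp <- if (spec$patient_plasma) sprintf("PT%02d", seq_len(n_tumor))
            else character()

  records <- list()
  for (i in seq_len(spec$n_normal))
    records[[ids_normal[i]]] <- draw_sample(P_normal, spec$mean_depth)
  P_tumor_of <- function(i) if (mvi[i] == "positive") P_tum_pos else P_tum_neg
  for (i in seq_len(n_tumor))
    records[[ids_tumor[i]]] <- draw_sample(P_tumor_of(i), spec$mean_depth)
  for (i in seq_len(spec$n_healthy_plasma))
    records[[ids_hp[i]]] <- draw_sample(P_normal, spec$plasma_depth)
  if (spec$patient_plasma) {
    tf <- spec$tumor_fraction
    for (i in seq_len(n_tumor)) {
      P_mix <- tf * P_tumor_of(i) + (1 - tf) * P_normal
      records[[ids_pp[i]]] <- draw_sample(P_mix, spec$plasma_depth)
    }
  }

  # matched pairs: normal j <-> tumor j while both exist
  n_pairs <- min(spec$n_normal, n_tumor)
  pair_of <- function(ids, n) {
    p <- rep(NA_character_, length(ids))
    p[seq_len(min(n, length(ids)))] <- sprintf("P%02d", seq_len(min(n, length(ids))))
    p
  }
  surv <- simulate_survival(
    ifelse(mvi == "positive", spec$hazard_mvi_pos, spec$hazard_mvi_neg),
    spec$censor_rate, spec$followup_max)

  meta <- rbind(
    data.frame(sample_id = ids_normal, specimen = "tissue",
               tumor_status = "normal", mvi_status = "not_applicable",
               pair_id = pair_of(ids_normal, n_pairs),
               surv_time = NA_real_, surv_event = "unknown",
               stringsAsFactors = FALSE),
    data.frame(sample_id = ids_tumor, specimen = "tissue",
               tumor_status = "tumor", mvi_status = mvi,
               pair_id = pair_of(ids_tumor, n_pairs),
               surv_time = surv$time,
               surv_event = ifelse(surv$event, "event", "censored"),
               stringsAsFactors = FALSE),
    if (spec$n_healthy_plasma > 0L)
      data.frame(sample_id = ids_hp, specimen = "plasma",
                 tumor_status = "healthy", mvi_status = "not_applicable",
                 pair_id = NA_character_, surv_time = NA_real_,
                 surv_event = "unknown", stringsAsFactors = FALSE),
    if (spec$patient_plasma)
      data.frame(sample_id = ids_pp, specimen = "plasma",
                 tumor_status = "tumor", mvi_status = mvi,
                 pair_id = NA_character_, surv_time = surv$time,
                 surv_event = ifelse(surv$event, "event", "censored"),
                 stringsAsFactors = FALSE))
  meta <- validate_metadata(meta)

  structure(list(sites = sites, regions = regions, records = records,
                 metadata = meta, truth = truth, spec = spec),
            class = "mhb_cohort")
}

#' Simulate censored exponential survival
#'
#' Event times are Exponential with the per-subject hazard; censoring is an
#' independent Exponential time truncated at `followup_max`.
#'
#' @param hazard Per-subject event hazard (vector; per month).
#' @param censor_rate Exponential censoring hazard.
#' @param followup_max Administrative cutoff (months).
#' @return A data.frame with `time` and logical `event`.
#' @export
simulate_survival <- function(hazard, censor_rate = 0.01, followup_max = 60) {
  n <- length(hazard)
  t_event <- stats::rexp(n, hazard)
  t_cens <- pmin(stats::rexp(n, censor_rate), followup_max)
  data.frame(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

#' @export
print.mhb_cohort <- function(x, ...) {
  cat("<mhb_cohort> ", length(x$records), " samples, ",
      nrow(x$regions), " blocks x ", x$spec$n_cpgs, " CpGs\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the io-format file set: `sites.tsv`, `regions.bed`,
#' `metadata.tsv`, `truth.tsv` and one haplotype TSV per sample under
#' `haplotypes/`.
#'
#' @param cohort An `mhb_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mhb_cohort"))
  dir.create(file.path(dir, "haplotypes"), recursive = TRUE,
             showWarnings = FALSE)
  write_sites(cohort$sites, file.path(dir, "sites.tsv"))
  write_regions(cohort$regions, file.path(dir, "regions.bed"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     na = "NA", quote = FALSE)
  for (s in names(cohort$records))
    write_haplotypes(cohort$records[[s]],
                     file.path(dir, "haplotypes", paste0(s, ".tsv")),
                     cohort$sites)
  invisible(dir)
}
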