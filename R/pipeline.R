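#' Pipeline configuration
#'
#' One configuration object drives the whole analysis: simulate (or
#' ingest) a cohort, discover blocks, score MHL/UMHL, select
#' tumor-vs-normal and MVI markers, cross-validate classifiers, transfer
#' the tissue model to plasma, and validate predicted MVI groups by
#' survival. A single top-level seed fans out to per-stage seeds by a
#' fixed linear-congruential derivation, so each stage is individually
#' reproducible.
#'
#' @param cohort A [cohort_spec()] (its own seed is overridden by the
#'   derived stage seed), or `NULL` in ingest mode.
#' @param input In ingest mode, a named list of paths: `haplotype_dir`,
#'   `sites`, `regions` (optional), `metadata`.
#' @param load A [load_params()].
#' @param filter_hcc [filter_config()] for the paired tumor-vs-normal
#'   contrast.
#' @param filter_mvi [filter_config()] for the unpaired MVI contrast.
#' @param model A [model_config()].
#' @param regions `"discover"` (partition blocks from the pooled tissue
#'   reads) or `"known"` (use the provided region set, e.g. a precomputed
#'   catalog or the simulated truth regions).
#' @param r2_threshold,min_pairs,max_gap Block-discovery parameters.
#' @param detection_floor Per-sample detected-block floor; `NULL` scales
#'   the full-genome default of 25,000 (out of a 225,025-region catalog)
#'   proportionally to the region set in use.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), input = NULL,
                            load = load_params(),
                            filter_hcc = filter_config(
                              test = "signed_rank", fdr_threshold = 0.05,
                              alternative = "both"),
                            filter_mvi = filter_config(
                              test = "rank_sum", fdr_threshold = 0.05,
                              alternative = "both"),
                            model = model_config(),
                            regions = c("discover", "known"),
                            r2_threshold = 0.5, min_pairs = 10L,
                            max_gap = 500L, detection_floor = NULL,
                            seed = 1L) {
  regions <- match.arg(regions)
  if (is.null(cohort) && is.null(input))
    stop("either a cohort spec (simulate) or input paths (ingest) required")
  structure(list(cohort = cohort, input = input, load = load,
                 filter_hcc = filter_hcc, filter_mvi = filter_mvi,
                 model = model, regions = regions,
                 r2_threshold = r2_threshold,
                 min_pairs = as.integer(min_pairs),
                 max_gap = max_gap, detection_floor = detection_floor,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `cohort`,
#' `load`, `filter_hcc`, `filter_mvi` and `model` are nested maps passed
#' to their constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_spec, y$cohort)
  if (!is.null(y$input)) args$input <- y$input
  if (!is.null(y$load)) args$load <- do.call(load_params, y$load)
  if (!is.null(y$filter_hcc))
    args$filter_hcc <- do.call(filter_config, y$filter_hcc)
  if (!is.null(y$filter_mvi))
    args$filter_mvi <- do.call(filter_config, y$filter_mvi)
  if (!is.null(y$model)) args$model <- do.call(model_config, y$model)
  for (k in c("regions", "r2_threshold", "min_pairs", "max_gap",
              "detection_floor", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

# deterministic per-stage seed derivation from the master seed
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1009 + stage * 9973) %% 2147483647)
}

scale_detection_floor <- function(n_regions) {
  max(1L, as.integer(ceiling(n_regions * 25000 / 225025)))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate/ingest, block discovery, MHL/UMHL scoring, marker
#' selection, classification, plasma transfer and survival validation,
#' writing every intermediate artifact in the package's file formats plus
#' a `manifest.json` recording parameters, per-stage seeds, output
#' checksums and headline results. Re-running with the same configuration
#' reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()] or the path to a YAML file for
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `regions`, `mhl`, `umhl`, `markers_hcc`, `cv_tissue`,
#'   `plasma`, `markers_mvi`, `mvi`, `survival`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  say <- function(...) {
    msg <- paste0(...)
    message("[mhbkit] ", msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- stats::setNames(
    vapply(1:5, stage_seed, 1L, seed = config$seed),
    c("cohort", "score", "cv_tissue", "transfer", "mvi"))

  # --- stage 1: cohort ------------------------------------------------
  if (!is.null(config$cohort)) {
    say("simulating cohort (seed ", seeds[["cohort"]], ")")
    spec <- config$cohort
    spec$seed <- seeds[["cohort"]]
    cohort <- run_stage("simulate", simulate_cohort(spec))
    data_dir <- file.path(out_dir, "data")
    run_stage("write_cohort", write_cohort(cohort, data_dir))
    sites <- cohort$sites
    meta <- cohort$metadata
    records <- cohort$records
    known_regions <- cohort$regions
  } else {
    say("ingesting cohort from ", config$input$haplotype_dir)
    sites <- run_stage("ingest", read_sites(config$input$sites))
    meta <- run_stage("ingest", read_metadata(config$input$metadata))
    paths <- list.files(config$input$haplotype_dir, full.names = TRUE)
    names(paths) <- sub("\\.tsv$", "", basename(paths))
    records <- run_stage("ingest", lapply(paths, read_haplotypes, sites = sites))
    known_regions <- if (!is.null(config$input$regions))
      read_regions(config$input$regions, sites) else NULL
    cohort <- NULL
  }

  # --- stage 2: blocks ------------------------------------------------
  tissue_ids <- meta$sample_id[meta$specimen == "tissue"]
  if (config$regions == "discover") {
    say("discovering blocks from pooled tissue reads")
    regions <- run_stage("blocks", partition_blocks(
      pool_records(records[tissue_ids]), sites,
      r2_threshold = config$r2_threshold, min_pairs = config$min_pairs,
      max_gap = config$max_gap))
  } else {
    if (is.null(known_regions))
      stop("pipeline stage 'blocks' failed: no known region set available")
    regions <- known_regions
  }
  if (nrow(regions) == 0L)
    stop("pipeline stage 'blocks' failed: no blocks found")
  say(nrow(regions), " blocks in use")
  write_regions(regions, file.path(out_dir, "regions.bed"))

  # --- stage 3: scoring -----------------------------------------------
  say("scoring MHL and UMHL")
  mhl_mat <- run_stage("score", score_cohort(records, regions, config$load,
                                             "MHL"))
  umhl_mat <- run_stage("score", score_cohort(records, regions, config$load,
                                              "UMHL"))
  write_matrix(mhl_mat, file.path(out_dir, "mhl.tsv"))
  write_matrix(umhl_mat, file.path(out_dir, "umhl.tsv"))

  floor <- if (is.null(config$detection_floor))
    scale_detection_floor(nrow(regions)) else config$detection_floor
  fh <- config$filter_hcc; fh$min_detected_per_sample <- floor
  fm <- config$filter_mvi; fm$min_detected_per_sample <- floor

  # --- stage 4: HCC markers + tissue model ----------------------------
  say("selecting tumor-vs-normal markers (paired ",
      fh$test, ", FDR < ", fh$fdr_threshold, ")")
  markers_hcc <- run_stage("markers_hcc",
                           select_markers(mhl_mat, meta, fh,
                                          "tumor_vs_normal"))
  say(nrow(markers_hcc), " tumor-vs-normal markers")
  write_marker_set(markers_hcc, file.path(out_dir, "markers_hcc.tsv"))
  if (nrow(markers_hcc) == 0L)
    stop("pipeline stage 'markers_hcc' failed: no markers selected")

  hcc_ids <- unique(markers_hcc$id)
  tis_lab <- factor(meta$tumor_status[match(tissue_ids, meta$sample_id)],
                    levels = c("normal", "tumor"))
  mc <- config$model; mc$seed <- seeds[["cv_tissue"]]
  say("cross-validating tissue classifier (", mc$model, ")")
  cv_tissue <- run_stage("cv_tissue", cross_validate(
    mhl_mat[tissue_ids, hcc_ids, drop = FALSE], tis_lab, mc))
  say(sprintf("tissue mean AUC %.3f", cv_tissue$mean_auc))

  # --- stage 5: plasma transfer ---------------------------------------
  plasma_ids <- meta$sample_id[meta$specimen == "plasma"]
  plasma <- NULL
  if (length(plasma_ids) >= 2L) {
    mt <- config$model; mt$seed <- seeds[["transfer"]]
    tissue_model <- run_stage("transfer", fit_model(
      mhl_mat[tissue_ids, hcc_ids, drop = FALSE], tis_lab, mt))
    prob <- run_stage("transfer", transfer_predict(
      tissue_model, mhl_mat[plasma_ids, hcc_ids, drop = FALSE]))
    lab <- meta$tumor_status[match(plasma_ids, meta$sample_id)] == "tumor"
    plasma_auc <- if (length(unique(lab)) == 2L) auc(prob, lab) else NA_real_
    plasma <- list(prob = prob, labels = lab, auc = plasma_auc)
    say(sprintf("plasma transfer AUC %.3f", plasma_auc))
    data.table::fwrite(data.table::data.table(
      sample_id = plasma_ids, prob_tumor = prob,
      truth = ifelse(lab, "tumor", "healthy")),
      file.path(out_dir, "plasma_predictions.tsv"), sep = "\t")
  }

  # --- stage 6: MVI markers + classifier ------------------------------
  say("selecting MVI markers (", fm$test, ", FDR < ", fm$fdr_threshold, ")")
  markers_mvi <- run_stage("markers_mvi", select_markers(
    list(MHL = mhl_mat, UMHL = umhl_mat), meta, fm, "mvi"))
  say(nrow(markers_mvi), " MVI markers")
  write_marker_set(markers_mvi, file.path(out_dir, "markers_mvi.tsv"))

  mvi <- NULL
  surv_res <- NULL
  if (nrow(markers_mvi) > 0L) {
    tumor_ids <- meta$sample_id[meta$specimen == "tissue" &
                                  meta$tumor_status == "tumor"]
    feats <- marker_features(list(MHL = mhl_mat, UMHL = umhl_mat),
                             markers_mvi, tumor_ids)
    mvi_lab <- factor(meta$mvi_status[match(tumor_ids, meta$sample_id)],
                      levels = c("negative", "positive"))
    mm <- config$model; mm$seed <- seeds[["mvi"]]
    mvi <- run_stage("mvi", predict_mvi(feats, mvi_lab, mm))
    say(sprintf("MVI mean AUC %.3f", mvi$cv$mean_auc))
    data.table::fwrite(data.table::data.table(
      sample_id = tumor_ids, prob_mvi_pos = mvi$prob,
      call = as.character(mvi$call), truth = as.character(mvi_lab)),
      file.path(out_dir, "mvi_calls.tsv"), sep = "\t")

    # --- stage 7: survival validation ---------------------------------
    st <- meta$surv_time[match(tumor_ids, meta$sample_id)]
    se <- meta$surv_event[match(tumor_ids, meta$sample_id)] == "event"
    if (sum(!is.na(st)) >= 4L && nlevels(droplevels(mvi$call)) == 2L) {
      surv_res <- run_stage("survival",
                            compare_survival(mvi$call, st, se))
      say(sprintf("log-rank chisq %.2f, p %.4g", surv_res$logrank$chisq,
                  surv_res$logrank$p))
      jsonlite::write_json(
        list(chisq = surv_res$logrank$chisq, p = surv_res$logrank$p,
             observed = surv_res$logrank$observed,
             expected = surv_res$logrank$expected),
        file.path(out_dir, "survival.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    } else say("survival comparison skipped (insufficient groups or times)")
  }

  # --- manifest -------------------------------------------------------
  results <- list(
    n_blocks = nrow(regions),
    n_markers_hcc = nrow(markers_hcc),
    n_markers_mvi = nrow(markers_mvi),
    tissue_mean_auc = cv_tissue$mean_auc,
    tissue_auc_ci = if (!is.null(cv_tissue$ci)) unname(cv_tissue$ci[2:3]),
    plasma_auc = if (!is.null(plasma)) plasma$auc,
    mvi_mean_auc = if (!is.null(mvi)) mvi$cv$mean_auc,
    logrank_p = if (!is.null(surv_res)) surv_res$logrank$p)
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, c("manifest.json", "run.log"))
  sums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(sums) <- files
  manifest <- list(
    package = "mhbkit",
    version = as.character(utils::packageVersion("mhbkit")),
    seed = config$seed, stage_seeds = as.list(seeds),
    parameters = config_echo(config),
    results = results, files = sums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done")
  invisible(list(cohort = cohort, regions = regions, mhl = mhl_mat,
                 umhl = umhl_mat, markers_hcc = markers_hcc,
                 cv_tissue = cv_tissue, plasma = plasma,
                 markers_mvi = markers_mvi, mvi = mvi, survival = surv_res,
                 manifest = manifest))
}

# flatten configuration objects into plain lists for the manifest
config_echo <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}

write_marker_set <- function(markers, path) {
  data.table::fwrite(as.data.frame(markers), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Assemble classifier features from a marker set
#'
#' Builds the samples x markers feature matrix for the given marker set,
#' taking each marker's values from the matrix of its score kind; columns
#' are named `kind:id` so MHL- and UMHL-quantified markers of the same
#' block stay distinct.
#'
#' @param matrices Named list of score matrices keyed by score kind.
#' @param markers A `marker_set` from [select_markers()].
#' @param sample_ids Rows to keep.
#' @return Numeric feature matrix.
#' @export
marker_features <- function(matrices, markers, sample_ids) {
  key <- unique(data.frame(kind = markers$score_kind, id = markers$id,
                           stringsAsFactors = FALSE))
  cols <- lapply(seq_len(nrow(key)), function(i)
    matrices[[key$kind[i]]][sample_ids, key$id[i]])
  out <- do.call(cbind, cols)
  dimnames(out) <- list(sample_ids, paste0(key$kind, ":", key$id))
  out
}

#' Match discovered regions to a reference region set
#'
#' Pairs each query region with the reference region sharing the largest
#' overlap in CpG ordinals (ties to the first; queries with no overlap get
#' `NA`). Useful for comparing discovered blocks with simulated truth.
#'
#' @param query,reference `mhb_regions` data.frames carrying `first_site`
#'   and `n_sites`.
#' @return A data.frame `query_id`, `reference_id`, `overlap_sites`.
#' @export
match_regions <- function(query, reference) {
  out <- data.frame(query_id = query$id, reference_id = NA_character_,
                    overlap_sites = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(query))) {
    same <- reference$chrom == query$chrom[i]
    if (!any(same)) next
    ref <- reference[same, , drop = FALSE]
    q_lo <- query$first_site[i]
    q_hi <- q_lo + query$n_sites[i] - 1L
    r_lo <- ref$first_site
    r_hi <- r_lo + ref$n_sites - 1L
    ov <- pmax(0L, pmin(q_hi, r_hi) - pmax(q_lo, r_lo) + 1L)
    j <- which.max(ov)
    if (ov[j] > 0L) {
      out$reference_id[i] <- ref$id[j]
      out$overlap_sites[i] <- ov[j]
    }
  }
  out
}
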