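#' Classifier configuration
#'
#' @param model `"random_forest"` (default) or `"svm_rbf"` (radial-kernel
#'   SVM, cost fixed at `svm_cost`, sigma tuned on the training folds over
#'   a power-of-two grid around the median heuristic).
#' @param n_trees Trees for the random forest.
#' @param svm_cost Soft-margin cost for the SVM.
#' @param k_folds Folds for stratified cross-validation.
#' @param n_repeats Repeats of the whole cross-validation.
#' @param seed Integer seed; all fold splits and model fits derive from it.
#' @return An object of class `model_config`.
#' @export
model_config <- function(model = c("random_forest", "svm_rbf"),
                         n_trees = 500L, svm_cost = 1, k_folds = 3L,
                         n_repeats = 10L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_trees >= 1L, k_folds >= 2L, n_repeats >= 1L, svm_cost > 0)
  structure(list(model = model, n_trees = as.integer(n_trees),
                 svm_cost = svm_cost, k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "model_config")
}

# coerce labels to a 2-level factor; positive class = second level
as_binary_factor <- function(labels) {
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  y
}

impute_medians <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(x, 2L, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0.5    # feature unobserved in training
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- medians[j]
  }
  list(x = x, medians = medians)
}

fit_single <- function(x, y, config) {
  if (config$model == "random_forest") {
    randomForest::randomForest(x, y, ntree = config$n_trees)
  } else {
    sig0 <- median_heuristic_sigma(x)
    grid <- sig0 * 2^(-4:4)
    best <- tune_svm_sigma(x, y, grid, config)
    kernlab::ksvm(x, y, kernel = "rbfdot",
                  kpar = list(sigma = best), C = config$svm_cost,
                  prob.model = TRUE)
  }
}

median_heuristic_sigma <- function(x) {
  d2 <- stats::dist(x)^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m == 0) return(1)
  1 / m
}

tune_svm_sigma <- function(x, y, grid, config) {
  folds <- stratified_folds(y, min(3L, min(table(y))))
  if (length(unique(folds)) < 2L) return(grid[ceiling(length(grid) / 2)])
  score <- vapply(grid, function(sig) {
    prob <- rep(NA_real_, length(y))
    for (f in unique(folds)) {
      tr <- folds != f
      fit <- try(kernlab::ksvm(x[tr, , drop = FALSE], y[tr],
                               kernel = "rbfdot", kpar = list(sigma = sig),
                               C = config$svm_cost, prob.model = TRUE),
                 silent = TRUE)
      if (inherits(fit, "try-error")) return(NA_real_)
      prob[!tr] <- kernlab::predict(fit, x[!tr, , drop = FALSE],
                                    type = "probabilities")[, levels(y)[2L]]
    }
    auc(prob, y == levels(y)[2L])
  }, 1)
  if (all(is.na(score))) return(grid[ceiling(length(grid) / 2)])
  grid[which.max(score)]
}

predict_single <- function(fit, x, positive) {
  if (inherits(fit, "randomForest")) {
    stats::predict(fit, x, type = "prob")[, positive]
  } else {
    kernlab::predict(fit, x, type = "probabilities")[, positive]
  }
}

#' Fit a classifier on a full feature matrix
#'
#' Imputes missing features by per-feature median (stored for later
#' prediction) and fits the configured model.
#'
#' @param x Samples x features numeric matrix (e.g. marker scores).
#' @param labels Two-class labels; the second factor level is the
#'   positive class.
#' @param config A [model_config()].
#' @return An object of class `mhb_model`.
#' @export
fit_model <- function(x, labels, config = model_config()) {
  y <- as_binary_factor(labels)
  set.seed(config$seed)
  imp <- impute_medians(as.matrix(x))
  fit <- fit_single(imp$x, y, config)
  structure(list(fit = fit, medians = imp$medians, config = config,
                 levels = levels(y), features = colnames(x)),
            class = "mhb_model")
}

#' Predict positive-class probabilities
#'
#' @param model An `mhb_model` from [fit_model()].
#' @param newdata Samples x features matrix containing all model feature
#'   columns (missing values allowed; imputed with training medians).
#' @return Named numeric vector of positive-class probabilities.
#' @export
transfer_predict <- function(model, newdata) {
  stopifnot(inherits(model, "mhb_model"))
  newdata <- as.matrix(newdata)
  missing_cols <- setdiff(model$features, colnames(newdata))
  if (length(missing_cols))
    stop("feature column(s) absent from new data: ",
         paste(missing_cols, collapse = ", "))
  x <- newdata[, model$features, drop = FALSE]
  x <- impute_medians(x, model$medians)$x
  p <- predict_single(model$fit, x, model$levels[2L])
  stats::setNames(as.numeric(p), rownames(newdata))
}

# deterministic stratified fold assignment (labels -> fold ids 1..k)
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, samples are split into stratified folds; the model is
#' fit on k-1 folds (with training-fold median imputation) and
#' out-of-fold positive-class probabilities are recorded, giving one AUC
#' per repeat. Fully deterministic given `config$seed`.
#'
#' @inheritParams fit_model
#' @return An object of class `cv_result`: `prob` (samples x repeats
#'   out-of-fold probabilities), `auc` (per repeat), `mean_auc`, `ci`
#'   (normal-approximation 95% interval over repeats, when >= 2),
#'   `folds` (samples x repeats fold ids), `levels`, `config`.
#' @export
cross_validate <- function(x, labels, config = model_config()) {
  x <- as.matrix(x)
  y <- as_binary_factor(labels)
  if (any(table(y) < config$k_folds))
    stop("each class needs at least k_folds samples for stratified folds")
  set.seed(config$seed)
  n <- nrow(x)
  prob <- matrix(NA_real_, n, config$n_repeats,
                 dimnames = list(rownames(x), NULL))
  fold_mat <- matrix(NA_integer_, n, config$n_repeats,
                     dimnames = list(rownames(x), NULL))
  for (r in seq_len(config$n_repeats)) {
    folds <- stratified_folds(y, config$k_folds)
    fold_mat[, r] <- folds
    for (f in seq_len(config$k_folds)) {
      tr <- folds != f
      imp <- impute_medians(x[tr, , drop = FALSE])
      fit <- fit_single(imp$x, y[tr], config)
      te <- impute_medians(x[!tr, , drop = FALSE], imp$medians)$x
      prob[!tr, r] <- predict_single(fit, te, levels(y)[2L])
    }
  }
  aucs <- apply(prob, 2L, auc, labels = y == levels(y)[2L])
  ci <- if (config$n_repeats >= 2L) auc_confidence_interval(aucs) else NULL
  structure(list(prob = prob, auc = aucs, mean_auc = mean(aucs), ci = ci,
                 folds = fold_mat, levels = levels(y), config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d repeats, mean AUC %.3f",
              x$config$k_folds, x$config$n_repeats, x$mean_auc))
  if (!is.null(x$ci))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci[["lower"]], x$ci[["upper"]]))
  cat("\n")
  invisible(x)
}

#' Rank-based AUC
#'
#' Probability that a random positive outranks a random negative, ties
#' counting one half — the normalised Mann-Whitney U statistic. The
#' trapezoidal integral of [roc_curve()] equals this value exactly.
#'
#' @param prob Numeric scores.
#' @param labels Logical (or two-level) vector; `TRUE`/second level is
#'   positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(prob, labels) {
  pos <- as.logical(if (is.logical(labels)) labels else
    as.factor(labels) == levels(as.factor(labels))[2L])
  ok <- !is.na(prob) & !is.na(pos)
  prob <- prob[ok]; pos <- pos[ok]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: a class is absent")
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams auc
#' @return A data.frame of `threshold`, `fpr`, `tpr`, ordered from (0,0)
#'   to (1,1).
#' @export
roc_curve <- function(prob, labels) {
  pos <- as.logical(if (is.logical(labels)) labels else
    as.factor(labels) == levels(as.factor(labels))[2L])
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("ROC undefined: a class is absent")
  th <- sort(unique(prob), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(prob >= t & pos) / n1, 1)
  fpr <- vapply(th, function(t) sum(prob >= t & !pos) / n0, 1)
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

# trapezoidal integral of a ROC curve (used in tests against auc())
roc_auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Confidence interval over repeat AUCs
#'
#' Normal-approximation interval `mean +/- 1.96 sd / sqrt(R)` over the
#' per-repeat AUCs, truncated to `[0, 1]`.
#'
#' @param aucs Per-repeat AUC values (>= 2).
#' @return Named vector `mean`, `lower`, `upper`.
#' @export
auc_confidence_interval <- function(aucs) {
  if (length(aucs) < 2L)
    stop("need at least two repeats for a confidence interval")
  m <- mean(aucs)
  half <- 1.96 * stats::sd(aucs) / sqrt(length(aucs))
  c(mean = m, lower = max(0, m - half), upper = min(1, m + half))
}

#' Cross-validate an MVI classifier and emit hard calls
#'
#' Runs [cross_validate()] on the combined marker features and converts
#' each sample's mean out-of-fold probability into a hard group call at
#' the 0.5 threshold (>= 0.5 is called positive). The calls feed the
#' survival validation.
#'
#' @inheritParams fit_model
#' @return A list: `cv` (the [cross_validate()] result), `prob` (mean
#'   out-of-fold probability per sample), `call` (factor of predicted
#'   classes).
#' @export
predict_mvi <- function(x, labels, config = model_config()) {
  y <- as_binary_factor(labels)
  cv <- cross_validate(x, y, config)
  prob <- rowMeans(cv$prob)
  call <- factor(ifelse(prob >= 0.5, cv$levels[2L], cv$levels[1L]),
                 levels = cv$levels)
  list(cv = cv, prob = prob, call = call)
}

#' Unsupervised views of a score matrix
#'
#' Selects the `k` blocks with the highest score standard deviation,
#' builds an average-linkage dendrogram on correlation distance between
#' samples, and computes principal-component scores of the centered data
#' (missing cells imputed by block median for these views only).
#'
#' @param mat Samples x blocks score matrix.
#' @param k Number of top-variance blocks to keep.
#' @return A list: `top_ids`, `hclust`, `pca` (a `prcomp`),
#'   `var_explained`.
#' @export
unsupervised_views <- function(mat, k = 100L) {
  stopifnot(nrow(mat) >= 2L)
  sds <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  top <- colnames(mat)[order(sds, decreasing = TRUE)][seq_len(min(k, ncol(mat)))]
  x <- impute_medians(mat[, top, drop = FALSE])$x
  cors <- suppressWarnings(stats::cor(t(x)))
  cors[!is.finite(cors)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cors), method = "average")
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(top_ids = top, hclust = hc, pca = pca,
       var_explained = pca$sdev^2 / sum(pca$sdev^2))
}
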