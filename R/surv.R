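#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`;
#' right-continuous and non-increasing with `S(0-) = 1`. Censored
#' observations tied with events leave the risk set after the events
#' (the standard convention).
#'
#' @param time Nonnegative follow-up times (months).
#' @param event Logical event indicator (`FALSE` = censored).
#' @return A data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(is.na(time)) || any(time < 0) || any(!is.finite(time)))
    stop("survival times must be finite and nonnegative")
  sf <- survival::survfit(survival::Surv(time, as.logical(event)) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv)
}

#' Two-group log-rank test
#'
#' Observed minus expected events accumulated over pooled event times,
#' variance from the hypergeometric formula; p-value from chi-square with
#' one degree of freedom.
#'
#' @param group Two-level group labels.
#' @param time Nonnegative follow-up times.
#' @param event Logical event indicator.
#' @return A list with `chisq`, `p`, and the per-group observed and
#'   expected event counts.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) != 2L)
    stop("log-rank test requires exactly two non-empty groups")
  if (sum(event) < 1L) stop("log-rank test requires at least one event")
  sd <- survival::survdiff(
    survival::Surv(time, as.logical(event)) ~ g,
    data = data.frame(time = time, event = as.logical(event), g = group))
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p = p, observed = sd$obs,
       expected = sd$exp)
}

#' Survival comparison of predicted MVI groups
#'
#' Kaplan-Meier curves and a log-rank test between samples called
#' MVI-positive and MVI-negative by the classifier.
#'
#' @param calls Factor/character of predicted groups per sample.
#' @param time,event Follow-up and event indicator per sample.
#' @return A list: per-group `km` tables and the `logrank` result.
#' @export
compare_survival <- function(calls, time, event) {
  ok <- !is.na(time) & !is.na(event) & !is.na(calls)
  calls <- droplevels(as.factor(calls[ok]))
  time <- time[ok]; event <- as.logical(event[ok])
  km <- lapply(stats::setNames(levels(calls), levels(calls)), function(g)
    kaplan_meier(time[calls == g], event[calls == g]))
  list(km = km, logrank = logrank_test(calls, time, event))
}
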