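# Independent brute-force oracles used to verify the package's
# implementations. These deliberately re-derive every quantity from first
# principles (window enumeration, read expansion, permutation enumeration,
# risk-set recomputation) and share no code with the package internals.

# enumerate every contiguous window of every length over reads split at '?'
oracle_window_counts <- function(haps, counts, l) {
  total <- meth <- unmeth <- numeric(l)
  for (r in seq_along(haps)) {
    for (seg in strsplit(haps[r], "?", fixed = TRUE)[[1]]) {
      L <- nchar(seg)
      if (L == 0) next
      for (i in seq_len(min(L, l))) {
        wins <- substring(seg, 1:(L - i + 1), i:L)
        total[i] <- total[i] + counts[r] * length(wins)
        meth[i] <- meth[i] + counts[r] * sum(wins == strrep("1", i))
        unmeth[i] <- unmeth[i] + counts[r] * sum(wins == strrep("0", i))
      }
    }
  }
  list(total = total, meth = meth, unmeth = unmeth)
}

oracle_load <- function(haps, counts, l, exponent = 3, kind = "meth") {
  oc <- oracle_window_counts(haps, counts, l)
  ok <- oc$total > 0
  if (!any(ok)) return(NA_real_)
  w <- (1:l)^exponent
  sum(w[ok] * oc[[kind]][ok] / oc$total[ok]) / sum(w[ok])
}

# random in-block record set (strings clipped to the block already)
random_block <- function(n_cpgs, max_reads, miss_prob = 0.15) {
  n <- sample.int(max_reads, 1)
  haps <- vapply(seq_len(n), function(i) {
    len <- sample.int(n_cpgs, 1)
    start <- sample.int(n_cpgs - len + 1L, 1)
    calls <- sample(c("0", "1", "?"), len, replace = TRUE,
                    prob = c((1 - miss_prob) / 2, (1 - miss_prob) / 2,
                             miss_prob))
    paste(calls, collapse = "")
  }, "")
  starts <- vapply(haps, function(h)
    sample.int(n_cpgs - nchar(h) + 1L, 1), 1L, USE.NAMES = FALSE)
  list(haps = haps, starts = starts,
       counts = sample.int(5L, n, replace = TRUE))
}

# squared Pearson correlation over count-expanded read lists
oracle_r2 <- function(a_calls, b_calls, counts) {
  a <- rep(a_calls, counts)
  b <- rep(b_calls, counts)
  suppressWarnings(stats::cor(a, b)^2)
}

# exhaustive maximal-run scan over an adjacent-pair "linked" vector
oracle_runs <- function(linked) {
  blocks <- list()
  i <- 1L
  while (i <= length(linked)) {
    if (isTRUE(linked[i])) {
      j <- i
      while (j <= length(linked) && isTRUE(linked[j])) j <- j + 1L
      blocks[[length(blocks) + 1L]] <- c(first = i, last = j)
      i <- j
    } else i <- i + 1L
  }
  blocks
}

# full-permutation rank-sum p-value (untied data)
oracle_rank_sum_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  stats <- colSums(matrix(r[combs], nrow = n))
  mu <- n * (length(pooled) + 1) / 2
  switch(alternative,
         greater = mean(stats >= obs),
         less = mean(stats <= obs),
         two_sided = mean(abs(stats - mu) >= abs(obs - mu) - 1e-12))
}

# full sign-flip signed-rank p-value (untied, nonzero differences)
oracle_signed_rank_p <- function(x, y, alternative) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  switch(alternative,
         greater = mean(stats >= obs),
         less = mean(stats <= obs),
         two_sided = mean(abs(stats - mu) >= abs(obs - mu) - 1e-12))
}

# literal step-up definition of the BH adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(m * p[o[rank_i:m]] / (rank_i:m)))
  }
  q
}

# pair-counting AUC
oracle_auc <- function(prob, pos) {
  pairs <- expand.grid(i = which(pos), j = which(!pos))
  mean(ifelse(prob[pairs$i] > prob[pairs$j], 1,
              ifelse(prob[pairs$i] == prob[pairs$j], 0.5, 0)))
}

# product-limit estimate by direct risk-set recomputation
oracle_km <- function(time, event) {
  times <- sort(unique(time))
  surv <- numeric(length(times))
  s <- 1
  for (k in seq_along(times)) {
    t <- times[k]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = times, surv = surv)
}

# two-group log-rank statistic by direct O-E/V accumulation
oracle_logrank <- function(group, time, event) {
  g <- as.integer(as.factor(group)) == 1L
  ts <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# reads over length(r2_targets)+1 sites: pair i gets length-2 haplotypes
# with the requested linkage (>= 0.5 -> perfectly linked, else independent)
make_pair_records <- function(r2_targets, n_per_pair = 40L) {
  haps <- character(); starts <- integer()
  for (i in seq_along(r2_targets)) {
    if (r2_targets[i] >= 0.5) {
      h <- rep(c("11", "00"), n_per_pair / 2)
    } else {
      h <- rep(c("11", "10", "01", "00"), n_per_pair / 4)
    }
    haps <- c(haps, h)
    starts <- c(starts, rep(i, length(h)))
  }
  haplotype_records(rep("chr1", length(haps)), as.integer(starts), haps,
                    rep(1L, length(haps)))
}

# small ready-made cohort reused by several test files (cached per session)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_spec(
        n_normal = 16, n_mvi_neg = 8, n_mvi_pos = 8, n_healthy_plasma = 10,
        n_blocks = 300, n_diff_tumor = 12, n_diff_mvi = 6, seed = 20260930))
    cache
  }
})
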