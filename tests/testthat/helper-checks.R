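# Shared helpers for Monte-Carlo assertions.

# |estimate - target| <= k standard errors (with a floor to avoid se = 0
# artifacts in binomial counts at the boundary)
expect_within_se <- function(estimate, target, se, k = 3, se_floor = 1e-12) {
  expect_lte(abs(estimate - target), k * max(se, se_floor))
}

# chi-square goodness of fit of observed counts against exact probabilities;
# pools categories with tiny expectation
gof_pvalue <- function(counts, probs) {
  keep <- probs * sum(counts) >= 5
  if (any(!keep)) {
    counts <- c(counts[keep], sum(counts[!keep]))
    probs <- c(probs[keep], sum(probs[!keep]))
  }
  suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs))$p.value)
}

# distributional-equality test with the retry rule: pass if any of the seeds
# yields p > 0.01 (guards against the multiple-testing false-alarm rate)
ks_retry_pass <- function(draw_a, draw_b, seeds = c(101, 202, 303), level = 0.01) {
  for (s in seeds) {
    set.seed(s)
    p <- suppressWarnings(stats::ks.test(draw_a(), draw_b())$p.value)
    if (p > level) return(TRUE)
  }
  FALSE
}

# empirical distribution of one-generation increments as counts per partition
increment_counts <- function(model, n, reps) {
  is_awf <- inherits(model, "frequency_model")
  keys <- vapply(all_partitions(n), format_partition, character(1))
  counts <- stats::setNames(numeric(length(keys)), keys)
  for (r in seq_len(reps)) {
    inc <- if (is_awf) awf_increment(model$sampler(), n) else
      ac_increment(model$sampler(), n)
    k <- format_partition(inc)
    counts[k] <- counts[k] + 1
  }
  counts
}
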