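# Convergence diagnostics: size-biased reordering, phi-moment estimators,
# the Lambda-limit and Kingman criteria, and the empirical harness for the
# transition-rate convergence condition.

#' Size-biased reordering of a probability vector
#'
#' Sequential draws without replacement with `P(next = eta_i | past) =
#' eta_i / (1 - sum chosen)`; zero entries are never chosen. Returns the
#' reordered values padded with zeros beyond the number `K` of non-zero
#' source entries.
#'
#' @param eta probability vector.
#' @return list with `values` (length `length(eta)`), `K` and `partial_sums`.
#' @export
size_biased_reorder <- function(eta) {
  check_prob_vector(eta)
  K <- sum(eta > 0)
  idx <- sample.int(length(eta), K, replace = FALSE, prob = eta)
  values <- c(eta[idx], rep(0, length(eta) - K))
  list(values = values, K = K, partial_sums = cumsum(values))
}

#' Size-biased moment functional phi
#'
#' Estimates `phi_j(b_1, ..., b_j) = E[prod_i s_i^{b_i - 1} prod_{i < j}
#' (1 - S_i)] / c_N` where `(s_i)` is the size-biased reordering of a
#' frequency draw and `S_i` its partial sums, with `c_N` estimated on the
#' same draws (common random numbers).
#'
#' The default `"conditional"` estimator replaces the size-biased product by
#' its exact conditional expectation given the frequency draw — the
#' distinct-index sum `sum prod eta_{i_k}^{b_k}` — which removes all
#' reordering noise; with it, `phi(2) = 1` and the additivity recursion in
#' the block sizes hold to machine precision on shared draws. The
#' `"sampling"` estimator uses the raw size-biased product.
#'
#' @param model a `frequency_model`.
#' @param block_sizes integer vector `b_1 >= ... >= b_j >= 1`.
#' @param reps Monte-Carlo draws (a warning is issued below 100); ignored for
#'   finite-outcome models, which are computed exactly.
#' @param estimator `"conditional"` or `"sampling"`.
#' @return list of class `"phi_estimate"`: `block_sizes`, `value`,
#'   `std_error`, `c_N_used`, `estimator`.
#' @export
phi_estimate <- function(model, block_sizes, reps = 10000L,
                         estimator = c("conditional", "sampling")) {
  estimator <- match.arg(estimator)
  b <- sort(as.integer(block_sizes), decreasing = TRUE)  # functional is symmetric
  if (any(b < 1)) stop("block sizes must be >= 1")
  if (is.null(model$outcomes) && reps < 100) {
    warning("phi_estimate with fewer than 100 replicates is unreliable")
  }

  cond_term <- function(eta) awf_profile_prob(eta, b)
  samp_term <- function(eta) {
    sb <- size_biased_reorder(eta)
    j <- length(b)
    if (sb$K < j) return(0)
    s <- sb$values[seq_len(j)]
    v <- prod(s^(b - 1))
    if (j > 1) v <- v * prod(1 - sb$partial_sums[seq_len(j - 1L)])
    v
  }
  term <- if (estimator == "conditional") cond_term else samp_term

  if (!is.null(model$outcomes) && estimator == "conditional") {
    num <- sum(vapply(model$outcomes, function(o) o$prob * cond_term(o$value), numeric(1)))
    den <- sum(vapply(model$outcomes, function(o) o$prob * sum(o$value^2), numeric(1)))
    out <- list(block_sizes = b, value = num / den, std_error = 0,
                c_N_used = den, estimator = "exact")
  } else {
    tx <- numeric(reps)
    ty <- numeric(reps)
    for (r in seq_len(reps)) {
      eta <- model$sampler()
      tx[r] <- term(eta)
      ty[r] <- sum(eta^2)
    }
    phi <- mean(tx) / mean(ty)
    se <- stats::sd(tx - phi * ty) / (mean(ty) * sqrt(reps))
    out <- list(block_sizes = b, value = phi, std_error = se,
                c_N_used = mean(ty), estimator = estimator)
  }
  class(out) <- "phi_estimate"
  out
}

#' @export
print.phi_estimate <- function(x, ...) {
  cat("phi(", paste(x$block_sizes, collapse = ","), ") = ",
      format(x$value), " (se ", format(x$std_error), ", ", x$estimator,
      ", c_N = ", format(x$c_N_used), ")\n", sep = "")
  invisible(x)
}

# ratio-of-means estimate with delta-method standard error
ratio_estimate <- function(x, y) {
  r <- mean(x) / mean(y)
  se <- stats::sd(x - r * y) / (mean(y) * sqrt(length(x)))
  c(estimate = r, se = se)
}

#' Lambda-coalescent limit criterion
#'
#' Checks the sufficient condition for convergence to a Lambda-coalescent:
#' the single-index moment ratios `r_b = E[eta_i^b] / c_N` should match the
#' collision-rate ratios `lambda_{b,b} / lambda_{2,2}` of the candidate
#' measure. Estimated by Monte-Carlo with `c_N` on the same draws; exact for
#' finite-outcome models. When `grid_models` is supplied (a list of models
#' at increasing `N`), the residual condition `E[sum_{k != i} eta_k^2] =
#' o(c_N)` is checked by a log-log trend across the grid.
#'
#' @param model a `frequency_model`.
#' @param b_max largest group size to test.
#' @param Lambda candidate `lambda_measure`.
#' @param reps Monte-Carlo draws.
#' @param index the distinguished family index `i` (default 1; the condition
#'   does not require it to be the largest entry).
#' @param grid_models optional named list (names = N) of frequency models for
#'   the residual trend check.
#' @return list with a per-`b` data frame (`estimate`, `se`, `target`, `z`)
#'   and, if requested, the residual trend (`ratios`, `slope`).
#' @export
lambda_criterion <- function(model, b_max, Lambda, reps = 10000L, index = 1L,
                             grid_models = NULL) {
  stopifnot(b_max >= 2)
  bs <- 2:b_max
  if (!is.null(model$outcomes)) {
    num <- vapply(bs, function(b) {
      sum(vapply(model$outcomes, function(o) o$prob * o$value[index]^b, numeric(1)))
    }, numeric(1))
    den <- sum(vapply(model$outcomes, function(o) o$prob * sum(o$value^2), numeric(1)))
    est <- num / den
    se <- rep(0, length(bs))
  } else {
    X <- matrix(0, reps, length(bs))
    y <- numeric(reps)
    for (r in seq_len(reps)) {
      eta <- model$sampler()
      X[r, ] <- eta[index]^bs
      y[r] <- sum(eta^2)
    }
    rs <- apply(X, 2L, ratio_estimate, y = y)
    est <- rs["estimate", ]
    se <- rs["se", ]
  }
  target <- vapply(bs, function(b) lambda_rate(b, b, Lambda), numeric(1)) /
    lambda_rate(2, 2, Lambda)
  z <- ifelse(se > 0, (est - target) / se, ifelse(abs(est - target) < 1e-12, 0, Inf))
  tab <- data.frame(b = bs, estimate = est, se = se, target = target, z = z)

  residual <- NULL
  if (!is.null(grid_models)) {
    Ns <- as.numeric(names(grid_models))
    ratios <- vapply(grid_models, function(m) {
      x <- numeric(reps); y <- numeric(reps)
      for (r in seq_len(reps)) {
        eta <- m$sampler()
        x[r] <- sum(eta[-index]^2)
        y[r] <- sum(eta^2)
      }
      ratio_estimate(x, y)[["estimate"]]
    }, numeric(1))
    slope <- unname(stats::coef(stats::lm(log(ratios) ~ log(Ns)))[2L])
    residual <- list(N = Ns, ratios = ratios, slope = slope,
                     decreasing = all(diff(ratios) < 0))
  }
  list(table = tab, residual = residual)
}

#' Kingman-coalescent limit criterion
#'
#' Across a grid of models at increasing `N`, estimates
#' `E[sum_{i >= 2} eta_i^3] / c_N` and `E[eta_1^beta] / c_N` and reports
#' whether both trend to zero (negative log-log slope) along with the trend
#' of `c_N` itself.
#'
#' @param grid_models named list (names = N) of frequency models.
#' @param beta_exponent exponent `beta > 2` for the largest-family moment.
#' @param reps Monte-Carlo draws per grid point.
#' @return list with the per-N table and the two log-log slopes plus a `pass`
#'   flag (both slopes negative).
#' @export
kingman_criterion <- function(grid_models, beta_exponent = 3, reps = 10000L) {
  stopifnot(beta_exponent > 2)
  Ns <- as.numeric(names(grid_models))
  res <- t(vapply(grid_models, function(m) {
    x3 <- numeric(reps); xb <- numeric(reps); y <- numeric(reps)
    for (r in seq_len(reps)) {
      eta <- m$sampler()
      x3[r] <- sum(eta[-1L]^3)
      xb[r] <- eta[1L]^beta_exponent
      y[r] <- sum(eta^2)
    }
    c(tail_third = ratio_estimate(x3, y)[["estimate"]],
      head_beta = ratio_estimate(xb, y)[["estimate"]],
      c_N = mean(y))
  }, numeric(3)))
  tab <- data.frame(N = Ns, res)
  slope_tail <- unname(stats::coef(stats::lm(log(pmax(tab$tail_third, 1e-300)) ~ log(Ns)))[2L])
  slope_head <- unname(stats::coef(stats::lm(log(pmax(tab$head_beta, 1e-300)) ~ log(Ns)))[2L])
  slope_cN <- unname(stats::coef(stats::lm(log(tab$c_N) ~ log(Ns)))[2L])
  list(table = tab, slope_tail = slope_tail, slope_head = slope_head,
       slope_c_N = slope_cN,
       pass = slope_tail < 0 && slope_head < 0)
}

#' Empirical harness for the transition-rate convergence condition
#'
#' Direct check of the convergence condition `P^(N,n)(pi~) = c_N Q(pi~) +
#' o(c_N)`: simulates one-generation increments, estimates
#' `P^(N,n)(pi~) / c_N` for every non-trivial partition (with `c_N` from the
#' same frequency draws) and reports z-scores against the candidate rates
#' `Q(pi~)` normalized by the pair rate of `Q` (so that the `n = 2` ratio is
#' 1 by construction).
#'
#' @param model a `frequency_model` or `offspring_model`.
#' @param n sample size.
#' @param Q a `rate_matrix` on partitions of `[n]` (the candidate limit).
#' @param reps Monte-Carlo replicates.
#' @return list with the per-partition data frame (`ratio`, `se`, `target`,
#'   `z`) and the estimated `c_N`.
#' @export
eq_convergence_harness <- function(model, n, Q, reps = 20000L) {
  is_awf <- inherits(model, "frequency_model")
  parts <- all_partitions(n)
  nb <- vapply(parts, n_blocks, integer(1))
  nontrivial <- parts[nb < n]
  keys <- vapply(nontrivial, format_partition, character(1))

  ind <- matrix(0, reps, length(keys), dimnames = list(NULL, keys))
  y <- numeric(reps)
  for (r in seq_len(reps)) {
    v <- model$sampler()
    inc <- if (is_awf) awf_increment(v, n) else ac_increment(v, n)
    k <- format_partition(inc)
    if (k %in% keys) ind[r, k] <- 1
    y[r] <- if (is_awf) sum(v^2) else {
      S <- sum(v); sum(v * (v - 1)) / (S * (S - 1))
    }
  }
  qpair <- pair_rate(Q)
  rows <- lapply(seq_along(keys), function(i) {
    re <- ratio_estimate(ind[, i], y)
    target <- rate_of(Q, keys[i]) / qpair
    z <- if (re[["se"]] > 0) (re[["estimate"]] - target) / re[["se"]] else
      ifelse(abs(re[["estimate"]] - target) < 1e-12, 0, Inf)
    data.frame(partition = keys[i], ratio = re[["estimate"]], se = re[["se"]],
               target = target, z = z, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), c_N = mean(y), reps = reps)
}

#' Serialize a diagnostics table to TSV and JSON
#'
#' @param table a data frame of diagnostics (statistic, estimate, se, target, z).
#' @param path_tsv,path_json output files (either may be `NULL`).
#' @export
write_report <- function(table, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(table, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(table, path_json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(table)
}
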