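# Forward one-generation dynamics and exact / Monte-Carlo coagulation
# transition matrices for asymmetric Wright-Fisher (AWF) and asymmetric
# Cannings (AC) populations.

#' Frequency model (AWF reproduction law)
#'
#' A sampler of random probability vectors `eta` of length `N`: children of a
#' generation pick their parent independently according to `eta` (sampling
#' with replacement). `outcomes` optionally lists a finite exact distribution
#' `list(list(value =, prob =), ...)` enabling exact enumeration.
#'
#' @param sampler function() returning a probability vector of length `N`.
#' @param N population size.
#' @param outcomes optional finite outcome list for exact computations.
#' @param c_N optional analytic pair-coalescence probability.
#' @param name model label.
#' @export
frequency_model <- function(sampler, N, outcomes = NULL, c_N = NULL,
                            name = "frequency model") {
  structure(list(sampler = sampler, N = as.integer(N), outcomes = outcomes,
                 c_N = c_N, name = name),
            class = "frequency_model")
}

#' Offspring model (AC reproduction law)
#'
#' A sampler of non-negative integer offspring vectors `xi` of length `N`
#' with `sum(xi) >= N`; the next generation is a uniform sample without
#' replacement of `N` (or, for a genealogy sample, `n`) of the `sum(xi)`
#' children.
#'
#' @param sampler function() returning an integer vector of length `N`.
#' @param N population size.
#' @param outcomes optional finite outcome list for exact computations.
#' @param name model label.
#' @export
offspring_model <- function(sampler, N, outcomes = NULL, name = "offspring model") {
  structure(list(sampler = sampler, N = as.integer(N), outcomes = outcomes,
                 name = name),
            class = "offspring_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat("frequency model '", x$name, "', N = ", x$N,
      if (!is.null(x$outcomes)) paste0(", ", length(x$outcomes), " exact outcomes"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.offspring_model <- function(x, ...) {
  cat("offspring model '", x$name, "', N = ", x$N,
      if (!is.null(x$outcomes)) paste0(", ", length(x$outcomes), " exact outcomes"),
      "\n", sep = "")
  invisible(x)
}

# -- convenience constructors -------------------------------------------------

#' Deterministic frequency model (a single fixed vector)
#' @param eta probability vector.
#' @param name model label.
#' @export
fm_deterministic <- function(eta, name = "deterministic") {
  check_prob_vector(eta)
  frequency_model(function() eta, length(eta),
                  outcomes = list(list(value = eta, prob = 1)),
                  c_N = sum(eta^2), name = name)
}

#' Uniform Wright-Fisher frequency model (eta_i = 1/N)
#' @param N population size.
#' @export
fm_uniform <- function(N) {
  fm_deterministic(rep(1 / N, N), name = "wright-fisher")
}

#' Finite-outcome frequency model
#' @param outcomes list of `list(value = eta, prob = p)`; probs must sum to 1.
#' @param name model label.
#' @export
fm_finite <- function(outcomes, name = "finite mixture") {
  probs <- vapply(outcomes, `[[`, numeric(1), "prob")
  stopifnot(abs(sum(probs) - 1) < 1e-12)
  for (o in outcomes) check_prob_vector(o$value)
  N <- length(outcomes[[1L]]$value)
  sampler <- function() outcomes[[sample.int(length(outcomes), 1L, prob = probs)]]$value
  c_N <- sum(probs * vapply(outcomes, function(o) sum(o$value^2), numeric(1)))
  frequency_model(sampler, N, outcomes = outcomes, c_N = c_N, name = name)
}

#' Deterministic / finite-outcome offspring models
#' @param xi integer offspring vector with `sum(xi) >= length(xi)`.
#' @param name model label.
#' @export
om_deterministic <- function(xi, name = "deterministic offspring") {
  xi <- as.integer(xi)
  offspring_model(function() xi, length(xi),
                  outcomes = list(list(value = xi, prob = 1)), name = name)
}

#' @rdname om_deterministic
#' @param outcomes list of `list(value = xi, prob = p)`.
#' @export
om_finite <- function(outcomes, name = "finite offspring mixture") {
  probs <- vapply(outcomes, `[[`, numeric(1), "prob")
  stopifnot(abs(sum(probs) - 1) < 1e-12)
  N <- length(outcomes[[1L]]$value)
  sampler <- function() outcomes[[sample.int(length(outcomes), 1L, prob = probs)]]$value
  offspring_model(sampler, N, outcomes = outcomes, name = name)
}

check_prob_vector <- function(eta, tol = 1e-8) {
  if (any(eta < 0) || abs(sum(eta) - 1) > tol) {
    stop("not a probability vector: entries must be >= 0 and sum to 1 (got sum ",
         format(sum(eta), digits = 15), ")")
  }
  invisible(TRUE)
}

falling_factorial <- function(a, b) {
  out <- rep(1, length(a))
  if (b >= 1) for (t in 0:(b - 1)) out <- out * (a - t)
  out
}

# -- one-generation increments ------------------------------------------------

#' AWF coagulation increment
#'
#' `n` children draw their parent index i.i.d. from `eta`; children sharing a
#' parent form a block. This is the paint-box on the (unordered) entries of
#' `eta`.
#'
#' @param eta probability vector.
#' @param n number of sampled children.
#' @return A `partition` of `[n]`.
#' @export
awf_increment <- function(eta, n) {
  check_prob_vector(eta)
  parents <- sample.int(length(eta), n, replace = TRUE, prob = eta)
  group_by_label(parents)
}

#' AC coagulation increment
#'
#' From the `sum(xi)` child slots labeled by parent, draw `n` uniformly
#' without replacement; children with equal parent label form a block. The
#' within-parent counts are drawn by a sequential multivariate-hypergeometric
#' scheme (no explicit slot lists, so `sum(xi)` may be large), then assigned
#' to the `n` exchangeable child labels by a uniform shuffle.
#'
#' @param xi non-negative integer offspring vector with `sum(xi) >= n`.
#' @param n number of sampled children.
#' @return A `partition` of `[n]`.
#' @export
ac_increment <- function(xi, n) {
  total <- sum(xi)
  if (total < n) stop("sum(xi) = ", total, " < n = ", n, ": cannot sample without replacement")
  counts <- integer(length(xi))
  rem_total <- total
  rem_n <- n
  for (i in seq_along(xi)) {
    if (rem_n == 0L) break
    if (rem_total == xi[i]) {
      counts[i] <- rem_n
      rem_n <- 0L
      break
    }
    ci <- stats::rhyper(1L, xi[i], rem_total - xi[i], rem_n)
    counts[i] <- ci
    rem_n <- rem_n - ci
    rem_total <- rem_total - xi[i]
  }
  labels <- rep.int(seq_along(xi), counts)
  group_by_label(sample(labels, n))
}

# -- exact per-draw coagulation probabilities ---------------------------------

#' Exact AWF coagulation probability given the frequency vector
#'
#' `sum over distinct i_1..i_j of prod_k eta_{i_k}^{b_k}`, the conditional
#' probability that grouping `n = sum(b)` children by parent yields a given
#' labeled partition with block sizes `b`. Computed by the augmented-monomial
#' expansion, so it scales to large `N`.
#'
#' @param eta probability vector.
#' @param bsizes integer block sizes of the target partition.
#' @export
awf_profile_prob <- function(eta, bsizes) {
  F <- vapply(bsizes, function(b) eta^b, numeric(length(eta)))
  sum_distinct_products(matrix(F, ncol = length(bsizes)))
}

#' Exact AC coagulation probability given the offspring vector
#'
#' `sum over distinct i_1..i_j of prod_k (xi_{i_k})_{b_k} / (sum xi)_n` with
#' falling factorials `(a)_b = a(a-1)...(a-b+1)`.
#'
#' @param xi integer offspring vector.
#' @param bsizes integer block sizes.
#' @param n sample size (defaults to `sum(bsizes)`).
#' @export
ac_profile_prob <- function(xi, bsizes, n = sum(bsizes)) {
  F <- vapply(bsizes, function(b) falling_factorial(xi, b), numeric(length(xi)))
  num <- sum_distinct_products(matrix(F, ncol = length(bsizes)))
  num / falling_factorial(sum(xi), n)
}

# -- transition matrices ------------------------------------------------------

transition_matrix_obj <- function(probs, se, n, method, reps = NA_integer_) {
  structure(list(probs = probs, se = se, n = n, method = method, reps = reps),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("one-generation transition probabilities on partitions of [", x$n,
      "] (", x$method, ")\n", sep = "")
  ord <- order(-x$probs)
  for (i in utils::head(ord, 8L)) {
    cat("  ", names(x$probs)[i], ": ", format(x$probs[[i]]), "\n", sep = "")
  }
  invisible(x)
}

#' One-generation transition probabilities of an AWF sample genealogy
#'
#' For each partition `pi~` of `[n]`, the probability that grouping `n`
#' sampled children by parent yields `pi~`:
#' `P(pi~) = E[sum over distinct i_1..i_j prod_k eta_{i_k}^{b_k}]`.
#' With `method = "enumerate"` the expectation is taken exactly over the
#' model's finite outcome list; with `"monte_carlo"` increments are simulated
#' from fresh frequency draws.
#'
#' @param model a `frequency_model`.
#' @param n sample size.
#' @param method `"enumerate"` (requires finite `outcomes`) or `"monte_carlo"`.
#' @param reps Monte-Carlo replicates.
#' @return A `transition_matrix` (named probabilities over compact partition
#'   strings, standard errors, method).
#' @export
awf_transition_matrix <- function(model, n, method = c("enumerate", "monte_carlo"),
                                  reps = 10000L) {
  method <- match.arg(method)
  parts <- all_partitions(n)
  keys <- vapply(parts, format_partition, character(1))
  if (method == "enumerate") {
    if (is.null(model$outcomes)) {
      stop("enumeration requested for a model without a finite outcome list")
    }
    probs <- vapply(parts, function(pi) {
      sum(vapply(model$outcomes, function(o) {
        o$prob * awf_profile_prob(o$value, block_sizes(pi))
      }, numeric(1)))
    }, numeric(1))
    names(probs) <- keys
    transition_matrix_obj(probs, se = probs * 0, n = n, method = "enumerate")
  } else {
    counts <- stats::setNames(numeric(length(keys)), keys)
    for (r in seq_len(reps)) {
      inc <- awf_increment(model$sampler(), n)
      k <- format_partition(inc)
      counts[k] <- counts[k] + 1
    }
    probs <- counts / reps
    transition_matrix_obj(probs, se = sqrt(probs * (1 - probs) / reps),
                          n = n, method = "monte_carlo", reps = reps)
  }
}

#' One-generation transition probabilities of an AC sample genealogy
#'
#' As [awf_transition_matrix()] but for sampling the `n` children without
#' replacement from the `sum(xi)` slots:
#' `P~(pi~) = E[sum over distinct prod_k (xi_{i_k})_{b_k} / (sum xi)_n]`.
#'
#' @param model an `offspring_model`.
#' @inheritParams awf_transition_matrix
#' @export
ac_transition_matrix <- function(model, n, method = c("enumerate", "monte_carlo"),
                                 reps = 10000L) {
  method <- match.arg(method)
  parts <- all_partitions(n)
  keys <- vapply(parts, format_partition, character(1))
  if (method == "enumerate") {
    if (is.null(model$outcomes)) {
      stop("enumeration requested for a model without a finite outcome list")
    }
    probs <- vapply(parts, function(pi) {
      sum(vapply(model$outcomes, function(o) {
        o$prob * ac_profile_prob(o$value, block_sizes(pi), n)
      }, numeric(1)))
    }, numeric(1))
    names(probs) <- keys
    transition_matrix_obj(probs, se = probs * 0, n = n, method = "enumerate")
  } else {
    counts <- stats::setNames(numeric(length(keys)), keys)
    for (r in seq_len(reps)) {
      inc <- ac_increment(model$sampler(), n)
      k <- format_partition(inc)
      counts[k] <- counts[k] + 1
    }
    probs <- counts / reps
    transition_matrix_obj(probs, se = sqrt(probs * (1 - probs) / reps),
                          n = n, method = "monte_carlo", reps = reps)
  }
}

#' Pair-coalescence probability c_N
#'
#' Probability that two randomly chosen individuals share a parent one
#' generation back: `E[sum eta_i^2]` for AWF models and
#' `E[sum xi_i (xi_i - 1) / (S (S - 1))]` (with `S = sum xi`) for AC models.
#' Exact for models with a finite outcome list, Monte-Carlo (with standard
#' error) otherwise.
#'
#' @param model a `frequency_model` or `offspring_model`.
#' @param reps Monte-Carlo replicates when no finite outcome list is present.
#' @return list with `estimate`, `se` (0 when exact) and `method`.
#' @export
pair_coalescence_probability <- function(model, reps = 10000L) {
  stat <- if (inherits(model, "frequency_model")) {
    function(v) sum(v^2)
  } else {
    function(v) {
      S <- sum(v)
      sum(v * (v - 1)) / (S * (S - 1))
    }
  }
  if (!is.null(model$outcomes)) {
    est <- sum(vapply(model$outcomes, function(o) o$prob * stat(o$value), numeric(1)))
    list(estimate = est, se = 0, method = "exact")
  } else {
    x <- vapply(seq_len(reps), function(r) stat(model$sampler()), numeric(1))
    list(estimate = mean(x), se = stats::sd(x) / sqrt(reps), method = "monte_carlo")
  }
}

#' Simulate the genealogy of a sample of n individuals
#'
#' Runs the discrete-time coalescent of the model: every generation a fresh
#' frequency/offspring vector is drawn (static environment) and the current
#' lineages receive an i.i.d. coagulation increment. Only generations with an
#' actual coagulation are recorded.
#'
#' @param model a `frequency_model` or `offspring_model`.
#' @param n sample size, `n <= model$N`.
#' @param horizon number of generations, or `"until_mrca"`.
#' @param time_scale `"generations"`, or `"rescaled"` to report times
#'   multiplied by `c_N` (coalescent time units).
#' @param c_N pair-coalescence probability used for rescaling; defaults to
#'   the model's analytic value or a plug-in Monte-Carlo estimate.
#' @param max_generations safety cap for `"until_mrca"`.
#' @return A `genealogy_trace`.
#' @export
simulate_genealogy <- function(model, n, horizon = "until_mrca",
                               time_scale = c("generations", "rescaled"),
                               c_N = NULL, max_generations = 1e6) {
  time_scale <- match.arg(time_scale)
  if (n > model$N) stop("sample size n = ", n, " exceeds population size N = ", model$N)
  until_mrca <- identical(horizon, "until_mrca")
  if (!until_mrca) {
    horizon <- as.numeric(horizon)
    if (is.na(horizon) || horizon <= 0) stop("horizon must be positive or 'until_mrca'")
  }
  if (time_scale == "rescaled" && is.null(c_N)) {
    c_N <- if (!is.null(model$c_N)) model$c_N else pair_coalescence_probability(model)$estimate
  }
  scale <- if (time_scale == "rescaled") c_N else 1

  is_awf <- inherits(model, "frequency_model")
  state <- singleton_partition(n)
  times <- 0
  partitions <- list(state)
  increments <- list(singleton_partition(n))
  t <- 0L
  limit <- if (until_mrca) max_generations else horizon
  while (t < limit && n_blocks(state) > 1L) {
    t <- t + 1L
    m <- n_blocks(state)
    inc <- if (is_awf) awf_increment(model$sampler(), m) else ac_increment(model$sampler(), m)
    if (n_blocks(inc) == m) next  # identity increment, not recorded
    state <- coagulate(state, inc)
    times <- c(times, t * scale)
    partitions[[length(partitions) + 1L]] <- state
    increments[[length(increments) + 1L]] <- inc
  }
  genealogy_trace(n, times, partitions, increments,
                  time_scale = time_scale, generations = t)
}

#' Sampling with vs without replacement: AC/AWF discrepancy report
#'
#' Builds the frequency model induced by normalizing each offspring draw
#' (`eta_i = xi_i / sum(xi)`), computes both one-generation transition
#' matrices on partitions of `[n]` (Rao-Blackwellized over shared offspring
#' draws: the coagulation probabilities are evaluated exactly given each
#' draw), and reports the maximum absolute row-sum norm of their difference
#' together with `c_N`, `c~_N` and `E[1/sum(xi)]`. When `c_N / E[1/S]` is
#' large the two models share their limit genealogy.
#'
#' @param model an `offspring_model`.
#' @param n sample size for the transition matrices.
#' @param reps number of offspring draws (ignored for finite-outcome models,
#'   which are computed exactly).
#' @return list with `norm`, `c_N`, `c_tilde_N`, `E_inv_sigma`, `ratio`,
#'   `same_limit` flag, and the per-partition probability table.
#' @export
ac_awf_discrepancy <- function(model, n, reps = 2000L) {
  parts <- all_partitions(n)
  keys <- vapply(parts, format_partition, character(1))
  sizes_list <- lapply(parts, block_sizes)

  draws <- if (!is.null(model$outcomes)) {
    lapply(model$outcomes, function(o) list(xi = o$value, w = o$prob))
  } else {
    lapply(seq_len(reps), function(r) list(xi = model$sampler(), w = 1 / reps))
  }

  P_awf <- stats::setNames(numeric(length(keys)), keys)
  P_ac <- P_awf
  c_N <- 0; c_tilde <- 0; e_inv <- 0
  for (d in draws) {
    xi <- d$xi
    S <- sum(xi)
    eta <- xi / S
    for (i in seq_along(parts)) {
      bs <- sizes_list[[i]]
      P_awf[i] <- P_awf[i] + d$w * awf_profile_prob(eta, bs)
      P_ac[i] <- P_ac[i] + d$w * ac_profile_prob(xi, bs, n)
    }
    c_N <- c_N + d$w * sum(eta^2)
    c_tilde <- c_tilde + d$w * sum(xi * (xi - 1)) / (S * (S - 1))
    e_inv <- e_inv + d$w / S
  }
  nrm <- sum(abs(P_ac - P_awf))  # max-row-sum over the explored set (row 0_n)
  ratio <- c_N / e_inv
  list(norm = nrm, c_N = c_N, c_tilde_N = c_tilde, E_inv_sigma = e_inv,
       ratio = ratio, same_limit = is.finite(ratio) && ratio > 50,
       table = data.frame(partition = keys, P_awf = unname(P_awf),
                          P_ac = unname(P_ac), stringsAsFactors = FALSE),
       n_draws = length(draws))
}
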