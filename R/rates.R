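# Exact Xi/Lambda-coalescent collision rates and a continuous-time
# Lambda-coalescent reference simulator.

#' Lambda measures on [0, 1]
#'
#' Finite measures driving Lambda-coalescents. `lambda_point_mass(0)` is
#' Kingman's coalescent; `lambda_beta(1, 1)` is the Bolthausen-Sznitman
#' coalescent.
#'
#' @param p location of the atom, in \[0, 1\].
#' @param mass total mass (default 1).
#' @return An object of class `"lambda_measure"`.
#' @export
lambda_point_mass <- function(p, mass = 1) {
  stopifnot(p >= 0, p <= 1, mass > 0)
  structure(list(kind = "point_mass", p = p, mass = mass), class = "lambda_measure")
}

#' @rdname lambda_point_mass
#' @param a,b shape parameters of the Beta density.
#' @export
lambda_beta <- function(a, b, mass = 1) {
  stopifnot(a > 0, b > 0, mass > 0)
  structure(list(kind = "beta", a = a, b = b, mass = mass), class = "lambda_measure")
}

#' @rdname lambda_point_mass
#' @param density vectorized density function on `(cutoff, 1]` (total mass is
#'   computed by quadrature).
#' @param cutoff lower cutoff of the support.
#' @export
lambda_density <- function(density, cutoff = 0) {
  stopifnot(is.function(density), cutoff >= 0, cutoff < 1)
  mass <- stats::integrate(density, cutoff, 1, rel.tol = 1e-12, abs.tol = 1e-10)$value
  structure(list(kind = "density", density = density, cutoff = cutoff, mass = mass),
            class = "lambda_measure")
}

#' Lambda-coalescent collision rate
#'
#' The rate at which a specific group of `b` out of `n` blocks merges:
#' `lambda_{n,b} = int p^{b-2} (1-p)^{n-b} Lambda(dp)`. Closed form for Beta
#' and point-mass measures, adaptive Gauss-Kronrod quadrature (absolute
#' tolerance 1e-10) otherwise.
#'
#' @param n current number of blocks.
#' @param b group size, `2 <= b <= n`.
#' @param Lambda a `lambda_measure`.
#' @export
lambda_rate <- function(n, b, Lambda) {
  if (b < 2 || b > n) stop("lambda_rate requires 2 <= b <= n; got b = ", b, ", n = ", n)
  switch(Lambda$kind,
    point_mass = {
      p <- Lambda$p
      if (p == 0) {
        if (b == 2) Lambda$mass else 0
      } else {
        Lambda$mass * p^(b - 2) * (1 - p)^(n - b)
      }
    },
    beta = Lambda$mass * beta(Lambda$a + b - 2, Lambda$b + n - b) / beta(Lambda$a, Lambda$b),
    density = stats::integrate(
      function(p) p^(b - 2) * (1 - p)^(n - b) * Lambda$density(p),
      Lambda$cutoff, 1, rel.tol = 1e-12, abs.tol = 1e-10
    )$value,
    stop("unknown lambda_measure kind")
  )
}

#' Xi measure with finite atom support plus a Kingman component
#'
#' A coagulation measure represented as a finite list of mass-partition atoms
#' with positive weights, plus `kingman_mass` at the zero mass partition
#' (driving pairwise merges at that rate). Atoms with `sum(parts^2) == 0`
#' are rejected. General continuous Xi is represented by Monte-Carlo atoms
#' sampled by the caller.
#'
#' @param atoms list of `list(rho = mass_partition, weight = positive real)`.
#' @param kingman_mass non-negative mass at the zero mass partition.
#' @export
xi_measure <- function(atoms = list(), kingman_mass = 0) {
  stopifnot(kingman_mass >= 0)
  for (a in atoms) {
    if (!inherits(a$rho, "mass_partition")) stop("each atom needs a mass_partition 'rho'")
    if (!is.numeric(a$weight) || a$weight <= 0) stop("each atom needs a positive 'weight'")
    if (sum(a$rho$parts^2) <= 0) {
      stop("atom with sum(rho_i^2) = 0 and positive weight; put that mass in kingman_mass")
    }
  }
  structure(list(atoms = atoms, kingman_mass = kingman_mass), class = "xi_measure")
}

#' Coagulation rate matrix of a Xi-coalescent on partitions of [n]
#'
#' For each non-trivial partition `pi~` of `[n]`, the rate from the singleton
#' partition is `kingman_mass * [pi~ is a single pair merge]` plus, for each
#' atom `(rho, w)`, `w / sum(rho_i^2)` times the exact paint-box probability
#' that `rho` produces `pi~` (singleton blocks may fall in dust).
#'
#' @param n ground-set size, `n >= 2`.
#' @param Xi a `xi_measure`.
#' @param exact_max_n paint-box probabilities are computed by exact
#'   enumeration up to this `n` and by Monte-Carlo beyond (the switchover
#'   knob).
#' @param mc_reps paint-box draws per atom on the Monte-Carlo path.
#' @return An object of class `"rate_matrix"`: fields `n`, `rates` (named by
#'   the compact partition strings), `partitions`.
#' @export
xi_rate_matrix <- function(n, Xi, exact_max_n = 8L, mc_reps = 200000L) {
  stopifnot(n >= 2)
  parts <- all_partitions(n)
  nb <- vapply(parts, n_blocks, integer(1))
  nontrivial <- parts[nb < n]
  keys <- vapply(nontrivial, format_partition, character(1))
  rates <- stats::setNames(numeric(length(keys)), keys)
  for (i in seq_along(nontrivial)) {
    if (Xi$kingman_mass > 0 && is_pair_merge(nontrivial[[i]])) {
      rates[i] <- Xi$kingman_mass
    }
  }
  for (a in Xi$atoms) {
    w <- a$weight / sum(a$rho$parts^2)
    if (n <= exact_max_n) {
      for (i in seq_along(nontrivial)) {
        rates[i] <- rates[i] + w * paintbox_prob(a$rho, nontrivial[[i]])
      }
    } else {
      for (r in seq_len(mc_reps)) {
        key <- format_partition(paintbox_sample(a$rho, n))
        if (!is.na(rates[key])) rates[key] <- rates[key] + w / mc_reps
      }
    }
  }
  structure(list(n = n, rates = rates, partitions = nontrivial), class = "rate_matrix")
}

#' Rate matrix of a Lambda-coalescent on partitions of [n]
#'
#' Convenience wrapper: the rate of a partition with one block of size `b`
#' and `n - b` singletons is `lambda_rate(n, b, Lambda)`; other non-trivial
#' partitions have rate 0.
#'
#' @inheritParams lambda_rate
#' @export
lambda_rate_matrix <- function(n, Lambda) {
  parts <- all_partitions(n)
  nb <- vapply(parts, n_blocks, integer(1))
  nontrivial <- parts[nb < n]
  rates <- vapply(nontrivial, function(pi) {
    sz <- block_sizes(pi)
    if (sum(sz >= 2) == 1L) lambda_rate(n, max(sz), Lambda) else 0
  }, numeric(1))
  names(rates) <- vapply(nontrivial, format_partition, character(1))
  structure(list(n = n, rates = rates, partitions = nontrivial), class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("coagulation rate matrix on partitions of [", x$n, "], ",
      length(x$rates), " non-trivial states\n", sep = "")
  show <- utils::head(sort(x$rates, decreasing = TRUE), 10L)
  for (nm in names(show)) cat("  ", nm, ": ", format(show[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Rate of one partition in a rate matrix
#' @param rm a `rate_matrix`.
#' @param pi a `partition` (or its compact string).
#' @export
rate_of <- function(rm, pi) {
  key <- if (is_partition(pi)) format_partition(pi) else pi
  r <- rm$rates[key]
  if (is.na(r)) 0 else unname(r)
}

#' Pair-merge rate implied by a rate matrix
#'
#' By sampling consistency, the rate at which blocks 1 and 2 merge (ignoring
#' the rest) is the sum of the rates of all partitions whose restriction to
#' \{1, 2\} is the pair merge. This equals `lambda_{2,2}` for Lambda-type
#' measures and is the natural normalization used by the convergence harness.
#'
#' @param rm a `rate_matrix`.
#' @export
pair_rate <- function(rm) {
  sum(vapply(seq_along(rm$partitions), function(i) {
    pi <- rm$partitions[[i]]
    together <- any(vapply(pi$blocks, function(b) all(c(1L, 2L) %in% b), logical(1)))
    if (together) rm$rates[[i]] else 0
  }, numeric(1)))
}

#' Export a rate matrix to TSV
#'
#' One row per block-size profile (rates are invariant under relabeling), with
#' columns `block_size_profile` and `rate`.
#'
#' @param rm a `rate_matrix`.
#' @param path output file.
#' @export
export_rates_tsv <- function(rm, path) {
  prof <- vapply(rm$partitions, function(p) {
    paste(sort(block_sizes(p), decreasing = TRUE), collapse = "+")
  }, character(1))
  df <- data.frame(block_size_profile = prof, rate = unname(rm$rates),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df$block_size_profile), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Simulate a Lambda-coalescent in continuous time
#'
#' Markov jump process started from the singleton partition of `[n]`: when
#' `m` blocks are present each specific group of `b` blocks merges at rate
#' `lambda_{m,b}`, so the total jump rate is `sum_b choose(m, b)
#' lambda_{m,b}`; the chain is absorbed at the single block.
#'
#' @param n sample size, `n >= 2`.
#' @param Lambda a `lambda_measure` with positive total mass.
#' @return A `genealogy_trace` in coalescent time units.
#' @export
simulate_lambda_coalescent <- function(n, Lambda) {
  stopifnot(n >= 2)
  if (Lambda$mass <= 0) stop("Lambda must have positive total mass")
  lam <- matrix(0, n, n)  # lam[m, b]
  for (m in 2:n) for (b in 2:m) lam[m, b] <- lambda_rate(m, b, Lambda)

  state <- singleton_partition(n)
  times <- 0
  partitions <- list(state)
  increments <- list(singleton_partition(n))
  t <- 0
  while (n_blocks(state) > 1L) {
    m <- n_blocks(state)
    group_rates <- choose(m, 2:m) * lam[m, 2:m]
    tot <- sum(group_rates)
    if (tot <= 0) break
    t <- t + stats::rexp(1, tot)
    b <- (2:m)[sample.int(m - 1L, 1L, prob = group_rates)]
    merged <- sort(sample.int(m, b))
    inc_blocks <- c(list(merged), as.list(setdiff(seq_len(m), merged)))
    inc <- partition(inc_blocks, m)
    state <- coagulate(state, inc)
    times <- c(times, t)
    partitions[[length(partitions) + 1L]] <- state
    increments[[length(increments) + 1L]] <- inc
  }
  genealogy_trace(n, times, partitions, increments, time_scale = "coalescent")
}
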