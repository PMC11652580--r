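# Concrete model families: generalized Eldon-Wakeley reproduction, recurrent
# bottlenecks, Poisson-Dirichlet power-law family frequencies, the
# branching-selection exponential model, and the asymptotic constants of the
# Poisson-Dirichlet analysis.

# ---- Eldon-Wakeley ----------------------------------------------------------

# inverse-CDF sampler for the normalized law y^{-2} Lambda(dy) on (cutoff, 1]
ew_y_sampler <- function(Lambda, cutoff, grid_points = 20000L) {
  if (cutoff <= 0 || cutoff >= 1) stop("Eldon-Wakeley cutoff must lie in (0, 1)")
  if (Lambda$kind == "point_mass") {
    p <- Lambda$p
    if (p <= cutoff) {
      stop("Lambda has no mass above the cutoff ", format(cutoff),
           " (atom at ", format(p), ")")
    }
    return(function(k) rep(p, k))
  }
  dens <- switch(Lambda$kind,
    beta = function(y) Lambda$mass * stats::dbeta(y, Lambda$a, Lambda$b),
    density = function(y) ifelse(y > Lambda$cutoff, Lambda$density(y), 0),
    stop("unsupported lambda_measure kind")
  )
  if (Lambda$kind == "beta" && Lambda$a == 1 && Lambda$b == 1) {
    # exact inverse CDF of y^{-2} on (cutoff, 1]
    t <- cutoff
    return(function(k) {
      u <- stats::runif(k)
      1 / (1 / t - u * (1 / t - 1))
    })
  }
  x <- exp(seq(log(cutoff), 0, length.out = grid_points + 1L))
  w <- dens(x) / x^2
  dF <- diff(x) * (w[-1L] + w[-length(w)]) / 2
  FF <- c(0, cumsum(dF))
  if (FF[length(FF)] <= 0) stop("Lambda has no mass above the cutoff ", format(cutoff))
  FF <- FF / FF[length(FF)]
  keep <- !duplicated(FF)
  x <- x[keep]; FF <- FF[keep]
  function(k) stats::approx(FF, x, stats::runif(k), rule = 2)$y
}

#' Moments of the Eldon-Wakeley reproduction fraction
#'
#' Quadrature oracle for `E[Y^m]` under the normalized law
#' `y^{-2} Lambda(dy)` restricted to `(cutoff, 1]`.
#'
#' @param Lambda a `lambda_measure` (beta, point mass or density).
#' @param cutoff lower truncation point.
#' @param m moment order.
#' @export
ew_y_moment <- function(Lambda, cutoff, m) {
  if (Lambda$kind == "point_mass") {
    if (Lambda$p <= cutoff) stop("no mass above the cutoff")
    return(Lambda$p^m)
  }
  dens <- switch(Lambda$kind,
    beta = function(y) stats::dbeta(y, Lambda$a, Lambda$b),
    density = Lambda$density
  )
  num <- stats::integrate(function(y) y^(m - 2) * dens(y), cutoff, 1,
                          rel.tol = 1e-12, abs.tol = 1e-12)$value
  den <- stats::integrate(function(y) y^(-2) * dens(y), cutoff, 1,
                          rel.tol = 1e-12, abs.tol = 1e-12)$value
  num / den
}

#' Generalized Eldon-Wakeley offspring model
#'
#' One randomly chosen individual produces `floor(Y * N)` copies of itself
#' which replace as many randomly chosen individuals; everyone else leaves
#' one child or none. `Y` is drawn from the normalized law `y^{-2}
#' Lambda(dy)` truncated to `(N^{(epsilon - 1)/2}, 1]`, so that the limit
#' genealogy is the Lambda-coalescent. `floor(Y N) = 0` gives a generation
#' of all singletons; `floor(Y N) = N` a deterministic full merge.
#'
#' @param Lambda a `lambda_measure`.
#' @param epsilon truncation exponent in (0, 1).
#' @param N population size.
#' @param big_first if `TRUE` the prolific parent is always index 1 (the
#'   law of the genealogy is unchanged by non-heritability; useful for the
#'   single-index criteria). Default `FALSE` (uniform random index).
#' @return An `offspring_model` with extra fields `Lambda`, `epsilon`,
#'   `cutoff`, `y_sampler`.
#' @export
eldon_wakeley_model <- function(Lambda, epsilon, N, big_first = FALSE) {
  stopifnot(epsilon > 0, epsilon < 1, N >= 2)
  cutoff <- N^((epsilon - 1) / 2)
  ysamp <- ew_y_sampler(Lambda, cutoff)
  sampler <- function() {
    Y <- ysamp(1L)
    D <- floor(Y * N)
    xi <- integer(N)
    K <- if (big_first) 1L else sample.int(N, 1L)
    xi[K] <- D
    others <- setdiff(seq_len(N), K)
    n_ones <- N - D
    if (n_ones > 0) {
      ones <- if (big_first) others[seq_len(n_ones)] else
        others[sample.int(N - 1L, n_ones)]
      xi[ones] <- 1L
    }
    xi
  }
  m <- offspring_model(sampler, N, name = "eldon-wakeley")
  m$Lambda <- Lambda; m$epsilon <- epsilon; m$cutoff <- cutoff
  m$y_sampler <- ysamp; m$big_first <- big_first
  m
}

#' Frequency model induced by an offspring model
#'
#' Normalizes each offspring draw: `eta_i = xi_i / sum(xi)`. This is the AWF
#' companion of an AC model (sampling with instead of without replacement).
#'
#' @param model an `offspring_model`.
#' @export
as_frequency_model <- function(model) {
  stopifnot(inherits(model, "offspring_model"))
  outcomes <- if (!is.null(model$outcomes)) {
    lapply(model$outcomes, function(o) list(value = o$value / sum(o$value), prob = o$prob))
  }
  frequency_model(function() {
    xi <- model$sampler()
    xi / sum(xi)
  }, model$N, outcomes = outcomes, name = paste0(model$name, " (normalized)"))
}

# ---- recurrent bottlenecks --------------------------------------------------

#' Wright-Fisher-type model with recurrent bottlenecks
#'
#' With probability `sum(F[1:b_N]) / a_N` the generation is produced by a
#' bottleneck: `k` individuals (drawn from `F` restricted to `1:b_N`)
#' reproduce with conditional frequency law `nubar(k)`; otherwise the
#' frequencies come from `hat_model`. `a_N` and `b_N` are diverging
#' sequences (`sum F = o(a_N)`, `b_N = o(N)`).
#'
#' @param F numeric vector of non-negative weights on bottleneck sizes
#'   `1, 2, ...` (finitely supported or truncated at `b_N`).
#' @param a_N,b_N values of the two sequences at this `N` (numbers, or
#'   functions of `N`).
#' @param nubar `"symmetric"` (frequencies `1/k`), `"dirichlet"` (normalized
#'   i.i.d. Exp(1) weights), or a function `k -> probability vector of
#'   length k`.
#' @param hat_model `frequency_model` for non-bottleneck generations.
#' @param N population size.
#' @return A `frequency_model` with extra fields describing the bottleneck.
#' @export
bottleneck_model <- function(F, a_N, b_N, nubar = "symmetric", hat_model, N) {
  aN <- if (is.function(a_N)) a_N(N) else a_N
  bN <- floor(if (is.function(b_N)) b_N(N) else b_N)
  Fb <- F[seq_len(min(length(F), bN))]
  p_bn <- sum(Fb) / aN
  if (p_bn > 1) stop("bottleneck probability ", format(p_bn), " > 1 at N = ", N)
  nufun <- bottleneck_nubar(nubar)
  sampler <- function() {
    if (stats::runif(1) < p_bn) {
      k <- sample.int(length(Fb), 1L, prob = Fb)
      c(nufun(k), rep(0, N - k))
    } else {
      hat_model$sampler()
    }
  }
  m <- frequency_model(sampler, N, name = "bottleneck")
  m$F <- F; m$a_N <- aN; m$b_N <- bN; m$p_bottleneck <- p_bn
  m$nubar <- nufun; m$hat_model <- hat_model
  m
}

bottleneck_nubar <- function(nubar) {
  if (is.function(nubar)) return(nubar)
  switch(nubar,
    symmetric = function(k) rep(1 / k, k),
    dirichlet = function(k) {
      w <- stats::rexp(k)
      w / sum(w)
    },
    stop("unknown bottleneck frequency law '", nubar, "'")
  )
}

#' Limit coagulation rates of the bottleneck model
#'
#' In the bottleneck-dominated regime the limit genealogy merges, at rate
#' `F(k)`, according to a paint-box driven by the conditional frequency law
#' on `k` reproducers: `Qbar(pi~) = sum_k F(k) E_nubar_k[paintbox prob of
#' pi~]`. Exact for the symmetric law, Monte-Carlo atoms otherwise.
#'
#' @param F finite vector of weights on bottleneck sizes (a truncation of an
#'   infinite `F` should be supplied with its remaining mass noted by the
#'   caller; the tail bound on any merge probability is `sum_{k > K} F(k)`).
#' @param nubar as in [bottleneck_model()].
#' @param n sample size.
#' @param mc_atoms Monte-Carlo atoms per `k` for random `nubar`.
#' @return A `rate_matrix`.
#' @export
bottleneck_limit_rates <- function(F, nubar = "symmetric", n, mc_atoms = 2000L) {
  parts <- all_partitions(n)
  nb <- vapply(parts, n_blocks, integer(1))
  nontrivial <- parts[nb < n]
  symmetric <- identical(nubar, "symmetric")
  nufun <- bottleneck_nubar(nubar)
  rates <- vapply(nontrivial, function(pi) {
    r <- 0
    for (k in seq_along(F)) {
      if (F[k] <= 0) next
      r <- r + F[k] * if (symmetric || k == 1L) {
        paintbox_prob(mass_partition(rep(1 / k, k)), pi)
      } else {
        mean(vapply(seq_len(mc_atoms), function(a) {
          paintbox_prob(mass_partition(sort(nufun(k), decreasing = TRUE)), pi)
        }, numeric(1)))
      }
    }
    r
  }, numeric(1))
  names(rates) <- vapply(nontrivial, format_partition, character(1))
  structure(list(n = n, rates = rates, partitions = nontrivial), class = "rate_matrix")
}

#' Classify the bottleneck limit regime
#'
#' The limit genealogy depends on `hat_c_N * a_N`: if it tends to 0 the
#' bottleneck paint-box rates `Qbar` dominate (regime "bottleneck"); if it
#' diverges the background model dominates ("background"); if it tends to a
#' positive constant `ell`, both matrices combine as `Qbar + ell * Q`
#' ("mixed").
#'
#' @param hat_c_N numeric vector of background pair-coalescence
#'   probabilities across the `N` grid.
#' @param a_N numeric vector of `a_N` values on the same grid.
#' @param Qbar bottleneck `rate_matrix` (optional, returned in the report).
#' @param Q background limit `rate_matrix` (needed for the mixed regime).
#' @return list with `regime`, the product trajectory, the estimated `ell`,
#'   and (in the mixed regime) the combined rate matrix.
#' @export
classify_bottleneck_regime <- function(hat_c_N, a_N, Qbar = NULL, Q = NULL) {
  prod <- hat_c_N * a_N
  k <- length(prod)
  slope <- if (k >= 2) {
    unname(stats::coef(stats::lm(log(prod) ~ log(seq_along(prod))))[2L])
  } else 0
  regime <- if (slope < -0.1) "bottleneck" else if (slope > 0.1) "background" else "mixed"
  ell <- prod[k]
  combined <- NULL
  if (regime == "mixed" && !is.null(Qbar) && !is.null(Q)) {
    keys <- union(names(Qbar$rates), names(Q$rates))
    rates <- stats::setNames(numeric(length(keys)), keys)
    rates[names(Qbar$rates)] <- Qbar$rates
    rates[names(Q$rates)] <- rates[names(Q$rates)] + ell * Q$rates
    combined <- structure(list(n = Qbar$n, rates = rates, partitions = Qbar$partitions),
                          class = "rate_matrix")
  }
  list(regime = regime, product = prod, slope = slope, ell = ell,
       combined = combined)
}

# ---- Poisson-Dirichlet power frequencies ------------------------------------

#' Stick-breaking construction of a Poisson-Dirichlet size-biased pick
#'
#' Draws `Y_i ~ Beta(1 - alpha, theta + i alpha)` independently and sets
#' `V~_1 = Y_1`, `V~_i = (1-Y_1)...(1-Y_{i-1}) Y_i`. Returns both sequences
#' for diagnostic reuse.
#'
#' @param alpha stability parameter in (0, 1).
#' @param theta concentration parameter, `theta > -alpha`.
#' @param N number of sticks.
#' @return list with `V` (size-biased frequencies), `Y` (stick proportions)
#'   and `logV`.
#' @export
pd_stick_breaking <- function(alpha, theta, N) {
  if (alpha <= 0 || alpha >= 1 || theta <= -alpha) {
    stop("Poisson-Dirichlet parameters require 0 < alpha < 1 and theta > -alpha")
  }
  Y <- stats::rbeta(N, 1 - alpha, theta + seq_len(N) * alpha)
  logV <- log(Y) + c(0, cumsum(log1p(-Y)))[seq_len(N)]
  list(V = exp(logV), Y = Y, logV = logV)
}

#' Poisson-Dirichlet power family frequencies
#'
#' One draw of the frequency vector `eta_i = V~_i^gamma / sum_j V~_j^gamma`
#' from a PD(alpha, theta) size-biased pick. `gamma = 0` gives the uniform
#' vector exactly; `gamma = 1` the renormalized PD prefix.
#'
#' @inheritParams pd_stick_breaking
#' @param gamma power applied to the frequencies (real).
#' @export
pd_power_frequencies <- function(alpha, theta, gamma, N) {
  if (gamma == 0) return(rep(1 / N, N))  # exactly uniform, no draws consumed
  sb <- pd_stick_breaking(alpha, theta, N)
  lw <- gamma * sb$logV
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Frequency model with Poisson-Dirichlet power frequencies
#'
#' @inheritParams pd_power_frequencies
#' @return A `frequency_model` with fields `alpha`, `theta`, `gamma`.
#' @export
pd_power_model <- function(alpha, theta, gamma, N) {
  m <- frequency_model(function() pd_power_frequencies(alpha, theta, gamma, N),
                       N, name = "pd-power")
  m$alpha <- alpha; m$theta <- theta; m$gamma <- gamma
  m
}

# ---- asymptotic constants ---------------------------------------------------

#' The constant Upsilon_a = lim (sum_{i<=M} (a+i)^{-1} - log M)
#'
#' Closed form `-digamma(a + 1)`; `Upsilon_0` is the Euler-Mascheroni
#' constant.
#'
#' @param a shift, `a > -1`.
#' @export
upsilon_constant <- function(a) {
  stopifnot(a > -1)
  -digamma(a + 1)
}

#' The centering constant K of the log-stick compensator
#'
#' Defined by the asymptotics of the compensator `mu_N` of the log-stick
#' martingale: `exp(gamma mu_N) ~ alpha^{-gamma} K^gamma N^{gamma (1 -
#' alpha) / alpha}`. Expanding `mu_N = psi(theta+1) - psi(theta + N alpha)
#' + sum_{i<N} (theta + i alpha)^{-1}` with `sum_{i<=M} (a+i)^{-1} = log M
#' + Upsilon_a + o(1)` gives `K = exp(psi(theta+1) + Upsilon_{theta/alpha} /
#' alpha) = exp(psi(theta+1) - psi(theta/alpha + 1)/alpha)`; a test checks
#' this against the defining limit. With it, `E[e^{gamma S_inf}] = K^gamma
#' Gamma(theta+1) Gamma((theta+gamma)/alpha + 1) / (Gamma(theta+gamma+1)
#' Gamma(theta/alpha + 1))`.
#'
#' @param alpha,theta Poisson-Dirichlet parameters.
#' @export
pd_K_constant <- function(alpha, theta) {
  exp(digamma(theta + 1) + upsilon_constant(theta / alpha) / alpha)
}

#' Asymptotic constants of the Poisson-Dirichlet power model
#'
#' Computes the timescale constants of the power family: `u_N = sum_{i<=N}
#' i^{-gamma/alpha}`; `mu_N = sum_{i<=N} [psi(theta + (i-1) alpha + 1) -
#' psi(theta + i alpha)]` (the compensator of the log-stick martingale);
#' `K = exp(psi(theta+1) - Upsilon_{theta/alpha} / alpha)`; the constant
#' `ell` of the coalescent timescale `L_N = ell * u_N^{1 + theta/alpha}`;
#' and the predicted pair-coalescence probability `c_N ~ (1 - theta/alpha)
#' / L_N` valid for `theta` in `(-alpha, alpha)`.
#'
#' @inheritParams pd_power_frequencies
#' @return list of class `"pd_constants"` with `u_N`, `mu_N`, `K`, `ell`,
#'   `L_N`, `c_N_predicted`.
#' @export
pd_constants <- function(alpha, theta, gamma, N) {
  if (gamma <= alpha / 2 || gamma > alpha) {
    warning("gamma = ", gamma, " outside (alpha/2, alpha]: the heavy-tail ",
            "timescale asymptotics are not guaranteed")
  }
  i <- seq_len(N)
  u_N <- sum(i^(-gamma / alpha))
  mu_N <- sum(digamma(theta + (i - 1) * alpha + 1) - digamma(theta + i * alpha))
  K <- pd_K_constant(alpha, theta)
  ell <- if (theta < alpha) 1 / ell_inverse(alpha, theta, gamma) else NA_real_
  L_N <- if (is.finite(ell)) ell * u_N^(1 + theta / alpha) else NA_real_
  c_N_pred <- if (is.finite(L_N) && theta > -alpha && theta < alpha) {
    (1 - theta / alpha) / L_N
  } else NA_real_
  structure(list(alpha = alpha, theta = theta, gamma = gamma, N = N,
                 u_N = u_N, mu_N = mu_N, K = K, ell = ell, L_N = L_N,
                 c_N_predicted = c_N_pred),
            class = "pd_constants")
}

#' @export
print.pd_constants <- function(x, ...) {
  cat("PD power-model constants (alpha = ", x$alpha, ", theta = ", x$theta,
      ", gamma = ", x$gamma, ", N = ", x$N, ")\n", sep = "")
  cat("  u_N = ", format(x$u_N), ", K = ", format(x$K),
      ", ell = ", format(x$ell), "\n  L_N = ", format(x$L_N),
      ", predicted c_N = ", format(x$c_N_predicted), "\n", sep = "")
  invisible(x)
}

# the full display for 1/ell
ell_inverse <- function(alpha, theta, gamma) {
  (alpha / gamma) *
    gamma(1 - alpha)^(theta / alpha) / gamma(1 + gamma - alpha)^(1 + theta / alpha) *
    gamma((alpha + theta) / alpha * (1 - gamma / alpha) + 1) /
    gamma((alpha + theta) * (1 - gamma / alpha) + 1) *
    gamma(1 + theta) * gamma(1 - theta / alpha) /
    beta(1 - theta / alpha, 1 + theta / alpha)
}

#' Simplified timescale constant at theta = 0
#'
#' Term-by-term simplification of the general display:
#' `1/ell = (alpha/gamma) Gamma(2 - gamma/alpha) /
#' (Gamma(1 + gamma - alpha) Gamma(1 + alpha - gamma))`.
#'
#' @param alpha,gamma model parameters.
#' @export
ell_inverse_theta0 <- function(alpha, gamma) {
  (alpha / gamma) * gamma(2 - gamma / alpha) /
    (gamma(1 + gamma - alpha) * gamma(1 + alpha - gamma))
}

#' Candidate limit constants for c_N * u_N in the exponential model
#'
#' Two closed forms for the limit of `c_N * sum_{i<=N} i^{-kappa}` in the
#' `(N, beta, kappa)` exponential model: `direct` is the specialization
#' `alpha = 1/beta, theta = 0, gamma = kappa/beta` of the general timescale
#' constant, `printed` is the alternative form with `Gamma(1 + (1+kappa)/
#' beta)` in the denominator. The two coincide at `kappa = 1` and differ
#' otherwise; Monte-Carlo estimation of `c_N u_N` adjudicates between them
#' (see the methods vignette).
#'
#' @param beta selection strength, `beta > 1`.
#' @param kappa fitness-scaling parameter in (1/2, 1].
#' @export
thm_exp_model_constants <- function(beta, kappa) {
  list(
    direct = gamma(2 - kappa) /
      (kappa * gamma(1 - (1 - kappa) / beta) * gamma(1 + (1 - kappa) / beta)),
    printed = gamma(2 - kappa) /
      (kappa * gamma(1 - (1 - kappa) / beta) * gamma(1 + (1 + kappa) / beta))
  )
}

#' Pathwise check of the normalizing-sum asymptotics
#'
#' On independent stick-breaking paths, computes `r_N = zeta_{N,gamma} /
#' (u_N exp(gamma S_N))` with `zeta_{N,gamma} = sum_{i<=N} V~_i^gamma` and
#' `S_N = mu_N + sum_{i<=N} log(1 - Y_i)`, and compares against the almost
#' sure limit `Gamma(1 + gamma - alpha) / Gamma(1 - alpha) * K^{-gamma}`
#' (valid for `alpha/2 < gamma <= alpha`). For `gamma > alpha` the sum
#' `zeta_N` instead converges to a finite random variable, and the report
#' contains its stabilization increments.
#'
#' @inheritParams pd_power_frequencies
#' @param N_grid increasing vector of evaluation points.
#' @param paths number of independent stick paths.
#' @return list with the per-path ratio matrix, the target constant, the
#'   relative deviations at the largest `N`, and (when `gamma > alpha`) the
#'   stabilization increments `zeta_{2N} - zeta_N`.
#' @export
zeta_limit_check <- function(alpha, theta, gamma, N_grid, paths = 5L) {
  N_grid <- sort(as.integer(N_grid))
  maxN <- N_grid[length(N_grid)]
  i <- seq_len(maxN)
  mu_cum <- cumsum(digamma(theta + (i - 1) * alpha + 1) - digamma(theta + i * alpha))
  u_cum <- cumsum(i^(-gamma / alpha))
  K <- pd_K_constant(alpha, theta)
  target <- gamma(1 + gamma - alpha) / gamma(1 - alpha) * K^(-gamma)

  ratios <- matrix(NA_real_, paths, length(N_grid),
                   dimnames = list(NULL, N_grid))
  zeta_at <- matrix(NA_real_, paths, length(N_grid))
  for (p in seq_len(paths)) {
    sb <- pd_stick_breaking(alpha, theta, maxN)
    zeta <- cumsum(exp(gamma * sb$logV))
    S <- mu_cum + cumsum(log1p(-sb$Y))
    ratios[p, ] <- zeta[N_grid] / (u_cum[N_grid] * exp(gamma * S[N_grid]))
    zeta_at[p, ] <- zeta[N_grid]
  }
  rel_dev <- abs(ratios[, length(N_grid)] / target - 1)
  stab <- if (gamma > alpha && length(N_grid) >= 2) {
    zeta_at[, length(N_grid)] - zeta_at[, length(N_grid) - 1L]
  }
  list(ratios = ratios, target = target, rel_dev_at_max = rel_dev,
       stabilization = stab, N_grid = N_grid)
}

# ---- exponential model ------------------------------------------------------

#' Parameters of the (N, beta, kappa) exponential model
#'
#' A branching-selection particle system: each parent at position `x` leaves
#' children along a Poisson point process of intensity `e^{-(s - kappa x)}
#' ds`; `N` children are then kept, sampled without replacement with weights
#' proportional to `e^{beta x}`. `beta > 1` makes the selection weights
#' summable. The countable offspring PPP is truncated to its top `K_atoms`
#' atoms; a run aborts if the last atom's selection-weight share exceeds
#' 1e-6.
#'
#' @param N population size.
#' @param beta selection strength, `beta > 1`.
#' @param kappa fitness scaling, `kappa > 0`.
#' @param K_atoms PPP truncation level (must be `>= N`).
#' @export
exp_model <- function(N, beta, kappa, K_atoms = max(40L * N, 2000L)) {
  stopifnot(beta > 1, kappa > 0, N >= 2)
  if (K_atoms < N) stop("K_atoms must be at least N")
  structure(list(N = as.integer(N), beta = beta, kappa = kappa,
                 K_atoms = as.integer(K_atoms)),
            class = "exp_model_params")
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' One generation of the exponential model
#'
#' Branches every parent (jointly, a single PPP of intensity
#' `e^{-(s - X_eq)} ds` with `X_eq = log sum e^{kappa X_i}`), selects `N`
#' children without replacement with weights `e^{beta z}` via Gumbel-top-k
#' in log space, and assigns each survivor a parent independently with
#' probability `e^{kappa X_i} / sum_j e^{kappa X_j}`.
#'
#' @param params an `exp_model` parameter object.
#' @param positions numeric vector of the `N` current parent positions.
#' @return list with `positions` (next generation), `parents` (assignment of
#'   each survivor), `frequencies` (the family-frequency vector
#'   `e^{kappa Z_i} / sum e^{kappa Z_j}` driving the next coagulation
#'   increment), `parent_probs` and `tail_share`.
#' @export
exp_model_step <- function(params, positions) {
  N <- params$N
  stopifnot(length(positions) == N)
  X_eq <- log_sum_exp(params$kappa * positions)
  # arrival times of the unit PPP; the tail is extended adaptively until the
  # last atom's selection-weight share drops below 1e-6 (the share scales with
  # 1 / sum(e^{beta z}), which is heavy-tailed, so no fixed truncation can
  # guarantee the bound)
  TT <- cumsum(stats::rexp(params$K_atoms))
  repeat {
    lw <- -params$beta * log(TT)
    tail_share <- exp(lw[length(lw)] - log_sum_exp(lw))
    if (tail_share <= 1e-6) break
    if (length(TT) >= 100L * params$K_atoms) {
      stop("PPP truncation too coarse: last-atom weight share ",
           format(tail_share), " > 1e-6 even after extension")
    }
    TT <- c(TT, TT[length(TT)] + cumsum(stats::rexp(length(TT))))
  }
  z <- -log(TT)
  g <- lw - log(-log(stats::runif(length(z))))  # Gumbel-top-k keys
  sel <- order(g, decreasing = TRUE)[seq_len(N)]
  Z <- z[sel]
  lpp <- params$kappa * positions
  parent_probs <- exp(lpp - log_sum_exp(lpp))
  parents <- sample.int(N, N, replace = TRUE, prob = parent_probs)
  lf <- params$kappa * Z
  freqs <- exp(lf - log_sum_exp(lf))
  list(positions = X_eq + Z, parents = parents, frequencies = freqs,
       parent_probs = parent_probs, tail_share = tail_share)
}

#' One draw of the exponential model's family-frequency vector
#'
#' The frequency vector does not depend on the current positions (the
#' equilibrium shift cancels), so a single step from any starting
#' configuration yields an exact draw.
#'
#' @param params an `exp_model` parameter object.
#' @export
exp_model_frequencies <- function(params) {
  exp_model_step(params, rep(0, params$N))$frequencies
}

#' Poisson-Dirichlet reduction of the exponential model
#'
#' The family-frequency vector of the `(N, beta, kappa)` exponential model
#' is distributed exactly as the Poisson-Dirichlet power frequencies with
#' `alpha = 1/beta`, `theta = 0`, `gamma = kappa/beta` — the shortcut used
#' for genealogy simulation.
#'
#' @param params an `exp_model` parameter object.
#' @return A `frequency_model` (PD power family).
#' @export
exp_model_reduction <- function(params) {
  pd_power_model(1 / params$beta, 0, params$kappa / params$beta, params$N)
}
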