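test_that("Eldon-Wakeley offspring vectors have the prescribed shape", {
  set.seed(441)
  # deterministic half-sweep: one parent with N/2 copies, N/2 parents with one
  ew <- eldon_wakeley_model(lambda_point_mass(0.5), 0.1, 10)
  for (r in 1:5) {
    xi <- ew$sampler()
    expect_equal(sum(xi), 10)
    expect_equal(sort(xi, decreasing = TRUE), c(5L, rep(1L, 5), rep(0L, 4)))
  }
  # Y = 1: a single parent produces everyone, full merge each generation
  ew1 <- eldon_wakeley_model(lambda_point_mass(1), 0.5, 8)
  expect_true(partitions_equal(ac_increment(ew1$sampler(), 4), one_block_partition(4)))
  # an atom below the truncation cutoff leaves no mass to sample
  expect_error(eldon_wakeley_model(lambda_point_mass(0.5), 0.5, 10), "no mass")
})

test_that("the truncated reproduction law matches its quadrature moments", {
  set.seed(442)
  # Lambda = Beta(1,1): the law y^{-2} on (t, 1] has E[Y^3]/E[Y^2] = (1+t)/2
  N <- 1000
  ew <- eldon_wakeley_model(lambda_beta(1, 1), 0.5, N)
  t <- N^(-0.25)
  expect_equal(ew_y_moment(lambda_beta(1, 1), t, 3) / ew_y_moment(lambda_beta(1, 1), t, 2),
               (1 + t) / 2, tolerance = 1e-10)
  y <- ew$y_sampler(20000L)
  expect_within_se(mean(y^2), ew_y_moment(lambda_beta(1, 1), t, 2),
                   stats::sd(y^2) / sqrt(length(y)))

  # grid-based inverse CDF path (non-uniform Beta measure)
  ew2 <- eldon_wakeley_model(lambda_beta(2, 2), 0.5, N)
  y2 <- ew2$y_sampler(20000L)
  expect_within_se(mean(y2), ew_y_moment(lambda_beta(2, 2), t, 1),
                   stats::sd(y2) / sqrt(length(y2)))
})

test_that("the sweep-fraction pair probability approaches E[Y^2]", {
  # Lambda = delta_{1/2}: c~_N = floor(N/2)(floor(N/2)-1)/(N(N-1)) -> 1/4
  vals <- vapply(c(20, 80, 320), function(N) {
    D <- floor(N / 2)
    D * (D - 1) / (N * (N - 1))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[3], 0.25, tolerance = 0.01)
})

test_that("bottleneck frequencies reduce to the background when F vanishes", {
  N <- 30
  m <- bottleneck_model(F = c(0, 0), a_N = sqrt(N), b_N = 2, hat_model = fm_uniform(N),
                        N = N)
  expect_equal(m$p_bottleneck, 0)
  set.seed(443)
  expect_equal(m$sampler(), rep(1 / N, N))
  expect_error(bottleneck_model(F = c(0, 50), a_N = 2, b_N = 2,
                                hat_model = fm_uniform(N), N = N), "> 1")
})

test_that("bottleneck limit rates match paint-box probabilities", {
  # conditional pair-merge probability given a symmetric bottleneck of size k
  for (k in 2:5) {
    expect_equal(paintbox_prob(mass_partition(rep(1 / k, k)), one_block_partition(2)),
                 1 / k, tolerance = 1e-12)
  }
  # F = lambda * delta_2, symmetric: Qbar(pair) = lambda / 2
  rm <- bottleneck_limit_rates(c(0, 0.7), "symmetric", 2)
  expect_equal(rate_of(rm, "1,2"), 0.35, tolerance = 1e-12)
  rm3 <- bottleneck_limit_rates(c(0, 1), "symmetric", 3)
  expect_equal(rate_of(rm3, "1,2|3"), 0.25, tolerance = 1e-12)
  expect_equal(rate_of(rm3, "1,2,3"), 0.25, tolerance = 1e-12)

  # normalized i.i.d. Exp weights at k = 2: E[U^2 + (1-U)^2] = 2/3, U uniform
  set.seed(444)
  rmd <- bottleneck_limit_rates(c(0, 1), "dirichlet", 2, mc_atoms = 4000L)
  expect_equal(rate_of(rmd, "1,2"), 2 / 3, tolerance = 0.02)
})

test_that("the bottleneck regime classifier separates the three regimes", {
  Ns <- c(1e2, 1e3, 1e4)
  # hat c_N = 1/N, a_N = N^{1/2}: product -> 0 (bottleneck-dominated)
  expect_equal(classify_bottleneck_regime(1 / Ns, sqrt(Ns))$regime, "bottleneck")
  # a_N = N^{1.5}: product diverges (background-dominated)
  expect_equal(classify_bottleneck_regime(1 / Ns, Ns^1.5)$regime, "background")
  # a_N = 3N: product flat at 3 (mixed), combined matrix adds ell * Q
  Qbar <- bottleneck_limit_rates(c(0, 1), "symmetric", 3)
  Q <- lambda_rate_matrix(3, lambda_point_mass(0))
  cl <- classify_bottleneck_regime(1 / Ns, 3 * Ns, Qbar = Qbar, Q = Q)
  expect_equal(cl$regime, "mixed")
  expect_equal(cl$ell, 3)
  expect_equal(rate_of(cl$combined, "1,2|3"), 0.25 + 3 * 1, tolerance = 1e-12)
})

test_that("stick-breaking has the Poisson-Dirichlet marginals and identities", {
  set.seed(445)
  alpha <- 0.6; theta <- 0.4
  reps <- 10000
  V1 <- vapply(seq_len(reps), function(r) pd_stick_breaking(alpha, theta, 2)$V[1L],
               numeric(1))
  expect_within_se(mean(V1), (1 - alpha) / (1 + theta), stats::sd(V1) / sqrt(reps))

  sb <- pd_stick_breaking(alpha, theta, 500)
  expect_true(all(diff(cumsum(sb$V)) > 0))
  expect_lt(sum(sb$V), 1)
  expect_error(pd_stick_breaking(1.2, 0, 5), "parameters")

  # removing the first stick and renormalizing shifts theta by alpha:
  # V2/(1 - V1) is Beta(1 - alpha, theta + 2 alpha)
  pass <- ks_retry_pass(
    function() {
      vapply(seq_len(4000), function(r) {
        sb <- pd_stick_breaking(alpha, theta, 2)
        sb$V[2L] / (1 - sb$V[1L])
      }, numeric(1))
    },
    function() stats::rbeta(4000, 1 - alpha, theta + 2 * alpha)
  )
  expect_true(pass)
})

test_that("power frequencies have their boundary identities", {
  set.seed(446)
  expect_equal(pd_power_frequencies(0.7, 0, 0, 25), rep(1 / 25, 25))
  s <- 447
  set.seed(s)
  eta <- pd_power_frequencies(0.5, 0.2, 1, 40)
  set.seed(s)
  sb <- pd_stick_breaking(0.5, 0.2, 40)
  expect_equal(eta, sb$V / sum(sb$V), tolerance = 1e-12)
  expect_equal(sum(eta), 1, tolerance = 1e-12)
  expect_true(all(eta > 0))
})

test_that("the timescale constants have their closed forms and defining limits", {
  pc <- suppressWarnings(pd_constants(0.7, 0, 0.7, 10))
  expect_equal(pc$u_N, sum(1 / (1:10)), tolerance = 1e-12)
  expect_equal(pc$u_N, 2.9289682539682538, tolerance = 1e-12)

  # Upsilon_a: partial sums minus log M converge to -digamma(a+1)
  M <- 1e6
  for (a in c(0, 0.3, 2)) {
    expect_equal(sum(1 / (a + seq_len(M))) - log(M), upsilon_constant(a),
                 tolerance = 1e-5)
  }

  # K from the defining limit of the compensator asymptotics
  alpha <- 0.7; theta <- 0.2
  N <- 2e5
  i <- seq_len(N)
  muN <- sum(digamma(theta + (i - 1) * alpha + 1) - digamma(theta + i * alpha))
  logK_emp <- muN + log(alpha) - (1 - alpha) / alpha * log(N)
  expect_equal(pd_K_constant(alpha, theta), exp(logK_emp), tolerance = 1e-3)

  # theta = 0 simplification of the general 1/ell display
  for (g in c(0.4, 0.55, 0.7)) {
    expect_equal(ell_inverse_theta0(0.7, g),
                 1 / suppressWarnings(pd_constants(0.7, 0, g, 10))$ell,
                 tolerance = 1e-12)
  }
  expect_warning(pd_constants(0.7, 0, 0.2, 10), "outside")

  # exponential-model candidates coincide at kappa = 1 and differ below
  cc <- thm_exp_model_constants(2, 1)
  expect_equal(cc$direct, 1, tolerance = 1e-12)
  expect_equal(cc$printed, 1, tolerance = 1e-12)
  cc2 <- thm_exp_model_constants(2, 0.75)
  expect_gt(abs(cc2$direct - cc2$printed), 0.01)
})

test_that("the normalizing sum stabilizes when gamma exceeds alpha", {
  set.seed(448)
  z <- zeta_limit_check(0.5, 0, 0.8, c(5000, 10000), paths = 3)
  expect_true(all(abs(z$stabilization) < 0.05))
})

test_that("the exponential model steps are well defined and symmetric", {
  set.seed(449)
  p <- exp_model(40, 2, 1)
  st <- exp_model_step(p, rep(3, 40))
  expect_equal(st$parent_probs, rep(1 / 40, 40))
  expect_equal(sum(st$frequencies), 1, tolerance = 1e-12)
  expect_lt(st$tail_share, 1e-6)
  expect_equal(length(st$positions), 40)
  expect_true(all(st$parents %in% 1:40))
  expect_error(exp_model(40, 2, 1, K_atoms = 10), "at least N")
  expect_error(exp_model(40, 0.9, 1), "beta > 1")

  # reduction parameters
  red <- exp_model_reduction(exp_model(40, 2, 1))
  expect_equal(red$alpha, 0.5)
  expect_equal(red$theta, 0)
  expect_equal(red$gamma, 0.5)

  # pair-coalescence probability agrees between the explicit step and the
  # Poisson-Dirichlet reduction
  reps <- 600
  a <- vapply(seq_len(reps), function(r) sum(exp_model_frequencies(p)^2), numeric(1))
  b <- vapply(seq_len(reps), function(r) sum(red$sampler()^2), numeric(1))
  expect_within_se(mean(a), mean(b),
                   sqrt(stats::var(a) / reps + stats::var(b) / reps))
})
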