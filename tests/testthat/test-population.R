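test_that("one-generation increments behave correctly on degenerate laws", {
  set.seed(421)
  expect_true(partitions_equal(awf_increment(c(1, 0, 0), 4), one_block_partition(4)))
  expect_true(partitions_equal(ac_increment(rep(1L, 5), 5), singleton_partition(5)))
  expect_true(partitions_equal(ac_increment(c(5L, 0L, 0L), 4), one_block_partition(4)))
  expect_true(partitions_equal(ac_increment(c(2L, 0L), 2), one_block_partition(2)))
  expect_error(awf_increment(c(0.5, 0.4), 2), "probability vector")
  expect_error(ac_increment(c(1L, 1L), 3), "without replacement")
})

test_that("increment frequencies match enumeration for the half-half vector", {
  set.seed(422)
  reps <- 10000
  counts <- increment_counts(fm_deterministic(c(0.5, 0.5)), 3, reps)
  # enumeration of the 2^3 parent assignments: P(profile (2,1)) = 0.75 split
  # evenly over the three labeled pair merges, P(triple) = 0.25
  exact <- c("1|2|3" = 0, "1,2|3" = 0.25, "1,3|2" = 0.25, "1|2,3" = 0.25,
             "1,2,3" = 0.25)
  expect_equal(sum(counts["1|2|3"]), 0)
  expect_gt(gof_pvalue(counts[names(exact)[-1]], exact[-1]), 0.01)
})

test_that("transition matrices equal exhaustive enumeration on all fixtures", {
  fx <- generate_fixtures()
  for (f in fx) {
    tm <- if (f$type == "awf") {
      awf_transition_matrix(fm_finite(f$outcomes), f$n)
    } else {
      ac_transition_matrix(om_finite(f$outcomes), f$n)
    }
    expect_equal(sum(tm$probs), 1, tolerance = 1e-12)
    expect_lt(max(abs(tm$probs[names(f$expected)] - f$expected)), 1e-12)
  }
})

test_that("enumeration is refused without a finite outcome list", {
  m <- frequency_model(function() stats::runif(3) / 1, 3)
  expect_error(awf_transition_matrix(m, 2, method = "enumerate"), "finite outcome")
})

test_that("Monte-Carlo transition estimates agree with enumeration", {
  set.seed(423)
  m <- fm_deterministic(c(0.6, 0.3, 0.1))
  exact <- awf_transition_matrix(m, 3)
  mc <- awf_transition_matrix(m, 3, method = "monte_carlo", reps = 8000L)
  for (k in names(exact$probs)) {
    expect_within_se(mc$probs[[k]], exact$probs[[k]], mc$se[[k]] + 1e-6)
  }
})

test_that("pair-coalescence probability equals the n = 2 transition entry", {
  m <- fm_deterministic(c(0.5, 0.5))
  expect_equal(pair_coalescence_probability(m)$estimate,
               awf_transition_matrix(m, 2)$probs[["1,2"]], tolerance = 1e-14)
  fx <- generate_fixtures()
  om <- om_finite(fx$multinomial4$outcomes)
  expect_equal(pair_coalescence_probability(om)$estimate,
               ac_transition_matrix(om, 2)$probs[["1,2"]], tolerance = 1e-14)
})

test_that("a deterministic half-population sweep has pair probability 20/90", {
  set.seed(424)
  ew <- eldon_wakeley_model(lambda_point_mass(0.5), 0.1, 10)
  xi <- ew$sampler()
  expect_equal(sort(xi, decreasing = TRUE), c(5L, rep(1L, 5), rep(0L, 4)))
  expect_equal(sum(xi * (xi - 1)) / (10 * 9), 20 / 90)
})

test_that("genealogies coalesce at the expected times and replay exactly", {
  set.seed(425)
  # everyone descends from parent 1: MRCA after one generation, always
  m1 <- fm_deterministic(c(1, 0, 0, 0, 0))
  tr <- simulate_genealogy(m1, 4)
  expect_equal(mrca_time(tr), 1)

  # Wright-Fisher, n = 2: MRCA time is geometric with mean N
  N <- 50
  reps <- 400
  wf <- fm_uniform(N)
  times <- vapply(seq_len(reps), function(r) mrca_time(simulate_genealogy(wf, 2)),
                  numeric(1))
  expect_within_se(mean(times), N, stats::sd(times) / sqrt(reps))

  # replaying the increments through the coagulation operator reproduces the
  # partition list
  tr2 <- simulate_genealogy(fm_deterministic(c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05)), 5)
  state <- singleton_partition(5)
  for (t in seq_along(tr2$times)[-1L]) {
    state <- coagulate(state, tr2$increments[[t]])
    expect_true(partitions_equal(state, tr2$partitions[[t]]))
  }
  expect_error(simulate_genealogy(wf, 2, horizon = 0), "horizon")
  expect_error(simulate_genealogy(wf, 60), "exceeds")

  # rescaled time scale divides generations by c_N (multiplies times)
  set.seed(426)
  tr3 <- simulate_genealogy(wf, 2, time_scale = "rescaled")
  expect_equal(tr3$times[2L] / tr3$generations, 1 / N, tolerance = 1e-12)
})

test_that("increments are exchangeable under relabeling of the sample", {
  set.seed(427)
  m <- fm_deterministic(c(0.6, 0.3, 0.1))
  exact <- awf_transition_matrix(m, 3)$probs
  reps <- 10000
  keys <- names(exact)
  counts <- stats::setNames(numeric(length(keys)), keys)
  sigma <- c(3L, 1L, 2L)
  for (r in seq_len(reps)) {
    inc <- awf_increment(m$sampler(), 3)
    # relabel individuals by sigma and re-canonicalize
    perm <- group_by_label(vapply(seq_len(3), function(i) {
      which(vapply(inc$blocks, function(b) sigma[i] %in% b, logical(1)))
    }, integer(1)))
    counts[format_partition(perm)] <- counts[format_partition(perm)] + 1
  }
  expect_gt(gof_pvalue(counts, exact), 0.01)
})

test_that("a fixed frequency vector reproduces the paint-box law exactly", {
  eta <- c(0.5, 0.3, 0.2)
  tm <- awf_transition_matrix(fm_deterministic(eta), 3)
  rho <- mass_partition(sort(eta, decreasing = TRUE))
  for (p in all_partitions(3)) {
    expect_equal(tm$probs[[format_partition(p)]], paintbox_prob(rho, p),
                 tolerance = 1e-12)
  }
})

test_that("the with/without-replacement discrepancy has its exact closed forms", {
  # every parent leaves exactly one child: sampling without replacement gives
  # no coalescence, while the induced with-replacement law still merges at the
  # Wright-Fisher rate; the row-sum discrepancy is exactly 2(1 - (N)_n / N^n)
  N <- 6L; n <- 3L
  d1 <- ac_awf_discrepancy(om_deterministic(rep(1L, N)), n)
  expect_equal(d1$c_tilde_N, 0)
  expect_equal(d1$c_N, 1 / N)
  expect_equal(d1$norm, 2 * (1 - prod(N - 0:(n - 1)) / N^n), tolerance = 1e-12)

  # a single parent: certain merge either way, zero discrepancy
  d2 <- ac_awf_discrepancy(om_deterministic(c(2L, 0L)), 2)
  expect_equal(d2$norm, 0, tolerance = 1e-12)
  expect_equal(d2$c_N, 1)
  expect_equal(d2$c_tilde_N, 1)
})
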