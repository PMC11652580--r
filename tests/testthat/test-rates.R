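test_that("collision rates: Kingman, Bolthausen-Sznitman and quadrature agree", {
  king <- lambda_point_mass(0)
  expect_equal(lambda_rate(5, 2, king), 1)
  expect_equal(lambda_rate(5, 3, king), 0)
  expect_equal(lambda_rate(5, 5, king), 0)

  bs <- lambda_beta(1, 1)
  for (b in 2:6) expect_equal(lambda_rate(b, b, bs), 1 / (b - 1), tolerance = 1e-12)
  expect_equal(lambda_rate(3, 2, bs), 0.5, tolerance = 1e-12)

  # adaptive quadrature path against the Beta closed form
  bs_num <- lambda_density(function(p) rep(1, length(p)))
  for (n in 2:6) for (b in 2:n) {
    expect_equal(lambda_rate(n, b, bs_num), lambda_rate(n, b, bs), tolerance = 1e-9)
  }
  expect_error(lambda_rate(3, 1, bs), "2 <= b <= n")
  expect_error(lambda_rate(3, 4, bs), "2 <= b <= n")
})

test_that("the collision-rate consistency recursion holds across measures", {
  measures <- list(lambda_beta(1, 1), lambda_beta(2, 3), lambda_beta(0.5, 0.5),
                   lambda_beta(1.5, 0.7, mass = 2),
                   lambda_point_mass(0.3), lambda_point_mass(0.7, mass = 0.5),
                   lambda_point_mass(0))
  for (L in measures) {
    for (n in 2:10) for (b in 2:n) {
      expect_equal(lambda_rate(n, b, L),
                   lambda_rate(n + 1, b, L) + lambda_rate(n + 1, b + 1, L),
                   tolerance = 1e-10)
    }
  }
})

test_that("Xi rate matrices match the paint-box formula on pinned cases", {
  # single atom at the full mass partition: only the full merge occurs
  Xi1 <- xi_measure(list(list(rho = mass_partition(1), weight = 1)))
  rm1 <- xi_rate_matrix(4, Xi1)
  expect_equal(rate_of(rm1, one_block_partition(4)), 1)
  others <- setdiff(names(rm1$rates), format_partition(one_block_partition(4)))
  expect_true(all(rm1$rates[others] == 0))

  # Lambda-type atom (p; dust 1-p) with weight p^2 at n = 2
  p <- 0.6
  Xi2 <- xi_measure(list(list(rho = mass_partition(p), weight = p^2)))
  expect_equal(rate_of(xi_rate_matrix(2, Xi2), "1,2"), p^2, tolerance = 1e-14)

  # symmetric two-interval atom
  Xi3 <- xi_measure(list(list(rho = mass_partition(c(0.5, 0.5)), weight = 0.5)))
  expect_equal(rate_of(xi_rate_matrix(2, Xi3), "1,2"), 0.5, tolerance = 1e-14)

  expect_error(xi_measure(list(list(rho = mass_partition(numeric(0), dust = 1),
                                    weight = 1))), "kingman_mass")
})

test_that("Lambda-type Xi measures reproduce the Lambda collision rates", {
  # Lambda = sum w_i delta_{p_i}  <->  Xi atoms (p_i; dust 1-p_i) with weight
  # w_i: the division by sum(rho^2) = p^2 in the rate formula converts the
  # paint-box factor p^b into the collision kernel p^{b-2}
  ps <- c(0.3, 0.8)
  ws <- c(0.4, 1.1)
  atoms <- lapply(seq_along(ps), function(i) {
    list(rho = mass_partition(ps[i]), weight = ws[i])
  })
  Xi <- xi_measure(atoms)
  n <- 5
  rm <- xi_rate_matrix(n, Xi)
  for (b in 2:n) {
    lam <- sum(ws * ps^(b - 2) * (1 - ps)^(n - b))
    blocks <- c(list(seq_len(b)), as.list(seq.int(b + 1, length.out = n - b)))
    expect_equal(rate_of(rm, partition(blocks, n)), lam, tolerance = 1e-10)
  }
  # non-simple merges have rate zero under a Lambda-type measure
  expect_equal(rate_of(rm, parse_partition("1,2|3,4|5")), 0)
})

test_that("rates are invariant under relabeling (depend only on block sizes)", {
  Xi <- xi_measure(list(list(rho = mass_partition(c(0.45, 0.35)), weight = 1),
                        list(rho = mass_partition(0.25), weight = 0.3)),
                   kingman_mass = 0.2)
  for (n in 2:4) {
    rm <- xi_rate_matrix(n, Xi)
    prof <- vapply(rm$partitions, function(p) {
      paste(sort(block_sizes(p), decreasing = TRUE), collapse = "+")
    }, character(1))
    for (pr in unique(prof)) {
      vals <- rm$rates[prof == pr]
      expect_lt(max(vals) - min(vals), 1e-12)
    }
  }
})

test_that("Monte-Carlo paint-box path of the rate matrix agrees with enumeration", {
  set.seed(411)
  Xi <- xi_measure(list(list(rho = mass_partition(c(0.5, 0.3)), weight = 1)))
  exact <- xi_rate_matrix(3, Xi)
  mc <- xi_rate_matrix(3, Xi, exact_max_n = 2L, mc_reps = 40000L)
  for (k in names(exact$rates)) {
    expect_lt(abs(mc$rates[[k]] - exact$rates[[k]]), 0.03)
  }
})

test_that("rate matrix TSV export is one row per block-size profile", {
  rm <- lambda_rate_matrix(4, lambda_beta(1, 1))
  path <- tempfile(fileext = ".tsv")
  df <- export_rates_tsv(rm, path)
  back <- utils::read.delim(path)
  expect_equal(names(back), c("block_size_profile", "rate"))
  expect_equal(nrow(back), length(unique(df$block_size_profile)))
})

test_that("the continuous-time Lambda-coalescent has the right jump law", {
  set.seed(412)
  # Kingman, n = 2: absorption time is Exponential(1)
  reps <- 5000
  tt <- vapply(seq_len(reps), function(r) {
    mrca_time(simulate_lambda_coalescent(2, lambda_point_mass(0)))
  }, numeric(1))
  expect_within_se(mean(tt), 1, stats::sd(tt) / sqrt(reps))

  # Bolthausen-Sznitman, n = 3: P(first jump is the triple merge)
  #   = lambda_33 / (3 lambda_32 + lambda_33) = 0.5 / (1.5 + 0.5) = 0.25
  triple <- vapply(seq_len(reps), function(r) {
    tr <- simulate_lambda_coalescent(3, lambda_beta(1, 1))
    n_blocks(tr$partitions[[2L]]) == 1L
  }, logical(1))
  expect_within_se(mean(triple), 0.25, sqrt(0.25 * 0.75 / reps))

  # block count is non-increasing along any trace
  tr <- simulate_lambda_coalescent(8, lambda_beta(2, 1))
  expect_true(all(diff(vapply(tr$partitions, n_blocks, integer(1))) < 0))
  expect_true(reached_mrca(tr))
})
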