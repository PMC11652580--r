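# Configuration, seeding, fixtures and the runners tying the modules into a
# reproducible command-line tool.

#' Deterministic per-replicate seed stream
#'
#' Derives the seed of replicate `r` from the root seed by a fixed integer
#' hash, so a run is reproducible and replicates are independent streams.
#' Values stay below 2^31.
#'
#' @param root root seed (integer).
#' @param r replicate index (1-based).
#' @export
replicate_seed <- function(root, r) {
  as.integer((as.numeric(root) * 48271 + as.numeric(r) * 1299721) %% 2147483629 + 1)
}

#' Run configuration
#'
#' Bundles a model key, its parameters and the run settings. The root seed
#' is recorded in every output artifact; replicate `r` uses
#' `replicate_seed(seed, r)`.
#'
#' @param model one of `"wright-fisher"`, `"eldon-wakeley"`,
#'   `"bottleneck-symmetric"`, `"bottleneck-dirichlet"`, `"pd-power"`,
#'   `"exp-model"`.
#' @param params named list of model parameters (see [make_model()]).
#' @param N population size.
#' @param n sample size.
#' @param generations integer horizon or `"until_mrca"`.
#' @param replicates number of replicates.
#' @param seed root seed.
#' @param time_scale `"generations"` or `"rescaled"`.
#' @param out_dir output directory.
#' @export
run_config <- function(model, params = list(), N, n, generations = "until_mrca",
                       replicates = 1L, seed = 1L, time_scale = "generations",
                       out_dir = tempfile("asymcoal_run_")) {
  if (n > N) stop("sample size n = ", n, " exceeds N = ", N)
  structure(list(model = model, params = params, N = as.integer(N),
                 n = as.integer(n), generations = generations,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 time_scale = time_scale, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file with the fields of [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' Instantiate a registered model
#'
#' String keys map to the model zoo: `"wright-fisher"` (uniform
#' frequencies), `"eldon-wakeley"` (`params`: `lambda_a`, `lambda_b` or
#' `lambda_p`, and `epsilon`), `"bottleneck-symmetric"` /
#' `"bottleneck-dirichlet"` (`params`: `F`, `a_exponent` with
#' `a_N = N^a_exponent`, optional `b_N`), `"pd-power"` (`alpha`, `theta`,
#' `gamma`) and `"exp-model"` (`beta`, `kappa`; simulated through its exact
#' Poisson-Dirichlet reduction).
#'
#' @param key model key.
#' @param params named parameter list.
#' @param N population size.
#' @return A `frequency_model` or `offspring_model`.
#' @export
make_model <- function(key, params = list(), N) {
  switch(key,
    "wright-fisher" = fm_uniform(N),
    "eldon-wakeley" = {
      Lambda <- if (!is.null(params$lambda_p)) lambda_point_mass(params$lambda_p)
                else lambda_beta(params$lambda_a %||% 1, params$lambda_b %||% 1)
      eldon_wakeley_model(Lambda, params$epsilon %||% 0.5, N)
    },
    "bottleneck-symmetric" = ,
    "bottleneck-dirichlet" = {
      nubar <- if (key == "bottleneck-symmetric") "symmetric" else "dirichlet"
      bottleneck_model(F = params$F %||% c(0, 1),
                       a_N = N^(params$a_exponent %||% 0.5),
                       b_N = params$b_N %||% max(2, floor(N^(1 / 3))),
                       nubar = nubar, hat_model = fm_uniform(N), N = N)
    },
    "pd-power" = pd_power_model(params$alpha, params$theta %||% 0,
                                params$gamma %||% params$alpha, N),
    "exp-model" = exp_model_reduction(exp_model(N, params$beta, params$kappa)),
    stop("unknown model key '", key, "'")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulation described by a configuration
#'
#' Simulates `replicates` genealogies, writing one JSON-lines trace per
#' replicate, a Newick file (one tree per line), a summary TSV
#' (pair-coalescence estimate with standard error, MRCA-time statistics and
#' the histogram of increment block-size profiles) and a resolved copy of
#' the configuration. Outputs are byte-identical for identical
#' `(config, seed)`.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the traces and the summary data frame.
#' @export
run_simulation <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- make_model(config$model, config$params, config$N)

  set.seed(replicate_seed(config$seed, 0L))
  cN <- pair_coalescence_probability(model, reps = 2000L)

  traces <- vector("list", config$replicates)
  newick <- character(config$replicates)
  mrca <- numeric(config$replicates)
  profile_keys <- character(0)
  for (r in seq_len(config$replicates)) {
    set.seed(replicate_seed(config$seed, r))
    tr <- simulate_genealogy(model, config$n, horizon = config$generations,
                             time_scale = config$time_scale,
                             c_N = cN$estimate)
    traces[[r]] <- tr
    newick[r] <- trace_to_newick(tr)
    mrca[r] <- mrca_time(tr)
    profile_keys <- c(profile_keys, vapply(tr$increments[-1L], function(inc) {
      paste(sort(block_sizes(inc), decreasing = TRUE), collapse = "+")
    }, character(1)))
    write_trace_jsonl(tr, file.path(config$out_dir, sprintf("trace_r%04d.jsonl", r)))
  }
  writeLines(newick, file.path(config$out_dir, "trees.nwk"))

  ptab <- table(profile_keys)
  profs <- sort(names(ptab))
  summary_df <- data.frame(
    statistic = c("c_N_estimate", "c_N_se", "mrca_mean", "mrca_sd",
                  "mrca_reached_fraction",
                  paste0("increment_profile_", profs)),
    value = c(cN$estimate, cN$se, mean(mrca, na.rm = TRUE),
              stats::sd(mrca, na.rm = TRUE), mean(!is.na(mrca)),
              as.numeric(ptab[profs])),
    stringsAsFactors = FALSE
  )
  utils::write.table(summary_df, file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config_resolved.yaml"))
  invisible(list(traces = traces, summary = summary_df, c_N = cN))
}

#' Run convergence diagnostics described by a configuration
#'
#' Runs the moment-ratio criterion against a candidate Lambda measure, the
#' Kingman criterion across an `N` grid, and/or the transition-rate harness,
#' writing a stable-schema TSV/JSON report (columns `statistic`, `estimate`,
#' `se`, `target`, `z`).
#'
#' @param config a `run_config`; `config$params` may carry `lambda_a`,
#'   `lambda_b` (candidate measure), `b_max`, `reps`, `N_grid`.
#' @param which subset of `c("lambda", "kingman", "harness")`.
#' @return The report data frame (also written to `out_dir`).
#' @export
run_diagnostics <- function(config, which = c("lambda", "harness")) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  reps <- p$reps %||% 5000L
  model <- make_model(config$model, p, config$N)
  if (inherits(model, "offspring_model")) model <- as_frequency_model(model)
  Lambda <- lambda_beta(p$lambda_a %||% 1, p$lambda_b %||% 1)
  rows <- list()

  set.seed(replicate_seed(config$seed, 1L))
  if ("lambda" %in% which) {
    lc <- lambda_criterion(model, b_max = p$b_max %||% 3L, Lambda, reps = reps)
    rows <- c(rows, list(data.frame(
      statistic = paste0("moment_ratio_b", lc$table$b),
      estimate = lc$table$estimate, se = lc$table$se,
      target = lc$table$target, z = lc$table$z, stringsAsFactors = FALSE)))
  }
  if ("kingman" %in% which) {
    grid <- p$N_grid %||% (config$N * c(1L, 4L, 16L))
    gm <- stats::setNames(lapply(grid, function(NN) make_model(config$model, p, NN)), grid)
    gm <- lapply(gm, function(m) if (inherits(m, "offspring_model")) as_frequency_model(m) else m)
    kc <- kingman_criterion(gm, beta_exponent = p$beta_exponent %||% 3, reps = reps)
    rows <- c(rows, list(data.frame(
      statistic = c("kingman_slope_tail_third", "kingman_slope_head_beta"),
      estimate = c(kc$slope_tail, kc$slope_head), se = NA_real_,
      target = c(0, 0), z = NA_real_, stringsAsFactors = FALSE)))
  }
  if ("harness" %in% which) {
    Q <- lambda_rate_matrix(config$n, Lambda)
    h <- eq_convergence_harness(model, config$n, Q, reps = reps)
    rows <- c(rows, list(data.frame(
      statistic = paste0("harness_ratio_", h$table$partition),
      estimate = h$table$ratio, se = h$table$se,
      target = h$table$target, z = h$table$z, stringsAsFactors = FALSE)))
  }
  report <- do.call(rbind, rows)
  write_report(report, file.path(config$out_dir, "diagnostics.tsv"),
               file.path(config$out_dir, "diagnostics.json"))
  report
}

# ---- fixtures and brute-force oracles --------------------------------------

#' Brute-force AWF transition table
#'
#' Exhaustive enumeration over all `N^n` parent assignments of `n` children,
#' weighting each assignment by `prod eta[parents]`. Independent of the
#' distinct-index formula; used as the oracle in tests and fixtures.
#'
#' @param outcomes finite outcome list `list(list(value = eta, prob), ...)`.
#' @param n sample size (small: cost is `N^n` per outcome).
#' @return named probability vector over compact partition strings.
#' @export
brute_force_awf_table <- function(outcomes, n) {
  keys <- vapply(all_partitions(n), format_partition, character(1))
  probs <- stats::setNames(numeric(length(keys)), keys)
  for (o in outcomes) {
    eta <- o$value
    grid <- as.matrix(expand.grid(rep(list(seq_along(eta)), n)))
    for (g in seq_len(nrow(grid))) {
      parents <- grid[g, ]
      w <- prod(eta[parents])
      if (w > 0) {
        key <- format_partition(group_by_label(parents))
        probs[key] <- probs[key] + o$prob * w
      }
    }
  }
  probs
}

#' Brute-force AC transition table
#'
#' Exhaustive enumeration over all ordered without-replacement samples of
#' `n` child slots from the `sum(xi)` slots labeled by parent; each ordered
#' sample has probability `1 / (sum(xi))_n`.
#'
#' @param outcomes finite outcome list `list(list(value = xi, prob), ...)`.
#' @param n sample size (small: cost is `(sum(xi))_n` per outcome).
#' @return named probability vector over compact partition strings.
#' @export
brute_force_ac_table <- function(outcomes, n) {
  keys <- vapply(all_partitions(n), format_partition, character(1))
  probs <- stats::setNames(numeric(length(keys)), keys)
  for (o in outcomes) {
    slots <- rep.int(seq_along(o$value), o$value)
    S <- length(slots)
    if (S < n) stop("sum(xi) < n in brute-force enumeration")
    w <- o$prob / prod(S - seq_len(n) + 1)
    rec <- function(chosen) {
      if (length(chosen) == n) {
        key <- format_partition(group_by_label(slots[chosen]))
        probs[key] <<- probs[key] + w
        return(invisible())
      }
      for (s in setdiff(seq_len(S), chosen)) rec(c(chosen, s))
    }
    rec(integer(0))
  }
  probs
}

#' Deterministic oracle fixtures
#'
#' Small frequency/offspring vectors with exhaustively enumerable outcome
#' spaces (all with `N <= 5`, `n <= 4`) and their brute-force transition
#' tables, computed at call time with no randomness. Used to pin down the
#' exact transition-probability formulas.
#'
#' @return named list of fixtures: `name`, `type` ("awf" or "ac"),
#'   `outcomes`, `n`, `expected` (brute-force table).
#' @export
generate_fixtures <- function() {
  # multinomial(4, uniform on 4) offspring law: enumerate 4^4 assignments
  grid <- as.matrix(expand.grid(rep(list(1:4), 4)))
  xi_keys <- apply(grid, 1L, function(g) paste(tabulate(g, nbins = 4L), collapse = ","))
  xi_tab <- table(xi_keys) / nrow(grid)
  multinom_outcomes <- lapply(names(xi_tab), function(k) {
    list(value = as.integer(strsplit(k, ",")[[1L]]), prob = as.numeric(xi_tab[[k]]))
  })

  fixtures <- list(
    uniform4 = list(type = "awf", n = 3L,
                    outcomes = list(list(value = rep(0.25, 4), prob = 1))),
    delta = list(type = "awf", n = 3L,
                 outcomes = list(list(value = c(1, 0, 0, 0), prob = 1))),
    `half-half` = list(type = "awf", n = 3L,
                       outcomes = list(list(value = c(0.5, 0.5), prob = 1))),
    `xi-two-zero` = list(type = "ac", n = 2L,
                         outcomes = list(list(value = c(2L, 0L), prob = 1))),
    `multinomial4` = list(type = "ac", n = 2L, outcomes = multinom_outcomes)
  )
  for (nm in names(fixtures)) {
    f <- fixtures[[nm]]
    f$name <- nm
    f$expected <- if (f$type == "awf") {
      brute_force_awf_table(f$outcomes, f$n)
    } else {
      brute_force_ac_table(f$outcomes, f$n)
    }
    fixtures[[nm]] <- f
  }
  fixtures
}
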