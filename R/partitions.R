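# Canonical set partitions of [n], the coagulation operator, and paint-box
# sampling of exchangeable partitions from a mass partition.

#' Set partition of \{1, ..., n\}
#'
#' Constructs a canonical set partition: blocks are disjoint non-empty integer
#' sets covering `1:n`, each block sorted increasingly, and blocks ordered by
#' their least elements. All labels are 1-based.
#'
#' @param blocks list of integer vectors, the blocks.
#' @param n ground-set size; defaults to the largest member found.
#' @return An object of class `"partition"` with fields `blocks` and `n`.
#' @examples
#' partition(list(c(3, 1), 2))
#' @export
partition <- function(blocks, n = NULL) {
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  members <- unlist(blocks)
  if (is.null(n)) n <- if (length(members)) max(members) else 0L
  n <- as.integer(n)
  if (n < 1L) stop("partition requires n >= 1")
  if (length(members) != n || anyDuplicated(members) > 0L ||
      min(members) < 1L || max(members) > n) {
    stop("blocks must be disjoint non-empty sets covering 1:", n)
  }
  blocks <- blocks[order(vapply(blocks, function(b) b[[1L]], integer(1)))]
  structure(list(blocks = blocks, n = n), class = "partition")
}

#' Partition of singletons 0_n
#' @param n ground-set size.
#' @export
singleton_partition <- function(n) {
  partition(as.list(seq_len(n)), n)
}

#' Single-block partition \{\{1,...,n\}\}
#' @param n ground-set size.
#' @export
one_block_partition <- function(n) {
  partition(list(seq_len(n)), n)
}

#' Block sizes, ordered by the blocks' least elements
#' @param pi a `partition`.
#' @export
block_sizes <- function(pi) {
  vapply(pi$blocks, length, integer(1))
}

#' Number of blocks
#' @param pi a `partition`.
#' @export
n_blocks <- function(pi) length(pi$blocks)

is_partition <- function(x) inherits(x, "partition")

#' @export
print.partition <- function(x, ...) {
  cat("partition of [", x$n, "]: ", format_partition(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.partition <- function(x, ...) format_partition(x)

#' Compact string form of a partition
#'
#' Blocks are joined by `|`, members by `,`, e.g. `"1,3|2"`. This is the form
#' used in JSON-lines trace files.
#'
#' @param pi a `partition`.
#' @export
format_partition <- function(pi) {
  paste(vapply(pi$blocks, function(b) paste(b, collapse = ","), character(1)),
        collapse = "|")
}

#' Parse the compact string form back into a partition
#' @param x a string such as `"1,3|2"`.
#' @param n ground-set size (optional; inferred from the labels otherwise).
#' @export
parse_partition <- function(x, n = NULL) {
  blocks <- lapply(strsplit(x, "|", fixed = TRUE)[[1L]],
                   function(b) as.integer(strsplit(b, ",", fixed = TRUE)[[1L]]))
  partition(blocks, n)
}

#' Test two partitions for equality (same canonical block lists)
#' @param a,b partitions.
#' @export
partitions_equal <- function(a, b) {
  a$n == b$n && identical(lapply(a$blocks, as.integer), lapply(b$blocks, as.integer))
}

#' Group indices by a label vector
#'
#' Children `1:length(labels)` sharing a label form a block; this is how
#' one-generation coagulation increments arise from parent assignments.
#'
#' @param labels vector of group labels, one per individual.
#' @export
group_by_label <- function(labels) {
  partition(unname(split(seq_along(labels), labels)), length(labels))
}

#' Coagulation operator
#'
#' Merges the blocks of `pi` according to `pi_prime`: the k-th block of the
#' result is the union of the blocks of `pi` whose indices lie in the k-th
#' block of `pi_prime` (indices beyond `|pi|` are dropped). The pair is
#' admissible when `pi` has at most `pi_prime$n` blocks. The result is
#' re-canonicalized by least elements.
#'
#' @param pi a `partition` of `[n]`.
#' @param pi_prime a `partition` of `[m]` with `m >= n_blocks(pi)`.
#' @return A `partition` of `[n]`.
#' @examples
#' coagulate(partition(list(c(1, 3), 2)), partition(list(c(1, 2))))
#' @export
coagulate <- function(pi, pi_prime) {
  k <- n_blocks(pi)
  if (k > pi_prime$n) {
    stop("inadmissible pair: first partition has ", k,
         " blocks but the coagulator is a partition of [", pi_prime$n, "]")
  }
  new_blocks <- list()
  for (idx in pi_prime$blocks) {
    idx <- idx[idx <= k]
    if (length(idx)) new_blocks[[length(new_blocks) + 1L]] <- unlist(pi$blocks[idx])
  }
  partition(new_blocks, pi$n)
}

#' Restriction of a partition to \{1, ..., m\}
#' @param pi a `partition`.
#' @param m new ground-set size, `m <= pi$n`.
#' @export
restrict_partition <- function(pi, m) {
  m <- as.integer(m)
  if (m > pi$n) stop("cannot restrict a partition of [", pi$n, "] to [", m, "]")
  blocks <- lapply(pi$blocks, function(b) b[b <= m])
  partition(Filter(length, blocks), m)
}

# ---- mass partitions --------------------------------------------------------

#' Mass partition (ranked frequencies with dust)
#'
#' A finite non-increasing sequence of reals in (0, 1] together with the dust
#' mass `rho_0 = 1 - sum(parts)`. The sum constraint is enforced to 1e-12
#' absolute; inputs violating it are rejected rather than silently
#' renormalized.
#'
#' @param parts numeric vector of interval lengths, non-increasing, in (0, 1].
#'   Zeros are dropped.
#' @param dust dust mass in \[0, 1\]; defaults to `1 - sum(parts)`.
#' @return An object of class `"mass_partition"` with fields `parts`, `dust`.
#' @export
mass_partition <- function(parts, dust = NULL) {
  parts <- as.numeric(parts)
  parts <- parts[parts != 0]
  if (any(parts < 0) || any(parts > 1)) stop("mass partition parts must lie in (0, 1]")
  if (is.unsorted(rev(parts))) stop("mass partition parts must be non-increasing")
  if (is.null(dust)) dust <- 1 - sum(parts)
  if (dust < -1e-12 || abs(sum(parts) + dust - 1) > 1e-12) {
    stop("mass partition parts and dust must sum to 1 (tolerance 1e-12); got sum ",
         format(sum(parts) + dust, digits = 17))
  }
  structure(list(parts = parts, dust = max(dust, 0)), class = "mass_partition")
}

#' @export
print.mass_partition <- function(x, ...) {
  cat("mass partition: (", paste(signif(x$parts, 6), collapse = ", "),
      "); dust ", signif(x$dust, 6), "\n", sep = "")
  invisible(x)
}

#' Paint-box sample of an exchangeable partition
#'
#' Assigns `n` i.i.d. uniforms to consecutive half-open intervals
#' `[sum(parts[1:(k-1)]), sum(parts[1:k]))` of lengths `rho_1, rho_2, ...`;
#' indices in the same interval form a block, and indices landing in the
#' terminal dust interval `[1 - rho_0, 1)` become singletons.
#'
#' @param rho a `mass_partition`.
#' @param n sample size.
#' @return A `partition` of `[n]`.
#' @export
paintbox_sample <- function(rho, n) {
  n <- as.integer(n)
  if (n < 1L) stop("paintbox_sample requires n >= 1")
  u <- stats::runif(n)
  cuts <- cumsum(rho$parts)
  k <- length(cuts)
  idx <- findInterval(u, cuts) + 1L  # half-open [cum_{k-1}, cum_k)
  dust <- idx > k
  if (any(dust)) idx[dust] <- k + seq_len(sum(dust))  # dust: all singletons
  group_by_label(idx)
}

#' Exact paint-box probability of a given partition
#'
#' Probability that the paint-box directed by `rho` produces the partition
#' `pi` of `[n]`: non-singleton blocks are assigned to distinct intervals
#' (factor `rho_i^{|block|}`), while singleton blocks may occupy a distinct
#' unused interval or fall into dust. Exact enumeration; intended for small
#' numbers of blocks/intervals.
#'
#' @param rho a `mass_partition`.
#' @param pi a `partition`.
#' @export
paintbox_prob <- function(rho, pi) {
  sizes <- block_sizes(pi)
  big <- sizes[sizes >= 2L]
  s <- sum(sizes == 1L)
  p <- rho$parts
  p0 <- rho$dust
  K <- length(p)

  singleton_factor <- function(used) {
    avail <- p[!used]
    # elementary symmetric polynomials of the unused interval lengths
    ej <- 1
    for (x in avail) ej <- c(ej, 0) + c(0, ej * x)
    jmax <- min(s, length(avail))
    g <- 0
    for (j in 0:jmax) {
      g <- g + choose(s, j) * factorial(j) * ej[j + 1L] * p0^(s - j)
    }
    g
  }

  rec <- function(bi, used) {
    if (bi > length(big)) return(singleton_factor(used))
    acc <- 0
    for (i in seq_len(K)) {
      if (!used[i]) {
        used[i] <- TRUE
        acc <- acc + p[i]^big[bi] * rec(bi + 1L, used)
        used[i] <- FALSE
      }
    }
    acc
  }

  if (length(big) > K) return(0)
  rec(1L, rep(FALSE, K))
}

# ---- enumeration of partitions ---------------------------------------------

.partition_cache <- new.env(parent = emptyenv())

#' Enumerate all set partitions of \{1, ..., n\}
#'
#' Restricted-growth-string enumeration; results are cached per `n`.
#'
#' @param n ground-set size (small; the count is the Bell number).
#' @return List of `partition` objects; the first element is `0_n`.
#' @export
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  rgs <- list(integer(0))
  res <- list()
  gen <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- group_by_label(prefix)
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      gen(c(prefix, lab), max(maxlab, lab))
    }
  }
  gen(integer(0), 0L)
  # put 0_n first, then by decreasing block count for readability
  nb <- vapply(res, n_blocks, integer(1))
  res <- res[order(-nb)]
  .partition_cache[[key]] <- res
  res
}

#' Is a partition the single-pair-merge type?
#'
#' TRUE when exactly one block has size 2 and all others are singletons.
#' @param pi a `partition`.
#' @export
is_pair_merge <- function(pi) {
  sz <- block_sizes(pi)
  sum(sz == 2L) == 1L && all(sz <= 2L)
}

# set partitions of 1:j as lists of integer vectors (for the
# augmented-monomial expansion of distinct-index sums); cached
.setpart_cache <- new.env(parent = emptyenv())

set_partitions_idx <- function(j) {
  key <- as.character(j)
  if (!is.null(.setpart_cache[[key]])) return(.setpart_cache[[key]])
  out <- lapply(all_partitions(j), function(p) p$blocks)
  .setpart_cache[[key]] <- out
  out
}

#' Sum over distinct indices of products of per-block functions
#'
#' Computes `sum over distinct i_1, ..., i_j of prod_k F[i_k, k]` by the
#' augmented-monomial (inclusion-exclusion) expansion over set partitions of
#' the block indices, with Moebius weight `prod_B (-1)^{|B|-1} (|B|-1)!`.
#' Cost is Bell(j) * N; exact for any column functions, e.g. powers
#' `eta_i^{b_k}` or falling factorials `(xi_i)_{b_k}`.
#'
#' @param F numeric matrix, N rows (population indices) by j columns (blocks).
#' @export
sum_distinct_products <- function(F) {
  j <- ncol(F)
  if (j == 1L) return(sum(F[, 1L]))
  tot <- 0
  for (sigma in set_partitions_idx(j)) {
    term <- 1
    for (B in sigma) {
      v <- F[, B[1L]]
      for (k in B[-1L]) v <- v * F[, k]
      w <- if (length(B) > 1L) (-1)^(length(B) - 1L) * factorial(length(B) - 1L) else 1
      term <- term * w * sum(v)
    }
    tot <- tot + term
  }
  tot
}
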