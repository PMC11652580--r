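# Time-indexed coagulation traces and their serializations.

#' Genealogy trace
#'
#' A time-indexed sequence of partitions with the coagulation increments that
#' produced them: `partitions[[t]] = coagulate(partitions[[t-1]],
#' increments[[t]])` and `partitions[[1]]` is the singleton partition. Only
#' steps at which a coagulation occurs are recorded (identity increments are
#' skipped), so replaying `increments` through `coagulate` reproduces
#' `partitions` exactly.
#'
#' @param n sample size.
#' @param times non-decreasing numeric event times (generations, rescaled
#'   time, or coalescent time).
#' @param partitions list of `partition` objects of `[n]`.
#' @param increments list of `partition` objects; `increments[[t]]` is the
#'   partition of block indices applied at step `t` (the first entry is a
#'   placeholder singleton partition for the initial state).
#' @param time_scale label: "generations", "rescaled" or "coalescent".
#' @param generations total number of forward generations simulated (optional).
#' @export
genealogy_trace <- function(n, times, partitions, increments,
                            time_scale = "generations", generations = NULL) {
  stopifnot(length(times) == length(partitions),
            length(times) == length(increments),
            !is.unsorted(times))
  structure(list(n = n, times = times, partitions = partitions,
                 increments = increments, time_scale = time_scale,
                 generations = generations),
            class = "genealogy_trace")
}

#' @export
print.genealogy_trace <- function(x, ...) {
  cat("genealogy trace: n = ", x$n, ", ", length(x$times) - 1L,
      " coagulation events, time scale '", x$time_scale, "'\n", sep = "")
  last <- x$partitions[[length(x$partitions)]]
  cat("  final state: ", format_partition(last),
      if (n_blocks(last) == 1L) "  (MRCA reached)" else "", "\n", sep = "")
  invisible(x)
}

#' Has the trace reached its most recent common ancestor?
#' @param trace a `genealogy_trace`.
#' @export
reached_mrca <- function(trace) {
  n_blocks(trace$partitions[[length(trace$partitions)]]) == 1L
}

#' Time of the most recent common ancestor
#' @param trace a `genealogy_trace`.
#' @return The time of the final coagulation, or `NA` if the MRCA was not
#'   reached within the horizon.
#' @export
mrca_time <- function(trace) {
  if (!reached_mrca(trace)) return(NA_real_)
  trace$times[[length(trace$times)]]
}

#' Newick string of a genealogy trace
#'
#' Branch lengths are inter-coalescence times in the trace's time scale. If
#' several lineages remain at the end of the trace (MRCA not reached), they
#' are joined at the final recorded time into an artificial root so that the
#' output is always a single tree.
#'
#' @param trace a `genealogy_trace`.
#' @export
trace_to_newick <- function(trace) {
  n <- trace$n
  labs <- as.character(seq_len(n))
  heights <- rep(0, n)       # per current block: time of its subtree root
  # current blocks tracked implicitly through the trace partitions
  for (t in seq_along(trace$times)[-1L]) {
    inc <- trace$increments[[t]]
    tt <- trace$times[[t]]
    new_labs <- character(0)
    new_heights <- numeric(0)
    for (idx in inc$blocks) {
      idx <- idx[idx <= length(labs)]
      if (!length(idx)) next
      if (length(idx) == 1L) {
        new_labs <- c(new_labs, labs[idx])
        new_heights <- c(new_heights, heights[idx])
      } else {
        child <- paste0(labs[idx], ":", format(tt - heights[idx], digits = 12),
                        collapse = ",")
        new_labs <- c(new_labs, paste0("(", child, ")"))
        new_heights <- c(new_heights, tt)
      }
    }
    # re-canonicalize order to match coagulate()'s least-element ordering:
    # coagulate() sorts blocks by least element, and inc$blocks are already in
    # that order relative to the previous block order, so new_labs align.
    labs <- new_labs
    heights <- new_heights
  }
  if (length(labs) > 1L) {
    tt <- trace$times[[length(trace$times)]]
    labs <- paste0("(", paste0(labs, ":", format(tt - heights, digits = 12),
                               collapse = ","), ")")
  }
  paste0(labs, ";")
}

#' Write a genealogy trace as JSON lines
#'
#' One record per recorded step: `time`, `partition` (compact string) and
#' `increment`. A first header-free record at time 0 carries the singleton
#' state.
#'
#' @param trace a `genealogy_trace`.
#' @param path output file.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (t in seq_along(trace$times)) {
    rec <- list(time = trace$times[[t]],
                partition = format_partition(trace$partitions[[t]]),
                increment = format_partition(trace$increments[[t]]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON-lines trace back
#' @param path file written by [write_trace_jsonl()].
#' @param time_scale label to attach.
#' @export
read_trace_jsonl <- function(path, time_scale = "generations") {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  n <- max(as.integer(strsplit(gsub("\\|", ",", recs[[1L]]$partition), ",")[[1L]]))
  genealogy_trace(
    n = n,
    times = vapply(recs, `[[`, numeric(1), "time"),
    partitions = lapply(recs, function(r) parse_partition(r$partition, n)),
    increments = lapply(recs, function(r) parse_partition(r$increment)),
    time_scale = time_scale
  )
}
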