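#' Benchmark retrieval schemes on one offset array
#'
#' Follows the retrieval benchmarking protocol: per trial, draw fresh
#' query indices uniformly over the space of adjacent-pair queries
#' (`0 .. n - 2`), visit the schemes in a freshly randomized order, and
#' retrieve the adjacent offset pair for every query while folding both
#' values into a 64-bit additive checksum. Trials are summarized by the
#' median time; the median loop overhead (iterating the query stream and
#' checksumming indices without any decoding) is subtracted. Checksums
#' must agree across all schemes — a mismatch signals an inconsistent
#' codec. Space is deterministic and reported exactly; times are
#' hardware-dependent and reported, never asserted.
#'
#' @param offsets numeric monotone offset array (e.g. from a hash table
#'   or [random_offsets()]).
#' @param schemes compression schemes to benchmark; `"uncompressed"`
#'   reads the raw array.
#' @param n_queries queries per trial.
#' @param trials number of trials (median-summarized).
#' @param seed RNG seed for query generation and scheme order.
#' @param onepass use one-pass pair retrieval for the bitpacked schemes.
#' @return a data.frame of class `bp_benchmark` with columns `scheme`,
#'   `bytes`, `ns_per_query_median`, `trials`, `n_queries`, `checksum`.
#' @export
run_benchmark <- function(offsets,
                          schemes = c("uncompressed", .SCHEMES),
                          n_queries = 1e5, trials = 3, seed = 1,
                          onepass = TRUE) {
  offsets <- check_u32(offsets, "offsets")
  n <- length(offsets)
  if (n < 2) op_stop("need at least 2 offsets to query pairs", "bad_parameter")
  schemes <- match.arg(schemes, c("uncompressed", .SCHEMES), several.ok = TRUE)
  vecs <- lapply(setdiff(schemes, "uncompressed"),
                 function(s) compress_offsets(offsets, s))
  names(vecs) <- setdiff(schemes, "uncompressed")
  times <- matrix(NA_real_, nrow = trials, ncol = length(schemes),
                  dimnames = list(NULL, schemes))
  overhead <- numeric(trials)
  checksums <- matrix(NA_character_, nrow = trials, ncol = length(schemes),
                      dimnames = list(NULL, schemes))
  with_seed(seed, {
    for (t in seq_len(trials)) {
      idx <- floor(runif(n_queries, 0, n - 1))  # query space excludes the last index
      overhead[t] <- system.time(cpp_overhead_checksum(idx))[["elapsed"]]
      for (s in sample(schemes)) {  # randomized scheme order per trial
        if (s == "uncompressed") {
          tm <- system.time(ck <- cpp_uncompressed_pair_checksum(offsets, idx))
        } else {
          v <- vecs[[s]]
          tm <- system.time(
            ck <- cpp_pair_checksum(v$words, v$meta$pointer, v$meta$prefix_sum,
                                    scheme_id(v$scheme), v$n, idx, onepass)
          )
        }
        times[t, s] <- tm[["elapsed"]]
        checksums[t, s] <- ck
      }
      if (length(unique(checksums[t, ])) != 1)
        op_stop("inconsistent codec: checksum mismatch across schemes",
                "inconsistent_codec")
    }
  })
  med <- apply(times, 2, median) - median(overhead)
  bytes <- vapply(schemes, function(s) {
    if (s == "uncompressed") storage_size_bytes("uncompressed", n = n)
    else storage_size_bytes(vecs[[s]])
  }, numeric(1))
  out <- data.frame(
    scheme = schemes,
    bytes = unname(bytes),
    ns_per_query_median = pmax(unname(med), 0) / n_queries * 1e9,
    trials = trials,
    n_queries = n_queries,
    checksum = checksums[1, schemes],
    row.names = NULL
  )
  class(out) <- c("bp_benchmark", "data.frame")
  out
}

#' @export
print.bp_benchmark <- function(x, ...) {
  cat(sprintf("pair-retrieval benchmark: %g queries x %d trials (median, overhead-subtracted)\n",
              x$n_queries[1], x$trials[1]))
  tab <- data.frame(
    scheme = format(x$scheme, width = 12),
    bytes = format(x$bytes, big.mark = ",", width = 12),
    `ns/query` = format(round(x$ns_per_query_median, 1), width = 9),
    checksum = x$checksum,
    check.names = FALSE
  )
  print.data.frame(tab, row.names = FALSE)
  cat("checksums agree across schemes\n")
  invisible(x)
}

#' Write a benchmark report as CSV
#'
#' @param x a `bp_benchmark` data.frame from [run_benchmark()].
#' @param path output CSV path.
#' @export
write_benchmark_csv <- function(x, path) {
  stopifnot(inherits(x, "bp_benchmark"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
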