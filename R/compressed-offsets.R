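.SCHEMES <- c("bp64v", "bp64c", "bp32c", "gamma", "delta", "fibonacci")

scheme_id <- function(scheme) {
  scheme <- match.arg(scheme, .SCHEMES)
  match(scheme, .SCHEMES) - 1L
}

scheme_block_size <- function(scheme) if (scheme == "bp32c") 32L else 64L
scheme_is_packed <- function(scheme) scheme %in% c("bp64v", "bp64c", "bp32c")

#' Compress a monotone offset array for random access
#'
#' Splits the offset array into blocks of `B` values (64, or 32 for
#' `bp32c`), difference-transforms each block, and appends its packed
#' differences to a bitstream. A metainformation array stores, for every
#' block, a pointer to its start in the bitstream and the block's
#' beginning prefix sum (its first value); one sentinel entry past the
#' last block supplies the ending prefix sum that the bidirectional
#' scheme needs. A final partial block is padded by repeating the last
#' offset; padded values are never exposed by lookups.
#'
#' For the bitpacked schemes the pointer is in 128-bit vector units, so
#' the block's bit width is recoverable implicitly as
#' `2 * (pointer[b+1] - pointer[b]) * (64 / B)`; for the universal-code
#' schemes it is a bit offset.
#'
#' @param offsets numeric vector of monotone nondecreasing values in
#'   `[0, 2^32)` (e.g. the offset array of a [build_hash_table()] result).
#' @param scheme `"bp64v"` (vertical layout, unidirectional differences),
#'   `"bp64c"` (columnar, bidirectional), `"bp32c"` (columnar,
#'   bidirectional, block size 32), or `"gamma"`, `"delta"`,
#'   `"fibonacci"` (universal codes at block size 64).
#' @param k oligomer length the offsets came from, if any (recorded in the
#'   container and its file header).
#' @return an object of class `compressed_offsets`.
#' @examples
#' o <- cumsum(c(0, rbinom(200, 5, 0.3)))
#' v <- compress_offsets(o, "bp64c")
#' all(decompress_offsets(v) == o)
#' @export
compress_offsets <- function(offsets, scheme = c("bp64c", "bp64v", "bp32c",
                                                 "gamma", "delta", "fibonacci"),
                             k = NULL) {
  scheme <- match.arg(scheme)
  offsets <- check_u32(offsets, "offsets")
  if (length(offsets) < 1) op_stop("offsets must be non-empty", "bad_parameter")
  if (is.unsorted(offsets))
    op_stop("negative difference: offsets must be monotone nondecreasing",
            "negative_difference")
  res <- cpp_compress(offsets, scheme_id(scheme))
  structure(
    list(scheme = scheme, block_size = scheme_block_size(scheme),
         n = length(offsets), k = if (is.null(k)) NA_integer_ else as.integer(k),
         words = res$words,
         meta = list(pointer = res$ptr, prefix_sum = res$prefix),
         widths = res$widths),
    class = "compressed_offsets"
  )
}

#' @export
print.compressed_offsets <- function(x, ...) {
  cat(sprintf("compressed offset array: scheme %s, n = %d values, %d blocks of %d\n",
              x$scheme, x$n, length(x$widths), x$block_size))
  cat(sprintf("  bitstream: %d words; meta: %d entries; total %s bytes (%.1f%% of uncompressed)\n",
              length(x$words), length(x$meta$pointer),
              format(storage_size_bytes(x), big.mark = ","),
              100 * storage_size_bytes(x) / (4 * x$n)))
  invisible(x)
}

check_idx <- function(i, max_excl) {
  if (!is.numeric(i) || length(i) == 0 || anyNA(i) || any(i != floor(i)) ||
      any(i < 0) || any(i >= max_excl))
    op_stop("index out of range", "index_range")
  as.numeric(i)
}

#' Random-access lookup in a compressed offset array
#'
#' Recovers `offsets[i]` (0-based `i`, vectorized). Indices at block
#' boundaries are answered from the metainformation prefix sum alone;
#' other positions dispatch to the scheme's random-access block decoder.
#'
#' @param v a `compressed_offsets` object.
#' @param i 0-based indices in `[0, n)`.
#' @return numeric vector of offset values.
#' @export
lookup_offset <- function(v, i) {
  stopifnot(inherits(v, "compressed_offsets"))
  i <- check_idx(i, v$n)
  cpp_lookup_many(v$words, v$meta$pointer, v$meta$prefix_sum,
                  scheme_id(v$scheme), v$n, i)
}

#' @rdname lookup_offset
#' @return `lookup_offset_stats()` returns, for a single index, a list
#'   with `value` and the decode statistics (`group_steps`,
#'   `vector_loads`, `scalar_terms`).
#' @export
lookup_offset_stats <- function(v, i) {
  stopifnot(inherits(v, "compressed_offsets"))
  i <- check_idx(i, v$n)
  stopifnot(length(i) == 1)
  cpp_lookup_stats(v$words, v$meta$pointer, v$meta$prefix_sum,
                   scheme_id(v$scheme), v$n, i)
}

#' Retrieve two adjacent offsets
#'
#' The pair `(offsets[i], offsets[i+1])` delimits the positions list of
#' k-mer `i`. The two-pass implementation makes two independent decode
#' calls. The one-pass implementation returns identical values but merges
#' the two decodes: in the cyclic difference schemes adjacent values sit
#' in neighboring columns (column 3 wrapping to column 0), so vectors
#' already loaded for the first column are reused — its vector-load count
#' never exceeds, and usually undercuts, the two-pass total. When `i + 1`
#' falls on a block boundary the second value is read from the
#' metainformation array alone.
#'
#' @param v a `compressed_offsets` object.
#' @param i 0-based indices in `[0, n - 1)` (vectorized).
#' @return list with numeric vectors `first` and `second`.
#' @export
lookup_pair_twopass <- function(v, i) lookup_pair(v, i, onepass = FALSE)

#' @rdname lookup_pair_twopass
#' @export
lookup_pair_onepass <- function(v, i) lookup_pair(v, i, onepass = TRUE)

lookup_pair <- function(v, i, onepass) {
  stopifnot(inherits(v, "compressed_offsets"))
  i <- check_idx(i, v$n - 1)
  cpp_pair_many(v$words, v$meta$pointer, v$meta$prefix_sum,
                scheme_id(v$scheme), v$n, i, onepass)
}

#' @rdname lookup_pair_twopass
#' @return `lookup_pair_stats()` returns, for a single index, `first`,
#'   `second`, and the combined `vector_loads` and `group_steps` of the
#'   chosen implementation.
#' @param onepass use the merged one-pass procedure.
#' @export
lookup_pair_stats <- function(v, i, onepass = TRUE) {
  stopifnot(inherits(v, "compressed_offsets"))
  i <- check_idx(i, v$n - 1)
  stopifnot(length(i) == 1)
  cpp_pair_stats(v$words, v$meta$pointer, v$meta$prefix_sum,
                 scheme_id(v$scheme), v$n, i, onepass)
}

#' Decompress the full offset array
#'
#' @param v a `compressed_offsets` object.
#' @return numeric vector equal to the array passed to
#'   [compress_offsets()].
#' @export
decompress_offsets <- function(v) {
  stopifnot(inherits(v, "compressed_offsets"))
  lookup_offset(v, seq_len(v$n) - 1)
}

#' Storage accounting
#'
#' For a `compressed_offsets` object: bitstream words at 4 bytes each plus
#' metainformation entries at 8 bytes (pointer + prefix sum). For the
#' uncompressed representation: 4 bytes per entry — `4 * 4^k` for the
#' offset array of a k-mer table (the accounting under which a 15-mer
#' table needs 4 GB), or `4 * n` for an arbitrary array of length `n`.
#'
#' @param x a `compressed_offsets` object, or `"uncompressed"` with `k`
#'   or `n` supplied.
#' @param k oligomer length (uncompressed accounting `4 * 4^k`).
#' @param n array length (uncompressed accounting `4 * n`).
#' @return size in bytes.
#' @examples
#' storage_size_bytes("uncompressed", k = 15) / 2^30  # 4 GB
#' @export
storage_size_bytes <- function(x, k = NULL, n = NULL) {
  if (inherits(x, "compressed_offsets"))
    return(4 * length(x$words) + 8 * length(x$meta$pointer))
  if (identical(x, "uncompressed")) {
    if (!is.null(k)) return(4 * 4^k)
    if (!is.null(n)) return(4 * n)
    op_stop("supply k or n for the uncompressed size", "bad_parameter")
  }
  op_stop("x must be a compressed_offsets object or \"uncompressed\"",
          "bad_parameter")
}

#' Per-block inspection dump
#'
#' `inspect_blocks()` tabulates each block's bitstream pointer, bit width
#' (implicit from pointer differences for bitpacked schemes; `NA` for
#' universal codes), and beginning prefix sum. `dump_blocks()` writes the
#' table as plain text for debugging.
#'
#' @param v a `compressed_offsets` object.
#' @param file connection or path for the text dump (default: stdout).
#' @return data.frame with columns `block`, `pointer`, `width`,
#'   `prefix_sum`.
#' @export
inspect_blocks <- function(v) {
  stopifnot(inherits(v, "compressed_offsets"))
  nb <- length(v$widths)
  data.frame(
    block = seq_len(nb) - 1L,
    pointer = v$meta$pointer[seq_len(nb)],
    width = v$widths,
    prefix_sum = v$meta$prefix_sum[seq_len(nb)]
  )
}

#' @rdname inspect_blocks
#' @export
dump_blocks <- function(v, file = "") {
  tab <- inspect_blocks(v)
  hdr <- sprintf("# scheme %s  n %d  block_size %d  blocks %d",
                 v$scheme, v$n, v$block_size, nrow(tab))
  lines <- c(hdr, sprintf("%-8s %-10s %-6s %s", "block", "pointer", "width",
                          "prefix_sum"),
             sprintf("%-8d %-10.0f %-6s %.0f", tab$block, tab$pointer,
                     ifelse(is.na(tab$width), "-", tab$width), tab$prefix_sum))
  if (identical(file, "")) cat(lines, sep = "\n") else writeLines(lines, con = file)
  invisible(tab)
}
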