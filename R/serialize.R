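#' Serialize a compressed offset array to a container file
#'
#' The "BPOF" container holds, in little-endian order: a 4-byte magic
#' `BPOF`; unsigned 32-bit header words (format version, scheme id, block
#' size, `n`, `k` or `0xFFFFFFFF` when unknown, number of meta entries,
#' number of bitstream words); the metainformation pointers as unsigned
#' 64-bit values; the metainformation prefix sums as unsigned 32-bit
#' values; and the bitstream words. `read_bpof()` restores a bit-exact
#' copy that answers lookups identically.
#'
#' @param v a `compressed_offsets` object.
#' @param path file path.
#' @return `write_bpof()` returns `path` invisibly; `read_bpof()` returns
#'   the `compressed_offsets` object.
#' @export
write_bpof <- function(v, path) {
  stopifnot(inherits(v, "compressed_offsets"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BPOF"), con)
  kfield <- if (is.na(v$k)) 2^32 - 1 else v$k
  write_u32(con, c(1, scheme_id(v$scheme), v$block_size, v$n, kfield,
                   length(v$meta$pointer), length(v$words)))
  ptr <- v$meta$pointer
  write_u32(con, ptr %% 2^32)          # pointer low words
  write_u32(con, ptr %/% 2^32)         # pointer high words
  write_u32(con, v$meta$prefix_sum)
  writeBin(v$words, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_bpof
#' @export
read_bpof <- function(path) {
  if (!file.exists(path)) op_stop(paste("no such file:", path), "bad_parameter")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4 || !identical(rawToChar(magic), "BPOF"))
    op_stop("unrecognized file: bad magic", "unrecognized_file")
  hdr <- read_u32(con, 7)
  if (hdr[1] != 1)
    op_stop(sprintf("unrecognized file: unsupported version %d", hdr[1]),
            "unrecognized_file")
  if (hdr[2] >= length(.SCHEMES))
    op_stop("unrecognized file: unknown scheme id", "unrecognized_file")
  scheme <- .SCHEMES[hdr[2] + 1]
  n_meta <- hdr[6]
  n_words <- hdr[7]
  ptr_lo <- read_u32(con, n_meta)
  ptr_hi <- read_u32(con, n_meta)
  prefix <- read_u32(con, n_meta)
  words <- readBin(con, "integer", n = n_words, size = 4L, endian = "little")
  if (length(words) < n_words) op_stop("truncated file", "corrupt_container")
  v <- structure(
    list(scheme = scheme, block_size = as.integer(hdr[3]), n = hdr[4],
         k = if (hdr[5] == 2^32 - 1) NA_integer_ else as.integer(hdr[5]),
         words = words,
         meta = list(pointer = ptr_hi * 2^32 + ptr_lo, prefix_sum = prefix),
         widths = NULL),
    class = "compressed_offsets"
  )
  v$widths <- recover_widths(v)
  v
}

# Implicit bit widths from successive pointer values (bitpacked schemes).
recover_widths <- function(v) {
  nb <- length(v$meta$pointer) - 1L
  if (!scheme_is_packed(v$scheme)) return(rep(NA_integer_, nb))
  as.integer(diff(v$meta$pointer) * 128 / v$block_size)
}
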