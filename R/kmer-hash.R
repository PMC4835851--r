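#' Encode k-mers as base-4 integer codes
#'
#' Maps a DNA k-mer over `{A, C, G, T}` to its integer code in
#' `[0, 4^k)`, with `A = 0`, `C = 1`, `G = 2`, `T = 3` and the leftmost
#' base most significant, so codes enumerate k-mers in lexicographic order.
#' Input is upper-cased first.
#'
#' @param kmer character vector of k-mer strings (all the same length).
#' @return numeric vector of codes.
#' @examples
#' encode_kmer("ACGT")  # 27
#' @export
encode_kmer <- function(kmer) {
  if (!is.character(kmer) || length(kmer) == 0)
    op_stop("kmer must be a character vector", "bad_parameter")
  codes <- cpp_encode_kmers(toupper(kmer))
  if (anyNA(codes))
    op_stop("unencodable k-mer: bases outside {A,C,G,T}", "unencodable_kmer")
  codes
}

#' Decode an integer code back to its k-mer string
#'
#' @param code numeric vector of codes in `[0, 4^k)`.
#' @param k oligomer length.
#' @return character vector of k-mers.
#' @export
decode_kmer <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  vapply(code, function(cd) {
    out <- character(k)
    for (j in k:1) {
      out[j] <- bases[cd %% 4 + 1]
      cd <- cd %/% 4
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Read a genome from a FASTA file
#'
#' Multi-record files are supported; records are returned as a named
#' character vector of upper-cased sequences. [build_hash_table()]
#' concatenates multiple records with an `N` separator so that no k-mer
#' spans a record boundary.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) op_stop(paste("no such file:", path), "bad_parameter")
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

.MAX_HASH_K <- 12L

#' Build a k-mer lookup hash table
#'
#' Scans the genome and stores every position `p` with `p %% sampling == 0`
#' whose k-mer lies fully within the sequence and contains only
#' `A`, `C`, `G`, `T` (k-mers touching any other character, such as `N`,
#' are skipped entirely). The table holds an offset array of length
#' `4^k + 1` — entry `m` points at the start of k-mer `m`'s positions,
#' entry `4^k` equals the total count — and a positions array of 0-based
#' genomic start positions grouped by k-mer code, ascending within each
#' group. Multiple sequences are concatenated with an `N` separator and
#' positions are global over the concatenation.
#'
#' @param genome a character vector of one or more DNA sequences, or a path
#'   to a FASTA file.
#' @param k oligomer length (1 to 12; the offset array has `4^k + 1`
#'   entries, so larger k cannot be allocated here).
#' @param sampling sampling interval in bp: only positions divisible by
#'   `sampling` are stored (phase anchored at coordinate 0).
#' @return an object of class `hash_table` with elements `k`, `sampling`,
#'   `offsets` and `positions`.
#' @examples
#' ht <- build_hash_table("AAAA", k = 2)
#' ht$offsets[1:3]        # 0 3 3
#' lookup_positions(ht, encode_kmer("AA"))
#' @export
build_hash_table <- function(genome, k, sampling = 1L) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k))
    op_stop("k must be a positive integer", "bad_parameter")
  if (k > .MAX_HASH_K)
    op_stop(sprintf("k too large: offset array of 4^%d + 1 entries cannot be allocated", k),
            "k_too_large")
  if (!is.numeric(sampling) || length(sampling) != 1 || sampling < 1 ||
      sampling != floor(sampling))
    op_stop("sampling must be a positive integer", "bad_parameter")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]*$", genome))
    genome <- read_genome_fasta(genome)
  if (!is.character(genome) || length(genome) < 1)
    op_stop("genome must be a character vector of sequences or a FASTA path",
            "bad_parameter")
  seq <- paste(toupper(genome), collapse = "N")
  res <- cpp_build_hash(seq, as.integer(k), as.integer(sampling))
  structure(
    list(k = as.integer(k), sampling = as.integer(sampling),
         offsets = res$offsets, positions = res$positions),
    class = "hash_table"
  )
}

#' @export
print.hash_table <- function(x, ...) {
  cat(sprintf("k-mer hash table: k = %d, sampling = %d bp\n", x$k, x$sampling))
  cat(sprintf("  offsets: %d entries (4^k + 1); positions stored: %d\n",
              length(x$offsets), length(x$positions)))
  invisible(x)
}

#' Look up the genomic positions of a k-mer
#'
#' Returns `positions[offsets[code] .. offsets[code + 1])`, the ascending
#' start positions of the k-mer with the given code; an empty vector when
#' the two adjacent offsets are equal.
#'
#' @param table a `hash_table`.
#' @param code k-mer code in `[0, 4^k)` (see [encode_kmer()]).
#' @return integer vector of 0-based positions.
#' @export
lookup_positions <- function(table, code) {
  stopifnot(inherits(table, "hash_table"))
  if (!is.numeric(code) || length(code) != 1 || is.na(code) ||
      code < 0 || code >= 4^table$k)
    op_stop("k-mer code out of range", "index_range")
  lo <- table$offsets[code + 1]
  hi <- table$offsets[code + 2]
  if (hi == lo) return(integer(0))
  table$positions[(lo + 1):hi]
}

#' Raw binary dump of an offset or positions array
#'
#' Writes values as little-endian unsigned 32-bit words with no header
#' (4 bytes per entry, matching the uncompressed storage accounting).
#'
#' @param x numeric vector of values in `[0, 2^32)`.
#' @param path output file.
#' @export
write_offsets_bin <- function(x, path) {
  x <- check_u32(x, "offsets")
  con <- file(path, "wb")
  on.exit(close(con))
  write_u32(con, x)
  invisible(path)
}

#' @rdname write_offsets_bin
#' @export
read_offsets_bin <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n %% 4 != 0) op_stop("not a raw u32 array file", "corrupt_container")
  con <- file(path, "rb")
  on.exit(close(con))
  read_u32(con, n / 4)
}
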