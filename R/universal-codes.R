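#' Universal integer codes: Elias gamma, Elias delta, Fibonacci
#'
#' Self-delimiting variable-length codes for positive integers, used as
#' compression baselines against the bitpacked formats.
#'
#' * **gamma**: a value needing `c` bits is written as `c - 1` zero bits
#'   followed by the `c` bits of the value, `2c - 1` bits in total.
#' * **delta**: the bit count `c` is gamma-coded, followed by the `c - 1`
#'   bits below the value's most significant bit.
#' * **fibonacci**: the Zeckendorf decomposition over 1, 2, 3, 5, 8, ...,
#'   emitted lowest Fibonacci number first with an appended 1, so every
#'   codeword ends in `11`.
#'
#' Zero cannot be coded directly; block encoders store `d + 1` (see
#' [encode_block_shifted()]).
#'
#' @param v a single positive integer (`>= 1`).
#' @param bits an integer vector of 0/1 code bits.
#' @return `*_encode()` return an integer vector of bits; `*_decode()`
#'   return the decoded value.
#' @examples
#' gamma_encode(1)        # single bit "1"
#' length(gamma_encode(5))  # 5: c = 3 bits, 2c - 1
#' fibonacci_encode(1)    # "11"
#' @name universal_codes
NULL

ucodec_id <- function(codec) {
  match(match.arg(codec, c("gamma", "delta", "fibonacci")),
        c("gamma", "delta", "fibonacci")) - 1L
}

ucode_encode1 <- function(v, codec) {
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v != floor(v) || v < 0)
    op_stop("v must be a nonnegative integer", "bad_parameter")
  if (v == 0)
    op_stop("0 requires shift encoding (store v + 1)", "requires_shift_encoding")
  cpp_ucode_encode(v, ucodec_id(codec))
}

ucode_decode1 <- function(bits, codec) {
  if (!is.numeric(bits) || any(!bits %in% c(0, 1)))
    op_stop("bits must be a 0/1 vector", "bad_parameter")
  cpp_ucode_decode(as.integer(bits), ucodec_id(codec))$value
}

#' @rdname universal_codes
#' @export
gamma_encode <- function(v) ucode_encode1(v, "gamma")

#' @rdname universal_codes
#' @export
gamma_decode <- function(bits) ucode_decode1(bits, "gamma")

#' @rdname universal_codes
#' @export
delta_encode <- function(v) ucode_encode1(v, "delta")

#' @rdname universal_codes
#' @export
delta_decode <- function(bits) ucode_decode1(bits, "delta")

#' @rdname universal_codes
#' @export
fibonacci_encode <- function(v) ucode_encode1(v, "fibonacci")

#' @rdname universal_codes
#' @export
fibonacci_decode <- function(bits) ucode_decode1(bits, "fibonacci")

#' Encode a block of adjacent differences with a universal code
#'
#' Stores each of the block's adjacent differences `d_i = x_{i+1} - x_i`
#' as `codec(d_i + 1)`: the subtract-1 modification lets the common
#' incremental value 0 take a short codeword (a single bit under gamma),
#' with the equivalent amount added back during decoding. The segment is
#' self-delimiting; per-block metainformation (bitstream pointer + prefix
#' sum) has the same shape as for the bitpacked formats.
#'
#' @param diffs numeric vector of nonnegative adjacent differences
#'   (conventionally 64, the baseline block size).
#' @param codec `"gamma"`, `"delta"`, or `"fibonacci"`.
#' @return an object of class `bitstream_segment` (fields `words`,
#'   `nbits`, `codec`, `block_size`).
#' @export
encode_block_shifted <- function(diffs, codec = c("gamma", "delta", "fibonacci")) {
  codec <- match.arg(codec)
  diffs <- check_u32(diffs, "diffs")
  seg <- cpp_encode_block_shifted(diffs, ucodec_id(codec))
  structure(list(words = seg$words, nbits = seg$nbits, codec = codec,
                 block_size = length(diffs)),
            class = "bitstream_segment")
}

#' @export
print.bitstream_segment <- function(x, ...) {
  cat(sprintf("%s-coded block segment: %d values in %g bits\n",
              x$codec, x$block_size, x$nbits))
  invisible(x)
}

#' Decode a value from a universal-coded block segment
#'
#' Serially decodes the first `r` codes of the segment and returns
#' `x0 + sum(decoded - 1)`, i.e. the cumulative value at block position
#' `r`.
#'
#' @param segment a `bitstream_segment` from [encode_block_shifted()].
#' @param x0 the block's beginning prefix sum.
#' @param r block position, 1..block_size.
#' @return the decoded value `x_r`.
#' @export
decode_block_at <- function(segment, x0, r) {
  stopifnot(inherits(segment, "bitstream_segment"))
  check_r(r, segment$block_size)
  tryCatch(
    cpp_decode_block_at(segment$words, segment$nbits, check_u32(x0, "x0"),
                        as.integer(r), ucodec_id(segment$codec)),
    error = function(e) op_stop(conditionMessage(e), "corrupt_code")
  )
}
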