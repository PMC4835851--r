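#' Block scheme descriptor
#'
#' Describes one block codec configuration: the packing layout, the
#' difference scheme, and the block size with its set of allowed uniform
#' bit widths. Block size 64 restricts widths to even values 0..32 (an odd
#' width saves no storage over the next even one and complicates decoding);
#' block size 32 restricts widths to multiples of 4. The shipped columnar
#' configurations use the bidirectional difference scheme and the vertical
#' configuration the unidirectional one.
#'
#' @param layout `"vertical"` or `"columnar"`.
#' @param direction `"unidirectional"` or `"bidirectional"`.
#' @param block_size 64 or 32.
#' @return an object of class `block_scheme`.
#' @export
block_scheme <- function(layout = c("vertical", "columnar"),
                         direction = c("unidirectional", "bidirectional"),
                         block_size = 64L) {
  layout <- match.arg(layout)
  direction <- match.arg(direction)
  if (!block_size %in% c(32L, 64L))
    op_stop("block_size must be 32 or 64", "bad_parameter")
  structure(
    list(layout = layout, direction = direction,
         block_size = as.integer(block_size),
         allowed_widths = allowed_widths(block_size)),
    class = "block_scheme"
  )
}

allowed_widths <- function(block_size) {
  if (block_size >= 128) 0:32 else seq(0L, 32L, by = if (block_size == 64) 2L else 4L)
}

#' @export
print.block_scheme <- function(x, ...) {
  cat(sprintf("block scheme: %s layout, %s differences, block size %d\n",
              x$layout, x$direction, x$block_size))
  cat("  allowed widths:", paste(x$allowed_widths, collapse = " "), "\n")
  invisible(x)
}

#' Select the uniform bit width for a block of differences
#'
#' The width is the smallest allowed value `w` such that every difference
#' is below `2^w`: even widths for block size 64, multiples of 4 for block
#' size 32 (and any width for 128-value BP128-style blocks, which align at
#' 128 bits regardless). A width of 0 marks the special all-zero block.
#'
#' @param diffs numeric vector of nonnegative differences (< 2^32).
#' @param block_size block size governing the allowed widths (default 64).
#' @return integer width in 0..32.
#' @examples
#' select_width(rep(0, 64))        # 0
#' select_width(c(63, rep(0, 63))) # 6
#' select_width(7, block_size = 64)  # 3 bits rounds up to 4
#' @export
select_width <- function(diffs, block_size = 64L) {
  diffs <- check_u32(diffs, "diffs")
  cpp_select_width(diffs, as.integer(block_size))
}

#' Storage size of one packed block, in 128-bit vectors
#'
#' `block_size * width / 128`; fractional for widths the block size does
#' not admit (the reason odd widths are excluded at block size 64: width 3
#' on 64 values takes 1.5 vectors, the same storage as width 4 once
#' rounded to whole registers).
#'
#' @param block_size number of values per block.
#' @param width uniform bit width, 0..32.
#' @return number of 128-bit vectors (possibly fractional).
#' @examples
#' storage_size_vectors(128, 3) # 3
#' storage_size_vectors(64, 6)  # 3
#' @export
storage_size_vectors <- function(block_size, width) {
  if (any(width < 0 | width > 32)) op_stop("width must be in 0..32", "bad_parameter")
  block_size * width / 128
}

new_diff_block <- function(diffs, x0, xB, direction, block_size) {
  structure(list(diffs = diffs, x0 = x0, xB = xB, direction = direction,
                 block_size = block_size),
            class = "diff_block")
}

#' Lane-cyclic difference transforms
#'
#' `diffs_unidirectional()` converts `block_size + 1` monotone values
#' `x_0..x_B` into the unidirectional cyclic differences used by the
#' vertical layout: `d_i = x_{i+1} - x_{i-3}`, except the first row of four
#' where differences are taken relative to the block prefix sum `x_0`.
#' Four running sums, one per vector lane, then reconstruct the values.
#'
#' `diffs_bidirectional()` encodes the first half-block the same way from
#' `x_0`, and the second half-block relative to the ending prefix sum
#' `x_B` (stored in the metainformation array as the next block's
#' beginning prefix sum), so that values in the second half are
#' reconstructed by subtracting a lane-cyclic cumulative sum from `x_B`.
#' The midpoint `x_{B/2}` is reachable from either end and agrees.
#'
#' `invert_diffs()` applies the inverse transform and recovers `x`
#' exactly.
#'
#' @param x numeric vector of `block_size + 1` monotone nondecreasing
#'   values in `[0, 2^32)`.
#' @param block_size 64 or 32.
#' @param block a `diff_block` from one of the forward transforms.
#' @return `diffs_*()` return a `diff_block` (fields `diffs`, `x0`, `xB`,
#'   `direction`, `block_size`); `invert_diffs()` returns the numeric `x`.
#' @export
diffs_unidirectional <- function(x, block_size = length(x) - 1L) {
  x <- check_diff_input(x, block_size)
  d <- cpp_diffs(x, as.integer(block_size), FALSE)
  new_diff_block(d, x[1], x[block_size + 1], "unidirectional", as.integer(block_size))
}

#' @rdname diffs_unidirectional
#' @export
diffs_bidirectional <- function(x, block_size = length(x) - 1L) {
  x <- check_diff_input(x, block_size)
  d <- cpp_diffs(x, as.integer(block_size), TRUE)
  new_diff_block(d, x[1], x[block_size + 1], "bidirectional", as.integer(block_size))
}

check_diff_input <- function(x, block_size) {
  x <- check_u32(x, "x")
  if (length(x) != block_size + 1)
    op_stop("x must hold block_size + 1 values (x_0..x_B)", "bad_parameter")
  if (is.unsorted(x)) op_stop("negative difference: x must be monotone nondecreasing",
                              "negative_difference")
  x
}

#' @rdname diffs_unidirectional
#' @export
invert_diffs <- function(block) {
  stopifnot(inherits(block, "diff_block"))
  cpp_undiff(block$diffs, block$x0, block$xB, block$block_size,
             block$direction == "bidirectional")
}

new_packed_block <- function(words, width, block_size, layout, direction) {
  structure(list(words = words, width = as.integer(width),
                 block_size = as.integer(block_size), layout = layout,
                 direction = direction),
            class = "packed_block")
}

#' @export
print.packed_block <- function(x, ...) {
  cat(sprintf("packed block: %s/%s, B = %d, width = %d (%d words, %g vectors)\n",
              x$layout, x$direction, x$block_size, x$width, length(x$words),
              length(x$words) / 4))
  invisible(x)
}

check_pack_args <- function(diffs, width, block_size) {
  diffs <- check_u32(diffs, "diffs")
  if (length(diffs) != block_size)
    op_stop("diffs must hold block_size values", "bad_parameter")
  if (!width %in% allowed_widths(block_size))
    op_stop(sprintf("width %d not allowed for block size %d", width, block_size),
            "bad_width")
  if (width < 32 && any(diffs >= 2^width))
    op_stop("width overflow: a difference does not fit the block width",
            "width_overflow")
  diffs
}

#' Pack and unpack a block in the vertical layout
#'
#' The vertical layout stripes differences in sets of four across the four
#' 32-bit lanes of each 128-bit vector: entry `i` sits in lane `i mod 4`
#' at lane-bit offset `(i div 4) * width`, least-significant bits first,
#' values straddling a word boundary continuing low-bits-first in the next
#' vector's same lane. A `block_size`-value block at width `w` occupies
#' exactly `block_size * w / 32` words.
#'
#' @param diffs numeric vector of `block_size` differences, each `< 2^width`.
#' @param width allowed uniform bit width (see [select_width()]).
#' @param block_size 64 or 32.
#' @param packed a `packed_block` from the matching pack function.
#' @return `pack_vertical()` returns a `packed_block`; `unpack_vertical()`
#'   the numeric vector of differences.
#' @export
pack_vertical <- function(diffs, width, block_size = 64L) {
  if (inherits(diffs, "diff_block")) diffs <- diffs$diffs
  diffs <- check_pack_args(diffs, width, block_size)
  words <- cpp_pack(diffs, as.integer(width), as.integer(block_size), FALSE, FALSE)
  new_packed_block(words, width, block_size, "vertical", "unidirectional")
}

#' @rdname pack_vertical
#' @export
unpack_vertical <- function(packed) {
  stopifnot(inherits(packed, "packed_block"), packed$layout == "vertical")
  cpp_unpack(packed$words, packed$width, packed$block_size, FALSE, FALSE)
}

#' Pack and unpack a block in the columnar layout
#'
#' The columnar layout packs one column at a time so that decoding a single
#' value touches only its own column: groups of four consecutive rows of a
#' column are striped across the four lanes at successive lane-bit offsets,
#' columns in order. Under the bidirectional scheme the first half-block's
#' columns are packed first (each column of 8 rows for block size 64 as two
#' four-row groups), followed by the mirrored second half-block's columns.
#' At width 6 this places column 2, rows 0-3 of the first half at lane bits
#' 24-29 of vector 0, and rows 4-7 straddling bit 30 into vector 1.
#'
#' @inheritParams pack_vertical
#' @param direction difference scheme the block was transformed with.
#' @return `pack_columnar()` returns a `packed_block`; `unpack_columnar()`
#'   the numeric vector of differences.
#' @export
pack_columnar <- function(diffs, width,
                          direction = c("bidirectional", "unidirectional"),
                          block_size = 64L) {
  direction <- match.arg(direction)
  if (inherits(diffs, "diff_block")) {
    direction <- diffs$direction
    diffs <- diffs$diffs
  }
  diffs <- check_pack_args(diffs, width, block_size)
  words <- cpp_pack(diffs, as.integer(width), as.integer(block_size), TRUE,
                    direction == "bidirectional")
  new_packed_block(words, width, block_size, "columnar", direction)
}

#' @rdname pack_columnar
#' @export
unpack_columnar <- function(packed) {
  stopifnot(inherits(packed, "packed_block"), packed$layout == "columnar")
  cpp_unpack(packed$words, packed$width, packed$block_size, TRUE,
             packed$direction == "bidirectional")
}

#' Random-access decode of one block position
#'
#' `decode_vertical_at()` replays the serial vertical decode: each group
#' step shifts and masks one row of four differences out of the loaded
#' vector and parallel-adds it onto four running sums, so reaching block
#' position `r` takes `ceiling(r / 4)` group steps.
#'
#' `decode_columnar_at()` reads only the column containing the target:
#' `delta = r - 1` steps toward the beginning prefix sum (unidirectional),
#' or `delta = 31 - |r - 32|` toward the nearest prefix sum
#' (bidirectional, block size 64), selecting column `delta mod 4` and rows
#' `0 .. floor(delta / 4)`. Each group step loads four column entries and
#' parallel-adds them onto the previous group's sums; the final value sums
#' at most four scalar terms from the resulting word array. Width-0 blocks
#' short-circuit to the prefix sum. Decode statistics (`group_steps`,
#' `vector_loads`, `scalar_terms`) are returned alongside the value.
#'
#' @param packed a `packed_block`.
#' @param x0 the block's beginning prefix sum.
#' @param xB the block's ending prefix sum (needed by the bidirectional
#'   scheme; ignored otherwise).
#' @param r block position, 1..block_size.
#' @return list with `value` (`x_r`) and the decode statistics.
#' @examples
#' x <- cumsum(c(100, rep(2, 64)))  # lane-cyclic differences are 8 = x_{i+4} - x_i
#' pb <- pack_vertical(diffs_unidirectional(x), width = 4)
#' decode_vertical_at(pb, x[1], r = 43)$group_steps  # 11
#' @export
decode_vertical_at <- function(packed, x0, r) {
  stopifnot(inherits(packed, "packed_block"), packed$layout == "vertical")
  check_r(r, packed$block_size)
  cpp_decode_vertical_at(packed$words, packed$width, packed$block_size,
                         check_u32(x0, "x0"), as.integer(r))
}

#' @rdname decode_vertical_at
#' @export
decode_columnar_at <- function(packed, x0, xB, r) {
  stopifnot(inherits(packed, "packed_block"), packed$layout == "columnar")
  check_r(r, packed$block_size)
  cpp_decode_columnar_at(packed$words, packed$width, packed$block_size,
                         packed$direction == "bidirectional",
                         check_u32(x0, "x0"), check_u32(xB, "xB"),
                         as.integer(r))
}

check_r <- function(r, block_size) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 1 || r > block_size ||
      r != floor(r))
    op_stop("block position r out of range", "index_range")
}

#' Column addressing for a block position
#'
#' Computes, for block position `r`, the distance `delta` to the nearest
#' prefix sum (`r-1` throughout for the unidirectional scheme;
#' `31 - |r - 32|` for the bidirectional scheme at block size 64, i.e.
#' `r-1` for the first half-block and `63 - r` for the second), the
#' column `delta mod 4`, the row `floor(delta / 4)` within that column,
#' and the quarter-block `floor((r - 1) / 16) + 1`. Block size 32 uses
#' halved quarters and `delta = 15 - |r - 16|`.
#'
#' For the bidirectional scheme, position `block_size` is the next block's
#' stored prefix sum (`delta = -1`): no column is needed and `column` and
#' `row` are `NA`.
#'
#' @param r block position, 1..block_size.
#' @param block_size 64 or 32.
#' @param direction difference scheme.
#' @return list with `r`, `delta`, `column`, `row`, `quarter`.
#' @examples
#' locate_column(23, direction = "bidirectional")  # delta 22, column 2, Q2
#' @export
locate_column <- function(r, block_size = 64L,
                          direction = c("bidirectional", "unidirectional")) {
  direction <- match.arg(direction)
  check_r(r, block_size)
  H <- block_size / 2
  delta <- if (direction == "unidirectional") r - 1 else (H - 1) - abs(r - H)
  quarter <- (r - 1) %/% (block_size / 4) + 1
  if (delta < 0)
    return(list(r = r, delta = delta, column = NA_integer_, row = NA_integer_,
                quarter = quarter))
  list(r = r, delta = delta, column = delta %% 4, row = delta %/% 4,
       quarter = quarter)
}

#' Enumerate the columnar decode dispatch table
#'
#' Random-access columnar decoding dispatches on the block's bit width (16
#' possible nonzero even widths at block size 64), the column of the
#' target (4), and its quarter-block (4): 256 jump-table entries. Q1
#' values fall out en route to Q2 values and Q4 en route to Q3, so only
#' the Q2 and Q3 procedures are primitive — 128 of them — with Q1/Q4
#' variants derived as their initial parts. (Width 0 short-circuits to the
#' prefix sum and needs no table entry.)
#'
#' @param block_size 64 or 32.
#' @return data.frame with one row per dispatch entry: `width`, `column`,
#'   `quarter`, and logical `primitive`.
#' @export
columnar_dispatch_table <- function(block_size = 64L) {
  widths <- setdiff(allowed_widths(block_size), 0L)
  tab <- expand.grid(width = widths, column = 0:3, quarter = 1:4,
                     KEEP.OUT.ATTRS = FALSE)
  tab <- tab[order(tab$width, tab$column, tab$quarter), , drop = FALSE]
  rownames(tab) <- NULL
  tab$primitive <- tab$quarter %in% c(2L, 3L)
  tab
}
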