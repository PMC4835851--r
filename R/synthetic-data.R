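#' Generate a random genome sequence
#'
#' Draws an i.i.d. DNA sequence at a given GC content, optionally
#' scatters `N` characters (which break k-mers, as in real assemblies),
#' and optionally injects repeats: a source segment is copied to random
#' locations (`dispersed`) or laid down back-to-back (`tandem`). Repeats
#' give some k-mers long position lists and hence occasional large
#' offset differences — the skew the block codecs face on real genomes.
#'
#' @param length sequence length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param n_rate fraction of positions replaced by `N`.
#' @param repeat_spec `NULL`, or a list with `count` (number of copies),
#'   `length` (repeat unit length), and optional `mode` (`"dispersed"`,
#'   the default, or `"tandem"`).
#' @param seed RNG seed for reproducibility (`NULL` leaves the RNG state
#'   alone).
#' @return a single character string over `{A, C, G, T, N}`.
#' @export
random_genome <- function(length, gc = 0.41, n_rate = 0, repeat_spec = NULL,
                          seed = NULL) {
  if (!is.numeric(length) || length < 1)
    op_stop("length must be >= 1", "bad_parameter")
  if (gc < 0 || gc > 1 || n_rate < 0 || n_rate > 1)
    op_stop("gc and n_rate must be fractions in [0, 1]", "bad_parameter")
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)
    if (!is.null(repeat_spec)) {
      count <- repeat_spec$count %||% 10L
      rlen <- min(repeat_spec$length %||% 100L, length)
      mode <- repeat_spec$mode %||% "dispersed"
      src <- sample.int(length - rlen + 1, 1)
      unit <- bases[src:(src + rlen - 1)]
      if (identical(mode, "tandem")) {
        at <- sample.int(max(length - count * rlen, 1), 1)
        for (j in seq_len(count)) {
          lo <- at + (j - 1) * rlen
          if (lo + rlen - 1 > length) break
          bases[lo:(lo + rlen - 1)] <- unit
        }
      } else {
        for (j in seq_len(count)) {
          lo <- sample.int(length - rlen + 1, 1)
          bases[lo:(lo + rlen - 1)] <- unit
        }
      }
    }
    if (n_rate > 0) {
      nn <- rbinom(1, length, n_rate)
      if (nn > 0) bases[sample.int(length, nn)] <- "N"
    }
    paste(bases, collapse = "")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Offset-array model for synthetic data
#'
#' Describes the difference distribution of a synthetic monotone offset
#' array emulating a k-mer hash table: most adjacent differences are zero
#' (absent k-mers) or small, with a heavy upper tail from repetitive
#' k-mers.
#'
#' @param n array length (a 15-mer table has `4^15 + 1` entries; tests
#'   use much shorter arrays with the same difference structure).
#' @param zero_fraction expected share of zero differences.
#' @param tail probability that a nonzero difference is drawn from the
#'   heavy (log-normal, median ~150) tail instead of the small-count
#'   (geometric) body.
#' @param seed RNG seed.
#' @return an object of class `offset_model`.
#' @export
offset_model <- function(n, zero_fraction = 0.6, tail = 0.002, seed = NULL) {
  if (!is.numeric(n) || n < 1) op_stop("n must be >= 1", "bad_parameter")
  if (zero_fraction < 0 || zero_fraction > 1 || tail < 0 || tail > 1)
    op_stop("zero_fraction and tail must be fractions in [0, 1]", "bad_parameter")
  structure(list(n = as.integer(n), zero_fraction = zero_fraction,
                 tail = tail, seed = seed),
            class = "offset_model")
}

#' Generate a synthetic monotone offset array
#'
#' Draws adjacent differences from the [offset_model()] mixture — zero
#' with probability `zero_fraction`, otherwise `1 + Geometric(0.5)` or,
#' with probability `tail`, a rounded log-normal — and accumulates them.
#' The result is monotone nondecreasing and must stay below `2^32`.
#'
#' @param model an `offset_model`, or an array length `n` (the other
#'   model parameters then take their defaults).
#' @param ... passed to [offset_model()] when `model` is a length.
#' @return numeric vector of `n` monotone nondecreasing values starting
#'   at 0.
#' @export
random_offsets <- function(model, ...) {
  if (is.numeric(model)) model <- offset_model(model, ...)
  stopifnot(inherits(model, "offset_model"))
  with_seed(model$seed, {
    n <- model$n
    d <- numeric(n - 1)
    nz <- runif(n - 1) >= model$zero_fraction
    knz <- sum(nz)
    if (knz > 0) {
      vals <- 1 + rgeom(knz, 0.5)
      big <- runif(knz) < model$tail
      if (any(big)) vals[big] <- 1 + floor(rlnorm(sum(big), meanlog = 5, sdlog = 1))
      d[nz] <- vals
    }
    o <- cumsum(c(0, d))
    if (o[n] >= 2^32)
      op_stop("dynamic range: cumulative sum exceeds 32 bits", "dynamic_range")
    o
  })
}
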