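# Internal helpers: classed error signals, seeded evaluation, and unsigned
# 32-bit file I/O (R integers are signed; values >= 2^31 are carried through
# the two's-complement wrap).

op_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("offsetpack_", class), "offsetpack_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# unsigned 32-bit values held as doubles; written byte-wise so the full
# [0, 2^32) range survives R's signed integer type
write_u32 <- function(con, x) {
  x <- as.numeric(x)
  bytes <- rbind(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
                 x %/% 16777216 %% 256)
  writeBin(as.raw(bytes), con)
}

read_u32 <- function(con, n) {
  raw <- readBin(con, what = "raw", n = 4 * n)
  if (length(raw) < 4 * n) op_stop("truncated file", "corrupt_container")
  b <- matrix(as.numeric(raw), nrow = 4)
  b[1, ] + 256 * b[2, ] + 65536 * b[3, ] + 16777216 * b[4, ]
}

check_u32 <- function(x, what = "values") {
  if (!is.numeric(x)) op_stop(paste(what, "must be numeric"), "bad_parameter")
  if (length(x) && (anyNA(x) || any(x < 0) || any(x >= 2^32) || any(x != floor(x))))
    op_stop(paste(what, "must be integers in [0, 2^32)"), "bad_parameter")
  as.numeric(x)
}
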