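# Shared fixtures and independent oracles, built in code at test time.

ALL_SCHEMES <- c("bp64v", "bp64c", "bp32c", "gamma", "delta", "fibonacci")

# Random monotone block values x_0..x_B with a skewed difference distribution.
random_block_values <- function(B = 64, x0 = NULL, big = FALSE) {
  if (is.null(x0)) x0 <- sample(0:1e6, 1)
  d <- if (big) {
    # keeps the cumulative sum below 2^32 for any block size
    sample(c(0, 1, 2, 5, 2^20, 2^25), B, replace = TRUE,
           prob = c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05))
  } else {
    sample(c(0, 1, 2, 3, 10, 200), B, replace = TRUE,
           prob = c(0.5, 0.25, 0.1, 0.05, 0.05, 0.05))
  }
  cumsum(c(x0, d))
}

# Heavy-tailed monotone offset arrays covering width-0, small, and large
# difference blocks plus a constant run (forces width-0 blocks mid-array).
oracle_offsets <- function(n, seed = 1) {
  set.seed(seed)
  d <- sample(c(0, 0, 0, 1, 2, 7, 100, 5000), n - 1, replace = TRUE)
  if (n > 200) d[round(n / 3) + seq_len(100)] <- 0
  cumsum(c(0, d))
}

# Greedy Zeckendorf decomposition (largest Fibonacci first): the textbook
# definition, independent of the bitstream codec.
zeckendorf <- function(v) {
  fibs <- c(1, 2)
  while (sum(tail(fibs, 2)) <= v) fibs <- c(fibs, sum(tail(fibs, 2)))
  used <- logical(length(fibs))
  rem <- v
  for (j in rev(seq_along(fibs))) {
    if (fibs[j] <= rem) {
      used[j] <- TRUE
      rem <- rem - fibs[j]
    }
  }
  stopifnot(rem == 0)
  used[seq_len(max(which(used)))]  # low-to-high, up to the highest used number
}

# Allowed uniform widths, restated independently of the package internals.
allowed_widths_for_test <- function(B) {
  if (B == 64) seq(0, 32, by = 2) else seq(0, 32, by = 4)
}

expect_offsetpack_error <- function(expr, class) {
  expect_error(expr, class = paste0("offsetpack_", class))
}
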