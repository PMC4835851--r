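test_that("width selection picks the smallest allowed width covering the block max", {
  expect_equal(select_width(rep(0, 64)), 0)
  expect_equal(select_width(c(rep(0, 63), 63)), 6)     # 63 needs exactly 6 bits
  expect_equal(select_width(c(rep(0, 63), 7)), 4)      # 3 bits rounds up to even 4
  expect_equal(select_width(c(rep(0, 31), 7), block_size = 32), 4)
  expect_equal(select_width(c(rep(0, 31), 63), block_size = 32), 8)  # 6 -> multiple of 4
  expect_equal(select_width(2^32 - 1), 32)
  # property: smallest allowed width, across random maxima
  set.seed(1)
  for (mx in sample(1:(2^31), 40)) {
    w <- select_width(mx, 64)
    expect_true(w %% 2 == 0 && mx < 2^w)
    expect_true(w == 2 || mx >= 2^(w - 2))
  }
})

test_that("block storage arithmetic in 128-bit vectors", {
  expect_equal(storage_size_vectors(128, 3), 3)
  expect_equal(storage_size_vectors(64, 4), 2)
  expect_equal(storage_size_vectors(64, 6), 3)
  expect_equal(storage_size_vectors(64, 3), 1.5)  # why odd widths are excluded
  expect_equal(storage_size_vectors(32, 4), 1)
})

test_that("difference transforms invert exactly on random monotone blocks", {
  set.seed(202)
  for (B in c(64, 32)) {
    for (rep in 1:25) {
      x <- random_block_values(B, big = rep > 20)
      for (fwd in list(diffs_unidirectional, diffs_bidirectional)) {
        blk <- fwd(x, B)
        expect_true(all(blk$diffs >= 0))
        expect_equal(invert_diffs(blk), x)
      }
    }
  }
  # constant block gives all-zero differences under both schemes
  xc <- rep(5, 65)
  expect_equal(diffs_unidirectional(xc)$diffs, rep(0, 64))
  expect_equal(diffs_bidirectional(xc)$diffs, rep(0, 64))
  # identity ramp round trips
  xi <- 0:64
  expect_equal(invert_diffs(diffs_unidirectional(xi)), xi)
})

test_that("unidirectional differences follow the lane-cyclic rule", {
  set.seed(3)
  x <- random_block_values(64)
  d <- diffs_unidirectional(x)$diffs
  expect_equal(d[1:4], x[2:5] - x[1])            # first row relative to x_0
  i <- 5:64                                      # d_i = x_{i+1} - x_{i-3} (0-based i)
  expect_equal(d[i], x[i + 1] - x[i - 3])
})

test_that("bidirectional scheme matches unidirectional on the first half and meets in the middle", {
  set.seed(4)
  x <- random_block_values(64)
  du <- diffs_unidirectional(x)$diffs
  db <- diffs_bidirectional(x)$diffs
  expect_equal(db[1:32], du[1:32])
  # second half: x_r reconstructed by subtracting a lane-cyclic sum from x_64
  for (r in c(33, 40, 55, 63)) {
    delta <- 63 - r
    lane <- delta %% 4
    j <- seq(lane, delta, by = 4)  # second-half difference indices (0-based)
    expect_equal(x[65] - sum(db[32 + j + 1]), x[r + 1])
  }
  # midpoint agrees computed from both ends
  expect_equal(x[1] + sum(du[seq(3, 31, by = 4) + 1]), x[33])
  expect_equal(x[65] - sum(db[32 + seq(3, 31, by = 4) + 1]), x[33])
})

test_that("non-monotone blocks signal a negative difference", {
  x <- c(0:63, 10)
  expect_offsetpack_error(diffs_unidirectional(x), "negative_difference")
  expect_offsetpack_error(diffs_bidirectional(x), "negative_difference")
})

test_that("vertical packing round trips at every allowed width and has exact word counts", {
  set.seed(5)
  for (B in c(64, 32)) {
    for (w in setdiff(allowed_widths_for_test(B), 0)) {
      d <- sample(0:(min(2^w, 2^31) - 1), B, replace = TRUE)
      pb <- pack_vertical(d, w, B)
      expect_length(pb$words, B * w / 32)
      expect_equal(unpack_vertical(pb), d)
    }
  }
  pb0 <- pack_vertical(rep(0, 64), 0)
  expect_length(pb0$words, 0)
  expect_equal(unpack_vertical(pb0), rep(0, 64))
  expect_offsetpack_error(pack_vertical(rep(64, 64), 6), "width_overflow")
  expect_offsetpack_error(pack_vertical(rep(1, 64), 3), "bad_width")
})

test_that("columnar packing round trips for both directions, widths, and block sizes", {
  set.seed(6)
  for (B in c(64, 32)) {
    for (dir in c("unidirectional", "bidirectional")) {
      for (w in setdiff(allowed_widths_for_test(B), 0)) {
        d <- sample(0:(min(2^w, 2^31) - 1), B, replace = TRUE)
        pb <- pack_columnar(d, w, direction = dir, block_size = B)
        expect_length(pb$words, B * w / 32)
        expect_equal(unpack_columnar(pb), d)
      }
    }
  }
  expect_equal(unpack_columnar(pack_columnar(rep(0, 64), 0)), rep(0, 64))
})

test_that("columnar bit placement matches the worked width-6 layout", {
  # first-half column 2, rows 0-3 occupy lane bits 24-29 of vector 0:
  # a parallel 24-bit right shift exposes d_2, d_6, d_10, d_14
  d <- rep(0, 64)
  d[c(2, 6, 10, 14) + 1] <- c(33, 42, 51, 60)
  pb <- pack_columnar(d, 6, direction = "bidirectional")
  expect_equal(bitwAnd(bitwShiftR(pb$words[1:4], 24), 63), c(33, 42, 51, 60))
  # rows 4-7 (d_18, d_22, d_26, d_30) straddle: right shift vector 0 by 30,
  # left shift vector 1 by 2
  d2 <- rep(0, 64)
  d2[c(18, 22, 26, 30) + 1] <- c(21, 22, 23, 24)
  pb2 <- pack_columnar(d2, 6, direction = "bidirectional")
  unsigned <- function(w) {  # words carry uint32 bit patterns (NA = 0x80000000)
    w <- ifelse(is.na(w), -2^31, w)
    ifelse(w < 0, w + 2^32, w)
  }
  u0 <- unsigned(pb2$words[1:4])
  u1 <- unsigned(pb2$words[5:8])
  expect_equal(u0 %/% 2^30 + (u1 %% 16) * 4, c(21, 22, 23, 24))
})

test_that("vertical random-access decode equals the scalar oracle with ceil(r/4) steps", {
  set.seed(7)
  for (B in c(64, 32)) {
    x <- random_block_values(B)
    blk <- diffs_unidirectional(x, B)
    w <- select_width(blk$diffs, B)
    pb <- pack_vertical(blk, w, B)
    for (r in 1:B) {
      res <- decode_vertical_at(pb, x[1], r)
      expect_equal(res$value, x[r + 1])
      expect_equal(res$group_steps, ceiling(r / 4))
    }
  }
  expect_offsetpack_error(decode_vertical_at(pb, x[1], 0), "index_range")
  expect_offsetpack_error(decode_vertical_at(pb, x[1], 65), "index_range")
})

test_that("columnar random-access decode equals the scalar oracle for all r, both directions", {
  set.seed(8)
  for (B in c(64, 32)) {
    for (trial in 1:5) {
      x <- random_block_values(B, big = trial == 5)
      for (dir in c("unidirectional", "bidirectional")) {
        blk <- if (dir == "unidirectional") diffs_unidirectional(x, B)
               else diffs_bidirectional(x, B)
        w <- select_width(blk$diffs, B)
        pb <- pack_columnar(blk, w, block_size = B)
        for (r in 1:B) {
          res <- decode_columnar_at(pb, x[1], x[B + 1], r)
          expect_equal(res$value, x[r + 1])
          expect_lte(res$scalar_terms, 4)
        }
      }
    }
  }
})

test_that("group-step accounting: quarter patterns and the worked x_43 example", {
  set.seed(9)
  x <- random_block_values(64)
  wu <- select_width(diffs_unidirectional(x)$diffs)
  wb <- select_width(diffs_bidirectional(x)$diffs)
  pu <- pack_columnar(diffs_unidirectional(x), wu)
  pb <- pack_columnar(diffs_bidirectional(x), wb)
  pv <- pack_vertical(diffs_unidirectional(x), wu)
  expect_equal(decode_vertical_at(pv, x[1], 43)$group_steps, 11)
  expect_equal(decode_columnar_at(pu, x[1], x[65], 43)$group_steps, 3)
  expect_equal(decode_columnar_at(pb, x[1], x[65], 43)$group_steps, 2)
  # unidirectional columnar needs quarter-index many steps: 1/2/3/4
  steps_u <- vapply(1:64, function(r) decode_columnar_at(pu, x[1], x[65], r)$group_steps,
                    numeric(1))
  expect_equal(steps_u, ceiling(1:64 / 16))
  # bidirectional pattern 1/2/2/1 at quarter interiors; never more than 2
  steps_b <- vapply(1:63, function(r) decode_columnar_at(pb, x[1], x[65], r)$group_steps,
                    numeric(1))
  expect_equal(steps_b[c(8, 23, 43, 55)], c(1, 2, 2, 1))
  expect_true(all(steps_b %in% c(1, 2)))
  expect_equal(steps_b[1:16], rep(1, 16))   # Q1
  expect_equal(steps_b[17:32], rep(2, 16))  # Q2
})

test_that("x_23 is assembled from exactly four scalar terms after the parallel addition", {
  set.seed(10)
  x <- random_block_values(64)
  pb <- pack_columnar(diffs_bidirectional(x), select_width(diffs_bidirectional(x)$diffs))
  res <- decode_columnar_at(pb, x[1], x[65], 23)
  expect_equal(res$value, x[24])
  expect_equal(res$scalar_terms, 4)
})

test_that("column addressing follows delta = 31 - |r - 32|", {
  lc <- locate_column(23, direction = "bidirectional")
  expect_equal(lc$delta, 22)
  expect_equal(lc$column, 2)
  expect_equal(lc$quarter, 2)
  expect_equal(locate_column(1, direction = "bidirectional")[c("delta", "column", "row", "quarter")],
               list(delta = 0, column = 0, row = 0, quarter = 1))
  lc43 <- locate_column(43, direction = "bidirectional")
  expect_equal(lc43[c("delta", "column", "row", "quarter")],
               list(delta = 20, column = 0, row = 5, quarter = 3))
  # unidirectional uses delta = r - 1 throughout
  expect_equal(locate_column(43, direction = "unidirectional")$delta, 42)
  # invariant delta = 31 - |r - 32| over the full block
  for (r in 1:63) {
    lc <- locate_column(r, direction = "bidirectional")
    expect_equal(lc$delta, 31 - abs(r - 32))
    expect_equal(lc$column, lc$delta %% 4)
    expect_equal(lc$row, lc$delta %/% 4)
  }
  # block 32 mirrors with delta = 15 - |r - 16|
  expect_equal(locate_column(10, 32, "bidirectional")$delta, 15 - abs(10 - 16))
  expect_offsetpack_error(locate_column(0), "index_range")
  expect_offsetpack_error(locate_column(65), "index_range")
})

test_that("width-0 blocks decode to the prefix sum without loads", {
  pb <- pack_columnar(rep(0, 64), 0)
  for (r in c(1, 17, 33, 63)) {
    res <- decode_columnar_at(pb, 77, 77, r)
    expect_equal(res$value, 77)
    expect_equal(res$vector_loads, 0)
  }
})

test_that("the columnar dispatch table enumerates 256 entries, 128 primitive", {
  tab <- columnar_dispatch_table(64)
  expect_equal(nrow(tab), 256)
  expect_equal(sum(tab$primitive), 128)
  expect_setequal(unique(tab$width), seq(2, 32, by = 2))
  expect_setequal(unique(tab$column), 0:3)
  expect_setequal(unique(tab$quarter), 1:4)
})
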