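test_that("every scheme reproduces the uncompressed array exactly", {
  arrays <- list(
    constant = rep(7, 300),
    unit_step = 0:400,
    single = 42,                        # n = 1: meta only
    block_exact = oracle_offsets(256),  # n a multiple of both block sizes
    partial = oracle_offsets(333, seed = 2),
    heavy = oracle_offsets(5000, seed = 3)
  )
  for (o in arrays) {
    for (s in ALL_SCHEMES) {
      v <- compress_offsets(o, s)
      expect_equal(decompress_offsets(v), as.numeric(o),
                   info = paste(s, length(o)))
    }
  }
})

test_that("lookups preserve monotonicity and match the oracle at block boundaries", {
  o <- oracle_offsets(1000, seed = 4)
  for (s in ALL_SCHEMES) {
    v <- compress_offsets(o, s)
    B <- v$block_size
    edges <- unique(pmin(c(seq(0, 999, by = B), seq(B - 1, 999, by = B),
                           seq(B, 999, by = B) + 1), 999))
    expect_equal(lookup_offset(v, edges), o[edges + 1])
    d <- lookup_offset(v, 1:999) - lookup_offset(v, 0:998)
    expect_true(all(d >= 0))
  }
})

test_that("constant arrays compress to width-0 blocks with an empty bitstream", {
  o <- rep(123, 500)
  for (s in c("bp64v", "bp64c", "bp32c")) {
    v <- compress_offsets(o, s)
    expect_length(v$words, 0)
    expect_true(all(v$widths == 0))
    expect_true(all(v$meta$prefix_sum == 123))
    expect_equal(lookup_offset(v, c(0, 250, 499)), rep(123, 3))
  }
})

test_that("metainformation invariants: sentinel entry, monotone pointers, implicit width", {
  o <- oracle_offsets(777, seed = 5)
  for (s in ALL_SCHEMES) {
    v <- compress_offsets(o, s)
    B <- v$block_size
    nb <- ceiling(777 / B)
    expect_length(v$meta$pointer, nb + 1)  # one sentinel past the last block
    expect_false(is.unsorted(v$meta$pointer))
    expect_false(is.unsorted(v$meta$prefix_sum))
    expect_equal(v$meta$prefix_sum[seq_len(nb)], o[(0:(nb - 1)) * B + 1])
    expect_equal(v$meta$prefix_sum[nb + 1], o[777])
    if (s %in% c("bp64v", "bp64c", "bp32c")) {
      implied <- 2 * diff(v$meta$pointer) * (64 / B)
      expect_equal(as.numeric(v$widths), implied)
    }
  }
})

test_that("hash-table offsets survive compression for all schemes", {
  ht <- build_hash_table("AAAA", k = 2)
  for (s in ALL_SCHEMES) {
    v <- compress_offsets(ht$offsets, s, k = 2)
    expect_equal(decompress_offsets(v), ht$offsets)
  }
})

test_that("pair retrieval: one-pass equals two-pass everywhere, including boundaries", {
  o <- oracle_offsets(400, seed = 6)
  for (s in ALL_SCHEMES) {
    v <- compress_offsets(o, s)
    i <- 0:398
    p1 <- lookup_pair_onepass(v, i)
    p2 <- lookup_pair_twopass(v, i)
    expect_identical(p1, p2)
    expect_equal(p1$first, o[1:399])
    expect_equal(p1$second, o[2:400])
    expect_true(all(p1$second >= p1$first))
  }
})

test_that("a pair at the block boundary reads its second value from meta alone", {
  o <- oracle_offsets(200, seed = 7)
  v <- compress_offsets(o, "bp64c")
  st_first <- lookup_offset_stats(v, 63)
  st <- lookup_pair_stats(v, 63, onepass = TRUE)
  expect_equal(st$first, o[64])
  expect_equal(st$second, o[65])
  # only the first value needed decoding
  expect_equal(st$vector_loads, st_first$vector_loads)
})

test_that("one-pass loads never exceed the two-pass total and undercut it when columns share vectors", {
  set.seed(8)
  o <- cumsum(c(0, sample(0:3, 4000, replace = TRUE)))  # small widths: columns share vectors
  saved <- 0
  for (s in c("bp64v", "bp64c", "bp32c")) {
    v <- compress_offsets(o, s)
    for (i in sample(0:3998, 300)) {
      one <- lookup_pair_stats(v, i, onepass = TRUE)
      two <- lookup_pair_stats(v, i, onepass = FALSE)
      expect_identical(one[c("first", "second")], two[c("first", "second")])
      expect_lte(one$vector_loads, two$vector_loads)
      saved <- saved + (two$vector_loads - one$vector_loads)
    }
  }
  expect_gt(saved, 0)
})

test_that("adjacent positions within a block sit in neighboring columns", {
  for (dir in c("unidirectional", "bidirectional")) {
    cols <- vapply(1:63, function(r) locate_column(r, 64, dir)$column, numeric(1))
    steps <- (cols[-1] - cols[-63]) %% 4
    expect_true(all(steps %in% c(1, 3)))  # column 3 and 0 are neighboring
    if (dir == "unidirectional") expect_true(all(steps == 1))  # 0->1->2->3->0
  }
})

test_that("index-range violations signal errors", {
  v <- compress_offsets(0:99, "bp64c")
  expect_offsetpack_error(lookup_offset(v, -1), "index_range")
  expect_offsetpack_error(lookup_offset(v, 100), "index_range")
  expect_offsetpack_error(lookup_pair_twopass(v, 99), "index_range")
  expect_offsetpack_error(compress_offsets(c(3, 2, 1), "bp64c"), "negative_difference")
})

test_that("BPOF serialization round trips bit-exactly and answers lookups", {
  o <- oracle_offsets(700, seed = 9)
  for (s in ALL_SCHEMES) {
    v <- compress_offsets(o, s, k = if (s == "bp64c") 5 else NULL)
    f <- tempfile(fileext = ".bpof")
    write_bpof(v, f)
    v2 <- read_bpof(f)
    expect_identical(v2$words, v$words)
    expect_equal(v2$meta, v$meta)
    expect_equal(v2$n, v$n)
    expect_equal(v2$scheme, v$scheme)
    expect_equal(decompress_offsets(v2), o)
    unlink(f)
  }
  # n = 1 container round trips
  f <- tempfile()
  write_bpof(compress_offsets(5, "bp32c"), f)
  expect_equal(decompress_offsets(read_bpof(f)), 5)
  unlink(f)
})

test_that("corrupt container files are rejected", {
  f <- tempfile()
  writeBin(charToRaw("NOPE"), f)
  expect_offsetpack_error(read_bpof(f), "unrecognized_file")
  v <- compress_offsets(oracle_offsets(300, seed = 10), "gamma")
  write_bpof(v, f)
  sz <- file.size(f)
  truncated <- readBin(f, "raw", sz - 40)
  writeBin(truncated, f)
  expect_offsetpack_error(read_bpof(f), "corrupt_container")
  unlink(f)
})

test_that("storage accounting matches the 4-bytes-per-entry and block formulas", {
  expect_equal(storage_size_bytes("uncompressed", k = 15), 4 * 4^15)  # 4 GB
  expect_equal(storage_size_bytes("uncompressed", k = 15) / 2^30, 4)
  expect_equal(storage_size_bytes("uncompressed", n = 1000), 4000)
  # a width-6 block contributes 3 vectors = 48 bytes of bitstream
  o <- c(rep(0, 30), rep(63, 35))  # single 63 jump: max cyclic difference 63
  v <- compress_offsets(o, "bp64v")
  expect_equal(v$widths[1], 6)
  expect_equal(4 * 4 * diff(v$meta$pointer)[1], 48)
  # halving the block size doubles the metainformation for fixed n
  o2 <- oracle_offsets(64 * 40, seed = 11)
  m64 <- length(compress_offsets(o2, "bp64c")$meta$pointer) - 1
  m32 <- length(compress_offsets(o2, "bp32c")$meta$pointer) - 1
  expect_equal(m32, 2 * m64)
  vv <- compress_offsets(o2, "bp64c")
  expect_equal(storage_size_bytes(vv),
               4 * length(vv$words) + 8 * length(vv$meta$pointer))
})

test_that("per-block inspection dump lists pointer, width and prefix sum", {
  o <- oracle_offsets(200, seed = 12)
  v <- compress_offsets(o, "bp64c")
  tab <- inspect_blocks(v)
  expect_equal(nrow(tab), ceiling(200 / 64))
  expect_named(tab, c("block", "pointer", "width", "prefix_sum"))
  expect_equal(tab$prefix_sum, o[tab$block * 64 + 1])
  txt <- capture.output(dump_blocks(v))
  expect_match(txt[1], "scheme bp64c")
  expect_length(txt, nrow(tab) + 2)
})
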