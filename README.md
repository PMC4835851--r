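# offsetpack

Compressed random-access offset arrays for genomic k-mer hash tables.

## The problem

Seed-and-extend aligners index a genome with a lookup hash table: for every
possible k-mer, a list of its genomic start positions. The table is stored as
two arrays — a monotone nondecreasing **offset array** of length 4^k + 1
whose adjacent entries `(offsets[m], offsets[m+1])` delimit k-mer *m*'s slice
of a concatenated **positions array**. The offset array grows exponentially
with k: at 4 bytes per entry, a 15-mer table needs 4 GB before a single
position is stored, which is what has historically kept aligners at 11- and
12-mers even though longer seeds are far more specific.

Because offsets are monotone, the array compresses well as *differences*
between successive values. The catch is access pattern: an aligner does not
stream the array, it asks for **two adjacent values at one random location**
per seed lookup. This package implements block-based differential bitpacking
designed for exactly that access pattern, for people building or studying
genome indexes (and anyone else with a large monotone integer array they need
to sample at random).

## The method

The offset array is split into blocks of B = 64 (or 32) values. Each block's
differences are stored at the uniform bit width sufficient for the block's
largest difference (even widths only for B = 64, multiples of 4 for B = 32,
width 0 marking all-zero blocks), and a **metainformation array** keeps, per
block, a pointer into the bitstream plus the block's beginning prefix sum
x₀ — so the width is implicit in successive pointer differences, and any
lookup sums only a few differences on top of a stored prefix sum.

Three bitpacked layouts are provided, plus three universal-code baselines:

* **bp64v** — the BP128 *vertical* layout at block size 64: differences
  striped row-wise across the four 32-bit lanes of 128-bit vectors, with
  lane-cyclic differences `d_i = x_{i+1} − x_{i−3}` (first row relative to
  x₀). Reaching position r costs ⌈r/4⌉ shift/mask/add group steps — 11 steps
  for x₄₃.
* **bp64c** — the *columnar* layout with a *bidirectional* difference
  scheme: each column (indices congruent mod 4 along the path to the target)
  is packed contiguously, the first half-block is coded forward from x₀ and
  the second half backward from the block's ending prefix sum x₆₄ (already
  stored as the next block's x₀). The target's distance to the nearest prefix
  sum is δ = 31 − |r − 32|; only column δ mod 4 is decoded, in 1/2/2/1 group
  steps for quarter-blocks Q1–Q4 (2 steps for x₄₃ instead of 11), and the
  final value needs at most 4 scalar terms after a last parallel addition.
* **bp32c** — the columnar design at block size 32: every lookup is a single
  group step, at the price of twice the metainformation.
* **gamma / delta / fibonacci** — block-wise Elias gamma, Elias delta and
  Fibonacci codes over adjacent differences (block size 64), each difference
  stored as `code(d + 1)` so the ubiquitous increment 0 takes one short
  codeword.

Retrieving the pair `(offsets[i], offsets[i+1])` is supported two-pass (two
independent decodes) and **one-pass**: adjacent values sit in neighboring
columns, so the merged procedure reuses vectors already loaded for the first
column and never loads more than the two-pass total.

## Worked example

```r
library(offsetpack)

g  <- random_genome(1e6, n_rate = 0.002,
                    repeat_spec = list(count = 40, length = 2000), seed = 1)
ht <- build_hash_table(g, k = 8, sampling = 3)
ht
#> k-mer hash table: k = 8, sampling = 3 bp
#>   offsets: 65537 entries (4^k + 1); positions stored: 328175

v <- compress_offsets(ht$offsets, "bp64c", k = 8)
v
#> compressed offset array: scheme bp64c, n = 65537 values, 1025 blocks of 64
#>   bitstream: 12508 words; meta: 1026 entries; total 58,240 bytes (22.2% of uncompressed)

code <- encode_kmer("ACGTACGT")   # 6939
lookup_pair_onepass(v, code)
#> $first
#> [1] 41414
#> $second
#> [1] 41419

lookup_positions(ht, code)
#> [1] 268239 362292 524607 690303 692667

lookup_offset_stats(v, code)
#> value 41414, group_steps 2, vector_loads 1, scalar_terms 4
```

The five positions are exactly the entries `41414..41418` of the positions
array: the compressed container answers the pair query from one loaded
vector in two group steps, against 58 KB instead of 256 KB of offsets. The
one-pass pair retrieval for this index costs 1 vector load where the
two-pass costs 2 (`lookup_pair_stats(v, code, onepass = FALSE)`).

A command-line front end wrapping these functions (subcommands `build`,
`query`, `bench`, `inspect`) is installed at
`system.file("cli/offsetpack.R", package = "offsetpack")`.

Space/time benchmarking across all schemes, with per-trial randomized scheme
order and a cross-scheme checksum guard, is available as `run_benchmark()`;
see the vignette for the protocol.

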