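---
title: "Block bitpacking for random access to k-mer offset arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block bitpacking for random access to k-mer offset arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offsetpack)
```

## The data structure

A lookup hash table indexes a genome by storing, for each of the 4^k
possible k-mers, the list of its genomic start positions. Two arrays
realize this: a *positions array* concatenating all lists in k-mer order,
and a monotone nondecreasing *offset array* of length 4^k + 1 where entry
*m* points at the start of k-mer *m*'s list and the final entry equals the
total position count. A seed lookup reads the adjacent pair
`(offsets[m], offsets[m+1])`; their difference is the list length. The
positions themselves stay uncompressed — lists must be consumed at full
speed — but the offset array, whose size is exponential in k, is the
compression target.

`build_hash_table()` constructs both arrays by counting k-mers and
prefix-summing the counts. Conventions: 0-based half-open coordinates;
`A=0, C=1, G=2, T=3` with the leftmost base most significant (the standard
2-bit encoding, so codes enumerate k-mers lexicographically); k-mers
containing any non-ACGT character are skipped whole, since the table
indexes the exhaustive set of unambiguous k-mers; sampling keeps positions
with `p %% sampling == 0`, the phase anchored at coordinate 0; multiple
FASTA records are concatenated with an `N` separator so no k-mer spans
records, and positions are global over the concatenation — the simplest
single-positions-space model. Only the forward strand is indexed; callers
wanting both strands can index the concatenation of a sequence and its
reverse complement. `k` is capped at 12 here (4^12 + 1 offsets ≈ 67 MB);
the 15-mer scale enters only through the storage accounting
`storage_size_bytes("uncompressed", k = 15)` = 4·4^15 bytes.

## Difference schemes

Blocks hold B = 64 (or 32) consecutive offsets. Within a block the values
x₀..x_B (x_B being the next block's first value) are converted to
nonnegative differences:

* **Unidirectional (lane-cyclic)**: `d_i = x_{i+1} − x_{i−3}`, the first
  row of four taken relative to x₀. Four running sums, one per 32-bit
  vector lane, reconstruct the values; x_r needs the differences with
  index ≡ (r−1) mod 4 up to r−1.
* **Bidirectional**: the first half-block is coded as above from x₀; the
  second half codes the mirrored series `y_s = x_B − x_{B−s}` with the
  same lane-cyclic rule, so x_r for r in the second half is x_B minus a
  lane-cyclic cumulative sum. The distance to the nearest prefix sum is
  `δ = 31 − |r − 32|` (B = 64), and x_{B/2} is reachable from both ends —
  an invariant the tests assert.

Non-monotone input surfaces as a `negative difference` error at the
transform boundary.

## Layouts and bit-level conventions

The bit width per block is the smallest *allowed* width covering the
block's largest difference: even values for B = 64, multiples of 4 for
B = 32, anything for 128-value blocks. The rationale is storage alignment:
64 values at an odd width occupy a fractional number of 128-bit vectors
(width 3 → 1.5 vectors, no better than width 4) and odd widths need extra
merge operations at word boundaries. Width 0 flags an all-zero block, for
which decoding returns the prefix sum without touching the bitstream.

Bit order is fixed package-wide: lane *l* of vector *v* is word `4v + l`;
within a lane, values are laid down least-significant-bits first; a value
straddling a 32-bit boundary puts its low bits in the earlier vector.

* **Vertical** (`bp64v`): entry *i* in lane `i mod 4` at lane-bit offset
  `(i div 4)·width`. Serial decode: each *group step* shifts/masks one row
  of four differences and parallel-adds it onto four running sums —
  ⌈r/4⌉ steps to reach x_r.
* **Columnar** (`bp64c`, `bp32c`): groups of four rows of one *column*
  (difference indices congruent mod 4) are packed contiguously per lane,
  columns in order. For the bidirectional scheme the first half-block's
  columns are packed first (lane-bit offsets 0..8w at B = 64), then the
  second half-block's columns continue at 8w..16w in the same column
  order. The layout of the mirrored half is not fully determined by the
  design's verbal description; this order is our choice, fixed by two
  requirements that the tests pin down: the worked width-6 example
  (column 2, Q2 at lane bits 24–29 of vector 0, its next group straddling
  bit 30), and exact round-trip and one-pass invariants.

Columnar decode reads only the target's column: `G = ⌊δ/4⌋ div 4 + 1`
group steps, each parallel-adding four column entries onto the previous
group's sums, then at most four scalar terms from the resulting word
array (the final parallel addition folds earlier groups in, which is why
x₂₃ needs words 2–5 only). The step patterns per quarter-block are 1/2/3/4
(unidirectional) and 1/2/2/1 (bidirectional, B = 64); bp32c always takes
one step. Two boundary cases deviate by construction and are documented
rather than special-cased away: r = 48 (the last element of Q3) has
δ = 15 and needs a single step, and r = 64 *is* the next block's stored
prefix sum, returned with no decoding at all (in container lookups that
position is always served from the metainformation array, so the block
decoder only ever sees it through the block-level API).

`DecodeStats` counts `group_steps` (one shift/mask/add cycle over a
four-entry group — the countable unit), `vector_loads` (distinct
four-word vectors read), and `scalar_terms`. The dispatch space of the
columnar decoder — 16 nonzero even widths × 4 columns × 4 quarters = 256
entries, of which the Q2/Q3 procedures (128) are primitive with Q1/Q4
falling out as their prefixes — is enumerable via
`columnar_dispatch_table()`; the implementation realizes the dispatch as a
parameterized loop rather than generated code, which changes nothing
countable.

## Universal-code baselines

Elias gamma, Elias delta, and Fibonacci coding operate on *adjacent*
differences (decoding within a block is serial anyway, so lane-cyclic
differences would only inflate values), at block size 64, with the same
pointer + prefix-sum metainformation shape. Each difference is stored as
`code(d + 1)`: monotone offset arrays are full of zero increments and this
shift gives them a 1-bit gamma codeword. Fibonacci codes use the
Zeckendorf decomposition emitted lowest-Fibonacci-first with an appended 1
("11" terminator). Gamma's 2c−1 length law is verified exhaustively below
2^20 in the tests.

## The container

`compress_offsets()` emits one bitstream plus ⌈n/B⌉ + 1 metainformation
entries — the sentinel past the last block supplies the x_B every
bidirectional decode of the final block needs. Choices worth stating:

* Meta pointers are in 128-bit vector units for bitpacked schemes, so the
  implicit width `2·Δpointer·(64/B)` is integral for every allowed width;
  universal-code pointers are bit offsets (their blocks are not
  vector-aligned).
* The meta prefix sum for block *b* is the value at element `b·B` (the
  block's first value), not `b·B − 1`.
* A final partial block is padded by repeating the last offset; padded
  positions decode to that value but are never exposed (`lookup` bounds
  to n).
* Offsets are 32-bit by contract; arrays whose last value reaches 2^32
  are rejected at the boundary (`dynamic range` / parameter errors).
* The `BPOF` file format is little-endian throughout with an 8-byte-wide
  pointer field, so bitstreams longer than 2^32 bits serialize correctly.

Pair retrieval contracts: one-pass and two-pass return identical values
everywhere; when `i+1` crosses a block boundary the second value comes
from the metainformation alone; one-pass `vector_loads` counts the union
of the two decodes' vector intervals, hence never exceeds the two-pass sum
and undercuts it exactly when the neighboring columns share a vector. For
universal codes "one-pass" decodes the (r+1)-th code on the same serial
scan.

## Synthetic data: what it emulates, what it does not

`random_offsets()` draws adjacent differences from a three-part mixture:
zero with probability `zero_fraction` (default 0.6 — at the 15-mer scale
most k-mers are absent or rare, and sampled 3-bp tables of gigabase
genomes leave the majority of increments at zero), otherwise
`1 + Geometric(0.5)` small counts, replaced with probability `tail`
(default 0.002) by `1 + ⌊LogNormal(meanlog 5, sdlog 1)⌋` — a heavy upper
tail with median ≈ 150 standing in for highly repetitive k-mers, which is
what forces occasional wide blocks. `random_genome()` adds the sequence
route: i.i.d. bases at a chosen GC (default 0.41, a vertebrate-like
composition), optional `N`s, and injected tandem or dispersed repeats that
skew k-mer counts.

These generators reproduce the *difference-distribution shape* the codecs
face — runs of zeros, small bodies, rare large jumps, and (via repeats)
wide blocks — which is the only property the codecs are sensitive to.
They do not reproduce genome-scale correlation structure (isochores,
repeat families with internal divergence, chromosome-scale composition
shifts) or real assembly gaps; passing tests therefore demonstrate
correctness and step-count behavior on realistic difference statistics,
not compression ratios of any particular real genome.

`run_benchmark()` follows the retrieval protocol: per trial a fresh
uniform query stream over pair indices `0..n−2` (the last index has no
adjacent successor), schemes visited in fresh random order, both retrieved
values folded into a 64-bit additive checksum that must agree across all
schemes, median over trials, and the median loop overhead (iterating the
stream and checksumming indices only) subtracted. Space numbers are exact
and asserted in tests; timing numbers are hardware-dependent and only ever
reported.

## Problem sizes and numerical choices in the test suite

The suite exercises: every allowed width × layout × direction × block size
at the block level (exhaustive in r); container equality against the
uncompressed array exhaustively at n = 4·10^4 and spot-checked at
n = 10^6 under the heavy-tailed model; width-32 blocks via a 2^31-sized
jump; and an end-to-end 1 Mb genome at k = 8, sampling 3, with all 4^8 + 1
indices compared across all six schemes. These sizes make the default test
run complete in well under a minute while covering every block-boundary
and width regime; all comparisons are exact integer equality — there are
no tolerances anywhere in the package.

## Known limitations

* No actual SIMD intrinsics: the implementation is scalar C++ that
  *counts* the vector operations (group steps, vector loads) the layouts
  are designed around. Step counts are exact; nanosecond timings of a
  true intrinsics build are out of reach by design.
* The horizontal packing layout and 128-value vertical blocks are not
  implemented (the latter appears only in storage arithmetic).
* Containers are immutable after construction; no appending, concurrent
  mutation, or memory-mapped access.
* Offsets beyond 2^32 − 1 positions are out of scope, as is compression
  of the positions array itself.
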