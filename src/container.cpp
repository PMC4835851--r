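// Random-access container over block codecs, plus the Rcpp interface for the
// block-level operations, universal codes, and benchmarking loops.

#include <Rcpp.h>
#include <cstdio>
#include "codec.h"

using namespace Rcpp;

SchemeInfo scheme_info(int scheme_id) {
  switch (scheme_id) {
    case 0: return SchemeInfo{64, true, true, false, -1};        // bp64v
    case 1: return SchemeInfo{64, true, false, true, -1};        // bp64c
    case 2: return SchemeInfo{32, true, false, true, -1};        // bp32c
    case 3: return SchemeInfo{64, false, false, false, UC_GAMMA};
    case 4: return SchemeInfo{64, false, false, false, UC_DELTA};
    case 5: return SchemeInfo{64, false, false, false, UC_FIBONACCI};
    default: throw std::runtime_error("unknown scheme id");
  }
}

// ---- small conversion helpers -------------------------------------------

static std::vector<uint32_t> nv_to_u32(const NumericVector &v) {
  std::vector<uint32_t> out((size_t)v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[(size_t)i] = (uint32_t)v[i];
  return out;
}

static NumericVector u32_to_nv(const std::vector<uint32_t> &v) {
  NumericVector out((R_xlen_t)v.size());
  for (size_t i = 0; i < v.size(); ++i) out[(R_xlen_t)i] = (double)v[i];
  return out;
}

static IntegerVector u32_to_iv(const std::vector<uint32_t> &v) {
  IntegerVector out((R_xlen_t)v.size());
  for (size_t i = 0; i < v.size(); ++i) out[(R_xlen_t)i] = (int32_t)v[i];
  return out;
}

static const uint32_t *iv_ptr(const IntegerVector &w) {
  return reinterpret_cast<const uint32_t *>(INTEGER(w));
}

// ---- block-level exports -------------------------------------------------

// [[Rcpp::export]]
int cpp_select_width(NumericVector diffs, int block_size) {
  std::vector<uint32_t> d = nv_to_u32(diffs);
  return select_width_core(d, block_size);
}

// [[Rcpp::export]]
NumericVector cpp_diffs(NumericVector x, int block_size, bool bidirectional) {
  std::vector<uint32_t> xs = nv_to_u32(x);
  std::vector<uint32_t> d = bidirectional ? diffs_bid_core(xs, block_size)
                                          : diffs_uni_core(xs, block_size);
  return u32_to_nv(d);
}

// [[Rcpp::export]]
NumericVector cpp_undiff(NumericVector diffs, double x0, double xB,
                         int block_size, bool bidirectional) {
  std::vector<uint32_t> d = nv_to_u32(diffs);
  std::vector<uint32_t> x =
      bidirectional ? undiff_bid_core(d, (uint32_t)x0, (uint32_t)xB, block_size)
                    : undiff_uni_core(d, (uint32_t)x0, block_size);
  return u32_to_nv(x);
}

// [[Rcpp::export]]
IntegerVector cpp_pack(NumericVector diffs, int width, int block_size,
                       bool columnar, bool bidirectional) {
  std::vector<uint32_t> d = nv_to_u32(diffs);
  uint64_t lim = (width == 32) ? 0x100000000ull : (1ull << width);
  for (uint32_t v : d)
    if ((uint64_t)v >= lim) throw std::runtime_error("width overflow");
  std::vector<uint32_t> w =
      columnar ? pack_columnar_core(d, width, block_size, bidirectional)
               : pack_vertical_core(d, width, block_size);
  return u32_to_iv(w);
}

// [[Rcpp::export]]
NumericVector cpp_unpack(IntegerVector words, int width, int block_size,
                         bool columnar, bool bidirectional) {
  std::vector<uint32_t> d =
      columnar ? unpack_columnar_core(iv_ptr(words), width, block_size,
                                      bidirectional)
               : unpack_vertical_core(iv_ptr(words), width, block_size);
  return u32_to_nv(d);
}

static List stats_list(double value, const DecodeStats &st) {
  return List::create(_["value"] = value,
                      _["group_steps"] = (double)st.group_steps,
                      _["vector_loads"] = (double)st.vector_loads,
                      _["scalar_terms"] = (double)st.scalar_terms);
}

// [[Rcpp::export]]
List cpp_decode_vertical_at(IntegerVector words, int width, int block_size,
                            double x0, int r) {
  DecodeStats st;
  uint32_t v =
      decode_vertical_core(iv_ptr(words), width, block_size, (uint32_t)x0, r, &st);
  return stats_list((double)v, st);
}

// [[Rcpp::export]]
List cpp_decode_columnar_at(IntegerVector words, int width, int block_size,
                            bool bidirectional, double x0, double xB, int r) {
  DecodeStats st;
  uint32_t v = decode_columnar_core(iv_ptr(words), width, block_size,
                                    bidirectional, (uint32_t)x0, (uint32_t)xB,
                                    r, &st);
  return stats_list((double)v, st);
}

// ---- universal-code exports ---------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_ucode_encode(double v, int codec) {
  BitWriter bw;
  ucode_put(bw, codec, (uint64_t)v);
  IntegerVector bits((R_xlen_t)bw.n);
  for (long i = 0; i < bw.n; ++i)
    bits[(R_xlen_t)i] = (int)((bw.w[(size_t)(i >> 5)] >> (i & 31)) & 1u);
  return bits;
}

// [[Rcpp::export]]
List cpp_ucode_decode(IntegerVector bits, int codec) {
  BitWriter bw;
  for (R_xlen_t i = 0; i < bits.size(); ++i) bw.push(bits[i]);
  BitReader br{bw.w.data(), bw.n, 0};
  uint64_t v = ucode_get(br, codec);
  return List::create(_["value"] = (double)v, _["nbits"] = (double)br.pos);
}

// Code lengths for v = 1..vmax (used for the gamma length-law check).
// [[Rcpp::export]]
NumericVector cpp_ucode_lengths(double vmax, int codec) {
  long m = (long)vmax;
  NumericVector out((R_xlen_t)m);
  for (long v = 1; v <= m; ++v) {
    BitWriter bw;
    ucode_put(bw, codec, (uint64_t)v);
    out[(R_xlen_t)(v - 1)] = (double)bw.n;
  }
  return out;
}

// Encode then decode each value; TRUE where the round trip is exact.
// [[Rcpp::export]]
LogicalVector cpp_ucode_roundtrip(NumericVector vs, int codec) {
  LogicalVector ok(vs.size());
  for (R_xlen_t i = 0; i < vs.size(); ++i) {
    BitWriter bw;
    ucode_put(bw, codec, (uint64_t)vs[i]);
    BitReader br{bw.w.data(), bw.n, 0};
    ok[i] = (ucode_get(br, codec) == (uint64_t)vs[i]);
  }
  return ok;
}

// Block of adjacent differences stored as codec(d + 1) (the subtract-1
// modification, applied in reverse at decode time).
// [[Rcpp::export]]
List cpp_encode_block_shifted(NumericVector diffs, int codec) {
  BitWriter bw;
  for (R_xlen_t i = 0; i < diffs.size(); ++i)
    ucode_put(bw, codec, (uint64_t)diffs[i] + 1ull);
  return List::create(_["words"] = u32_to_iv(bw.w), _["nbits"] = (double)bw.n);
}

// [[Rcpp::export]]
double cpp_decode_block_at(IntegerVector words, double nbits, double x0, int r,
                           int codec) {
  BitReader br{iv_ptr(words), (long)nbits, 0};
  uint64_t sum = 0;
  for (int t = 0; t < r; ++t) sum += ucode_get(br, codec) - 1ull;
  return (double)((uint32_t)((uint32_t)x0 + (uint32_t)sum));
}

// ---- container ----------------------------------------------------------

// [[Rcpp::export]]
List cpp_compress(NumericVector offsets, int scheme_id) {
  SchemeInfo si = scheme_info(scheme_id);
  long n = (long)offsets.size();
  if (n < 1) throw std::runtime_error("empty offset array");
  int B = si.B;
  long nb = (n + B - 1) / B;
  uint32_t last = (uint32_t)offsets[(R_xlen_t)(n - 1)];
  std::vector<uint32_t> x((size_t)(B + 1));
  std::vector<uint32_t> words;
  NumericVector ptr((R_xlen_t)(nb + 1)), prefix((R_xlen_t)(nb + 1));
  IntegerVector widths((R_xlen_t)nb);
  BitWriter bw;
  for (long b = 0; b < nb; ++b) {
    for (int t = 0; t <= B; ++t) {
      long idx = b * B + t;
      x[(size_t)t] = (idx < n) ? (uint32_t)offsets[(R_xlen_t)idx] : last;
    }
    prefix[(R_xlen_t)b] = (double)x[0];
    if (si.packed) {
      ptr[(R_xlen_t)b] = (double)(words.size() / 4);
      std::vector<uint32_t> d = si.bidir ? diffs_bid_core(x, B)
                                         : diffs_uni_core(x, B);
      int w = select_width_core(d, B);
      widths[(R_xlen_t)b] = w;
      std::vector<uint32_t> pk =
          si.vertical ? pack_vertical_core(d, w, B)
                      : pack_columnar_core(d, w, B, si.bidir);
      words.insert(words.end(), pk.begin(), pk.end());
    } else {
      ptr[(R_xlen_t)b] = (double)bw.n;
      widths[(R_xlen_t)b] = NA_INTEGER;
      for (int t = 0; t < B; ++t) {
        if (x[(size_t)(t + 1)] < x[(size_t)t])
          throw std::runtime_error("negative difference");
        ucode_put(bw, si.codec,
                  (uint64_t)(x[(size_t)(t + 1)] - x[(size_t)t]) + 1ull);
      }
    }
  }
  prefix[(R_xlen_t)nb] = (double)last;
  if (si.packed) {
    ptr[(R_xlen_t)nb] = (double)(words.size() / 4);
  } else {
    ptr[(R_xlen_t)nb] = (double)bw.n;
    words = bw.w;
  }
  return List::create(_["words"] = u32_to_iv(words), _["ptr"] = ptr,
                      _["prefix"] = prefix, _["widths"] = widths);
}

uint32_t container_lookup_core(const uint32_t *words, long nwords,
                               const double *ptr, const double *prefix,
                               int scheme_id, long n, long i, DecodeStats *st) {
  SchemeInfo si = scheme_info(scheme_id);
  if (i < 0 || i >= n) throw std::runtime_error("index range");
  int B = si.B;
  long b = i / B;
  int r = (int)(i % B);
  if (st) *st = DecodeStats();
  if (r == 0) return (uint32_t)prefix[b];
  uint32_t x0 = (uint32_t)prefix[b];
  uint32_t xB = (uint32_t)prefix[b + 1];
  if (si.packed) {
    long vec0 = (long)ptr[b];
    int width = (int)((ptr[b + 1] - ptr[b]) * 128.0 / B);
    const uint32_t *w = words + 4 * vec0;
    uint32_t v = si.vertical
                     ? decode_vertical_core(w, width, B, x0, r, st)
                     : decode_columnar_core(w, width, B, si.bidir, x0, xB, r, st);
    if (st && st->vec_lo <= st->vec_hi) { st->vec_lo += vec0; st->vec_hi += vec0; }
    return v;
  }
  BitReader br{words, nwords * 32, (long)ptr[b]};
  uint64_t sum = 0;
  for (int t = 0; t < r; ++t) sum += ucode_get(br, si.codec) - 1ull;
  return (uint32_t)(x0 + (uint32_t)sum);
}

// Retrieve offsets[i] and offsets[i+1]. Results are identical for the
// one-pass and two-pass procedures; one-pass counts each vector shared by
// the two columns once (a merged procedure reuses loaded registers), and for
// universal codes decodes the second value on the same serial scan.
static void container_pair_core(const uint32_t *words, long nwords,
                                const double *ptr, const double *prefix,
                                int scheme_id, long n, long i, bool onepass,
                                uint32_t *v1, uint32_t *v2, long *loads,
                                long *steps) {
  if (i < 0 || i >= n - 1) throw std::runtime_error("index range");
  SchemeInfo si = scheme_info(scheme_id);
  DecodeStats s1, s2;
  if (!si.packed && onepass) {
    int B = si.B;
    long b = i / B;
    int r = (int)(i % B);
    if (r == B - 1 || r == 0) {
      *v1 = container_lookup_core(words, nwords, ptr, prefix, scheme_id, n, i, &s1);
      *v2 = container_lookup_core(words, nwords, ptr, prefix, scheme_id, n, i + 1, &s2);
    } else {
      uint32_t x0 = (uint32_t)prefix[b];
      BitReader br{words, nwords * 32, (long)ptr[b]};
      uint64_t sum = 0;
      for (int t = 0; t < r; ++t) sum += ucode_get(br, si.codec) - 1ull;
      *v1 = (uint32_t)(x0 + (uint32_t)sum);
      sum += ucode_get(br, si.codec) - 1ull;
      *v2 = (uint32_t)(x0 + (uint32_t)sum);
    }
    if (loads) *loads = 0;
    if (steps) *steps = 0;
    return;
  }
  *v1 = container_lookup_core(words, nwords, ptr, prefix, scheme_id, n, i, &s1);
  *v2 = container_lookup_core(words, nwords, ptr, prefix, scheme_id, n, i + 1, &s2);
  if (steps) *steps = s1.group_steps + s2.group_steps;
  if (loads) {
    long l1 = (s1.vec_lo <= s1.vec_hi) ? s1.vec_hi - s1.vec_lo + 1 : 0;
    long l2 = (s2.vec_lo <= s2.vec_hi) ? s2.vec_hi - s2.vec_lo + 1 : 0;
    if (!onepass) {
      *loads = l1 + l2;
    } else {
      long overlap = 0;
      if (l1 > 0 && l2 > 0) {
        long lo = std::max(s1.vec_lo, s2.vec_lo);
        long hi = std::min(s1.vec_hi, s2.vec_hi);
        if (hi >= lo) overlap = hi - lo + 1;
      }
      *loads = l1 + l2 - overlap;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_lookup_many(IntegerVector words, NumericVector ptr,
                              NumericVector prefix, int scheme_id, double n,
                              NumericVector idx) {
  NumericVector out(idx.size());
  const uint32_t *w = iv_ptr(words);
  for (R_xlen_t q = 0; q < idx.size(); ++q)
    out[q] = (double)container_lookup_core(w, (long)words.size(), REAL(ptr),
                                           REAL(prefix), scheme_id, (long)n,
                                           (long)idx[q], nullptr);
  return out;
}

// [[Rcpp::export]]
List cpp_lookup_stats(IntegerVector words, NumericVector ptr,
                      NumericVector prefix, int scheme_id, double n, double i) {
  DecodeStats st;
  uint32_t v = container_lookup_core(iv_ptr(words), (long)words.size(),
                                     REAL(ptr), REAL(prefix), scheme_id,
                                     (long)n, (long)i, &st);
  return stats_list((double)v, st);
}

// [[Rcpp::export]]
List cpp_pair_many(IntegerVector words, NumericVector ptr, NumericVector prefix,
                   int scheme_id, double n, NumericVector idx, bool onepass) {
  NumericVector first(idx.size()), second(idx.size());
  const uint32_t *w = iv_ptr(words);
  for (R_xlen_t q = 0; q < idx.size(); ++q) {
    uint32_t v1, v2;
    container_pair_core(w, (long)words.size(), REAL(ptr), REAL(prefix),
                        scheme_id, (long)n, (long)idx[q], onepass, &v1, &v2,
                        nullptr, nullptr);
    first[q] = (double)v1;
    second[q] = (double)v2;
  }
  return List::create(_["first"] = first, _["second"] = second);
}

// [[Rcpp::export]]
List cpp_pair_stats(IntegerVector words, NumericVector ptr, NumericVector prefix,
                    int scheme_id, double n, double i, bool onepass) {
  uint32_t v1, v2;
  long loads = 0, steps = 0;
  container_pair_core(iv_ptr(words), (long)words.size(), REAL(ptr),
                      REAL(prefix), scheme_id, (long)n, (long)i, onepass, &v1,
                      &v2, &loads, &steps);
  return List::create(_["first"] = (double)v1, _["second"] = (double)v2,
                      _["vector_loads"] = (double)loads,
                      _["group_steps"] = (double)steps);
}

static String hex64(uint64_t v) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
  return String(buf);
}

// Benchmark inner loop: retrieve the adjacent pair for every query index and
// fold both values into a 64-bit additive checksum.
// [[Rcpp::export]]
String cpp_pair_checksum(IntegerVector words, NumericVector ptr,
                         NumericVector prefix, int scheme_id, double n,
                         NumericVector idx, bool onepass) {
  uint64_t ck = 0;
  const uint32_t *w = iv_ptr(words);
  for (R_xlen_t q = 0; q < idx.size(); ++q) {
    uint32_t v1, v2;
    container_pair_core(w, (long)words.size(), REAL(ptr), REAL(prefix),
                        scheme_id, (long)n, (long)idx[q], onepass, &v1, &v2,
                        nullptr, nullptr);
    ck += (uint64_t)v1 + (uint64_t)v2;
  }
  return hex64(ck);
}

// Same protocol against the raw (uncompressed) offset array.
// [[Rcpp::export]]
String cpp_uncompressed_pair_checksum(NumericVector offsets, NumericVector idx) {
  uint64_t ck = 0;
  long n = (long)offsets.size();
  for (R_xlen_t q = 0; q < idx.size(); ++q) {
    long i = (long)idx[q];
    if (i < 0 || i >= n - 1) throw std::runtime_error("index range");
    ck += (uint64_t)(uint32_t)offsets[(R_xlen_t)i] +
          (uint64_t)(uint32_t)offsets[(R_xlen_t)(i + 1)];
  }
  return hex64(ck);
}

// Loop overhead surrogate: iterate the query stream and checksum the indices
// themselves, without any decoding.
// [[Rcpp::export]]
String cpp_overhead_checksum(NumericVector idx) {
  uint64_t ck = 0;
  for (R_xlen_t q = 0; q < idx.size(); ++q) ck += (uint64_t)idx[q];
  return hex64(ck);
}
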