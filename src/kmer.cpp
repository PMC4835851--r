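// Lookup hash table construction: count k-mers, prefix-sum into the offset
// array, then fill the positions array in a second scan.  Positions are
// stored ascending within each k-mer list because the scan is left to right.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static void base_lut(int8_t *lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  lut['A'] = lut['a'] = 0;
  lut['C'] = lut['c'] = 1;
  lut['G'] = lut['g'] = 2;
  lut['T'] = lut['t'] = 3;
}

// [[Rcpp::export]]
List cpp_build_hash(std::string seq, int k, int sampling) {
  int8_t lut[256];
  base_lut(lut);
  long n = (long)seq.size();
  long ncodes = 1L << (2 * k);
  std::vector<uint32_t> counts((size_t)ncodes, 0u);
  for (long p = 0; p + k <= n; p += sampling) {
    long code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int8_t c = lut[(uint8_t)seq[(size_t)(p + j)]];
      if (c < 0) { ok = false; break; }
      code = (code << 2) | c;
    }
    if (ok) counts[(size_t)code]++;
  }
  NumericVector offsets((R_xlen_t)(ncodes + 1));
  uint64_t cum = 0;
  std::vector<uint32_t> cursor((size_t)ncodes);
  offsets[0] = 0.0;
  for (long m = 0; m < ncodes; ++m) {
    cursor[(size_t)m] = (uint32_t)cum;
    cum += counts[(size_t)m];
    offsets[(R_xlen_t)(m + 1)] = (double)cum;
  }
  if (cum > 0x7FFFFFFFull) stop("too many positions for a single table");
  IntegerVector positions((R_xlen_t)cum);
  for (long p = 0; p + k <= n; p += sampling) {
    long code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int8_t c = lut[(uint8_t)seq[(size_t)(p + j)]];
      if (c < 0) { ok = false; break; }
      code = (code << 2) | c;
    }
    if (ok) positions[(R_xlen_t)cursor[(size_t)code]++] = (int)p;
  }
  return List::create(_["offsets"] = offsets, _["positions"] = positions);
}

// Base-4 codes for a vector of k-mer strings; NA where any base is not ACGT.
// [[Rcpp::export]]
NumericVector cpp_encode_kmers(CharacterVector kmers) {
  int8_t lut[256];
  base_lut(lut);
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    double code = 0;
    bool ok = true;
    for (const char *p = s; *p; ++p) {
      int8_t c = lut[(uint8_t)*p];
      if (c < 0) { ok = false; break; }
      code = code * 4 + c;
    }
    out[i] = ok ? code : NA_REAL;
  }
  return out;
}
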