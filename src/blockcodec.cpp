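// Block codecs: cyclic difference schemes, bit-width selection, and the
// vertical and columnar packing layouts with random-access decode.
//
// Conventions (fixed across the package):
//   * a "vector" is four consecutive 32-bit words; lane l of vector v is
//     word 4*v + l;
//   * within a lane, packed values are laid down least-significant-bits
//     first; a value straddling a 32-bit word boundary puts its low bits in
//     the earlier vector's lane and the remaining high bits at bit 0 of the
//     next vector's same lane;
//   * block positions r run 1..B; difference index i runs 0..B-1.

#include "codec.h"

int bits_needed(uint32_t v) {
  int b = 0;
  while (v) { ++b; v >>= 1; }
  return b;
}

// Smallest allowed uniform width for a block: even for B = 64 (and any B not
// a multiple-of-4 special case), multiples of 4 for B = 32, unrestricted for
// B >= 128 (BP128-style blocks align at 128 bits for every width).
int select_width_core(const std::vector<uint32_t> &d, int B) {
  uint32_t mx = 0;
  for (uint32_t v : d)
    if (v > mx) mx = v;
  int b = bits_needed(mx);
  if (b == 0) return 0;
  int step = (B >= 128) ? 1 : (B == 64 ? 2 : 4);
  int w = ((b + step - 1) / step) * step;
  return w > 32 ? 32 : w;
}

// ---- lane-level bit I/O --------------------------------------------------

static inline uint32_t lane_read(const uint32_t *w, int lane, long off,
                                 int width) {
  if (width == 0) return 0u;
  long wi = 4 * (off / 32) + lane;
  int bit = (int)(off % 32);
  uint64_t v = (uint64_t)w[(size_t)wi] >> bit;
  if (bit + width > 32) v |= (uint64_t)w[(size_t)(wi + 4)] << (32 - bit);
  uint64_t mask = (width == 32) ? 0xFFFFFFFFull : ((1ull << width) - 1);
  return (uint32_t)(v & mask);
}

static inline void lane_write(std::vector<uint32_t> &w, int lane, long off,
                              int width, uint32_t val) {
  if (width == 0) return;
  long wi = 4 * (off / 32) + lane;
  int bit = (int)(off % 32);
  w[(size_t)wi] |= (uint32_t)(((uint64_t)val << bit) & 0xFFFFFFFFull);
  if (bit + width > 32)
    w[(size_t)(wi + 4)] |= (uint32_t)((uint64_t)val >> (32 - bit));
}

// ---- difference schemes --------------------------------------------------

// Unidirectional lane-cyclic differences: d_i = x_{i+1} - x_{i-3}, except the
// first row (i < 4) where differences are taken relative to x_0.
std::vector<uint32_t> diffs_uni_core(const std::vector<uint32_t> &x, int B) {
  std::vector<uint32_t> d((size_t)B);
  for (int i = 0; i < B; ++i) {
    uint32_t lo = (i < 4) ? x[0] : x[(size_t)(i - 3)];
    uint32_t hi = x[(size_t)(i + 1)];
    if (hi < lo) throw std::runtime_error("negative difference");
    d[(size_t)i] = hi - lo;
  }
  return d;
}

std::vector<uint32_t> undiff_uni_core(const std::vector<uint32_t> &d,
                                      uint32_t x0, int B) {
  std::vector<uint32_t> x((size_t)(B + 1));
  x[0] = x0;
  uint32_t lane[4] = {x0, x0, x0, x0};
  for (int i = 0; i < B; ++i) {
    uint32_t v = lane[i & 3] + d[(size_t)i];
    x[(size_t)(i + 1)] = v;
    lane[i & 3] = v;
  }
  return x;
}

// Bidirectional: first half-block as the unidirectional scheme from x_0;
// second half encodes the mirrored series y_s = x_B - x_{B-s} (s = 0..B/2)
// with the same lane-cyclic rule, so reconstruction for r > B/2 subtracts a
// lane-cyclic cumulative sum from x_B.  x_{B/2} is reachable from both ends.
std::vector<uint32_t> diffs_bid_core(const std::vector<uint32_t> &x, int B) {
  int H = B / 2;
  std::vector<uint32_t> d((size_t)B);
  for (int i = 0; i < H; ++i) {
    uint32_t lo = (i < 4) ? x[0] : x[(size_t)(i - 3)];
    uint32_t hi = x[(size_t)(i + 1)];
    if (hi < lo) throw std::runtime_error("negative difference");
    d[(size_t)i] = hi - lo;
  }
  uint32_t xB = x[(size_t)B];
  for (int j = 0; j < H; ++j) {
    // e_j = y_{j+1} - y_{j-3}; y_s = xB - x_{B-s}
    uint32_t yhi = xB - x[(size_t)(B - 1 - j)];
    uint32_t ylo = (j < 4) ? 0u : xB - x[(size_t)(B + 3 - j)];
    if (x[(size_t)(B - 1 - j)] > xB || yhi < ylo)
      throw std::runtime_error("negative difference");
    d[(size_t)(H + j)] = yhi - ylo;
  }
  return d;
}

std::vector<uint32_t> undiff_bid_core(const std::vector<uint32_t> &d,
                                      uint32_t x0, uint32_t xB, int B) {
  int H = B / 2;
  std::vector<uint32_t> x((size_t)(B + 1));
  x[0] = x0;
  x[(size_t)B] = xB;
  uint32_t lane[4] = {x0, x0, x0, x0};
  for (int i = 0; i < H; ++i) {
    uint32_t v = lane[i & 3] + d[(size_t)i];
    x[(size_t)(i + 1)] = v;
    lane[i & 3] = v;
  }
  uint32_t ylane[4] = {0u, 0u, 0u, 0u};
  for (int j = 0; j < H; ++j) {
    uint32_t y = ylane[j & 3] + d[(size_t)(H + j)];
    if (B - 1 - j >= H)  // x_{B/2} already set from the forward pass
      x[(size_t)(B - 1 - j)] = xB - y;
    ylane[j & 3] = y;
  }
  return x;
}

// ---- vertical layout -----------------------------------------------------
// Entry i sits in lane i mod 4, lane-bit offset (i div 4) * width.

std::vector<uint32_t> pack_vertical_core(const std::vector<uint32_t> &d,
                                         int width, int B) {
  std::vector<uint32_t> w((size_t)((long)B * width / 32), 0u);
  for (int i = 0; i < B; ++i)
    lane_write(w, i & 3, (long)(i >> 2) * width, width, d[(size_t)i]);
  return w;
}

std::vector<uint32_t> unpack_vertical_core(const uint32_t *w, int width,
                                           int B) {
  std::vector<uint32_t> d((size_t)B);
  for (int i = 0; i < B; ++i)
    d[(size_t)i] = lane_read(w, i & 3, (long)(i >> 2) * width, width);
  return d;
}

// Serial group-wise decode: step g extracts row g of all four lanes (one
// shift/mask/add cycle) and updates four running sums.  ceil(r/4) steps put
// x_r in lane (r-1) mod 4.
uint32_t decode_vertical_core(const uint32_t *w, int width, int B, uint32_t x0,
                              int r, DecodeStats *st) {
  if (r < 1 || r > B) throw std::runtime_error("index range");
  int G = (r + 3) / 4;
  uint32_t cum[4] = {0u, 0u, 0u, 0u};
  for (int g = 0; g < G; ++g)
    for (int l = 0; l < 4; ++l)
      cum[l] += lane_read(w, l, (long)g * width, width);
  if (st) {
    st->group_steps = G;
    st->scalar_terms = 1;
    if (width > 0) {
      st->vec_lo = 0;
      st->vec_hi = ((long)G * width - 1) / 32;
      st->vector_loads = st->vec_hi + 1;
    } else {
      st->vec_lo = 0; st->vec_hi = -1; st->vector_loads = 0;
    }
  }
  return x0 + cum[(r - 1) & 3];
}

// ---- columnar layout -----------------------------------------------------
// Groups of four rows of one column are packed contiguously per lane.  Group
// sequence (lane-bit offset = seq * width):
//   unidirectional: column c occupies group indices c*(B/16) .. c*(B/16)+B/16-1;
//     entry (c, row j) = d_{c + 4j}, j = 0..B/4-1.
//   bidirectional (half H = B/2): first half columns at 0..4*(H/16)-1 as above
//     over d_0..d_{H-1}; second half columns follow at 4*(H/16).. over the
//     mirrored differences d_H..d_{B-1}.

static inline int col_groups(int B, bool bidir) {
  return (bidir ? B / 2 : B) / 16;  // groups per column (per half if bidir)
}

static int columnar_diff_index(int B, bool bidir, int s, int lam) {
  int Gc = col_groups(B, bidir);
  int half = 0;
  if (bidir && s >= 4 * Gc) { half = 1; s -= 4 * Gc; }
  int c = s / Gc, g = s % Gc;
  return half * (B / 2) + c + 4 * (4 * g + lam);
}

std::vector<uint32_t> pack_columnar_core(const std::vector<uint32_t> &d,
                                         int width, int B, bool bidir) {
  std::vector<uint32_t> w((size_t)((long)B * width / 32), 0u);
  int ngroups = B / 4;
  for (int s = 0; s < ngroups; ++s)
    for (int lam = 0; lam < 4; ++lam)
      lane_write(w, lam, (long)s * width, width,
                 d[(size_t)columnar_diff_index(B, bidir, s, lam)]);
  return w;
}

std::vector<uint32_t> unpack_columnar_core(const uint32_t *w, int width, int B,
                                           bool bidir) {
  std::vector<uint32_t> d((size_t)B);
  int ngroups = B / 4;
  for (int s = 0; s < ngroups; ++s)
    for (int lam = 0; lam < 4; ++lam)
      d[(size_t)columnar_diff_index(B, bidir, s, lam)] =
          lane_read(w, lam, (long)s * width, width);
  return d;
}

// Decode x_r reading only the target's column.  Each group step loads four
// column entries and parallel-adds them onto the previous group's sums; the
// resulting word array W[4g+l] holds partial column sums, and x_r needs at
// most four scalar terms from it.
uint32_t decode_columnar_core(const uint32_t *w, int width, int B, bool bidir,
                              uint32_t x0, uint32_t xB, int r,
                              DecodeStats *st) {
  if (r < 1 || r > B) throw std::runtime_error("index range");
  if (st) { st->group_steps = 0; st->vector_loads = 0; st->scalar_terms = 0;
            st->vec_lo = 0; st->vec_hi = -1; }
  int H = B / 2;
  if (bidir && r == B) return xB;  // the next block's stored prefix sum
  if (width == 0) return x0;       // all-zero block: every value equals x_0
  int Gc = col_groups(B, bidir);
  int delta, c, J;
  long s0;
  bool second = false;
  if (!bidir) {
    delta = r - 1;
  } else if (r <= H) {
    delta = r - 1;
  } else {
    delta = B - 1 - r;
    second = true;
  }
  c = delta & 3;
  J = delta >> 2;  // last row of the column that is needed
  s0 = (long)c * Gc + (second ? 4L * Gc : 0L);
  int G = J / 4 + 1;  // group steps
  uint32_t cum[4] = {0u, 0u, 0u, 0u};
  // W[4g + l] as in the final-parallel-addition word array
  uint32_t W[16];
  for (int g = 0; g < G; ++g)
    for (int l = 0; l < 4; ++l) {
      cum[l] += lane_read(w, l, (s0 + g) * (long)width, width);
      W[4 * g + l] = cum[l];
    }
  int m = J & 3, Gl = J >> 2;
  uint32_t sum = 0;
  int terms = 0;
  for (int l = 0; l <= m; ++l) { sum += W[4 * Gl + l]; ++terms; }
  if (Gl > 0)
    for (int l = m + 1; l < 4; ++l) { sum += W[4 * (Gl - 1) + l]; ++terms; }
  if (st) {
    st->group_steps = G;
    st->scalar_terms = terms;
    st->vec_lo = (s0 * width) / 32;
    st->vec_hi = ((s0 + G) * (long)width - 1) / 32;
    st->vector_loads = st->vec_hi - st->vec_lo + 1;
  }
  return second ? (xB - sum) : (x0 + sum);
}
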