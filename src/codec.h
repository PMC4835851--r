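#ifndef OFFSETPACK_CODEC_H
#define OFFSETPACK_CODEC_H

#include <cstdint>
#include <vector>
#include <stdexcept>

// Decode instrumentation. group_steps counts shift/mask/add cycles over groups
// of four lane entries; vector_loads counts distinct four-word vectors read.
// vec_lo/vec_hi is the (closed) interval of vector indices touched, local to
// the block; empty when vec_lo > vec_hi.
struct DecodeStats {
  long group_steps = 0;
  long vector_loads = 0;
  int scalar_terms = 0;
  long vec_lo = 0, vec_hi = -1;
};

int bits_needed(uint32_t v);
int select_width_core(const std::vector<uint32_t> &d, int block_size);

// Difference transforms. x has B+1 values (x_0..x_B); returns B differences.
std::vector<uint32_t> diffs_uni_core(const std::vector<uint32_t> &x, int B);
std::vector<uint32_t> undiff_uni_core(const std::vector<uint32_t> &d,
                                      uint32_t x0, int B);
std::vector<uint32_t> diffs_bid_core(const std::vector<uint32_t> &x, int B);
std::vector<uint32_t> undiff_bid_core(const std::vector<uint32_t> &d,
                                      uint32_t x0, uint32_t xB, int B);

std::vector<uint32_t> pack_vertical_core(const std::vector<uint32_t> &d,
                                         int width, int B);
std::vector<uint32_t> unpack_vertical_core(const uint32_t *w, int width, int B);
std::vector<uint32_t> pack_columnar_core(const std::vector<uint32_t> &d,
                                         int width, int B, bool bidir);
std::vector<uint32_t> unpack_columnar_core(const uint32_t *w, int width, int B,
                                           bool bidir);

uint32_t decode_vertical_core(const uint32_t *w, int width, int B, uint32_t x0,
                              int r, DecodeStats *st);
uint32_t decode_columnar_core(const uint32_t *w, int width, int B, bool bidir,
                              uint32_t x0, uint32_t xB, int r, DecodeStats *st);

// ---- universal codes ----------------------------------------------------
struct BitWriter {
  std::vector<uint32_t> w;
  long n = 0;
  void push(int b) {
    if ((n >> 5) >= (long)w.size()) w.push_back(0u);
    if (b) w[(size_t)(n >> 5)] |= (1u << (n & 31));
    ++n;
  }
};

struct BitReader {
  const uint32_t *w;
  long nbits;  // total readable bits (for bounds checking)
  long pos;
  int next() {
    if (pos >= nbits) throw std::runtime_error("corrupt code: bitstream exhausted");
    int b = (int)((w[(size_t)(pos >> 5)] >> (pos & 31)) & 1u);
    ++pos;
    return b;
  }
};

// codec ids for universal codes
enum UCodec { UC_GAMMA = 0, UC_DELTA = 1, UC_FIBONACCI = 2 };

void ucode_put(BitWriter &bw, int codec, uint64_t v);
uint64_t ucode_get(BitReader &br, int codec);

// ---- container schemes --------------------------------------------------
// scheme ids: 0 bp64v, 1 bp64c, 2 bp32c, 3 gamma, 4 delta, 5 fibonacci
struct SchemeInfo {
  int B;
  bool packed;
  bool vertical;
  bool bidir;
  int codec;  // UCodec for universal schemes
};
SchemeInfo scheme_info(int scheme_id);

uint32_t container_lookup_core(const uint32_t *words, long nwords,
                               const double *ptr, const double *prefix,
                               int scheme_id, long n, long i, DecodeStats *st);

#endif
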