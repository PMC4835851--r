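// Universal (self-delimiting) integer codes: Elias gamma, Elias delta, and
// Fibonacci (Zeckendorf) coding over an LSB-first bitstream.
//
// gamma(v), v >= 1: (c-1) zero bits followed by the c bits of v starting at
//   its most significant 1; total 2c-1 bits where c = bits(v).
// delta(v): gamma(c) followed by the (c-1) bits of v below its MSB.
// fibonacci(v): Zeckendorf decomposition over F = 1, 2, 3, 5, 8, ...,
//   emitted lowest Fibonacci number first, terminated by an appended 1 so
//   every codeword ends in "11".

#include "codec.h"

static int bits64(uint64_t v) {
  int b = 0;
  while (v) { ++b; v >>= 1; }
  return b;
}

static void gamma_put(BitWriter &bw, uint64_t v) {
  if (v == 0) throw std::runtime_error("requires shift encoding");
  int c = bits64(v);
  for (int i = 0; i < c - 1; ++i) bw.push(0);
  for (int i = c - 1; i >= 0; --i) bw.push((int)((v >> i) & 1));
}

static uint64_t gamma_get(BitReader &br) {
  int z = 0;
  while (br.next() == 0) {
    if (++z > 63) throw std::runtime_error("corrupt code");
  }
  uint64_t v = 1;
  for (int i = 0; i < z; ++i) v = (v << 1) | (uint64_t)br.next();
  return v;
}

static void delta_put(BitWriter &bw, uint64_t v) {
  if (v == 0) throw std::runtime_error("requires shift encoding");
  int c = bits64(v);
  gamma_put(bw, (uint64_t)c);
  for (int i = c - 2; i >= 0; --i) bw.push((int)((v >> i) & 1));
}

static uint64_t delta_get(BitReader &br) {
  int c = (int)gamma_get(br);
  if (c < 1 || c > 64) throw std::runtime_error("corrupt code");
  uint64_t v = 1;
  for (int i = 0; i < c - 1; ++i) v = (v << 1) | (uint64_t)br.next();
  return v;
}

// Fibonacci numbers used for coding: F[0]=1, F[1]=2, F[2]=3, F[3]=5, ...
static const int NFIB = 91;
static uint64_t FIB[NFIB];
static bool fib_ready = false;
static void fib_init() {
  if (fib_ready) return;
  FIB[0] = 1;
  FIB[1] = 2;
  for (int i = 2; i < NFIB; ++i) FIB[i] = FIB[i - 1] + FIB[i - 2];
  fib_ready = true;
}

static void fib_put(BitWriter &bw, uint64_t v) {
  if (v == 0) throw std::runtime_error("requires shift encoding");
  fib_init();
  int hi = 0;
  while (hi + 1 < NFIB && FIB[hi + 1] <= v) ++hi;
  std::vector<char> use((size_t)(hi + 1), 0);
  uint64_t rem = v;
  for (int j = hi; j >= 0; --j)
    if (FIB[j] <= rem) { use[(size_t)j] = 1; rem -= FIB[j]; }
  for (int j = 0; j <= hi; ++j) bw.push(use[(size_t)j]);
  bw.push(1);  // terminator: together with bit `hi` forms the trailing "11"
}

static uint64_t fib_get(BitReader &br) {
  fib_init();
  uint64_t v = 0;
  int prev = 0, j = 0;
  for (;;) {
    int b = br.next();
    if (b && prev) return v;  // second of two consecutive 1s is the terminator
    if (b) { v += FIB[j]; prev = 1; } else prev = 0;
    if (++j >= NFIB) throw std::runtime_error("corrupt code");
  }
}

void ucode_put(BitWriter &bw, int codec, uint64_t v) {
  switch (codec) {
    case UC_GAMMA: gamma_put(bw, v); break;
    case UC_DELTA: delta_put(bw, v); break;
    case UC_FIBONACCI: fib_put(bw, v); break;
    default: throw std::runtime_error("unknown codec");
  }
}

uint64_t ucode_get(BitReader &br, int codec) {
  switch (codec) {
    case UC_GAMMA: return gamma_get(br);
    case UC_DELTA: return delta_get(br);
    case UC_FIBONACCI: return fib_get(br);
    default: throw std::runtime_error("unknown codec");
  }
}
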