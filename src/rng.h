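#ifndef ENEMYFIX_RNG_H
#define ENEMYFIX_RNG_H

#include <cstdint>
#include <cmath>

// PCG32 (O'Neill): small, fast, reproducible across platforms.  Each
// simulation owns its own generator; the (seed, stream) pair is supplied
// from R so that every trial is individually re-runnable.
struct Pcg32 {
  uint64_t state;
  uint64_t inc;

  Pcg32(uint64_t initstate, uint64_t initseq) {
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }

  inline uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }

  // uniform double in [0, 1) with 32 bits of resolution
  inline double unif() {
    return next() * 2.3283064365386963e-10;
  }

  // unbiased-enough integer in [0, n) (Lemire multiply-shift)
  inline uint32_t below(uint32_t n) {
    return (uint32_t)(((uint64_t)next() * (uint64_t)n) >> 32);
  }

  // exponential waiting time with given rate
  inline double rexp(double rate) {
    double u = unif();
    // guard against log(0)
    if (u <= 0.0) u = 2.3283064365386963e-10;
    return -std::log(u) / rate;
  }
};

#endif
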