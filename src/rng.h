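#ifndef CRITSAMPLE_RNG_H
#define CRITSAMPLE_RNG_H

#include <cstdint>

// xoshiro256++ with splitmix64 seeding; simulation RNG independent of R's
// global stream so rasters are bit-reproducible given (topology, seed).
struct Xoshiro256pp {
    uint64_t s[4];

    explicit Xoshiro256pp(uint64_t seed) {
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {
            x += 0x9e3779b97f4a7c15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
            z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
            s[i] = z ^ (z >> 31);
        }
    }

    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }

    inline uint64_t next() {
        const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0];
        s[3] ^= s[1];
        s[1] ^= s[2];
        s[0] ^= s[3];
        s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return result;
    }

    // uniform double in [0, 1)
    inline double unif() {
        return (next() >> 11) * 0x1.0p-53;
    }

    // uniform integer in [0, n)
    inline int below(int n) {
        return (int)(unif() * n);
    }
};

#endif
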