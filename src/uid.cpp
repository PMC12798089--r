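#include <Rcpp.h>
#include <cstdint>
#include <cstdio>

using namespace Rcpp;

// 128-bit content digest built from two independent 64-bit FNV-1a lanes
// (distinct offset bases). Deterministic across platforms, fixed length,
// collision-safe at network scale (birthday bound ~2^-64 per pair).
// [[Rcpp::export]]
CharacterVector fnv1a128_hex(CharacterVector x) {
  const uint64_t PRIME = 1099511628211ULL;
  const uint64_t BASIS1 = 14695981039346656037ULL;
  const uint64_t BASIS2 = BASIS1 ^ 0x9e3779b97f4a7c15ULL;
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[33];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) {
      out[i] = NA_STRING;
      continue;
    }
    const char* s = Rf_translateCharUTF8(STRING_ELT(x, i));
    uint64_t h1 = BASIS1, h2 = BASIS2;
    for (const unsigned char* p = (const unsigned char*)s; *p; ++p) {
      h1 ^= (uint64_t)(*p); h1 *= PRIME;
      h2 ^= (uint64_t)(*p); h2 *= PRIME;
    }
    std::snprintf(buf, sizeof(buf), "%016llx%016llx",
                  (unsigned long long)h1, (unsigned long long)h2);
    out[i] = buf;
  }
  return out;
}
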