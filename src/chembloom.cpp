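#include <Rcpp.h>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// 64-bit hash values cross the R boundary as 8-byte big-endian raw blocks:
// R doubles cannot hold all uint64 values exactly, raw vectors can.

static inline uint64_t u64_from_raw(const Rbyte *p) {
    uint64_t v = 0;
    for (int i = 0; i < 8; ++i) v = (v << 8) | (uint64_t)p[i];
    return v;
}

static inline void u64_to_raw(uint64_t v, Rbyte *p) {
    for (int i = 7; i >= 0; --i) { p[i] = (Rbyte)(v & 0xff); v >>= 8; }
}

static const uint64_t FNV_PRIME = 1099511628211ULL;

static inline uint64_t fnv1a64(const char *data, size_t len, uint64_t basis,
                               bool reverse) {
    uint64_t h = basis;
    for (size_t i = 0; i < len; ++i) {
        h ^= (uint64_t)(unsigned char)data[reverse ? len - 1 - i : i];
        h *= FNV_PRIME;  // mod 2^64 by unsigned wraparound
    }
    return h;
}

// reverse = consume bytes back-to-front: the second universal hash walks
// the string in the opposite direction, which decorrelates it from the
// forward hash (two FNV-1a runs differing only in offset basis propagate a
// near-additive difference and stay correlated for equal-length inputs).
// [[Rcpp::export]]
RawVector cpp_fnv1a64(CharacterVector x, RawVector basis,
                      bool reverse = false) {
    if (basis.size() != 8) stop("basis must be 8 bytes");
    uint64_t b = u64_from_raw(&basis[0]);
    R_xlen_t n = x.size();
    RawVector out(8 * n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *s = Rf_translateCharUTF8(STRING_ELT(x, i));
        u64_to_raw(fnv1a64(s, strlen(s), b, reverse), &out[8 * i]);
    }
    return out;
}

// splitmix64 finalizer: a bijective 64-bit avalanche mix. FNV-1a's low
// output bits are XOR-linear in the input bytes' low bits (the trailing
// multiply by an odd prime fixes bit 0), so two FNV runs over the same
// bytes agree on that linear structure whatever their basis or byte order;
// finalizing the second hash removes the shared structure.
// [[Rcpp::export]]
RawVector cpp_mix64(RawVector x) {
    R_xlen_t n = x.size() / 8;
    RawVector out(x.size());
    for (R_xlen_t i = 0; i < n; ++i) {
        uint64_t z = u64_from_raw(&x[8 * i]);
        z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
        z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
        z = z ^ (z >> 31);
        u64_to_raw(z, &out[8 * i]);
    }
    return out;
}

/* ---- MD5 (RFC 1321) ------------------------------------------------- */

typedef struct { uint32_t a, b, c, d; uint64_t len; unsigned char buf[64]; } md5_ctx;

static const uint32_t MD5_K[64] = {
    0xd76aa478,0xe8c7b756,0x242070db,0xc1bdceee,0xf57c0faf,0x4787c62a,
    0xa8304613,0xfd469501,0x698098d8,0x8b44f7af,0xffff5bb1,0x895cd7be,
    0x6b901122,0xfd987193,0xa679438e,0x49b40821,0xf61e2562,0xc040b340,
    0x265e5a51,0xe9b6c7aa,0xd62f105d,0x02441453,0xd8a1e681,0xe7d3fbc8,
    0x21e1cde6,0xc33707d6,0xf4d50d87,0x455a14ed,0xa9e3e905,0xfcefa3f8,
    0x676f02d9,0x8d2a4c8a,0xfffa3942,0x8771f681,0x6d9d6122,0xfde5380c,
    0xa4beea44,0x4bdecfa9,0xf6bb4b60,0xbebfbc70,0x289b7ec6,0xeaa127fa,
    0xd4ef3085,0x04881d05,0xd9d4d039,0xe6db99e5,0x1fa27cf8,0xc4ac5665,
    0xf4292244,0x432aff97,0xab9423a7,0xfc93a039,0x655b59c3,0x8f0ccc92,
    0xffeff47d,0x85845dd1,0x6fa87e4f,0xfe2ce6e0,0xa3014314,0x4e0811a1,
    0xf7537e82,0xbd3af235,0x2ad7d2bb,0xeb86d391};

static const int MD5_S[64] = {
    7,12,17,22,7,12,17,22,7,12,17,22,7,12,17,22,
    5, 9,14,20,5, 9,14,20,5, 9,14,20,5, 9,14,20,
    4,11,16,23,4,11,16,23,4,11,16,23,4,11,16,23,
    6,10,15,21,6,10,15,21,6,10,15,21,6,10,15,21};

static inline uint32_t rotl32(uint32_t x, int c) { return (x << c) | (x >> (32 - c)); }

static void md5_block(md5_ctx *ctx, const unsigned char *p) {
    uint32_t M[16];
    for (int i = 0; i < 16; ++i)
        M[i] = (uint32_t)p[4*i] | ((uint32_t)p[4*i+1] << 8) |
               ((uint32_t)p[4*i+2] << 16) | ((uint32_t)p[4*i+3] << 24);
    uint32_t A = ctx->a, B = ctx->b, C = ctx->c, D = ctx->d;
    for (int i = 0; i < 64; ++i) {
        uint32_t F; int g;
        if (i < 16)      { F = (B & C) | (~B & D);        g = i; }
        else if (i < 32) { F = (D & B) | (~D & C);        g = (5*i + 1) % 16; }
        else if (i < 48) { F = B ^ C ^ D;                 g = (3*i + 5) % 16; }
        else             { F = C ^ (B | ~D);              g = (7*i) % 16; }
        F = F + A + MD5_K[i] + M[g];
        A = D; D = C; C = B;
        B = B + rotl32(F, MD5_S[i]);
    }
    ctx->a += A; ctx->b += B; ctx->c += C; ctx->d += D;
}

static void md5_init(md5_ctx *ctx) {
    ctx->a = 0x67452301; ctx->b = 0xefcdab89;
    ctx->c = 0x98badcfe; ctx->d = 0x10325476;
    ctx->len = 0;
}

static void md5_update(md5_ctx *ctx, const unsigned char *data, size_t n) {
    size_t have = (size_t)(ctx->len % 64);
    ctx->len += n;
    if (have) {
        size_t need = 64 - have;
        if (n < need) { memcpy(ctx->buf + have, data, n); return; }
        memcpy(ctx->buf + have, data, need);
        md5_block(ctx, ctx->buf);
        data += need; n -= need;
    }
    while (n >= 64) { md5_block(ctx, data); data += 64; n -= 64; }
    if (n) memcpy(ctx->buf, data, n);
}

static void md5_final(md5_ctx *ctx, unsigned char out[16]) {
    uint64_t bitlen = ctx->len * 8;
    unsigned char pad[72];
    size_t have = (size_t)(ctx->len % 64);
    size_t padlen = (have < 56) ? (56 - have) : (120 - have);
    memset(pad, 0, sizeof(pad));
    pad[0] = 0x80;
    md5_update(ctx, pad, padlen);
    unsigned char lenb[8];
    for (int i = 0; i < 8; ++i) lenb[i] = (unsigned char)((bitlen >> (8*i)) & 0xff);
    md5_update(ctx, lenb, 8);
    uint32_t st[4] = {ctx->a, ctx->b, ctx->c, ctx->d};
    for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j)
            out[4*i + j] = (unsigned char)((st[i] >> (8*j)) & 0xff);
}

// 16-byte digest per input string, concatenated.
// [[Rcpp::export]]
RawVector cpp_md5(CharacterVector x) {
    R_xlen_t n = x.size();
    RawVector out(16 * n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *s = Rf_translateCharUTF8(STRING_ELT(x, i));
        md5_ctx ctx;
        md5_init(&ctx);
        md5_update(&ctx, (const unsigned char *)s, strlen(s));
        unsigned char d[16];
        md5_final(&ctx, d);
        memcpy(&out[16 * i], d, 16);
    }
    return out;
}

/* ---- double hashing & bit array ------------------------------------- */

// h_beta restrictions: h_beta != 0 and h_beta mod M != 0; fallback value 1.
// [[Rcpp::export]]
RawVector cpp_enforce_beta(RawVector beta, double M) {
    if (M < 1) stop("M must be >= 1");
    uint64_t m = (uint64_t)M;
    R_xlen_t n = beta.size() / 8;
    RawVector out = clone(beta);
    for (R_xlen_t i = 0; i < n; ++i) {
        uint64_t b = u64_from_raw(&out[8 * i]);
        if (b == 0 || b % m == 0) u64_to_raw(1, &out[8 * i]);
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_hash_indices(RawVector alpha, RawVector beta, int k, double M) {
    if (M < 1) stop("M must be >= 1");
    if (k < 1) stop("k must be >= 1");
    if (alpha.size() != 8 || beta.size() != 8) stop("hash values must be 8 bytes");
    uint64_t m = (uint64_t)M;
    uint64_t a = u64_from_raw(&alpha[0]), b = u64_from_raw(&beta[0]);
    NumericVector out(k);
    uint64_t h = a;  // (a + i*b) mod 2^64, reduced mod M
    for (int i = 0; i < k; ++i) {
        out[i] = (double)(h % m);
        h += b;
    }
    return out;
}

// Sets all k bits for each (alpha, beta) pair. Bit i of the filter is bit
// (i mod 8), LSB-first, of byte floor(i/8) -- the on-disk packing.
// [[Rcpp::export]]
RawVector cpp_bloom_set(RawVector bits, RawVector alpha, RawVector beta,
                        int k, double M) {
    uint64_t m = (uint64_t)M;
    R_xlen_t n = alpha.size() / 8;
    RawVector out = clone(bits);
    for (R_xlen_t e = 0; e < n; ++e) {
        uint64_t a = u64_from_raw(&alpha[8 * e]), b = u64_from_raw(&beta[8 * e]);
        uint64_t h = a;
        for (int i = 0; i < k; ++i) {
            uint64_t idx = h % m;
            out[idx >> 3] |= (Rbyte)(1u << (idx & 7));
            h += b;
        }
    }
    return out;
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_check(RawVector bits, RawVector alpha, RawVector beta,
                              int k, double M) {
    uint64_t m = (uint64_t)M;
    R_xlen_t n = alpha.size() / 8;
    LogicalVector out(n);
    for (R_xlen_t e = 0; e < n; ++e) {
        uint64_t a = u64_from_raw(&alpha[8 * e]), b = u64_from_raw(&beta[8 * e]);
        uint64_t h = a;
        bool all = true;
        for (int i = 0; i < k && all; ++i) {
            uint64_t idx = h % m;
            if (!(bits[idx >> 3] & (1u << (idx & 7)))) all = false;
            h += b;
        }
        out[e] = all;
    }
    return out;
}

// [[Rcpp::export]]
double cpp_popcount(RawVector bits) {
    double total = 0;
    for (R_xlen_t i = 0; i < bits.size(); ++i) {
        unsigned char v = bits[i];
        while (v) { total += v & 1; v >>= 1; }
    }
    return total;
}

// Big-endian integer value of a 0/1 matrix row (column 1 most significant),
// reduced mod 2^64: equivalently the trailing 64 columns.
// [[Rcpp::export]]
RawVector cpp_fp_to_u64(IntegerMatrix fp) {
    int n = fp.nrow(), w = fp.ncol();
    RawVector out(8 * n);
    for (int r = 0; r < n; ++r) {
        uint64_t v = 0;
        int from = w > 64 ? w - 64 : 0;
        for (int c = from; c < w; ++c) v = (v << 1) | (uint64_t)(fp(r, c) != 0);
        u64_to_raw(v, &out[8 * r]);
    }
    return out;
}

// FPS-style hex fingerprint strings to a 0/1 matrix: the hex string is
// read as a big-endian bit string (first hex digit = leftmost 4 columns).
// All strings must have equal length.
// [[Rcpp::export]]
IntegerMatrix cpp_hex_to_bits(CharacterVector hex) {
    R_xlen_t n = hex.size();
    if (n == 0) stop("no fingerprints");
    int nc = LENGTH(STRING_ELT(hex, 0));
    IntegerMatrix out(n, 4 * nc);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(hex, i));
        if ((int)strlen(s) != nc) stop("fingerprint hex length mismatch");
        for (int j = 0; j < nc; ++j) {
            char c = s[j];
            int v = (c >= '0' && c <= '9') ? c - '0'
                  : (c >= 'a' && c <= 'f') ? c - 'a' + 10
                  : (c >= 'A' && c <= 'F') ? c - 'A' + 10 : -1;
            if (v < 0) stop("invalid hex digit in fingerprint");
            for (int b = 0; b < 4; ++b)
                out(i, 4 * j + b) = (v >> (3 - b)) & 1;
        }
    }
    return out;
}

// Per-pair Hamming distance between 8-byte blocks (avalanche measurements).
// [[Rcpp::export]]
IntegerVector cpp_hamming64(RawVector a, RawVector b) {
    R_xlen_t n = a.size() / 8;
    if (b.size() != a.size()) stop("length mismatch");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        int d = 0;
        for (int j = 0; j < 8; ++j) {
            unsigned char x = a[8 * i + j] ^ b[8 * i + j];
            while (x) { d += x & 1; x >>= 1; }
        }
        out[i] = d;
    }
    return out;
}

// Residues of 8-byte hash blocks mod M, as doubles (M < 2^53).
// [[Rcpp::export]]
NumericVector cpp_mod_u64(RawVector a, double M) {
    uint64_t m = (uint64_t)M;
    R_xlen_t n = a.size() / 8;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = (double)(u64_from_raw(&a[8 * i]) % m);
    return out;
}
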