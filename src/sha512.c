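/* SHA-512 (FIPS 180-4), streamed over a file in fixed-size chunks so memory
 * use is constant in the file size.  Exposed to R as a single .Call entry
 * returning the lowercase hex digest of a file's bytes. */

#include <stdint.h>
#include <stdio.h>
#include <string.h>
#include <R.h>
#include <Rinternals.h>

static const uint64_t K[80] = {
  0x428a2f98d728ae22ULL, 0x7137449123ef65cdULL, 0xb5c0fbcfec4d3b2fULL, 0xe9b5dba58189dbbcULL,
  0x3956c25bf348b538ULL, 0x59f111f1b605d019ULL, 0x923f82a4af194f9bULL, 0xab1c5ed5da6d8118ULL,
  0xd807aa98a3030242ULL, 0x12835b0145706fbeULL, 0x243185be4ee4b28cULL, 0x550c7dc3d5ffb4e2ULL,
  0x72be5d74f27b896fULL, 0x80deb1fe3b1696b1ULL, 0x9bdc06a725c71235ULL, 0xc19bf174cf692694ULL,
  0xe49b69c19ef14ad2ULL, 0xefbe4786384f25e3ULL, 0x0fc19dc68b8cd5b5ULL, 0x240ca1cc77ac9c65ULL,
  0x2de92c6f592b0275ULL, 0x4a7484aa6ea6e483ULL, 0x5cb0a9dcbd41fbd4ULL, 0x76f988da831153b5ULL,
  0x983e5152ee66dfabULL, 0xa831c66d2db43210ULL, 0xb00327c898fb213fULL, 0xbf597fc7beef0ee4ULL,
  0xc6e00bf33da88fc2ULL, 0xd5a79147930aa725ULL, 0x06ca6351e003826fULL, 0x142929670a0e6e70ULL,
  0x27b70a8546d22ffcULL, 0x2e1b21385c26c926ULL, 0x4d2c6dfc5ac42aedULL, 0x53380d139d95b3dfULL,
  0x650a73548baf63deULL, 0x766a0abb3c77b2a8ULL, 0x81c2c92e47edaee6ULL, 0x92722c851482353bULL,
  0xa2bfe8a14cf10364ULL, 0xa81a664bbc423001ULL, 0xc24b8b70d0f89791ULL, 0xc76c51a30654be30ULL,
  0xd192e819d6ef5218ULL, 0xd69906245565a910ULL, 0xf40e35855771202aULL, 0x106aa07032bbd1b8ULL,
  0x19a4c116b8d2d0c8ULL, 0x1e376c085141ab53ULL, 0x2748774cdf8eeb99ULL, 0x34b0bcb5e19b48a8ULL,
  0x391c0cb3c5c95a63ULL, 0x4ed8aa4ae3418acbULL, 0x5b9cca4f7763e373ULL, 0x682e6ff3d6b2b8a3ULL,
  0x748f82ee5defb2fcULL, 0x78a5636f43172f60ULL, 0x84c87814a1f0ab72ULL, 0x8cc702081a6439ecULL,
  0x90befffa23631e28ULL, 0xa4506cebde82bde9ULL, 0xbef9a3f7b2c67915ULL, 0xc67178f2e372532bULL,
  0xca273eceea26619cULL, 0xd186b8c721c0c207ULL, 0xeada7dd6cde0eb1eULL, 0xf57d4f7fee6ed178ULL,
  0x06f067aa72176fbaULL, 0x0a637dc5a2c898a6ULL, 0x113f9804bef90daeULL, 0x1b710b35131c471bULL,
  0x28db77f523047d84ULL, 0x32caab7b40c72493ULL, 0x3c9ebe0a15c9bebcULL, 0x431d67c49c100d4cULL,
  0x4cc5d4becb3e42b6ULL, 0x597f299cfc657e2aULL, 0x5fcb6fab3ad6faecULL, 0x6c44198c4a475817ULL
};

static const uint64_t H0[8] = {
  0x6a09e667f3bcc908ULL, 0xbb67ae8584caa73bULL, 0x3c6ef372fe94f82bULL, 0xa54ff53a5f1d36f1ULL,
  0x510e527fade682d1ULL, 0x9b05688c2b3e6c1fULL, 0x1f83d9abfb41bd6bULL, 0x5be0cd19137e2179ULL
};

#define ROTR(x, n) (((x) >> (n)) | ((x) << (64 - (n))))
#define CH(x, y, z)  (((x) & (y)) ^ (~(x) & (z)))
#define MAJ(x, y, z) (((x) & (y)) ^ ((x) & (z)) ^ ((y) & (z)))
#define BSIG0(x) (ROTR(x, 28) ^ ROTR(x, 34) ^ ROTR(x, 39))
#define BSIG1(x) (ROTR(x, 14) ^ ROTR(x, 18) ^ ROTR(x, 41))
#define SSIG0(x) (ROTR(x, 1)  ^ ROTR(x, 8)  ^ ((x) >> 7))
#define SSIG1(x) (ROTR(x, 19) ^ ROTR(x, 61) ^ ((x) >> 6))

typedef struct {
    uint64_t h[8];
    unsigned char buf[128];   /* partial block */
    size_t buflen;
    uint64_t nbytes;          /* total message length (< 2^64 bytes suffices) */
} sha512_ctx;

static void sha512_init(sha512_ctx *ctx)
{
    memcpy(ctx->h, H0, sizeof H0);
    ctx->buflen = 0;
    ctx->nbytes = 0;
}

static void sha512_block(sha512_ctx *ctx, const unsigned char *p)
{
    uint64_t w[80], a, b, c, d, e, f, g, h, t1, t2;
    int i;

    for (i = 0; i < 16; i++)
        w[i] = ((uint64_t)p[8*i]   << 56) | ((uint64_t)p[8*i+1] << 48) |
               ((uint64_t)p[8*i+2] << 40) | ((uint64_t)p[8*i+3] << 32) |
               ((uint64_t)p[8*i+4] << 24) | ((uint64_t)p[8*i+5] << 16) |
               ((uint64_t)p[8*i+6] << 8)  |  (uint64_t)p[8*i+7];
    for (i = 16; i < 80; i++)
        w[i] = SSIG1(w[i-2]) + w[i-7] + SSIG0(w[i-15]) + w[i-16];

    a = ctx->h[0]; b = ctx->h[1]; c = ctx->h[2]; d = ctx->h[3];
    e = ctx->h[4]; f = ctx->h[5]; g = ctx->h[6]; h = ctx->h[7];

    for (i = 0; i < 80; i++) {
        t1 = h + BSIG1(e) + CH(e, f, g) + K[i] + w[i];
        t2 = BSIG0(a) + MAJ(a, b, c);
        h = g; g = f; f = e; e = d + t1;
        d = c; c = b; b = a; a = t1 + t2;
    }

    ctx->h[0] += a; ctx->h[1] += b; ctx->h[2] += c; ctx->h[3] += d;
    ctx->h[4] += e; ctx->h[5] += f; ctx->h[6] += g; ctx->h[7] += h;
}

static void sha512_update(sha512_ctx *ctx, const unsigned char *p, size_t n)
{
    ctx->nbytes += n;
    if (ctx->buflen) {
        size_t need = 128 - ctx->buflen;
        size_t take = n < need ? n : need;
        memcpy(ctx->buf + ctx->buflen, p, take);
        ctx->buflen += take;
        p += take; n -= take;
        if (ctx->buflen == 128) {
            sha512_block(ctx, ctx->buf);
            ctx->buflen = 0;
        }
    }
    while (n >= 128) {
        sha512_block(ctx, p);
        p += 128; n -= 128;
    }
    if (n) {
        memcpy(ctx->buf, p, n);
        ctx->buflen = n;
    }
}

static void sha512_final(sha512_ctx *ctx, unsigned char out[64])
{
    unsigned char pad[256];
    size_t padlen;
    uint64_t bitlen = ctx->nbytes << 3;
    int i;

    /* pad to 112 mod 128, then 128-bit big-endian length (high word 0) */
    padlen = (ctx->buflen < 112) ? 112 - ctx->buflen : 240 - ctx->buflen;
    memset(pad, 0, sizeof pad);
    pad[0] = 0x80;
    sha512_update(ctx, pad, padlen);
    memset(pad, 0, 16);
    for (i = 0; i < 8; i++)
        pad[15 - i] = (unsigned char)(bitlen >> (8 * i));
    ctx->nbytes -= padlen;  /* updates above must not count toward length */
    sha512_update(ctx, pad, 16);

    for (i = 0; i < 8; i++) {
        out[8*i]   = (unsigned char)(ctx->h[i] >> 56);
        out[8*i+1] = (unsigned char)(ctx->h[i] >> 48);
        out[8*i+2] = (unsigned char)(ctx->h[i] >> 40);
        out[8*i+3] = (unsigned char)(ctx->h[i] >> 32);
        out[8*i+4] = (unsigned char)(ctx->h[i] >> 24);
        out[8*i+5] = (unsigned char)(ctx->h[i] >> 16);
        out[8*i+6] = (unsigned char)(ctx->h[i] >> 8);
        out[8*i+7] = (unsigned char)(ctx->h[i]);
    }
}

SEXP wf_sha512_file(SEXP path)
{
    const char *fname;
    FILE *fp;
    unsigned char chunk[65536], digest[64];
    char hex[129];
    size_t n;
    sha512_ctx ctx;
    static const char alphabet[] = "0123456789abcdef";
    int i;

    if (TYPEOF(path) != STRSXP || LENGTH(path) != 1)
        error("'path' must be a single string");
    fname = R_ExpandFileName(CHAR(STRING_ELT(path, 0)));
    fp = fopen(fname, "rb");
    if (fp == NULL)
        error("cannot open file '%s'", fname);

    sha512_init(&ctx);
    while ((n = fread(chunk, 1, sizeof chunk, fp)) > 0)
        sha512_update(&ctx, chunk, n);
    if (ferror(fp)) {
        fclose(fp);
        error("read error on file '%s'", fname);
    }
    fclose(fp);
    sha512_final(&ctx, digest);

    for (i = 0; i < 64; i++) {
        hex[2*i]     = alphabet[digest[i] >> 4];
        hex[2*i + 1] = alphabet[digest[i] & 0x0f];
    }
    hex[128] = '\0';
    return mkString(hex);
}
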