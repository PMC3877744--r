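// SHA-256 (FIPS 180-4) and AES-256 (FIPS 197) encryption in CBC mode.
// Only the forward (encrypt/digest) direction is needed: protected values
// are mapped back to plaintext through the owner-side lookup table, never
// by cipher decryption.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- SHA-256

static const uint32_t SHA256_K[64] = {
    0x428a2f98, 0x71374491, 0xb5c0fbcf, 0xe9b5dba5, 0x3956c25b, 0x59f111f1,
    0x923f82a4, 0xab1c5ed5, 0xd807aa98, 0x12835b01, 0x243185be, 0x550c7dc3,
    0x72be5d74, 0x80deb1fe, 0x9bdc06a7, 0xc19bf174, 0xe49b69c1, 0xefbe4786,
    0x0fc19dc6, 0x240ca1cc, 0x2de92c6f, 0x4a7484aa, 0x5cb0a9dc, 0x76f988da,
    0x983e5152, 0xa831c66d, 0xb00327c8, 0xbf597fc7, 0xc6e00bf3, 0xd5a79147,
    0x06ca6351, 0x14292967, 0x27b70a85, 0x2e1b2138, 0x4d2c6dfc, 0x53380d13,
    0x650a7354, 0x766a0abb, 0x81c2c92e, 0x92722c85, 0xa2bfe8a1, 0xa81a664b,
    0xc24b8b70, 0xc76c51a3, 0xd192e819, 0xd6990624, 0xf40e3585, 0x106aa070,
    0x19a4c116, 0x1e376c08, 0x2748774c, 0x34b0bcb5, 0x391c0cb3, 0x4ed8aa4a,
    0x5b9cca4f, 0x682e6ff3, 0x748f82ee, 0x78a5636f, 0x84c87814, 0x8cc70208,
    0x90befffa, 0xa4506ceb, 0xbef9a3f7, 0xc67178f2};

static inline uint32_t rotr(uint32_t x, int n) {
  return (x >> n) | (x << (32 - n));
}

static void sha256(const uint8_t *msg, size_t len, uint8_t out[32]) {
  uint32_t h[8] = {0x6a09e667, 0xbb67ae85, 0x3c6ef372, 0xa54ff53a,
                   0x510e527f, 0x9b05688c, 0x1f83d9ab, 0x5be0cd19};

  // padded message: len + 1 + pad zeros + 8-byte big-endian bit length
  size_t total = ((len + 8) / 64 + 1) * 64;
  std::vector<uint8_t> buf(total, 0);
  std::copy(msg, msg + len, buf.begin());
  buf[len] = 0x80;
  uint64_t bits = (uint64_t)len * 8;
  for (int i = 0; i < 8; ++i)
    buf[total - 1 - i] = (uint8_t)(bits >> (8 * i));

  uint32_t w[64];
  for (size_t off = 0; off < total; off += 64) {
    const uint8_t *p = buf.data() + off;
    for (int i = 0; i < 16; ++i)
      w[i] = ((uint32_t)p[4 * i] << 24) | ((uint32_t)p[4 * i + 1] << 16) |
             ((uint32_t)p[4 * i + 2] << 8) | (uint32_t)p[4 * i + 3];
    for (int i = 16; i < 64; ++i) {
      uint32_t s0 = rotr(w[i - 15], 7) ^ rotr(w[i - 15], 18) ^ (w[i - 15] >> 3);
      uint32_t s1 = rotr(w[i - 2], 17) ^ rotr(w[i - 2], 19) ^ (w[i - 2] >> 10);
      w[i] = w[i - 16] + s0 + w[i - 7] + s1;
    }
    uint32_t a = h[0], b = h[1], c = h[2], d = h[3], e = h[4], f = h[5],
             g = h[6], hh = h[7];
    for (int i = 0; i < 64; ++i) {
      uint32_t S1 = rotr(e, 6) ^ rotr(e, 11) ^ rotr(e, 25);
      uint32_t ch = (e & f) ^ (~e & g);
      uint32_t t1 = hh + S1 + ch + SHA256_K[i] + w[i];
      uint32_t S0 = rotr(a, 2) ^ rotr(a, 13) ^ rotr(a, 22);
      uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
      uint32_t t2 = S0 + maj;
      hh = g; g = f; f = e; e = d + t1;
      d = c; c = b; b = a; a = t1 + t2;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d;
    h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
  }
  for (int i = 0; i < 8; ++i) {
    out[4 * i] = (uint8_t)(h[i] >> 24);
    out[4 * i + 1] = (uint8_t)(h[i] >> 16);
    out[4 * i + 2] = (uint8_t)(h[i] >> 8);
    out[4 * i + 3] = (uint8_t)h[i];
  }
}

//' @noRd
// [[Rcpp::export(name = ".sha256_raw")]]
RawVector sha256_raw(RawVector data) {
  uint8_t out[32];
  sha256(data.length() ? &data[0] : (uint8_t *)"", data.length(), out);
  RawVector res(32);
  std::copy(out, out + 32, res.begin());
  return res;
}

// ---------------------------------------------------------------- AES-256

static const uint8_t SBOX[256] = {
    0x63, 0x7c, 0x77, 0x7b, 0xf2, 0x6b, 0x6f, 0xc5, 0x30, 0x01, 0x67, 0x2b,
    0xfe, 0xd7, 0xab, 0x76, 0xca, 0x82, 0xc9, 0x7d, 0xfa, 0x59, 0x47, 0xf0,
    0xad, 0xd4, 0xa2, 0xaf, 0x9c, 0xa4, 0x72, 0xc0, 0xb7, 0xfd, 0x93, 0x26,
    0x36, 0x3f, 0xf7, 0xcc, 0x34, 0xa5, 0xe5, 0xf1, 0x71, 0xd8, 0x31, 0x15,
    0x04, 0xc7, 0x23, 0xc3, 0x18, 0x96, 0x05, 0x9a, 0x07, 0x12, 0x80, 0xe2,
    0xeb, 0x27, 0xb2, 0x75, 0x09, 0x83, 0x2c, 0x1a, 0x1b, 0x6e, 0x5a, 0xa0,
    0x52, 0x3b, 0xd6, 0xb3, 0x29, 0xe3, 0x2f, 0x84, 0x53, 0xd1, 0x00, 0xed,
    0x20, 0xfc, 0xb1, 0x5b, 0x6a, 0xcb, 0xbe, 0x39, 0x4a, 0x4c, 0x58, 0xcf,
    0xd0, 0xef, 0xaa, 0xfb, 0x43, 0x4d, 0x33, 0x85, 0x45, 0xf9, 0x02, 0x7f,
    0x50, 0x3c, 0x9f, 0xa8, 0x51, 0xa3, 0x40, 0x8f, 0x92, 0x9d, 0x38, 0xf5,
    0xbc, 0xb6, 0xda, 0x21, 0x10, 0xff, 0xf3, 0xd2, 0xcd, 0x0c, 0x13, 0xec,
    0x5f, 0x97, 0x44, 0x17, 0xc4, 0xa7, 0x7e, 0x3d, 0x64, 0x5d, 0x19, 0x73,
    0x60, 0x81, 0x4f, 0xdc, 0x22, 0x2a, 0x90, 0x88, 0x46, 0xee, 0xb8, 0x14,
    0xde, 0x5e, 0x0b, 0xdb, 0xe0, 0x32, 0x3a, 0x0a, 0x49, 0x06, 0x24, 0x5c,
    0xc2, 0xd3, 0xac, 0x62, 0x91, 0x95, 0xe4, 0x79, 0xe7, 0xc8, 0x37, 0x6d,
    0x8d, 0xd5, 0x4e, 0xa9, 0x6c, 0x56, 0xf4, 0xea, 0x65, 0x7a, 0xae, 0x08,
    0xba, 0x78, 0x25, 0x2e, 0x1c, 0xa6, 0xb4, 0xc6, 0xe8, 0xdd, 0x74, 0x1f,
    0x4b, 0xbd, 0x8b, 0x8a, 0x70, 0x3e, 0xb5, 0x66, 0x48, 0x03, 0xf6, 0x0e,
    0x61, 0x35, 0x57, 0xb9, 0x86, 0xc1, 0x1d, 0x9e, 0xe1, 0xf8, 0x98, 0x11,
    0x69, 0xd9, 0x8e, 0x94, 0x9b, 0x1e, 0x87, 0xe9, 0xce, 0x55, 0x28, 0xdf,
    0x8c, 0xa1, 0x89, 0x0d, 0xbf, 0xe6, 0x42, 0x68, 0x41, 0x99, 0x2d, 0x0f,
    0xb0, 0x54, 0xbb, 0x16};

static inline uint8_t xtime(uint8_t x) {
  return (uint8_t)((x << 1) ^ ((x & 0x80) ? 0x1b : 0x00));
}

// expands a 32-byte key into 15 round keys (Nr = 14)
static void aes256_expand(const uint8_t key[32], uint8_t rk[240]) {
  std::copy(key, key + 32, rk);
  uint8_t rcon = 1;
  for (int i = 32; i < 240; i += 4) {
    uint8_t t[4] = {rk[i - 4], rk[i - 3], rk[i - 2], rk[i - 1]};
    if (i % 32 == 0) {
      uint8_t tmp = t[0];
      t[0] = (uint8_t)(SBOX[t[1]] ^ rcon);
      t[1] = SBOX[t[2]];
      t[2] = SBOX[t[3]];
      t[3] = SBOX[tmp];
      rcon = xtime(rcon);
    } else if (i % 32 == 16) {
      for (int j = 0; j < 4; ++j) t[j] = SBOX[t[j]];
    }
    for (int j = 0; j < 4; ++j) rk[i + j] = (uint8_t)(rk[i - 32 + j] ^ t[j]);
  }
}

static void aes256_encrypt_block(const uint8_t rk[240], uint8_t st[16]) {
  for (int j = 0; j < 16; ++j) st[j] ^= rk[j];
  for (int round = 1; round <= 14; ++round) {
    // SubBytes
    for (int j = 0; j < 16; ++j) st[j] = SBOX[st[j]];
    // ShiftRows (state is column-major: byte r + 4c)
    uint8_t t;
    t = st[1]; st[1] = st[5]; st[5] = st[9]; st[9] = st[13]; st[13] = t;
    t = st[2]; st[2] = st[10]; st[10] = t;
    t = st[6]; st[6] = st[14]; st[14] = t;
    t = st[15]; st[15] = st[11]; st[11] = st[7]; st[7] = st[3]; st[3] = t;
    // MixColumns (skipped in final round)
    if (round != 14) {
      for (int c = 0; c < 4; ++c) {
        uint8_t *col = st + 4 * c;
        uint8_t a0 = col[0], a1 = col[1], a2 = col[2], a3 = col[3];
        uint8_t all = (uint8_t)(a0 ^ a1 ^ a2 ^ a3);
        col[0] ^= (uint8_t)(all ^ xtime((uint8_t)(a0 ^ a1)));
        col[1] ^= (uint8_t)(all ^ xtime((uint8_t)(a1 ^ a2)));
        col[2] ^= (uint8_t)(all ^ xtime((uint8_t)(a2 ^ a3)));
        col[3] ^= (uint8_t)(all ^ xtime((uint8_t)(a3 ^ a0)));
      }
    }
    for (int j = 0; j < 16; ++j) st[j] ^= rk[16 * round + j];
  }
}

//' @noRd
// [[Rcpp::export(name = ".aes256_cbc_encrypt")]]
RawVector aes256_cbc_encrypt(RawVector key, RawVector iv, RawVector data) {
  if (key.length() != 32) stop("AES-256 key must be exactly 32 bytes");
  if (iv.length() != 16) stop("AES IV must be exactly 16 bytes");
  uint8_t rk[240];
  aes256_expand(&key[0], rk);

  // PKCS#7 padding to a whole number of 16-byte blocks
  size_t n = data.length();
  size_t pad = 16 - (n % 16);
  size_t total = n + pad;
  std::vector<uint8_t> buf(total);
  if (n) std::copy(data.begin(), data.end(), buf.begin());
  for (size_t i = n; i < total; ++i) buf[i] = (uint8_t)pad;

  uint8_t chain[16];
  std::copy(iv.begin(), iv.end(), chain);
  for (size_t off = 0; off < total; off += 16) {
    for (int j = 0; j < 16; ++j) buf[off + j] ^= chain[j];
    aes256_encrypt_block(rk, buf.data() + off);
    std::copy(buf.data() + off, buf.data() + off + 16, chain);
  }
  RawVector res(total);
  std::copy(buf.begin(), buf.end(), res.begin());
  return res;
}
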