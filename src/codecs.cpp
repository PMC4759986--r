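#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// MSB-first bit accumulator; final byte zero-padded, exact bit length kept
// by the caller in the member header.
struct BitWriter {
  std::vector<uint8_t> buf;
  uint64_t nbits = 0;
  inline void push(int b) {
    if ((nbits & 7) == 0) buf.push_back(0);
    if (b) buf[nbits >> 3] |= (uint8_t)(1u << (7 - (nbits & 7)));
    ++nbits;
  }
  inline void push_value(uint64_t v, int width) {
    for (int i = width - 1; i >= 0; --i) push((int)((v >> i) & 1));
  }
  RawVector bytes() const {
    RawVector out(buf.size());
    std::copy(buf.begin(), buf.end(), out.begin());
    return out;
  }
};

struct BitReader {
  const uint8_t* p;
  uint64_t nbits, pos;
  BitReader(const uint8_t* p_, uint64_t n_) : p(p_), nbits(n_), pos(0) {}
  inline int next() {
    if (pos >= nbits) stop("bit stream exhausted mid-codeword");
    int b = (p[pos >> 3] >> (7 - (pos & 7))) & 1;
    ++pos;
    return b;
  }
  inline uint64_t read_value(int width) {
    uint64_t v = 0;
    for (int i = 0; i < width; ++i) v = (v << 1) | (uint64_t)next();
    return v;
  }
};

static inline int floor_log2(uint64_t m) {
  int k = 0;
  while ((m >> (k + 1)) > 0) ++k;
  return k;
}

static inline void unary_put(BitWriter& w, uint64_t n) {
  for (uint64_t i = 0; i < n; ++i) w.push(1);
  w.push(0);
}

static inline uint64_t unary_get(BitReader& r) {
  uint64_t n = 0;
  while (r.next() == 1) ++n;
  return n;
}

// Truncated binary over an alphabet of size m: the first 2^(k+1)-m symbols
// get k bits, the rest k+1 bits, k = floor(log2 m). m = 1 emits nothing.
static inline void truncbin_put(BitWriter& w, uint64_t r, uint64_t m) {
  if (m == 1) return;
  int k = floor_log2(m);
  uint64_t t = (1ull << (k + 1)) - m;
  if (r < t) w.push_value(r, k);
  else w.push_value(r + t, k + 1);
}

static inline uint64_t truncbin_get(BitReader& rd, uint64_t m) {
  if (m == 1) return 0;
  int k = floor_log2(m);
  uint64_t t = (1ull << (k + 1)) - m;
  uint64_t v = rd.read_value(k);
  if (v < t) return v;
  v = (v << 1) | (uint64_t)rd.next();
  return v - t;
}

static inline void golomb_put(BitWriter& w, uint64_t n, uint64_t m) {
  unary_put(w, n / m);
  truncbin_put(w, n % m, m);
}

static inline uint64_t golomb_get(BitReader& r, uint64_t m) {
  uint64_t q = unary_get(r);
  return q * m + truncbin_get(r, m);
}

// Extended Golomb: divide by m until the quotient is 0, emit the iteration
// count M in unary, then the remainders most-recent-first; the final
// remainder lives on the reduced alphabet {1..m-1}. n = 0 is the reserved
// M = 0 codeword ("0").
static inline void egolomb_put(BitWriter& w, uint64_t n, uint64_t m) {
  if (n == 0) { w.push(0); return; }
  std::vector<uint64_t> rs;
  while (n > 0) {
    rs.push_back(n % m);
    n /= m;
  }
  size_t M = rs.size();
  unary_put(w, M);
  truncbin_put(w, rs[M - 1] - 1, m - 1);
  for (size_t i = M - 1; i-- > 0;) truncbin_put(w, rs[i], m);
}

static inline uint64_t egolomb_get(BitReader& r, uint64_t m) {
  uint64_t M = unary_get(r);
  if (M == 0) return 0;
  uint64_t n = truncbin_get(r, m - 1) + 1;
  for (uint64_t i = 1; i < M; ++i) n = n * m + truncbin_get(r, m);
  return n;
}

static void check_nonneg(IntegerVector v) {
  for (R_xlen_t i = 0; i < v.size(); ++i)
    if (v[i] == NA_INTEGER || v[i] < 0)
      stop("codec input must be non-negative integers");
}

// [[Rcpp::export]]
List cpp_golomb_encode(IntegerVector values, int m) {
  if (m < 1) stop("Golomb divisor m must be >= 1");
  check_nonneg(values);
  BitWriter w;
  for (R_xlen_t i = 0; i < values.size(); ++i) golomb_put(w, (uint64_t)values[i], (uint64_t)m);
  return List::create(_["bytes"] = w.bytes(), _["nbits"] = (double)w.nbits);
}

// [[Rcpp::export]]
List cpp_golomb_decode(RawVector bytes, double nbits, int m, double count) {
  if (m < 1) stop("Golomb divisor m must be >= 1");
  BitReader r(RAW(bytes), (uint64_t)nbits);
  R_xlen_t n = (R_xlen_t)count;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (int)golomb_get(r, (uint64_t)m);
  return List::create(_["values"] = out, _["bits_consumed"] = (double)r.pos);
}

// [[Rcpp::export]]
List cpp_egolomb_encode(IntegerVector values, int m) {
  if (m < 2) stop("extended Golomb divisor m must be >= 2");
  check_nonneg(values);
  BitWriter w;
  for (R_xlen_t i = 0; i < values.size(); ++i) egolomb_put(w, (uint64_t)values[i], (uint64_t)m);
  return List::create(_["bytes"] = w.bytes(), _["nbits"] = (double)w.nbits);
}

// [[Rcpp::export]]
List cpp_egolomb_decode(RawVector bytes, double nbits, int m, double count) {
  if (m < 2) stop("extended Golomb divisor m must be >= 2");
  BitReader r(RAW(bytes), (uint64_t)nbits);
  R_xlen_t n = (R_xlen_t)count;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (int)egolomb_get(r, (uint64_t)m);
  return List::create(_["values"] = out, _["bits_consumed"] = (double)r.pos);
}

// Optimal prefix-code lengths by Huffman merging with a deterministic
// tie-break (earlier-created node wins), so the length table is unique for
// a given count vector.
// [[Rcpp::export]]
IntegerVector cpp_huffman_lengths(NumericVector counts) {
  R_xlen_t n = counts.size();
  if (n == 0) stop("empty alphabet");
  for (R_xlen_t i = 0; i < n; ++i)
    if (counts[i] < 0 || NumericVector::is_na(counts[i])) stop("counts must be non-negative");
  double tot = 0;
  for (R_xlen_t i = 0; i < n; ++i) tot += counts[i];
  if (tot <= 0) stop("at least one symbol must have a positive count");
  if (n == 1) return IntegerVector::create(1);

  struct Node { double w; int left, right; };
  std::vector<Node> nodes;
  nodes.reserve(2 * n);
  std::vector<int> order(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    nodes.push_back({counts[i], -1, -1});
    order[i] = (int)i;
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return nodes[a].w < nodes[b].w; });
  // two-queue merge: leaves (sorted) + internal nodes (created in
  // non-decreasing weight order)
  std::vector<int> q2;
  size_t h1 = 0, h2 = 0;
  auto take = [&]() -> int {
    bool has1 = h1 < order.size(), has2 = h2 < q2.size();
    if (has1 && (!has2 || nodes[order[h1]].w <= nodes[q2[h2]].w))
      return order[h1++];
    return q2[h2++];
  };
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    int a = take();
    int b = take();
    nodes.push_back({nodes[a].w + nodes[b].w, a, b});
    q2.push_back((int)nodes.size() - 1);
  }
  // depth-first depth assignment
  IntegerVector lengths(n);
  std::vector<std::pair<int, int>> stack;
  stack.push_back({(int)nodes.size() - 1, 0});
  while (!stack.empty()) {
    auto [idx, d] = stack.back();
    stack.pop_back();
    if (nodes[idx].left < 0) lengths[idx] = d;
    else {
      stack.push_back({nodes[idx].left, d + 1});
      stack.push_back({nodes[idx].right, d + 1});
    }
  }
  return lengths;
}

// Canonical codeword values for a length table: symbols are taken in the
// order given (caller sorts by (length, symbol)); codes assigned
// sequentially per length.
static void canonical_codes(const IntegerVector& lengths,
                            std::vector<uint64_t>& codes,
                            std::vector<int>& ord) {
  R_xlen_t n = lengths.size();
  ord.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return lengths[a] < lengths[b]; });
  codes.assign(n, 0);
  uint64_t code = 0;
  int prev_len = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int s = ord[i];
    int len = lengths[s];
    if (len > 63) stop("Huffman code length exceeds 63 bits");
    code <<= (len - prev_len);
    codes[s] = code;
    ++code;
    prev_len = len;
  }
}

// [[Rcpp::export]]
List cpp_huffman_encode(IntegerVector values, IntegerVector symbols, IntegerVector lengths) {
  if (symbols.size() != lengths.size()) stop("symbols/lengths size mismatch");
  std::vector<uint64_t> codes;
  std::vector<int> ord;
  canonical_codes(lengths, codes, ord);
  std::unordered_map<int, std::pair<uint64_t, int>> table;
  for (R_xlen_t i = 0; i < symbols.size(); ++i)
    table[symbols[i]] = {codes[i], lengths[i]};
  BitWriter w;
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    auto it = table.find(values[i]);
    if (it == table.end()) stop("symbol absent from Huffman code table");
    w.push_value(it->second.first, it->second.second);
  }
  return List::create(_["bytes"] = w.bytes(), _["nbits"] = (double)w.nbits);
}

// [[Rcpp::export]]
List cpp_huffman_decode(RawVector bytes, double nbits, IntegerVector symbols,
                        IntegerVector lengths, double count) {
  std::vector<uint64_t> codes;
  std::vector<int> ord;
  canonical_codes(lengths, codes, ord);
  int maxlen = 0;
  for (R_xlen_t i = 0; i < lengths.size(); ++i) maxlen = std::max(maxlen, lengths[i]);
  // per-length first code and symbol offset within canonical order
  std::vector<uint64_t> first(maxlen + 1, 0);
  std::vector<int> cnt(maxlen + 1, 0), off(maxlen + 1, 0);
  for (size_t i = 0; i < ord.size(); ++i) {
    int len = lengths[ord[i]];
    if (cnt[len] == 0) {
      first[len] = codes[ord[i]];
      off[len] = (int)i;
    }
    ++cnt[len];
  }
  BitReader r(RAW(bytes), (uint64_t)nbits);
  R_xlen_t n = (R_xlen_t)count;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = 0;
    int len = 0;
    for (;;) {
      code = (code << 1) | (uint64_t)r.next();
      ++len;
      if (len > maxlen) stop("corrupt Huffman stream: no codeword matched");
      if (cnt[len] > 0 && code >= first[len] && code < first[len] + (uint64_t)cnt[len]) {
        out[i] = symbols[ord[off[len] + (int)(code - first[len])]];
        break;
      }
    }
  }
  return List::create(_["values"] = out, _["bits_consumed"] = (double)r.pos);
}

// 2-bit packing for the reference-free fallback; caller has already mapped
// non-ACGT characters away.
// [[Rcpp::export]]
RawVector cpp_pack_dna(std::string seq) {
  size_t n = seq.size();
  RawVector out((n + 3) / 4);
  std::fill(out.begin(), out.end(), 0);
  for (size_t i = 0; i < n; ++i) {
    int code;
    switch (seq[i]) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'T': code = 3; break;
      default: stop("non-ACGT character in 2-bit packer");
    }
    out[i >> 2] |= (Rbyte)(code << (6 - 2 * (i & 3)));
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_unpack_dna(RawVector bytes, double n) {
  static const char* alpha = "ACGT";
  size_t len = (size_t)n;
  std::string out(len, 'A');
  for (size_t i = 0; i < len; ++i)
    out[i] = alpha[(bytes[i >> 2] >> (6 - 2 * (i & 3))) & 3];
  return out;
}

// 0-based offsets at which equal-length strings differ; used for
// SAM-vs-reference mismatch extraction.
// [[Rcpp::export]]
List cpp_mismatch_offsets(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("length mismatch");
  List out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char* x = CHAR(STRING_ELT(a, i));
    const char* y = CHAR(STRING_ELT(b, i));
    size_t nx = strlen(x);
    if (nx != strlen(y)) stop("strings must have equal length");
    std::vector<int> hits;
    for (size_t j = 0; j < nx; ++j)
      if (x[j] != y[j]) hits.push_back((int)j);
    out[i] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}

// Hamming distance between equal-length strings, capped early at maxd + 1.
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b, int maxd) {
  if (a.size() != b.size()) stop("length mismatch");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char* x = CHAR(STRING_ELT(a, i));
    const char* y = CHAR(STRING_ELT(b, i));
    size_t nx = strlen(x), ny = strlen(y);
    if (nx != ny) { out[i] = maxd + 1; continue; }
    int d = 0;
    for (size_t j = 0; j < nx && d <= maxd; ++j)
      if (x[j] != y[j]) ++d;
    out[i] = d;
  }
  return out;
}
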