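#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Bit vectors cross the R boundary as IntegerVectors of 0/1.  All coders are
// bit-exact: encoder and decoder share identical integer arithmetic.

// ---------------------------------------------------------------------------
// Golomb-Rice coding, M = 2^k: quotient v >> k in unary (q ones, then a 0),
// remainder in k bits MSB-first.

// [[Rcpp::export(name = ".rice_encode_cpp")]]
IntegerVector rice_encode_cpp(IntegerVector values, int k) {
  if (k < 0 || k > 30) stop("rice parameter k out of range");
  std::vector<int> bits;
  bits.reserve(values.size() * (k + 2));
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    int v = values[i];
    if (v == NA_INTEGER || v < 0) stop("rice_encode: values must be non-negative");
    int q = v >> k;
    for (int j = 0; j < q; ++j) bits.push_back(1);
    bits.push_back(0);
    for (int j = k - 1; j >= 0; --j) bits.push_back((v >> j) & 1);
  }
  return wrap(bits);
}

// Decodes n values starting at 0-based bit offset `start`; returns the values
// and the offset of the first unread bit.
// [[Rcpp::export(name = ".rice_decode_cpp")]]
List rice_decode_cpp(IntegerVector bits, int k, int n, int start) {
  if (k < 0 || k > 30) stop("rice parameter k out of range");
  std::vector<int> out;
  out.reserve(n);
  R_xlen_t p = start, nb = bits.size();
  for (int i = 0; i < n; ++i) {
    int q = 0;
    while (p < nb && bits[p] == 1) { ++q; ++p; }
    if (p >= nb) stop("rice_decode: truncated unary run");
    ++p;  // terminating zero
    if (p + k > nb) stop("rice_decode: truncated remainder");
    int r = 0;
    for (int j = 0; j < k; ++j) r = (r << 1) | bits[p + j];
    p += k;
    out.push_back((q << k) | r);
  }
  return List::create(_["values"] = wrap(out), _["next"] = (int)p);
}

// ---------------------------------------------------------------------------
// Integer arithmetic coder (32-bit Witten-Neal-Cleary construction with
// bits-plus-follow carry handling).  The model is a frozen cumulative count
// table over mapped residuals 0..1022 plus one escape symbol (index 1023);
// escaped values are coded as 12 raw bits through a uniform binary model.

static const uint64_t AC_TOP  = 1ULL << 32;
static const uint64_t AC_HALF = AC_TOP >> 1;
static const uint64_t AC_QTR  = AC_TOP >> 2;
static const uint64_t AC_3QTR = AC_HALF + AC_QTR;

struct ACEncoder {
  uint64_t low = 0, high = AC_TOP - 1;
  long pending = 0;
  std::vector<int> bits;
  void emit(int b) {
    bits.push_back(b);
    for (; pending > 0; --pending) bits.push_back(1 - b);
  }
  void encode(uint32_t cum_lo, uint32_t cum_hi, uint32_t total) {
    uint64_t range = high - low + 1;
    high = low + (range * cum_hi) / total - 1;
    low  = low + (range * cum_lo) / total;
    for (;;) {
      if (high < AC_HALF) {
        emit(0);
      } else if (low >= AC_HALF) {
        emit(1); low -= AC_HALF; high -= AC_HALF;
      } else if (low >= AC_QTR && high < AC_3QTR) {
        ++pending; low -= AC_QTR; high -= AC_QTR;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
    }
  }
  void finish() {
    ++pending;
    emit(low < AC_QTR ? 0 : 1);
  }
};

struct ACDecoder {
  uint64_t low = 0, high = AC_TOP - 1, value = 0;
  const int *bits; R_xlen_t p = 0, nb;
  ACDecoder(const int *b, R_xlen_t n) : bits(b), nb(n) {
    for (int i = 0; i < 32; ++i) value = (value << 1) | next_bit();
  }
  int next_bit() { return (p < nb) ? bits[p++] : 0; }
  uint32_t scaled(uint32_t total) {
    uint64_t range = high - low + 1;
    return (uint32_t)(((value - low + 1) * total - 1) / range);
  }
  void update(uint32_t cum_lo, uint32_t cum_hi, uint32_t total) {
    uint64_t range = high - low + 1;
    high = low + (range * cum_hi) / total - 1;
    low  = low + (range * cum_lo) / total;
    for (;;) {
      if (high < AC_HALF) {
        // nothing
      } else if (low >= AC_HALF) {
        low -= AC_HALF; high -= AC_HALF; value -= AC_HALF;
      } else if (low >= AC_QTR && high < AC_3QTR) {
        low -= AC_QTR; high -= AC_QTR; value -= AC_QTR;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
      value = (value << 1) | next_bit();
    }
  }
};

// cum: cumulative counts, length n_sym + 1, cum[0] = 0, strictly increasing,
// cum[n_sym] = total <= 2^16.  Escape symbol is the last (index n_sym - 1).
// [[Rcpp::export(name = ".ac_encode_cpp")]]
IntegerVector ac_encode_cpp(IntegerVector values, IntegerVector cum) {
  int n_sym = cum.size() - 1;
  uint32_t total = (uint32_t)cum[n_sym];
  if (total > (1u << 16)) stop("ac_encode: total count exceeds 2^16");
  int esc = n_sym - 1;
  ACEncoder enc;
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    int v = values[i];
    if (v == NA_INTEGER || v < 0) stop("ac_encode: values must be non-negative");
    if (v < esc) {
      enc.encode((uint32_t)cum[v], (uint32_t)cum[v + 1], total);
    } else {
      if (v > 4095) stop("ac_encode: value exceeds 12-bit escape literal");
      enc.encode((uint32_t)cum[esc], (uint32_t)cum[esc + 1], total);
      for (int j = 11; j >= 0; --j) {
        int b = (v >> j) & 1;
        enc.encode(b, b + 1, 2);  // uniform binary model
      }
    }
  }
  enc.finish();
  return wrap(enc.bits);
}

// [[Rcpp::export(name = ".ac_decode_cpp")]]
IntegerVector ac_decode_cpp(IntegerVector bits, IntegerVector cum, int n) {
  int n_sym = cum.size() - 1;
  uint32_t total = (uint32_t)cum[n_sym];
  int esc = n_sym - 1;
  ACDecoder dec(INTEGER(bits), bits.size());
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t sc = dec.scaled(total);
    // binary search: largest s with cum[s] <= sc
    int lo = 0, hi = n_sym - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if ((uint32_t)cum[mid] <= sc) lo = mid; else hi = mid - 1;
    }
    int sym = lo;
    dec.update((uint32_t)cum[sym], (uint32_t)cum[sym + 1], total);
    if (sym == esc) {
      int v = 0;
      for (int j = 0; j < 12; ++j) {
        uint32_t b = dec.scaled(2);
        dec.update(b, b + 1, 2);
        v = (v << 1) | (int)b;
      }
      out[i] = v;
    } else {
      out[i] = sym;
    }
  }
  return out;
}
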