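#include <Rcpp.h>
using namespace Rcpp;

// DICOM Annex G byte-segment codec (PackBits variant).
// Control byte n:
//   0..127   -> copy the next n+1 bytes literally
//   129..255 -> repeat the next byte 257-n times (run lengths 2..128)
//   128      -> reserved; ignored on decode, never emitted on encode

// [[Rcpp::export(name = ".packbits_encode")]]
RawVector packbits_encode(RawVector input) {
  const R_xlen_t n = input.size();
  if (n == 0) stop("cannot encode an empty byte sequence");
  std::vector<unsigned char> out;
  out.reserve(n + n / 64 + 16);

  R_xlen_t i = 0;
  R_xlen_t lit_start = -1;  // start of pending literal run
  while (i < n) {
    // measure run of identical bytes starting at i (capped at 128)
    R_xlen_t run = 1;
    while (i + run < n && run < 128 && input[i + run] == input[i]) ++run;
    if (run >= 2) {
      // flush pending literals first
      if (lit_start >= 0) {
        R_xlen_t len = i - lit_start;
        while (len > 0) {
          R_xlen_t chunk = len > 128 ? 128 : len;
          out.push_back((unsigned char)(chunk - 1));
          for (R_xlen_t k = 0; k < chunk; ++k)
            out.push_back(input[lit_start + k]);
          lit_start += chunk;
          len -= chunk;
        }
        lit_start = -1;
      }
      out.push_back((unsigned char)(257 - run));
      out.push_back(input[i]);
      i += run;
    } else {
      if (lit_start < 0) lit_start = i;
      ++i;
      // cap literal accumulation at 128 to bound the flush below
      if (i - lit_start == 128) {
        out.push_back((unsigned char)127);
        for (R_xlen_t k = 0; k < 128; ++k) out.push_back(input[lit_start + k]);
        lit_start = -1;
      }
    }
  }
  if (lit_start >= 0) {
    R_xlen_t len = n - lit_start;
    while (len > 0) {
      R_xlen_t chunk = len > 128 ? 128 : len;
      out.push_back((unsigned char)(chunk - 1));
      for (R_xlen_t k = 0; k < chunk; ++k) out.push_back(input[lit_start + k]);
      lit_start += chunk;
      len -= chunk;
    }
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".packbits_decode")]]
RawVector packbits_decode(RawVector payload, R_xlen_t expected_length) {
  std::vector<unsigned char> out;
  if (expected_length > 0) out.reserve(expected_length);
  const R_xlen_t n = payload.size();
  R_xlen_t i = 0;
  while (i < n) {
    if (expected_length > 0 && (R_xlen_t)out.size() >= expected_length) break;
    unsigned char ctrl = payload[i++];
    if (ctrl <= 127) {
      R_xlen_t len = (R_xlen_t)ctrl + 1;
      if (i + len > n)
        stop("corrupt RLE frame: literal run extends past end of payload");
      for (R_xlen_t k = 0; k < len; ++k) out.push_back(payload[i + k]);
      i += len;
    } else if (ctrl >= 129) {
      if (i >= n)
        stop("corrupt RLE frame: replicate run truncated before repeated byte");
      R_xlen_t len = 257 - (R_xlen_t)ctrl;
      unsigned char b = payload[i++];
      for (R_xlen_t k = 0; k < len; ++k) out.push_back(b);
    }
    // ctrl == 128: reserved, skip
  }
  if (expected_length > 0 && (R_xlen_t)out.size() < expected_length)
    stop("corrupt RLE frame: decoded %d bytes, expected %d",
         (int)out.size(), (int)expected_length);
  if (expected_length > 0 && (R_xlen_t)out.size() > expected_length)
    out.resize(expected_length);
  return RawVector(out.begin(), out.end());
}
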