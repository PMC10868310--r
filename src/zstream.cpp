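// Thin zlib shims used by the BGZF layer: raw (headerless) DEFLATE,
// raw INFLATE, and CRC32.  All BGZF framing lives in R code; only the
// byte-level compression primitives are delegated to zlib.
#include <Rcpp.h>
#include <zlib.h>

using namespace Rcpp;

// [[Rcpp::export(name = ".deflate_raw")]]
RawVector deflate_raw(RawVector input, int level) {
  if (level < 0 || level > 9) stop("compression level must be in 0..9");
  z_stream zs;
  std::memset(&zs, 0, sizeof(zs));
  // windowBits = -15: raw deflate, no zlib/gzip wrapper
  if (deflateInit2(&zs, level, Z_DEFLATED, -15, 8, Z_DEFAULT_STRATEGY) != Z_OK)
    stop("deflateInit2 failed");
  uLong bound = deflateBound(&zs, input.size());
  std::vector<unsigned char> out(bound ? bound : 64);
  zs.next_in = (Bytef*)(input.size() ? &input[0] : (Rbyte*)"");
  zs.avail_in = input.size();
  zs.next_out = out.data();
  zs.avail_out = out.size();
  int ret = deflate(&zs, Z_FINISH);
  if (ret != Z_STREAM_END) {
    deflateEnd(&zs);
    stop("deflate failed (code %d)", ret);
  }
  R_xlen_t n = zs.total_out;
  deflateEnd(&zs);
  RawVector res(n);
  std::copy(out.begin(), out.begin() + n, res.begin());
  return res;
}

// [[Rcpp::export(name = ".inflate_raw")]]
RawVector inflate_raw(RawVector input, int isize) {
  if (isize < 0) stop("negative uncompressed size");
  z_stream zs;
  std::memset(&zs, 0, sizeof(zs));
  if (inflateInit2(&zs, -15) != Z_OK) stop("inflateInit2 failed");
  RawVector out(isize);
  zs.next_in = (Bytef*)(input.size() ? &input[0] : (Rbyte*)"");
  zs.avail_in = input.size();
  zs.next_out = isize ? (Bytef*)&out[0] : (Bytef*)"";
  zs.avail_out = isize;
  int ret = inflate(&zs, Z_FINISH);
  uLong got = zs.total_out;
  inflateEnd(&zs);
  if (ret != Z_STREAM_END || (int)got != isize)
    stop("inflate failed or size mismatch (code %d, got %lu, want %d)",
         ret, got, isize);
  return out;
}

// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector input) {
  uLong crc = crc32(0L, Z_NULL, 0);
  if (input.size())
    crc = crc32(crc, (const Bytef*)&input[0], input.size());
  return (double)crc;  // fits exactly in a double (32-bit value)
}
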