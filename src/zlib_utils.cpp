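// Thin zlib wrappers for the PNG/NPZ readers and writers.
// windowBits: 15 = zlib stream, -15 = raw deflate, 31 = gzip.

#include <Rcpp.h>
#include <zlib.h>

using namespace Rcpp;

// [[Rcpp::export]]
RawVector cpp_deflate(const RawVector& data, int window_bits, int level = 6) {
  z_stream zs{};
  if (deflateInit2(&zs, level, Z_DEFLATED, window_bits, 8,
                   Z_DEFAULT_STRATEGY) != Z_OK)
    stop("deflateInit2 failed");
  std::vector<unsigned char> out;
  out.resize(deflateBound(&zs, data.size()) + 64);
  zs.next_in = (Bytef*)RAW(data);
  zs.avail_in = data.size();
  zs.next_out = out.data();
  zs.avail_out = out.size();
  int ret = deflate(&zs, Z_FINISH);
  if (ret != Z_STREAM_END) {
    deflateEnd(&zs);
    stop("deflate failed");
  }
  size_t n = zs.total_out;
  deflateEnd(&zs);
  RawVector res(n);
  std::copy(out.begin(), out.begin() + n, res.begin());
  return res;
}

// [[Rcpp::export]]
RawVector cpp_inflate(const RawVector& data, int window_bits) {
  z_stream zs{};
  if (inflateInit2(&zs, window_bits) != Z_OK) stop("inflateInit2 failed");
  std::vector<unsigned char> out;
  size_t cap = std::max<size_t>(4 * (size_t)data.size(), 1 << 16);
  out.resize(cap);
  zs.next_in = (Bytef*)RAW(data);
  zs.avail_in = data.size();
  int ret;
  do {
    if (zs.total_out >= out.size()) out.resize(out.size() * 2);
    zs.next_out = out.data() + zs.total_out;
    zs.avail_out = out.size() - zs.total_out;
    ret = inflate(&zs, Z_NO_FLUSH);
    if (ret != Z_OK && ret != Z_STREAM_END) {
      inflateEnd(&zs);
      stop("inflate failed (corrupt stream?)");
    }
  } while (ret != Z_STREAM_END);
  size_t n = zs.total_out;
  inflateEnd(&zs);
  RawVector res(n);
  std::copy(out.begin(), out.begin() + n, res.begin());
  return res;
}

// [[Rcpp::export]]
double cpp_crc32(const RawVector& data) {
  uLong c = crc32(0L, Z_NULL, 0);
  c = crc32(c, (const Bytef*)RAW(data), data.size());
  return (double)c;
}
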