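// Minimal deterministic PNG codec (zlib-backed).
//
// Writes 8-bit grayscale (label maps, masks), 16-bit grayscale (depth in
// 0.1 mm units) and 8-bit RGB (chromadepth).  All scanlines use filter 0 and
// zlib level 1 (fast), so identical rasters give byte-identical files.  The
// reader handles the subset this package writes plus the standard filter
// reconstruction (0-4) for robustness.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>
using namespace Rcpp;

namespace {

const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff); v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);  v.push_back(x & 0xff);
}

static void write_chunk(FILE* f, const char* type,
                        const unsigned char* data, size_t len) {
  unsigned char hdr[8];
  hdr[0] = (len >> 24) & 0xff; hdr[1] = (len >> 16) & 0xff;
  hdr[2] = (len >> 8) & 0xff;  hdr[3] = len & 0xff;
  std::memcpy(hdr + 4, type, 4);
  std::fwrite(hdr, 1, 8, f);
  if (len) std::fwrite(data, 1, len, f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, hdr + 4, 4);
  if (len) crc = crc32(crc, data, len);
  unsigned char cb[4] = {(unsigned char)((crc >> 24) & 0xff),
                         (unsigned char)((crc >> 16) & 0xff),
                         (unsigned char)((crc >> 8) & 0xff),
                         (unsigned char)(crc & 0xff)};
  std::fwrite(cb, 1, 4, f);
}

static void write_png(const std::string& path, int width, int height,
                      int bitdepth, int channels,
                      const std::vector<unsigned char>& raw) {
  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("write_png: cannot open '%s'", path.c_str());
  std::fwrite(PNG_SIG, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, width); put_u32(ihdr, height);
  ihdr.push_back((unsigned char)bitdepth);
  ihdr.push_back(channels == 1 ? 0 : 2);  // gray or truecolour
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr.data(), ihdr.size());
  uLongf clen = compressBound(raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), raw.size(), 1) != Z_OK) {
    std::fclose(f);
    stop("write_png: zlib compression failed");
  }
  write_chunk(f, "IDAT", comp.data(), clen);
  write_chunk(f, "IEND", NULL, 0);
  std::fclose(f);
}

}  // namespace

// img: height x width integer matrix, values in [0, 2^bitdepth).
// [[Rcpp::export]]
void cpp_write_png_gray(std::string path, IntegerMatrix img, int bitdepth) {
  int H = img.nrow(), W = img.ncol();
  int bpp = bitdepth / 8;
  std::vector<unsigned char> raw((size_t)H * (1 + (size_t)W * bpp));
  size_t k = 0;
  for (int v = 0; v < H; ++v) {
    raw[k++] = 0;  // filter: none
    for (int u = 0; u < W; ++u) {
      int x = img(v, u);
      if (bitdepth == 8) {
        raw[k++] = (unsigned char)(x & 0xff);
      } else {
        raw[k++] = (unsigned char)((x >> 8) & 0xff);
        raw[k++] = (unsigned char)(x & 0xff);
      }
    }
  }
  write_png(path, W, H, bitdepth, 1, raw);
}

// [[Rcpp::export]]
void cpp_write_png_rgb(std::string path, IntegerMatrix r, IntegerMatrix g,
                       IntegerMatrix b) {
  int H = r.nrow(), W = r.ncol();
  std::vector<unsigned char> raw((size_t)H * (1 + (size_t)W * 3));
  size_t k = 0;
  for (int v = 0; v < H; ++v) {
    raw[k++] = 0;
    for (int u = 0; u < W; ++u) {
      raw[k++] = (unsigned char)(r(v, u) & 0xff);
      raw[k++] = (unsigned char)(g(v, u) & 0xff);
      raw[k++] = (unsigned char)(b(v, u) & 0xff);
    }
  }
  write_png(path, W, H, 8, 3, raw);
}

static inline int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// Returns list(width, height, bitdepth, channels, data) where data is a
// height x width matrix (gray) or list of three such matrices (RGB).
// [[Rcpp::export]]
List cpp_read_png(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("read_png: cannot open '%s'", path.c_str());
  unsigned char sig[8];
  if (std::fread(sig, 1, 8, f) != 8 || std::memcmp(sig, PNG_SIG, 8) != 0) {
    std::fclose(f);
    stop("read_png: not a PNG file");
  }
  int width = 0, height = 0, bitdepth = 0, colortype = 0;
  std::vector<unsigned char> idat;
  for (;;) {
    unsigned char hdr[8];
    if (std::fread(hdr, 1, 8, f) != 8) break;
    uint32_t len = ((uint32_t)hdr[0] << 24) | ((uint32_t)hdr[1] << 16) |
                   ((uint32_t)hdr[2] << 8) | hdr[3];
    char type[5] = {(char)hdr[4], (char)hdr[5], (char)hdr[6], (char)hdr[7], 0};
    std::vector<unsigned char> data(len);
    if (len && std::fread(data.data(), 1, len, f) != len) break;
    std::fseek(f, 4, SEEK_CUR);  // skip CRC
    if (!std::strcmp(type, "IHDR")) {
      width = ((int)data[0] << 24) | (data[1] << 16) | (data[2] << 8) | data[3];
      height = ((int)data[4] << 24) | (data[5] << 16) | (data[6] << 8) | data[7];
      bitdepth = data[8];
      colortype = data[9];
      if (data[12] != 0) { std::fclose(f); stop("read_png: interlacing unsupported"); }
    } else if (!std::strcmp(type, "IDAT")) {
      idat.insert(idat.end(), data.begin(), data.end());
    } else if (!std::strcmp(type, "IEND")) {
      break;
    }
  }
  std::fclose(f);
  if (width <= 0 || height <= 0) stop("read_png: bad header");
  if (colortype != 0 && colortype != 2) stop("read_png: unsupported colour type");
  int channels = colortype == 0 ? 1 : 3;
  int bpp = channels * bitdepth / 8;           // bytes per pixel
  size_t stride = (size_t)width * bpp;
  std::vector<unsigned char> raw(height * (stride + 1));
  uLongf rlen = raw.size();
  if (uncompress(raw.data(), &rlen, idat.data(), idat.size()) != Z_OK)
    stop("read_png: zlib decompression failed");
  // filter reconstruction
  std::vector<unsigned char> img(height * stride);
  for (int y = 0; y < height; ++y) {
    int ft = raw[y * (stride + 1)];
    const unsigned char* src = &raw[y * (stride + 1) + 1];
    unsigned char* dst = &img[y * stride];
    const unsigned char* up = y ? &img[(y - 1) * stride] : NULL;
    for (size_t x = 0; x < stride; ++x) {
      int a = x >= (size_t)bpp ? dst[x - bpp] : 0;
      int b = up ? up[x] : 0;
      int c = (up && x >= (size_t)bpp) ? up[x - bpp] : 0;
      int val = src[x];
      switch (ft) {
        case 0: break;
        case 1: val = (val + a) & 0xff; break;
        case 2: val = (val + b) & 0xff; break;
        case 3: val = (val + (a + b) / 2) & 0xff; break;
        case 4: val = (val + paeth(a, b, c)) & 0xff; break;
        default: stop("read_png: bad filter type");
      }
      dst[x] = (unsigned char)val;
    }
  }
  int sampbytes = bitdepth / 8;
  List out;
  for (int ch = 0; ch < channels; ++ch) {
    IntegerMatrix m(height, width);
    for (int y = 0; y < height; ++y)
      for (int x = 0; x < width; ++x) {
        const unsigned char* p = &img[y * stride + ((size_t)x * channels + ch) * sampbytes];
        m(y, x) = sampbytes == 1 ? p[0] : ((p[0] << 8) | p[1]);
      }
    out.push_back(m);
  }
  return List::create(_["width"] = width, _["height"] = height,
                      _["bitdepth"] = bitdepth, _["channels"] = channels,
                      _["data"] = channels == 1 ? out[0] : (SEXP)out);
}
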