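#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3D median filter with a cubic (2r+1)^3 neighbourhood, truncated at the
// volume boundary. Even-sized boundary neighbourhoods use the mean of the
// two central order statistics, matching R's median().
// [[Rcpp::export(name = ".median_filter3d")]]
NumericVector median_filter3d(NumericVector vol, IntegerVector dim,
                              int radius = 1) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != vol.size())
    stop("dim does not match volume length");
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        for (int dz = -radius; dz <= radius; ++dz) {
          const int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dy = -radius; dy <= radius; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            const size_t rowoff = (size_t)nx * (yy + (size_t)ny * zz);
            for (int dx = -radius; dx <= radius; ++dx) {
              const int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              buf.push_back(vol[xx + rowoff]);
            }
          }
        }
        const size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          const double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = (med + lo) / 2.0;
        }
        out[x + (size_t)nx * (y + (size_t)ny * z)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
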