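#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of img at continuous (x, y) in centered coordinates.
// x runs along columns, y along rows; (0, 0) is the image center
// (rotation axis). Outside the support the phantom is zero.
static inline double bilinear(const NumericMatrix& img, double x, double y) {
  const int h = img.nrow(), w = img.ncol();
  // column/row index of the sample in 0-based pixel coordinates
  double cj = x + 0.5 * (w - 1);
  double ci = y + 0.5 * (h - 1);
  int j0 = (int)std::floor(cj);
  int i0 = (int)std::floor(ci);
  double fj = cj - j0, fi = ci - i0;
  double v = 0.0;
  for (int di = 0; di <= 1; ++di) {
    int i = i0 + di;
    if (i < 0 || i >= h) continue;
    double wi = di ? fi : 1.0 - fi;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= w) continue;
      double wj = dj ? fj : 1.0 - fj;
      v += wi * wj * img(i, j);
    }
  }
  return v;
}

// Discrete parallel-beam Radon transform. Rays at detector coordinates
// s_coords (global frame: s = 0 on the rotation axis), one row per angle.
// theta = 0 integrates along +y; ray step is 1 pixel.
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector angles_rad,
                                  NumericVector s_coords) {
  const int na = angles_rad.size(), ns = s_coords.size();
  const int h = img.nrow(), w = img.ncol();
  // symmetric ray-parameter lattice (t -> -t maps it onto itself), so the
  // parallel-beam identity proj(theta + 180, s) == proj(theta, -s) holds
  // exactly on centered grids
  const int nt = (int)std::ceil(std::sqrt((double)h * h + (double)w * w) + 2.0);
  const double tmax = 0.5 * nt;
  NumericMatrix out(na, ns);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles_rad[a]), sn = std::sin(angles_rad[a]);
    for (int k = 0; k < ns; ++k) {
      const double s = s_coords[k];
      double acc = 0.0;
      for (int it = 0; it < nt; ++it) {
        const double t = -tmax + it + 0.5;
        const double x = s * c - t * sn;
        const double y = s * sn + t * c;
        acc += bilinear(img, x, y);
      }
      out(a, k) = acc;
    }
  }
  return out;
}

// Backprojection of a filtered sinogram (rows = angles) onto a wxw grid.
// s_coords gives the global detector coordinate of each sinogram column;
// pixel (i, j) of the output sits at centered coordinates
// (x, y) = (j - (w-1)/2, i - (w-1)/2). Linear interpolation along s.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector angles_rad,
                              NumericVector s_coords, int w) {
  const int na = angles_rad.size(), ns = s_coords.size();
  const double s0 = s_coords[0];
  const double ds = ns > 1 ? s_coords[1] - s_coords[0] : 1.0;
  NumericMatrix out(w, w);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles_rad[a]), sn = std::sin(angles_rad[a]);
    for (int i = 0; i < w; ++i) {
      const double y = i - 0.5 * (w - 1);
      for (int j = 0; j < w; ++j) {
        const double x = j - 0.5 * (w - 1);
        const double s = x * c + y * sn;
        const double u = (s - s0) / ds;
        const int k0 = (int)std::floor(u);
        if (k0 < 0 || k0 >= ns - 1) continue;
        const double f = u - k0;
        out(i, j) += (1.0 - f) * sino(a, k0) + f * sino(a, k0 + 1);
      }
    }
  }
  return out;
}
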