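#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Parallel-beam Siddon ray tracing: exact ray-pixel intersection lengths.
//
// Conventions (must match the R side):
//  - image is an n_row x n_col grid of square pixels of side `px`, centered
//    at the origin; matrix row 1 is the top of the image;
//  - angle 0 deg sends rays parallel to the y-axis, angles increase
//    counter-clockwise;
//  - detector bin d (1-based) sits at transverse offset
//    t = (d - (n_det + 1)/2) * ds along the detector axis (cos a, sin a);
//  - ray index i = (angle_index - 1) * n_det + d (1-based);
//  - pixel index j is the R column-major index (col - 1) * n_row + row.
//
// Weights are the geometric intersection lengths (the "probability" q_ij of
// the EM forward model, unnormalized). Rays lying exactly on a pixel
// boundary are assigned by the floor rule of the segment midpoint, which is
// deterministic.
// [[Rcpp::export(name = ".siddon_trace")]]
List siddon_trace(NumericVector angles_deg, int n_det, double ds,
                  int n_row, int n_col, double px) {
  const double xmin = -0.5 * n_col * px, xmax = 0.5 * n_col * px;
  const double ymin = -0.5 * n_row * px, ymax = 0.5 * n_row * px;
  const double tiny = 1e-12;
  const int n_ang = angles_deg.size();

  std::vector<int> ri, pj;
  std::vector<double> w;
  ri.reserve((size_t)n_ang * n_det * 8);
  pj.reserve((size_t)n_ang * n_det * 8);
  w.reserve((size_t)n_ang * n_det * 8);

  std::vector<double> sv;
  sv.reserve(2 * (n_row + n_col) + 8);

  for (int a = 0; a < n_ang; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ux = std::cos(th), uy = std::sin(th);   // detector axis
    const double vx = -std::sin(th), vy = std::cos(th);  // ray direction
    for (int d = 0; d < n_det; ++d) {
      const double t = (d + 1 - 0.5 * (n_det + 1)) * ds;
      const double x0 = t * ux, y0 = t * uy;
      const double big = (n_row + n_col) * px + std::fabs(t) + 10.0;
      double s0 = -big, s1 = big;
      if (std::fabs(vx) > tiny) {
        double sa = (xmin - x0) / vx, sb = (xmax - x0) / vx;
        s0 = std::max(s0, std::min(sa, sb));
        s1 = std::min(s1, std::max(sa, sb));
      } else if (x0 < xmin || x0 >= xmax) {
        continue;
      }
      if (std::fabs(vy) > tiny) {
        double sa = (ymin - y0) / vy, sb = (ymax - y0) / vy;
        s0 = std::max(s0, std::min(sa, sb));
        s1 = std::min(s1, std::max(sa, sb));
      } else if (y0 < ymin || y0 >= ymax) {
        continue;
      }
      if (s1 - s0 <= tiny) continue;

      sv.clear();
      sv.push_back(s0);
      sv.push_back(s1);
      if (std::fabs(vx) > tiny) {
        for (int i = 0; i <= n_col; ++i) {
          double s = (xmin + i * px - x0) / vx;
          if (s > s0 + tiny && s < s1 - tiny) sv.push_back(s);
        }
      }
      if (std::fabs(vy) > tiny) {
        for (int i = 0; i <= n_row; ++i) {
          double s = (ymin + i * px - y0) / vy;
          if (s > s0 + tiny && s < s1 - tiny) sv.push_back(s);
        }
      }
      std::sort(sv.begin(), sv.end());

      const int ray = a * n_det + d + 1;
      for (size_t k = 0; k + 1 < sv.size(); ++k) {
        const double len = sv[k + 1] - sv[k];
        if (len <= tiny) continue;
        const double sm = 0.5 * (sv[k] + sv[k + 1]);
        const double xm = x0 + sm * vx, ym = y0 + sm * vy;
        int c = (int)std::floor((xm - xmin) / px);
        int r = (int)std::floor((ymax - ym) / px);
        if (c < 0 || c >= n_col || r < 0 || r >= n_row) continue;
        ri.push_back(ray);
        pj.push_back(c * n_row + r + 1);
        w.push_back(len);
      }
    }
  }

  return List::create(_["i"] = wrap(ri), _["j"] = wrap(pj), _["x"] = wrap(w));
}
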