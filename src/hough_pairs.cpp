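#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pair-sampling ellipse Hough transform.
//
// Every pair of edge points whose separation lies inside the admissible
// major-axis range is treated as a hypothetical pair of major-axis
// endpoints.  All remaining edge points vote for the semi-minor length
// they would imply if they lay on that ellipse; the votes fall into a
// 1-px-wide 1-D accumulator.  A 3-bin box window is summed around the
// peak so that half-pixel jitter in the contour does not split votes.
//
// Returns one candidate row per admissible pair that reaches min_votes:
//   cx, cy, a, b, theta(rad), votes (3-bin window sum at the peak).
//
// [[Rcpp::export]]
NumericMatrix hough_pairs(NumericVector px, NumericVector py,
                          double min_major, double max_major,
                          int min_votes) {
  const int n = px.size();
  std::vector<double> out;
  if (n < 3) return NumericMatrix(0, 6);

  const double min2 = min_major * min_major;
  const double max2 = max_major * max_major;
  std::vector<int> acc;

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = px[j] - px[i], dy = py[j] - py[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 < min2 || d2 > max2) continue;

      const double major = std::sqrt(d2);
      const double a = 0.5 * major;
      const double cx = 0.5 * (px[i] + px[j]);
      const double cy = 0.5 * (py[i] + py[j]);
      const int nbin = (int)std::floor(a) + 1;
      acc.assign(nbin + 1, 0);

      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        const double tx = px[k] - cx, ty = py[k] - cy;
        const double d = std::sqrt(tx * tx + ty * ty);
        if (d >= a || d < 1e-9) continue;
        const double fx = px[k] - px[j], fy = py[k] - py[j];
        const double f2 = fx * fx + fy * fy;
        double costau = (a * a + d * d - f2) / (2.0 * a * d);
        if (costau > 1.0) costau = 1.0;
        if (costau < -1.0) costau = -1.0;
        const double cos2 = costau * costau;
        const double sin2 = 1.0 - cos2;
        const double denom = a * a - d * d * cos2;
        if (denom < 1e-9) continue;
        const double b2 = a * a * d * d * sin2 / denom;
        if (b2 < 0.25) continue;
        const double b = std::sqrt(b2);
        if (b > a) continue;
        const int bin = (int)std::lround(b);
        if (bin >= 1 && bin <= nbin) acc[bin]++;
      }

      // peak of the smoothed accumulator; ties resolved toward smaller b
      int best_bin = -1, best_votes = 0;
      for (int bb = 1; bb <= nbin; ++bb) {
        int v = acc[bb];
        if (bb > 1) v += acc[bb - 1];
        if (bb < nbin) v += acc[bb + 1];
        if (v > best_votes) { best_votes = v; best_bin = bb; }
      }
      if (best_bin < 0 || best_votes < min_votes) continue;

      double theta = std::atan2(dy, dx);
      out.push_back(cx); out.push_back(cy);
      out.push_back(a);  out.push_back((double)best_bin);
      out.push_back(theta); out.push_back((double)best_votes);
    }
  }

  const int m = (int)(out.size() / 6);
  NumericMatrix res(m, 6);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < 6; ++c) res(r, c) = out[r * 6 + c];
  colnames(res) = CharacterVector::create("cx", "cy", "a", "b",
                                          "theta", "votes");
  return res;
}
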