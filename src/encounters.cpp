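#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clamp01(double v) {
  if (v < 0.0) return 0.0;
  if (v > 1.0) return 1.0;
  return v;
}

// minimum distance between closed segments P0-P1 and Q0-Q1 (Ericson 2005)
static double seg_seg_dist(double p0x, double p0y, double p1x, double p1y,
                           double q0x, double q0y, double q1x, double q1y) {
  double d1x = p1x - p0x, d1y = p1y - p0y;
  double d2x = q1x - q0x, d2y = q1y - q0y;
  double rx = p0x - q0x, ry = p0y - q0y;
  double a = d1x * d1x + d1y * d1y;
  double e = d2x * d2x + d2y * d2y;
  double f = d2x * rx + d2y * ry;
  double s, t;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) {
    s = t = 0.0;
  } else if (a <= EPS) {
    s = 0.0;
    t = clamp01(f / e);
  } else {
    double c = d1x * rx + d1y * ry;
    if (e <= EPS) {
      t = 0.0;
      s = clamp01(-c / a);
    } else {
      double b = d1x * d2x + d1y * d2y;
      double denom = a * e - b * b;
      s = (denom > EPS) ? clamp01((b * f - c * e) / denom) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = clamp01(-c / a);
      } else if (t > 1.0) {
        t = 1.0;
        s = clamp01((b - c) / a);
      }
    }
  }
  double cx = p0x + s * d1x - (q0x + t * d2x);
  double cy = p0y + s * d1y - (q0y + t * d2y);
  return std::sqrt(cx * cx + cy * cy);
}

// [[Rcpp::export]]
NumericVector seg_dist_cpp(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = seg_seg_dist(a(i, 0), a(i, 1), a(i, 2), a(i, 3),
                          b(i, 0), b(i, 1), b(i, 2), b(i, 3));
  return out;
}

// All male x female path pairs whose segment-segment distance does not exceed
// max(perception_male, perception_female).  Bounding-circle quick reject
// before the exact distance.  Returns a 3-column matrix: male row index,
// female row index (both 1-based), distance.
// [[Rcpp::export]]
NumericMatrix encounter_pairs_cpp(NumericVector mx0, NumericVector my0,
                                  NumericVector mx1, NumericVector my1,
                                  NumericVector pm,
                                  NumericVector fx0, NumericVector fy0,
                                  NumericVector fx1, NumericVector fy1,
                                  NumericVector pf) {
  int nm = mx0.size(), nf = fx0.size();
  std::vector<double> mcx(nm), mcy(nm), mr(nm), fcx(nf), fcy(nf), fr(nf);
  for (int i = 0; i < nm; ++i) {
    mcx[i] = 0.5 * (mx0[i] + mx1[i]);
    mcy[i] = 0.5 * (my0[i] + my1[i]);
    double dx = mx1[i] - mx0[i], dy = my1[i] - my0[i];
    mr[i] = 0.5 * std::sqrt(dx * dx + dy * dy);
  }
  for (int j = 0; j < nf; ++j) {
    fcx[j] = 0.5 * (fx0[j] + fx1[j]);
    fcy[j] = 0.5 * (fy0[j] + fy1[j]);
    double dx = fx1[j] - fx0[j], dy = fy1[j] - fy0[j];
    fr[j] = 0.5 * std::sqrt(dx * dx + dy * dy);
  }
  std::vector<double> out_m, out_f, out_d;
  for (int i = 0; i < nm; ++i) {
    for (int j = 0; j < nf; ++j) {
      double thr = std::max(pm[i], pf[j]);
      double reach = mr[i] + fr[j] + thr;
      double dx = mcx[i] - fcx[j], dy = mcy[i] - fcy[j];
      if (dx * dx + dy * dy > reach * reach) continue;
      double d = seg_seg_dist(mx0[i], my0[i], mx1[i], my1[i],
                              fx0[j], fy0[j], fx1[j], fy1[j]);
      if (d <= thr) {
        out_m.push_back(i + 1);
        out_f.push_back(j + 1);
        out_d.push_back(d);
      }
    }
  }
  int k = out_m.size();
  NumericMatrix res(k, 3);
  for (int r = 0; r < k; ++r) {
    res(r, 0) = out_m[r];
    res(r, 1) = out_f[r];
    res(r, 2) = out_d[r];
  }
  return res;
}
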