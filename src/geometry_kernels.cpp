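#include <Rcpp.h>
using namespace Rcpp;

// squared distance from point (px,py) to segment (sx,sy)-(ex,ey)
static inline double sqdist_point_seg(double px, double py, double sx,
                                      double sy, double ex, double ey) {
  double dx = ex - sx, dy = ey - sy;
  double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0.0) {
    t = ((px - sx) * dx + (py - sy) * dy) / l2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double ddx = px - (sx + t * dx), ddy = py - (sy + t * dy);
  return ddx * ddx + ddy * ddy;
}

// [[Rcpp::export]]
NumericVector min_sqdist_to_segments_cpp(NumericMatrix P, NumericMatrix S,
                                         NumericMatrix E) {
  int m = P.nrow(), n = S.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    double px = P(i, 0), py = P(i, 1);
    for (int j = 0; j < n; ++j) {
      double d = sqdist_point_seg(px, py, S(j, 0), S(j, 1), E(j, 0), E(j, 1));
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// directed Hausdorff distance from sample points P to the segment set;
// the inner minimisation stops early once a point cannot raise the maximum
// [[Rcpp::export]]
double directed_hausdorff_cpp(NumericMatrix P, NumericMatrix S,
                              NumericMatrix E) {
  int m = P.nrow(), n = S.nrow();
  double worst = 0.0;
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    double px = P(i, 0), py = P(i, 1);
    for (int j = 0; j < n; ++j) {
      double d = sqdist_point_seg(px, py, S(j, 0), S(j, 1), E(j, 0), E(j, 1));
      if (d < best) {
        best = d;
        if (best <= worst) break;
      }
    }
    if (best > worst && best < R_PosInf) worst = best;
  }
  return std::sqrt(worst);
}

// all crossings between two edge sets; mirrors the parametric solution of
// the R caller: proper crossings carry (t, u), collinear overlaps emit the
// projections of the second edge's endpoints onto the first (u = NA)
// [[Rcpp::export]]
List segment_crossings_cpp(NumericMatrix S1, NumericMatrix E1,
                           NumericMatrix S2, NumericMatrix E2,
                           double param_tol) {
  int n1 = S1.nrow(), n2 = S2.nrow();
  std::vector<int> oi, oj;
  std::vector<double> ot, ou;
  std::vector<int> ocol;
  double lo = -param_tol, hi = 1.0 + param_tol;
  for (int i = 0; i < n1; ++i) {
    double sx = S1(i, 0), sy = S1(i, 1), ex = E1(i, 0), ey = E1(i, 1);
    double d1x = ex - sx, d1y = ey - sy;
    double len1 = std::sqrt(d1x * d1x + d1y * d1y);
    double xlo = std::min(sx, ex), xhi = std::max(sx, ex);
    double ylo = std::min(sy, ey), yhi = std::max(sy, ey);
    for (int j = 0; j < n2; ++j) {
      double qx = S2(j, 0), qy = S2(j, 1), rx = E2(j, 0), ry = E2(j, 1);
      if (std::min(qx, rx) > xhi || std::max(qx, rx) < xlo ||
          std::min(qy, ry) > yhi || std::max(qy, ry) < ylo) continue;
      double d2x = rx - qx, d2y = ry - qy;
      double denom = d1x * d2y - d1y * d2x;
      double qpx = qx - sx, qpy = qy - sy;
      double len2 = std::sqrt(d2x * d2x + d2y * d2y);
      double scale = std::max(len1 * len2, 1e-300);
      double num_u = qpx * d1y - qpy * d1x;
      if (std::fabs(denom) > 1e-12 * scale) {
        double t = (qpx * d2y - qpy * d2x) / denom;
        double u = num_u / denom;
        if (t >= lo && t <= hi && u >= lo && u <= hi) {
          oi.push_back(i + 1); oj.push_back(j + 1);
          ot.push_back(std::min(std::max(t, 0.0), 1.0));
          ou.push_back(std::min(std::max(u, 0.0), 1.0));
          ocol.push_back(0);
        }
      } else if (std::fabs(num_u) <= 1e-9 * scale) {
        double l2 = std::max(d1x * d1x + d1y * d1y, 1e-300);
        double tA = ((qx - sx) * d1x + (qy - sy) * d1y) / l2;
        double tB = ((rx - sx) * d1x + (ry - sy) * d1y) / l2;
        if (std::max(tA, tB) > 0.0 && std::min(tA, tB) < 1.0) {
          double cA = std::min(std::max(tA, 0.0), 1.0);
          double cB = std::min(std::max(tB, 0.0), 1.0);
          oi.push_back(i + 1); oj.push_back(j + 1);
          ot.push_back(cA); ou.push_back(NA_REAL); ocol.push_back(1);
          oi.push_back(i + 1); oj.push_back(j + 1);
          ot.push_back(cB); ou.push_back(NA_REAL); ocol.push_back(1);
        }
      }
    }
  }
  int n = oi.size();
  LogicalVector col(n);
  for (int k = 0; k < n; ++k) col[k] = ocol[k] == 1;
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["t"] = wrap(ot), _["u"] = wrap(ou),
                      _["collinear"] = col);
}

// even-odd crossing test (boundary handling left to the caller)
// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericMatrix P, NumericMatrix V) {
  int m = P.nrow(), n = V.nrow();
  LogicalVector out(m);
  for (int i = 0; i < m; ++i) {
    double px = P(i, 0), py = P(i, 1);
    bool inside = false;
    for (int j = 0, k = n - 1; j < n; k = j++) {
      double y1 = V(j, 1), y2 = V(k, 1);
      if ((y1 > py) != (y2 > py)) {
        double xint = V(j, 0) + (py - y1) * (V(k, 0) - V(j, 0)) / (y2 - y1);
        if (px < xint) inside = !inside;
      }
    }
    out[i] = inside;
  }
  return out;
}
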