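#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Additive rasterization of birefringent fibers under crossed polarizers.
//
// Each fiber is a rectangle (length x width, pixel units) centered at
// (fx, fy) with in-plane orientation phi (degrees, counterclockwise from
// +x with y pointing down on screen).  At stage rotation theta the whole
// specimen rotates counterclockwise about (cx, cy) and is shifted by
// (sx, sy); the fiber then transmits A * sin^2(2 * (phi + theta)) through
// the crossed polarizers, added over overlapping fibers.
//
// Rasterization is area-weighted (antialiased): a camera pixel integrates
// irradiance over its footprint, so edge pixels receive the covered
// fraction of the fiber intensity (separable linear coverage ramp).  A
// hard in/out rasterization would make the rendered footprint depend on
// the stage angle at the half-pixel level -- an aliasing artifact that
// physical acquisition does not show.
// [[Rcpp::export]]
NumericMatrix render_fibers_cpp(int height, int width,
                                NumericVector fx, NumericVector fy,
                                NumericVector phi_deg, NumericVector amp,
                                double fiber_length, double fiber_width,
                                double theta_deg, double cx, double cy,
                                double sx, double sy) {
  NumericMatrix out(height, width);
  const int n = fx.size();
  const double ct = std::cos(theta_deg * DEG), st = std::sin(theta_deg * DEG);
  const double hl = fiber_length / 2.0, hw = fiber_width / 2.0;
  for (int f = 0; f < n; ++f) {
    // Malus-type crossed-polarizer response of the rotated fiber
    double s2 = std::sin(2.0 * (phi_deg[f] + theta_deg) * DEG);
    double val = amp[f] * s2 * s2;
    // rotate fiber center counterclockwise (y down => minus sign on y')
    double dx0 = fx[f] - cx, dy0 = fy[f] - cy;
    double x0 = cx + ct * dx0 + st * dy0 + sx;
    double y0 = cy - st * dx0 + ct * dy0 + sy;
    double a = (phi_deg[f] + theta_deg) * DEG;
    double ux = std::cos(a), uy = -std::sin(a);   // fiber long axis
    double vx = -uy, vy = ux;                     // perpendicular
    double hx = std::fabs(ux) * hl + std::fabs(vx) * hw;
    double hy = std::fabs(uy) * hl + std::fabs(vy) * hw;
    int xlo = std::max(0, (int)std::floor(x0 - hx) - 1);
    int xhi = std::min(width - 1, (int)std::ceil(x0 + hx) + 1);
    int ylo = std::max(0, (int)std::floor(y0 - hy) - 1);
    int yhi = std::min(height - 1, (int)std::ceil(y0 + hy) + 1);
    for (int y = ylo; y <= yhi; ++y) {
      for (int x = xlo; x <= xhi; ++x) {
        double px = x - x0, py = y - y0;
        double du = px * ux + py * uy;
        double dv = px * vx + py * vy;
        double cu = hl + 0.5 - std::fabs(du);
        double cv = hw + 0.5 - std::fabs(dv);
        if (cu > 0.0 && cv > 0.0) {
          double cov = std::min(cu, 1.0) * std::min(cv, 1.0);
          out(y, x) += val * cov;
        }
      }
    }
  }
  return out;
}

// Rigid warp with bilinear interpolation.  Applying transform (rot, t)
// means the image content rotates counterclockwise by rot about (cx, cy)
// and then translates by (tx, ty); the output pixel p samples the input
// at R_{-rot}(p - t - c) + c.  Pixels needing data outside the frame are
// set to `fill` and flagged invalid.
// [[Rcpp::export]]
List warp_rigid_cpp(NumericMatrix img, double rot_deg,
                    double tx, double ty, double cx, double cy,
                    double fill = 0.0) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  LogicalMatrix valid(h, w);
  const double c = std::cos(rot_deg * DEG), s = std::sin(rot_deg * DEG);
  for (int y = 0; y < h; ++y) {
    double qy0 = y - ty - cy;
    for (int x = 0; x < w; ++x) {
      double qx = x - tx - cx, qy = qy0;
      // R_{-rot} in the y-down counterclockwise convention
      double xin = c * qx - s * qy + cx;
      double yin = s * qx + c * qy + cy;
      int x0 = (int)std::floor(xin), y0 = (int)std::floor(yin);
      if (x0 < 0 || y0 < 0 || x0 + 1 > w - 1 || y0 + 1 > h - 1) {
        out(y, x) = fill;
        valid(y, x) = false;
      } else {
        double ax = xin - x0, ay = yin - y0;
        double v00 = img(y0, x0), v01 = img(y0, x0 + 1);
        double v10 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
        out(y, x) = (1 - ay) * ((1 - ax) * v00 + ax * v01) +
                    ay * ((1 - ax) * v10 + ax * v11);
        valid(y, x) = true;
      }
    }
  }
  return List::create(_["pixels"] = out, _["validity"] = valid);
}
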