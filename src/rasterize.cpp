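#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Z-buffered triangle rasterisation over pre-projected vertices.
//
// px:    V x 2 screen coordinates (pixels; pixel (c, r) covers
//        [c, c+1) x [r, r+1), sample point at the centre (c+0.5, r+0.5))
// depth: V camera-frame depths along the optical axis
// faces: F x 3 one-based vertex indices
// fcol:  F x 3 per-face flat colours in [0, 1]
//
// Coverage uses inclusive edge tests (a pixel centre exactly on an edge is
// covered by both adjacent faces; the smaller depth wins, ties go to the
// earlier face). Depth is interpolated perspective-correctly via 1/z.
// [[Rcpp::export]]
List raster_triangles_cpp(NumericMatrix px, NumericVector depth,
                          IntegerMatrix faces, NumericMatrix fcol,
                          int width, int height) {
  const int npix = width * height;
  NumericVector rgba(npix * 4);   // dims (height, width, 4), column-major
  NumericVector zbuf(npix, R_PosInf);
  IntegerVector faceid(npix, NA_INTEGER);
  const double znear = 1e-6;

  for (int f = 0; f < faces.nrow(); ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double za = depth[a], zb = depth[b], zc = depth[c];
    if (za <= znear || zb <= znear || zc <= znear) continue; // behind camera
    double ax = px(a, 0), ay = px(a, 1);
    double bx = px(b, 0), by = px(b, 1);
    double cx = px(c, 0), cy = px(c, 1);
    double area = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(area) < 1e-12) continue; // degenerate in screen space
    int x0 = std::max(0, (int)std::floor(std::min(ax, std::min(bx, cx)) - 0.5));
    int x1 = std::min(width - 1, (int)std::ceil(std::max(ax, std::max(bx, cx)) - 0.5));
    int y0 = std::max(0, (int)std::floor(std::min(ay, std::min(by, cy)) - 0.5));
    int y1 = std::min(height - 1, (int)std::ceil(std::max(ay, std::max(by, cy)) - 0.5));
    if (x1 < x0 || y1 < y0) continue;
    double inv_area = 1.0 / area;
    double iza = 1.0 / za, izb = 1.0 / zb, izc = 1.0 / zc;
    for (int yy = y0; yy <= y1; ++yy) {
      double sy = yy + 0.5;
      for (int xx = x0; xx <= x1; ++xx) {
        double sx = xx + 0.5;
        double w0 = (bx - ax) * (sy - ay) - (by - ay) * (sx - ax); // opposite c
        double w1 = (cx - bx) * (sy - by) - (cy - by) * (sx - bx); // opposite a
        double w2 = (ax - cx) * (sy - cy) - (ay - cy) * (sx - cx); // opposite b
        // inclusive test, orientation-independent
        bool inside = (area > 0) ? (w0 >= 0 && w1 >= 0 && w2 >= 0)
                                 : (w0 <= 0 && w1 <= 0 && w2 <= 0);
        if (!inside) continue;
        double la = w1 * inv_area, lb = w2 * inv_area, lc = w0 * inv_area;
        double invz = la * iza + lb * izb + lc * izc;
        double z = 1.0 / invz;
        int pix = yy + xx * height;
        if (z < zbuf[pix]) {
          zbuf[pix] = z;
          faceid[pix] = f + 1;
          rgba[pix] = fcol(f, 0);
          rgba[pix + npix] = fcol(f, 1);
          rgba[pix + 2 * npix] = fcol(f, 2);
          rgba[pix + 3 * npix] = 1.0;
        }
      }
    }
  }
  rgba.attr("dim") = IntegerVector::create(height, width, 4);
  zbuf.attr("dim") = IntegerVector::create(height, width);
  faceid.attr("dim") = IntegerVector::create(height, width);
  return List::create(_["rgba"] = rgba, _["zbuf"] = zbuf,
                      _["faceid"] = faceid);
}

// Alpha-over compositing of an RGBA layer onto an RGB background through a
// similarity transform (scale s, translation tx/ty in target pixels), with
// nearest-neighbour sampling. bg dims (h, w, 3); layer dims (lh, lw, 4).
// [[Rcpp::export]]
NumericVector composite_layer_cpp(NumericVector bg, NumericVector layer,
                                  double s, double tx, double ty,
                                  int h, int w, int lh, int lw) {
  NumericVector out = clone(bg);
  // target pixels possibly touched: transform of layer bounds
  int x0 = std::max(0, (int)std::floor(tx));
  int y0 = std::max(0, (int)std::floor(ty));
  int x1 = std::min(w - 1, (int)std::ceil(tx + s * lw));
  int y1 = std::min(h - 1, (int)std::ceil(ty + s * lh));
  const int npix = h * w;
  const int lpix = lh * lw;
  for (int yy = y0; yy <= y1; ++yy) {
    for (int xx = x0; xx <= x1; ++xx) {
      double sx = ((xx + 0.5) - tx) / s;
      double sy = ((yy + 0.5) - ty) / s;
      int lx = (int)std::floor(sx);
      int ly = (int)std::floor(sy);
      if (lx < 0 || lx >= lw || ly < 0 || ly >= lh) continue;
      int lp = ly + lx * lh;
      double a = layer[lp + 3 * lpix];
      if (a <= 0) continue;
      int tp = yy + xx * h;
      for (int ch = 0; ch < 3; ++ch) {
        out[tp + ch * npix] = a * layer[lp + ch * lpix] +
                              (1.0 - a) * out[tp + ch * npix];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, 3);
  return out;
}

// Nearest-neighbour image rotation onto an expanded canvas. Rotation is by
// theta radians about the image centre ((w-1)/2, (h-1)/2) using the pixel
// coordinate convention x right / y down; exposed pixels are filled black.
// img dims (h, w, ch).
// [[Rcpp::export]]
NumericVector rotate_image_cpp(NumericVector img, double theta,
                               int h, int w, int ch,
                               int hout, int wout) {
  NumericVector out(hout * wout * ch);
  double c = std::cos(theta), s = std::sin(theta);
  double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  double cxo = (wout - 1) / 2.0, cyo = (hout - 1) / 2.0;
  const int onp = hout * wout, inp = h * w;
  for (int yy = 0; yy < hout; ++yy) {
    for (int xx = 0; xx < wout; ++xx) {
      double dx = xx - cxo, dy = yy - cyo;
      // inverse rotation (R(-theta))
      double sx = c * dx + s * dy + cx;
      double sy = -s * dx + c * dy + cy;
      int ix = (int)std::lround(sx);
      int iy = (int)std::lround(sy);
      if (ix < 0 || ix >= w || iy < 0 || iy >= h) continue;
      for (int k = 0; k < ch; ++k) {
        out[yy + xx * hout + k * onp] = img[iy + ix * h + k * inp];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(hout, wout, ch);
  return out;
}
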