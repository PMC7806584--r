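// Dense optical flow by polynomial expansion (Farneback 2003) and a
// per-pixel temporal median, the two inner loops of the tracking stage.
//
// Images are R matrices in column-major order: h rows (y, down),
// w columns (x, right); element (y, x) sits at index y + x*h.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;
typedef std::vector<double> Vec;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double sampleBilinear(const double *img, int h, int w,
                                    double x, double y) {
  if (x < 0) x = 0;
  if (x > w - 1) x = w - 1;
  if (y < 0) y = 0;
  if (y > h - 1) y = h - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, w - 1), y1 = std::min(y0 + 1, h - 1);
  double fx = x - x0, fy = y - y0;
  double v00 = img[y0 + (size_t)x0 * h], v10 = img[y0 + (size_t)x1 * h];
  double v01 = img[y1 + (size_t)x0 * h], v11 = img[y1 + (size_t)x1 * h];
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

static void resizeBilinearV(const Vec &src, int sh, int sw, Vec &dst, int dh,
                            int dw) {
  dst.assign((size_t)dh * dw, 0.0);
  double rx = (double)sw / dw, ry = (double)sh / dh;
  for (int x = 0; x < dw; ++x) {
    double sx = (x + 0.5) * rx - 0.5;
    for (int y = 0; y < dh; ++y) {
      double sy = (y + 0.5) * ry - 0.5;
      dst[y + (size_t)x * dh] = sampleBilinear(src.data(), sh, sw, sx, sy);
    }
  }
}

// Quadratic polynomial expansion with a Gaussian applicability of std
// `sigma` on a (2n+1)^2 window. Writes 5 planes: the linear coefficients
// (b_x, b_y) and the quadratic ones (a_xx, a_yy, a_xy).
static void polyExpansion(const Vec &f, int h, int w, int n, double sigma,
                          Vec &out) {
  int win = 2 * n + 1;
  Vec g(win), xg(win), xxg(win);
  double s = 0;
  for (int i = -n; i <= n; ++i) {
    g[i + n] = std::exp(-(double)i * i / (2 * sigma * sigma));
    s += g[i + n];
  }
  double a2 = 0, a4 = 0;
  for (int i = -n; i <= n; ++i) {
    g[i + n] /= s;
    xg[i + n] = i * g[i + n];
    xxg[i + n] = (double)i * i * g[i + n];
    a2 += g[i + n] * i * i;
    a4 += g[i + n] * (double)i * i * i * i;
  }
  // Weighted LS normal equations for (c1, a_xx, a_yy) are constant over the
  // image (applicability does not vary): invert the 3x3 Gram matrix once.
  double M[9] = {1, a2, a2, a2, a4, a2 * a2, a2, a2 * a2, a4};
  double inv[9];
  {
    double a = M[0], b = M[1], c = M[2], d = M[3], e = M[4], fm = M[5],
           g2 = M[6], hh = M[7], ii = M[8];
    double A0 = e * ii - fm * hh, B0 = -(d * ii - fm * g2),
           C0 = d * hh - e * g2;
    double det = a * A0 + b * B0 + c * C0;
    inv[0] = A0 / det;
    inv[1] = -(b * ii - c * hh) / det;
    inv[2] = (b * fm - c * e) / det;
    inv[3] = B0 / det;
    inv[4] = (a * ii - c * g2) / det;
    inv[5] = -(a * fm - c * d) / det;
    inv[6] = C0 / det;
    inv[7] = -(a * hh - b * g2) / det;
    inv[8] = (a * e - b * d) / det;
  }

  size_t plane = (size_t)h * w;
  Vec t0(plane), t1(plane), t2(plane);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double v0 = 0, v1 = 0, v2 = 0;
      for (int i = -n; i <= n; ++i) {
        int xi = clampi(x + i, 0, w - 1);
        double fv = f[y + (size_t)xi * h];
        v0 += g[i + n] * fv;
        v1 += xg[i + n] * fv;
        v2 += xxg[i + n] * fv;
      }
      size_t idx = y + (size_t)x * h;
      t0[idx] = v0;
      t1[idx] = v1;
      t2[idx] = v2;
    }
  }
  out.assign(plane * 5, 0.0);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double s00 = 0, s01 = 0, s02 = 0, s10 = 0, s11 = 0, s20 = 0;
      for (int j = -n; j <= n; ++j) {
        int yj = clampi(y + j, 0, h - 1);
        size_t idj = yj + (size_t)x * h;
        s00 += g[j + n] * t0[idj];
        s01 += xg[j + n] * t0[idj];
        s02 += xxg[j + n] * t0[idj];
        s10 += g[j + n] * t1[idj];
        s11 += xg[j + n] * t1[idj];
        s20 += g[j + n] * t2[idj];
      }
      size_t idx = y + (size_t)x * h;
      out[idx] = s10 / a2;                                      // b_x
      out[idx + plane] = s01 / a2;                              // b_y
      out[idx + 2 * plane] = inv[3] * s00 + inv[4] * s20 + inv[5] * s02; // a_xx
      out[idx + 3 * plane] = inv[6] * s00 + inv[7] * s20 + inv[8] * s02; // a_yy
      out[idx + 4 * plane] = s11 / (a2 * a2);                   // a_xy
    }
  }
}

// Separable box mean with truncated (renormalized) windows at the borders.
static void boxBlurPlane(double *img, int h, int w, int r, Vec &tmp) {
  tmp.assign((size_t)h * w, 0.0);
  // horizontal
  for (int y = 0; y < h; ++y) {
    double acc = 0;
    int cnt = 0;
    for (int x = 0; x <= std::min(r, w - 1); ++x) {
      acc += img[y + (size_t)x * h];
      ++cnt;
    }
    for (int x = 0; x < w; ++x) {
      tmp[y + (size_t)x * h] = acc / cnt;
      int xin = x + r + 1, xout = x - r;
      if (xin < w) {
        acc += img[y + (size_t)xin * h];
        ++cnt;
      }
      if (xout >= 0) {
        acc -= img[y + (size_t)xout * h];
        --cnt;
      }
    }
  }
  // vertical
  for (int x = 0; x < w; ++x) {
    const double *col = tmp.data() + (size_t)x * h;
    double acc = 0;
    int cnt = 0;
    for (int y = 0; y <= std::min(r, h - 1); ++y) {
      acc += col[y];
      ++cnt;
    }
    for (int y = 0; y < h; ++y) {
      img[y + (size_t)x * h] = acc / cnt;
      int yin = y + r + 1, yout = y - r;
      if (yin < h) {
        acc += col[yin];
        ++cnt;
      }
      if (yout >= 0) {
        acc -= col[yout];
        --cnt;
      }
    }
  }
}

// One pyramid level: iterative displacement refinement from the two
// polynomial expansions, averaging the local systems over a box window.
static void updateFlow(const Vec &R1, const Vec &R2, int h, int w, Vec &dx,
                       Vec &dy, int winsize, int iters) {
  size_t plane = (size_t)h * w;
  int r = winsize / 2;
  double dmax = 1.0 * winsize;
  Vec M(plane * 5), tmp;
  for (int it = 0; it < iters; ++it) {
    for (int x = 0; x < w; ++x) {
      for (int y = 0; y < h; ++y) {
        size_t idx = y + (size_t)x * h;
        double fx = x + dx[idx], fy = y + dy[idx];
        double b1x = R1[idx], b1y = R1[idx + plane];
        double b2x = sampleBilinear(R2.data(), h, w, fx, fy);
        double b2y = sampleBilinear(R2.data() + plane, h, w, fx, fy);
        double axx =
            0.5 * (R1[idx + 2 * plane] +
                   sampleBilinear(R2.data() + 2 * plane, h, w, fx, fy));
        double ayy =
            0.5 * (R1[idx + 3 * plane] +
                   sampleBilinear(R2.data() + 3 * plane, h, w, fx, fy));
        double axy =
            0.25 * (R1[idx + 4 * plane] +
                    sampleBilinear(R2.data() + 4 * plane, h, w, fx, fy));
        double db1 = -0.5 * (b2x - b1x) + axx * dx[idx] + axy * dy[idx];
        double db2 = -0.5 * (b2y - b1y) + axy * dx[idx] + ayy * dy[idx];
        M[idx] = axx * axx + axy * axy;
        M[idx + plane] = axy * (axx + ayy);
        M[idx + 2 * plane] = ayy * ayy + axy * axy;
        M[idx + 3 * plane] = axx * db1 + axy * db2;
        M[idx + 4 * plane] = axy * db1 + ayy * db2;
      }
    }
    for (int p = 0; p < 5; ++p)
      boxBlurPlane(M.data() + (size_t)p * plane, h, w, r, tmp);
    for (size_t idx = 0; idx < plane; ++idx) {
      double g11 = M[idx], g12 = M[idx + plane], g22 = M[idx + 2 * plane];
      double h1 = M[idx + 3 * plane], h2 = M[idx + 4 * plane];
      // require a well-conditioned local system: flat (textureless)
      // neighborhoods carry no displacement evidence and solve to zero
      double det = g11 * g22 - g12 * g12;
      if (det > 1e-12 && g11 + g22 > 1e-6) {
        double ux = (g22 * h1 - g12 * h2) / det;
        double uy = (g11 * h2 - g12 * h1) / det;
        if (ux > dmax) ux = dmax;
        if (ux < -dmax) ux = -dmax;
        if (uy > dmax) uy = dmax;
        if (uy < -dmax) uy = -dmax;
        dx[idx] = ux;
        dy[idx] = uy;
      } else {
        dx[idx] = 0;
        dy[idx] = 0;
      }
    }
  }
}

// [[Rcpp::export]]
List cppFarneback(NumericMatrix a, NumericMatrix b, double pyrScale,
                  int levels, int winsize, int iters, int polyN,
                  double polySigma) {
  int H = a.nrow(), W = a.ncol();
  std::vector<int> hs, ws;
  double sc = 1.0;
  for (int l = 0; l < levels; ++l) {
    int hh = (int)std::round(H * sc), ww = (int)std::round(W * sc);
    if (hh < 2 * polyN + 3 || ww < 2 * polyN + 3) break;
    hs.push_back(hh);
    ws.push_back(ww);
    sc *= pyrScale;
  }
  if (hs.empty()) {
    hs.push_back(H);
    ws.push_back(W);
  }
  int L = (int)hs.size();
  Vec A0(a.begin(), a.end()), B0(b.begin(), b.end());
  Vec dx, dy;
  for (int l = L - 1; l >= 0; --l) {
    int h = hs[l], w = ws[l];
    Vec Al, Bl;
    if (h == H && w == W) {
      Al = A0;
      Bl = B0;
    } else {
      resizeBilinearV(A0, H, W, Al, h, w);
      resizeBilinearV(B0, H, W, Bl, h, w);
    }
    Vec R1, R2;
    polyExpansion(Al, h, w, polyN, polySigma, R1);
    polyExpansion(Bl, h, w, polyN, polySigma, R2);
    if (dx.empty()) {
      dx.assign((size_t)h * w, 0.0);
      dy.assign((size_t)h * w, 0.0);
    } else {
      int ph = hs[l + 1], pw = ws[l + 1];
      Vec ndx, ndy;
      resizeBilinearV(dx, ph, pw, ndx, h, w);
      resizeBilinearV(dy, ph, pw, ndy, h, w);
      double rx = (double)w / pw, ry = (double)h / ph;
      for (size_t i = 0; i < ndx.size(); ++i) {
        ndx[i] *= rx;
        ndy[i] *= ry;
      }
      dx.swap(ndx);
      dy.swap(ndy);
    }
    updateFlow(R1, R2, h, w, dx, dy, winsize, iters);
  }
  NumericMatrix DX(H, W), DY(H, W);
  std::copy(dx.begin(), dx.end(), DX.begin());
  std::copy(dy.begin(), dy.end(), DY.begin());
  return List::create(_["dx"] = DX, _["dy"] = DY);
}

// In-place Adam parameter update (bias-corrected). The caller owns all
// four buffers exclusively; avoiding R-level temporaries matters because
// the autoencoder weight matrices hold ~10^7 parameters.
// [[Rcpp::export]]
void cppAdamStep(NumericVector par, NumericVector m, NumericVector v,
                 NumericVector g, double lr, double b1, double b2,
                 double c1, double c2, double eps) {
  R_xlen_t n = par.size();
  double *P = par.begin(), *M = m.begin(), *V = v.begin(), *G = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    M[i] = b1 * M[i] + (1 - b1) * G[i];
    V[i] = b2 * V[i] + (1 - b2) * G[i] * G[i];
    P[i] -= lr * (M[i] / c1) / (std::sqrt(V[i] / c2) + eps);
  }
}

// Per-pixel median over the frame dimension; px is npixels x nframes.
// [[Rcpp::export]]
NumericVector cppMedianStack(NumericMatrix px) {
  int n = px.nrow(), t = px.ncol();
  NumericVector out(n);
  std::vector<double> buf(t);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < t; ++j) buf[j] = px(i, j);
    int m = t / 2;
    std::nth_element(buf.begin(), buf.begin() + m, buf.end());
    double med = buf[m];
    if (t % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + m);
      med = 0.5 * (med + lo);
    }
    out[i] = med;
  }
  return out;
}
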