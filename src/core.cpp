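#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-pixel Gaussian-mixture background model update (Stauffer-Grimson /
// Zivkovic style, K modes per pixel). State matrices are npix x K and are
// modified in place; returns the foreground mask as an integer vector
// (1 = foreground). A pixel is foreground when its matched mode is not in
// the background set (modes of largest weight whose cumulative weight first
// exceeds bg_ratio) or when no mode matches within the squared-Mahalanobis
// threshold var_threshold.
// [[Rcpp::export]]
IntegerVector gmm_update_cpp(NumericMatrix w, NumericMatrix mu,
                             NumericMatrix var, NumericVector x,
                             double alpha, double var_threshold,
                             double var_init, double var_min, double var_max,
                             double bg_ratio) {
  const int n = x.size();
  const int K = w.ncol();
  if (w.nrow() != n || mu.nrow() != n || var.nrow() != n)
    stop("model state does not match frame size");
  if (K > 8) stop("at most 8 modes supported");
  IntegerVector mask(n);
  double *pw = REAL(w), *pm = REAL(mu), *pv = REAL(var);
  const double *px = REAL(x);
  int *pmask = INTEGER(mask);
  for (int i = 0; i < n; ++i) {
    const double xi = px[i];
    double wi[8], mi[8], vi[8];
    for (int k = 0; k < K; ++k) {
      const int off = k * n + i;
      wi[k] = pw[off]; mi[k] = pm[off]; vi[k] = pv[off];
    }
    // find matching mode: smallest normalized distance among matches
    int matched = -1;
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      if (wi[k] <= 0.0) continue;
      const double d = xi - mi[k];
      const double d2 = d * d;
      if (d2 < var_threshold * vi[k]) {
        const double nd = d2 / vi[k];
        if (nd < best) { best = nd; matched = k; }
      }
    }
    if (matched >= 0) {
      for (int k = 0; k < K; ++k) wi[k] *= (1.0 - alpha);
      wi[matched] += alpha;
      const double d = xi - mi[matched];
      mi[matched] += alpha * d;
      double v = vi[matched] + alpha * (d * d - vi[matched]);
      vi[matched] = std::min(std::max(v, var_min), var_max);
    } else {
      // replace the weakest mode with a new one centred on the observation
      int weakest = 0;
      for (int k = 1; k < K; ++k)
        if (wi[k] < wi[weakest]) weakest = k;
      for (int k = 0; k < K; ++k) wi[k] *= (1.0 - alpha);
      wi[weakest] = alpha;
      mi[weakest] = xi;
      vi[weakest] = var_init;
    }
    // renormalize weights
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += wi[k];
    if (s > 0.0) { const double inv = 1.0 / s;
                   for (int k = 0; k < K; ++k) wi[k] *= inv; }
    // background set: modes sorted by descending weight until cumulative
    // weight exceeds bg_ratio (the crossing mode included)
    bool fg = true;
    if (matched >= 0) {
      int ord[8];
      for (int k = 0; k < K; ++k) ord[k] = k;
      for (int a = 1; a < K; ++a) {            // insertion sort, K small
        const int o = ord[a];
        int b = a;
        while (b > 0 && wi[ord[b - 1]] < wi[o]) { ord[b] = ord[b - 1]; --b; }
        ord[b] = o;
      }
      double cum = 0.0;
      for (int k = 0; k < K; ++k) {
        cum += wi[ord[k]];
        if (ord[k] == matched) { fg = false; break; }
        if (cum > bg_ratio) break;
      }
    }
    pmask[i] = fg ? 1 : 0;
    for (int k = 0; k < K; ++k) {
      const int off = k * n + i;
      pw[off] = wi[k]; pm[off] = mi[k]; pv[off] = vi[k];
    }
  }
  return mask;
}

// 3x3 median filter with replicate padding at the borders.
// [[Rcpp::export]]
NumericMatrix median3_cpp(NumericMatrix src) {
  const int nr = src.nrow(), nc = src.ncol();
  NumericMatrix out(nr, nc);
  const double *p = REAL(src);
  double *q = REAL(out);
  double buf[9];
  for (int j = 0; j < nc; ++j) {
    const int jm = (j > 0 ? j - 1 : 0) * nr;
    const int j0 = j * nr;
    const int jp = (j < nc - 1 ? j + 1 : nc - 1) * nr;
    for (int i = 0; i < nr; ++i) {
      const int im = i > 0 ? i - 1 : 0;
      const int ip = i < nr - 1 ? i + 1 : nr - 1;
      buf[0] = p[jm + im]; buf[1] = p[jm + i]; buf[2] = p[jm + ip];
      buf[3] = p[j0 + im]; buf[4] = p[j0 + i]; buf[5] = p[j0 + ip];
      buf[6] = p[jp + im]; buf[7] = p[jp + i]; buf[8] = p[jp + ip];
      // 9-element median by sorting network (branchless)
      auto cswap = [](double &a, double &b) {
        const double lo = std::min(a, b), hi = std::max(a, b);
        a = lo; b = hi;
      };
      cswap(buf[1], buf[2]); cswap(buf[4], buf[5]); cswap(buf[7], buf[8]);
      cswap(buf[0], buf[1]); cswap(buf[3], buf[4]); cswap(buf[6], buf[7]);
      cswap(buf[1], buf[2]); cswap(buf[4], buf[5]); cswap(buf[7], buf[8]);
      cswap(buf[0], buf[3]); cswap(buf[5], buf[8]); cswap(buf[4], buf[7]);
      cswap(buf[3], buf[6]); cswap(buf[1], buf[4]); cswap(buf[2], buf[5]);
      cswap(buf[4], buf[7]); cswap(buf[4], buf[2]); cswap(buf[6], buf[4]);
      cswap(buf[4], buf[2]);
      q[j0 + i] = buf[4];
    }
  }
  return out;
}

// Grayscale erosion (dilate = false) or dilation (dilate = true) with an
// arbitrary flat structuring element; neighbourhoods are truncated at the
// image border (pixels outside the frame are ignored). The accumulation
// runs one kernel offset at a time down whole columns, which keeps the
// inner loop sequential in memory.
// [[Rcpp::export]]
NumericMatrix morph_cpp(NumericMatrix src, LogicalMatrix kernel, bool dilate) {
  const int nr = src.nrow(), nc = src.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  const int cr = kr / 2, cc = kc / 2;
  std::vector<int> di, dj;
  for (int kj = 0; kj < kc; ++kj)
    for (int ki = 0; ki < kr; ++ki)
      if (kernel(ki, kj)) { di.push_back(ki - cr); dj.push_back(kj - cc); }
  const int nk = (int)di.size();
  NumericMatrix out(nr, nc);
  const double *p = REAL(src);
  double *q = REAL(out);
  const double init = dilate ? R_NegInf : R_PosInf;
  std::fill(q, q + (size_t)nr * nc, init);
  for (int j = 0; j < nc; ++j) {
    double *col = q + (size_t)j * nr;
    for (int k = 0; k < nk; ++k) {
      const int jj = j + dj[k];
      if (jj < 0 || jj >= nc) continue;
      const int d = di[k];
      const int i0 = std::max(0, -d), i1 = std::min(nr, nr - d);
      const double *s = p + (size_t)jj * nr + d;
      if (dilate) {
        for (int i = i0; i < i1; ++i)
          col[i] = std::max(col[i], s[i]);
      } else {
        for (int i = i0; i < i1; ++i)
          col[i] = std::min(col[i], s[i]);
      }
    }
  }
  return out;
}

// Render anti-aliased dark discs onto a frame (in place). Centres are
// 0-based (x, y) image coordinates; alpha blends linearly over a soft edge
// of the given width just inside the disc radius.
// [[Rcpp::export]]
void draw_discs_cpp(NumericMatrix frame, NumericVector cx, NumericVector cy,
                    double radius, double intensity, double soft_edge) {
  const int nr = frame.nrow(), nc = frame.ncol();
  const int nd = cx.size();
  double *p = REAL(frame);
  const double pad = radius + 1.0;
  for (int d = 0; d < nd; ++d) {
    const double x = cx[d], y = cy[d];
    const int i0 = std::max((int)std::floor(y - pad), 0);
    const int i1 = std::min((int)std::ceil(y + pad), nr - 1);
    const int j0 = std::max((int)std::floor(x - pad), 0);
    const int j1 = std::min((int)std::ceil(x + pad), nc - 1);
    for (int j = j0; j <= j1; ++j) {
      const double dx = j - x;
      double *col = p + (size_t)j * nr;
      for (int i = i0; i <= i1; ++i) {
        const double dy = i - y;
        const double dist = std::sqrt(dx * dx + dy * dy);
        double a;
        if (dist <= radius - soft_edge) a = 1.0;
        else if (dist >= radius) a = 0.0;
        else a = (radius - dist) / soft_edge;
        if (a > 0.0)
          col[i] = (1.0 - a) * col[i] + a * intensity;
      }
    }
  }
}
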