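#include <Rcpp.h>
using namespace Rcpp;

// Separable Gaussian convolution with replicate (edge-clamp) padding.
// Kernel radius 3*sigma, matching the usual truncation in imaging toolkits.
// [[Rcpp::export(name = ".gaussBlurCpp")]]
NumericMatrix gaussBlurCpp(NumericMatrix x, double sigma) {
  int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  int klen = 2 * r + 1;
  std::vector<double> k(klen);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *px = x.begin();
  double *ptmp = tmp.begin(), *pout = out.begin();

  // vertical pass: contiguous down each column, borders clamped separately
  for (int j = 0; j < nc; ++j) {
    const double *col = px + (size_t)j * nr;
    double *dst = ptmp + (size_t)j * nr;
    int lo = std::min(r, nr), hi = std::max(nr - r, lo);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t; if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += k[t + r] * col[ii];
      }
      dst[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double *src = col + i - r;
      for (int t = 0; t < klen; ++t) acc += k[t] * src[t];
      dst[i] = acc;
    }
    for (int i = hi; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t; if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += k[t + r] * col[ii];
      }
      dst[i] = acc;
    }
  }
  // horizontal pass: for each output column, accumulate k-weighted columns
  for (int j = 0; j < nc; ++j) {
    double *dst = pout + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) dst[i] = 0.0;
    for (int t = -r; t <= r; ++t) {
      int jj = j + t; if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
      const double *src = ptmp + (size_t)jj * nr;
      double w = k[t + r];
      for (int i = 0; i < nr; ++i) dst[i] += w * src[i];
    }
  }
  return out;
}

// additive Gaussian noise (Box-Muller over R's uniform stream) plus
// clamping to [0,1], in place
// [[Rcpp::export(name = ".noiseClampCpp")]]
void noiseClampCpp(NumericMatrix img, double sd) {
  R_len_t n = img.size();
  double *p = img.begin();
  GetRNGstate();
  R_len_t i = 0;
  while (i < n) {
    double u1 = unif_rand(), u2 = unif_rand();
    while (u1 <= 0.0) u1 = unif_rand();
    double r = std::sqrt(-2.0 * std::log(u1));
    double z1 = r * std::cos(2.0 * M_PI * u2);
    double z2 = r * std::sin(2.0 * M_PI * u2);
    p[i] += sd * z1;
    if (p[i] < 0) p[i] = 0; else if (p[i] > 1) p[i] = 1;
    ++i;
    if (i < n) {
      p[i] += sd * z2;
      if (p[i] < 0) p[i] = 0; else if (p[i] > 1) p[i] = 1;
      ++i;
    }
  }
  PutRNGstate();
}

// fused dark-object thresholding (img < thr) and 8-connected labeling
// [[Rcpp::export(name = ".labelDarkCpp")]]
IntegerMatrix labelDarkCpp(NumericMatrix img, double thr) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  const double *p = img.begin();
  int *l = lab.begin();
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t q0 = (size_t)j * nr + i;
      if (p[q0] >= thr || l[q0]) continue;
      ++next;
      stack.clear();
      stack.push_back((int)q0);
      l[q0] = next;
      while (!stack.empty()) {
        int q = stack.back(); stack.pop_back();
        int pi = q % nr, pj = q / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            size_t qq = (size_t)qj * nr + qi;
            if (p[qq] < thr && !l[qq]) {
              l[qq] = next;
              stack.push_back((int)qq);
            }
          }
        }
      }
    }
  }
  return lab;
}

// single-pass per-label pixel statistics: area, centroid sums, bbox
// [[Rcpp::export(name = ".labelStatsCpp")]]
List labelStatsCpp(IntegerMatrix lab, int nlab) {
  IntegerVector area(nlab), minR(nlab, INT_MAX), maxR(nlab, -1),
                minC(nlab, INT_MAX), maxC(nlab, -1);
  NumericVector sumR(nlab), sumC(nlab);
  int nr = lab.nrow(), nc = lab.ncol();
  const int *p = lab.begin();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int v = p[(size_t)j * nr + i];
      if (!v) continue;
      int k = v - 1;
      ++area[k];
      sumR[k] += i; sumC[k] += j;
      if (i < minR[k]) minR[k] = i;
      if (i > maxR[k]) maxR[k] = i;
      if (j < minC[k]) minC[k] = j;
      if (j > maxC[k]) maxC[k] = j;
    }
  }
  return List::create(_["area"] = area, _["sumR"] = sumR, _["sumC"] = sumC,
                      _["minR"] = minR, _["maxR"] = maxR,
                      _["minC"] = minC, _["maxC"] = maxC);
}

// 4-connected component labeling (background/hole convention)
// [[Rcpp::export(name = ".label4Cpp")]]
IntegerMatrix label4Cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(j * nr + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int qi = pi + di[d], qj = pj + dj[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qj * nr + qi);
          }
        }
      }
    }
  }
  return lab;
}

// stamp a polyline stroke of radius rw (um) into img (modified in place):
// pixel (i,j) 0-based has physical centre (j*u, i*u); set to fg when within
// rw of any polyline point
// [[Rcpp::export(name = ".strokeCpp")]]
void strokeCpp(NumericMatrix img, NumericVector xs, NumericVector ys,
               NumericVector rws, double u, double fg) {
  int nr = img.nrow(), nc = img.ncol();
  for (int p = 0; p < xs.size(); ++p) {
    double x = xs[p], y = ys[p];
    double rw = rws[p];
    if (rw <= 0) continue;
    double rw2 = rw * rw;
    int i0 = std::max(0, (int)std::floor((y - rw) / u));
    int i1 = std::min(nr - 1, (int)std::ceil((y + rw) / u));
    int j0 = std::max(0, (int)std::floor((x - rw) / u));
    int j1 = std::min(nc - 1, (int)std::ceil((x + rw) / u));
    for (int j = j0; j <= j1; ++j) {
      double dx = j * u - x;
      for (int i = i0; i <= i1; ++i) {
        double dy = i * u - y;
        if (dx * dx + dy * dy <= rw2) img(i, j) = fg;
      }
    }
  }
}

// 256-bin intensity histogram of values in [0,1]; out-of-range values clamp.
// [[Rcpp::export(name = ".hist256Cpp")]]
IntegerVector hist256Cpp(NumericMatrix x) {
  IntegerVector h(256);
  int n = x.size();
  const double *p = x.begin();
  for (int i = 0; i < n; ++i) {
    double v = p[i];
    int b = (int)(v * 256.0);
    if (b < 0) b = 0; else if (b > 255) b = 255;
    ++h[b];
  }
  return h;
}

// 8-connected component labeling of a binary mask; labels assigned in
// column-major order of first encounter (deterministic).
// [[Rcpp::export(name = ".label8Cpp")]]
IntegerMatrix label8Cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(j * nr + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = next;
              stack.push_back(qj * nr + qi);
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int at(const IntegerMatrix &m, int i, int j) { return m(i, j); }

// Zhang-Suen morphological thinning of a binary mask (1 = foreground).
// Returns a one-pixel-wide 8-connected skeleton.
// [[Rcpp::export(name = ".thinCpp")]]
IntegerMatrix thinCpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m = clone(mask);
  std::vector<std::pair<int,int>> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (!m(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(m, i - 1, j),     p3 = at(m, i - 1, j + 1);
          int p4 = at(m, i,     j + 1), p5 = at(m, i + 1, j + 1);
          int p6 = at(m, i + 1, j),     p7 = at(m, i + 1, j - 1);
          int p8 = at(m, i,     j - 1), p9 = at(m, i - 1, j - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t t = 0; t < del.size(); ++t)
          m(del[t].first, del[t].second) = 0;
      }
    }
  }
  return m;
}
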