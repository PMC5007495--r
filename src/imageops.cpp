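#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Box mean filter with border clipping (window renormalised at edges).
// [[Rcpp::export]]
NumericMatrix box_mean_filter_cpp(NumericMatrix img, int radius) {
  int H = img.nrow(), W = img.ncol();
  // integral image with one-pixel zero border
  std::vector<double> S((H + 1) * (W + 1), 0.0);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      S[(i + 1) * (W + 1) + (j + 1)] =
        img(i, j) + S[i * (W + 1) + (j + 1)] + S[(i + 1) * (W + 1) + j] -
        S[i * (W + 1) + j];
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    int r0 = std::max(0, i - radius), r1 = std::min(H - 1, i + radius);
    for (int j = 0; j < W; ++j) {
      int c0 = std::max(0, j - radius), c1 = std::min(W - 1, j + radius);
      double sum = S[(r1 + 1) * (W + 1) + (c1 + 1)] - S[r0 * (W + 1) + (c1 + 1)] -
                   S[(r1 + 1) * (W + 1) + c0] + S[r0 * (W + 1) + c0];
      out(i, j) = sum / ((r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }
  return out;
}

// Conservative smoothing: clamp each pixel to the [min, max] of its
// neighbourhood (square of given radius, centre excluded).
// [[Rcpp::export]]
NumericMatrix conservative_smooth_cpp(NumericMatrix img, int radius) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int di = -radius; di <= radius; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= H) continue;
        for (int dj = -radius; dj <= radius; ++dj) {
          if (di == 0 && dj == 0) continue;
          int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          double v = img(ii, jj);
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
      }
      double v = img(i, j);
      out(i, j) = v < lo ? lo : (v > hi ? hi : v);
    }
  }
  return out;
}

static std::vector<std::pair<int, int> > disk_offsets(int r) {
  std::vector<std::pair<int, int> > off;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if (di * di + dj * dj <= r * r) off.push_back(std::make_pair(di, dj));
  return off;
}

// Grey-scale erosion / dilation with a disk structuring element.
// [[Rcpp::export]]
NumericMatrix erode_disk_cpp(NumericMatrix img, int radius) {
  int H = img.nrow(), W = img.ncol();
  std::vector<std::pair<int, int> > off = disk_offsets(radius);
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double m = R_PosInf;
      for (size_t k = 0; k < off.size(); ++k) {
        int ii = i + off[k].first, jj = j + off[k].second;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (img(ii, jj) < m) m = img(ii, jj);
      }
      out(i, j) = m;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix dilate_disk_cpp(NumericMatrix img, int radius) {
  int H = img.nrow(), W = img.ncol();
  std::vector<std::pair<int, int> > off = disk_offsets(radius);
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double m = R_NegInf;
      for (size_t k = 0; k < off.size(); ++k) {
        int ii = i + off[k].first, jj = j + off[k].second;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (img(ii, jj) > m) m = img(ii, jj);
      }
      out(i, j) = m;
    }
  return out;
}

// 8-connected components of img >= low. 0 = background, labels 1..K.
// [[Rcpp::export]]
IntegerMatrix label_regions_cpp(NumericMatrix img, double low) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (lab(i, j) != 0 || img(i, j) < low) continue;
      ++next;
      stack.clear();
      stack.push_back(i * W + j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p / W, pj = p % W;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (lab(ii, jj) == 0 && img(ii, jj) >= low) {
              lab(ii, jj) = next;
              stack.push_back(ii * W + jj);
            }
          }
      }
    }
  return lab;
}

// Local maxima above thr with greedy non-maximum suppression (min_dist).
// Returns a k x 3 matrix (row, col, value), 0-based, sorted by value desc.
// [[Rcpp::export]]
NumericMatrix local_maxima_cpp(NumericMatrix img, double thr, double min_dist) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> ri, ci;
  std::vector<double> vv;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double v = img(i, j);
      if (v <= thr) continue;
      bool mx = true;
      for (int di = -1; di <= 1 && mx; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          // strict on earlier (row-major) neighbours breaks plateau ties
          double u = img(ii, jj);
          if (u > v || (u == v && (ii < i || (ii == i && jj < j)))) {
            mx = false;
            break;
          }
        }
      if (mx) { ri.push_back(i); ci.push_back(j); vv.push_back(v); }
    }
  std::vector<size_t> ord(vv.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](size_t a, size_t b) { return vv[a] > vv[b]; });
  std::vector<size_t> keep;
  double d2 = min_dist * min_dist;
  for (size_t a = 0; a < ord.size(); ++a) {
    size_t k = ord[a];
    bool ok = true;
    for (size_t b = 0; b < keep.size(); ++b) {
      size_t m = keep[b];
      double dr = ri[k] - ri[m], dc = ci[k] - ci[m];
      if (dr * dr + dc * dc < d2) { ok = false; break; }
    }
    if (ok) keep.push_back(k);
  }
  NumericMatrix out(keep.size(), 3);
  for (size_t a = 0; a < keep.size(); ++a) {
    out(a, 0) = ri[keep[a]];
    out(a, 1) = ci[keep[a]];
    out(a, 2) = vv[keep[a]];
  }
  return out;
}

// Even-odd scanline fill of a closed polygon (vertices 0-based, row/col,
// implicitly closed). Pixel (i, j) is inside if its centre is.
// [[Rcpp::export]]
LogicalMatrix fill_polygon_cpp(NumericVector pr, NumericVector pc, int H, int W) {
  int n = pr.size();
  LogicalMatrix mask(H, W);
  std::fill(mask.begin(), mask.end(), false);
  double rmin = R_PosInf, rmax = R_NegInf;
  for (int k = 0; k < n; ++k) {
    rmin = std::min(rmin, pr[k]);
    rmax = std::max(rmax, pr[k]);
  }
  int i0 = std::max(0, (int)std::floor(rmin)), i1 = std::min(H - 1, (int)std::ceil(rmax));
  std::vector<double> xs;
  for (int i = i0; i <= i1; ++i) {
    double y = (double)i;
    xs.clear();
    for (int k = 0; k < n; ++k) {
      double y1 = pr[k], y2 = pr[(k + 1) % n];
      double x1 = pc[k], x2 = pc[(k + 1) % n];
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        double t = (y - y1) / (y2 - y1);
        xs.push_back(x1 + t * (x2 - x1));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int j0 = std::max(0, (int)std::ceil(xs[k]));
      int j1 = std::min(W - 1, (int)std::floor(xs[k + 1]));
      for (int j = j0; j <= j1; ++j) mask(i, j) = true;
    }
  }
  return mask;
}

static inline double bilin(const NumericMatrix &G, double r, double c) {
  int H = G.nrow(), W = G.ncol();
  if (r < 0) r = 0;
  if (c < 0) c = 0;
  if (r > H - 1) r = H - 1;
  if (c > W - 1) c = W - 1;
  int i = (int)std::floor(r), j = (int)std::floor(c);
  if (i >= H - 1) i = H - 2;
  if (j >= W - 1) j = W - 2;
  if (i < 0) i = 0;
  if (j < 0) j = 0;
  double fr = r - i, fc = c - j;
  return G(i, j) * (1 - fr) * (1 - fc) + G(i + 1, j) * fr * (1 - fc) +
         G(i, j + 1) * (1 - fr) * fc + G(i + 1, j + 1) * fr * fc;
}

static double signed_area(const std::vector<double> &r,
                          const std::vector<double> &c) {
  int n = r.size();
  double A = 0;
  for (int i = 0; i < n; ++i) {
    int q = (i + 1) % n;
    A += c[i] * r[q] - c[q] * r[i];
  }
  return 0.5 * A;
}

static double snake_total_energy(const std::vector<double> &r,
                                 const std::vector<double> &c,
                                 const NumericMatrix &G, double alpha,
                                 double beta, double gamma, double dbar,
                                 double kappa_sgn) {
  int n = r.size();
  double E = kappa_sgn * signed_area(r, c);
  for (int i = 0; i < n; ++i) {
    int p = (i + n - 1) % n, q = (i + 1) % n;
    double d = std::sqrt((r[i] - r[p]) * (r[i] - r[p]) +
                         (c[i] - c[p]) * (c[i] - c[p]));
    double sr = r[p] + r[q] - 2 * r[i], sc = c[p] + c[q] - 2 * c[i];
    E += alpha * (d - dbar) * (d - dbar) + beta * (sr * sr + sc * sc) -
         gamma * bilin(G, r[i], c[i]);
  }
  return E;
}

// Active contour on a (normalised) gradient-magnitude image G.
// Sequential node moves are evaluated on every energy term the node
// participates in -- continuity (both sides), curvature (own and both
// neighbours), image attraction, and a contraction pressure kappa times
// the enclosed area -- so each accepted move strictly lowers the total
// energy and the per-iteration trace is non-increasing by construction.
// The pressure term is what contracts the contour on featureless
// frames; at a rim the image term dominates and holds the nodes.
// [[Rcpp::export]]
List snake_refine_cpp(NumericMatrix G, NumericMatrix nodes, double alpha,
                      double beta, double gamma, int max_iter, double eps,
                      double step, double kappa = 0.2) {
  int n = nodes.nrow();
  std::vector<double> r(n), c(n);
  for (int i = 0; i < n; ++i) { r[i] = nodes(i, 0); c[i] = nodes(i, 1); }
  // pressure acts against the seed's orientation so it always contracts
  double kappa_sgn = signed_area(r, c) >= 0 ? kappa : -kappa;
  // include half-step candidates: curvature-driven contraction moves by
  // the chord depth R*theta^2/2, which shrinks with node density, and
  // must stay representable or dense contours freeze
  const double offs[7] = {-2 * step, -step, -0.5 * step, 0.0, 0.5 * step,
                          step, 2 * step};
  std::vector<double> e_start, e_end;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    double dbar = 0;
    for (int i = 0; i < n; ++i) {
      int p = (i + n - 1) % n;
      dbar += std::sqrt((r[i] - r[p]) * (r[i] - r[p]) +
                        (c[i] - c[p]) * (c[i] - c[p]));
    }
    dbar /= n;
    e_start.push_back(snake_total_energy(r, c, G, alpha, beta, gamma, dbar,
                                         kappa_sgn));
    double maxmove = 0;
    for (int i = 0; i < n; ++i) {
      int p1 = (i + n - 1) % n, q1 = (i + 1) % n;
      int p2 = (i + n - 2) % n, q2 = (i + 2) % n;
      double best = R_PosInf, br = r[i], bc = c[i];
      for (int a = 0; a < 7; ++a)
        for (int b = 0; b < 7; ++b) {
          double rr = r[i] + offs[a], cc = c[i] + offs[b];
          // continuity terms (i-1,i) and (i,i+1)
          double d1 = std::sqrt((rr - r[p1]) * (rr - r[p1]) +
                                (cc - c[p1]) * (cc - c[p1]));
          double d2 = std::sqrt((r[q1] - rr) * (r[q1] - rr) +
                                (c[q1] - cc) * (c[q1] - cc));
          double E = alpha * ((d1 - dbar) * (d1 - dbar) +
                              (d2 - dbar) * (d2 - dbar));
          // curvature at i-1, i, i+1 (every term involving node i)
          double sr = r[p2] + rr - 2 * r[p1], sc = c[p2] + cc - 2 * c[p1];
          E += beta * (sr * sr + sc * sc);
          sr = r[p1] + r[q1] - 2 * rr; sc = c[p1] + c[q1] - 2 * cc;
          E += beta * (sr * sr + sc * sc);
          sr = rr + r[q2] - 2 * r[q1]; sc = cc + c[q2] - 2 * c[q1];
          E += beta * (sr * sr + sc * sc);
          E -= gamma * bilin(G, rr, cc);
          // pressure: the node's shoelace contribution to the area
          E += kappa_sgn * 0.5 * (rr * (c[p1] - c[q1]) + cc * (r[q1] - r[p1]));
          if (E < best - 1e-12) { best = E; br = rr; bc = cc; }
        }
      double mv = std::sqrt((br - r[i]) * (br - r[i]) +
                            (bc - c[i]) * (bc - c[i]));
      if (mv > maxmove) maxmove = mv;
      r[i] = br; c[i] = bc;
    }
    e_end.push_back(snake_total_energy(r, c, G, alpha, beta, gamma, dbar,
                                       kappa_sgn));
    if (maxmove < eps) { ++it; break; }
  }
  NumericMatrix out(n, 2);
  double img_e = 0;
  for (int i = 0; i < n; ++i) {
    out(i, 0) = r[i];
    out(i, 1) = c[i];
    img_e -= bilin(G, r[i], c[i]);
  }
  return List::create(_["nodes"] = out, _["iterations"] = it,
                      _["energy_start"] = wrap(e_start),
                      _["energy_end"] = wrap(e_end),
                      _["image_energy"] = img_e / n);
}

// Add isotropic Gaussian spots (continuous centres, given amplitudes) to img.
// [[Rcpp::export]]
NumericMatrix render_spots_cpp(NumericMatrix img, NumericVector rows,
                               NumericVector cols, NumericVector amps,
                               double sigma) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out = clone(img);
  int wr = (int)std::ceil(4 * sigma) + 1;
  double s2 = 2 * sigma * sigma;
  for (int k = 0; k < rows.size(); ++k) {
    int ic = (int)std::round(rows[k]), jc = (int)std::round(cols[k]);
    for (int i = std::max(0, ic - wr); i <= std::min(H - 1, ic + wr); ++i)
      for (int j = std::max(0, jc - wr); j <= std::min(W - 1, jc + wr); ++j) {
        double dr = i - rows[k], dc = j - cols[k];
        out(i, j) += amps[k] * std::exp(-(dr * dr + dc * dc) / s2);
      }
  }
  return out;
}

// Seeded region growing: multi-source BFS from seed pixels over
// img >= low. Contested pixels go to the earlier (brighter) seed.
// Returns labels 1..k in seed order, 0 = unclaimed.
// [[Rcpp::export]]
IntegerMatrix region_grow_cpp(NumericMatrix img, IntegerVector seed_rows,
                              IntegerVector seed_cols, double low) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> queue;
  for (int k = 0; k < seed_rows.size(); ++k) {
    int i = seed_rows[k], j = seed_cols[k];
    if (i < 0 || i >= H || j < 0 || j >= W) continue;
    if (lab(i, j) == 0 && img(i, j) >= low) {
      lab(i, j) = k + 1;
      queue.push_back(i * W + j);
    }
  }
  size_t head = 0;
  while (head < queue.size()) {
    int p = queue[head++];
    int pi = p / W, pj = p % W, l = lab(pi, pj);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        int ii = pi + di, jj = pj + dj;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (lab(ii, jj) == 0 && img(ii, jj) >= low) {
          lab(ii, jj) = l;
          queue.push_back(ii * W + jj);
        }
      }
  }
  return lab;
}
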