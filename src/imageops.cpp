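// Low-level raster primitives for worm-posture analysis.
// Image matrices follow the EBImage layout: dim1 = x (width), dim2 = y (height).
// All connectivity is 8-connected unless stated otherwise.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// ---- 8-connected component labeling (union-find) -------------------------

static int uf_find(std::vector<int> &par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int W = mask.nrow(), H = mask.ncol();
  IntegerMatrix lab(W, H);
  std::vector<int> par(1, 0);
  int next = 1;
  // first pass: scan in y-major order, look at already-visited neighbors
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(x, y)) continue;
      int best = 0;
      int nb[4][2] = {{x - 1, y}, {x - 1, y - 1}, {x, y - 1}, {x + 1, y - 1}};
      int roots[4], nr = 0;
      for (int k = 0; k < 4; ++k) {
        int nx = nb[k][0], ny = nb[k][1];
        if (nx < 0 || ny < 0 || nx >= W) continue;
        int l = lab(nx, ny);
        if (l > 0) {
          int r = uf_find(par, l);
          roots[nr++] = r;
          if (best == 0 || r < best) best = r;
        }
      }
      if (best == 0) {
        par.push_back(next);
        lab(x, y) = next++;
      } else {
        lab(x, y) = best;
        for (int k = 0; k < nr; ++k) par[roots[k]] = best;
      }
    }
  }
  // second pass: flatten and renumber 1..n
  std::vector<int> newid(next, 0);
  int n = 0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (lab(x, y) > 0) {
        int r = uf_find(par, lab(x, y));
        if (!newid[r]) newid[r] = ++n;
        lab(x, y) = newid[r];
      }
  lab.attr("n") = n;
  return lab;
}

// ---- multilevel Otsu over a 256-bin histogram -----------------------------
// Exhaustive maximization of between-class variance sum_k w_k * mu_k^2.
// Threshold t assigns bins [lo, t] to the lower class; ties break toward
// the smaller threshold tuple (lexicographically).

// [[Rcpp::export]]
IntegerVector cpp_otsu_multi(NumericVector counts, int m) {
  const int B = counts.size();
  if (B != 256) stop("expected a 256-bin histogram");
  if (m < 1 || m > 3) stop("m must be 1, 2 or 3");
  std::vector<double> cw(B + 1, 0.0), cm(B + 1, 0.0);
  for (int i = 0; i < B; ++i) {
    cw[i + 1] = cw[i] + counts[i];
    cm[i + 1] = cm[i] + counts[i] * i;
  }
  double tot = cw[B];
  if (tot <= 0) stop("empty histogram");
  // class statistic for bins [a, b] inclusive
  auto score = [&](int a, int b) {
    double w = cw[b + 1] - cw[a];
    if (w <= 0) return 0.0;
    double mu = (cm[b + 1] - cm[a]) / w;
    return (w / tot) * mu * mu;
  };
  double best = -1.0;
  IntegerVector th(m);
  if (m == 1) {
    for (int t = 0; t < B - 1; ++t) {
      double s = score(0, t) + score(t + 1, B - 1);
      if (s > best + 1e-12) { best = s; th[0] = t; }
    }
  } else if (m == 2) {
    for (int t1 = 0; t1 < B - 2; ++t1) {
      double s1 = score(0, t1);
      for (int t2 = t1 + 1; t2 < B - 1; ++t2) {
        double s = s1 + score(t1 + 1, t2) + score(t2 + 1, B - 1);
        if (s > best + 1e-12) { best = s; th[0] = t1; th[1] = t2; }
      }
    }
  } else {
    for (int t1 = 0; t1 < B - 3; ++t1) {
      double s1 = score(0, t1);
      for (int t2 = t1 + 1; t2 < B - 2; ++t2) {
        double s2 = s1 + score(t1 + 1, t2);
        for (int t3 = t2 + 1; t3 < B - 1; ++t3) {
          double s = s2 + score(t2 + 1, t3) + score(t3 + 1, B - 1);
          if (s > best + 1e-12) { best = s; th[0] = t1; th[1] = t2; th[2] = t3; }
        }
      }
    }
  }
  return th;
}

// ---- tube rasterizer ------------------------------------------------------
// Union of disks centered on centerline samples (cx, cy) with radii r,
// in raster coordinates (x right, y down), 1-based centers from R.

// [[Rcpp::export]]
IntegerMatrix cpp_render_tube(NumericVector cx, NumericVector cy,
                              NumericVector r, int W, int H) {
  IntegerMatrix out(W, H);
  const int n = cx.size();
  for (int i = 0; i < n; ++i) {
    double xc = cx[i] - 1.0, yc = cy[i] - 1.0, ri = r[i];
    if (ri <= 0) continue;
    int x0 = std::max(0, (int)std::floor(xc - ri)),
        x1 = std::min(W - 1, (int)std::ceil(xc + ri)),
        y0 = std::max(0, (int)std::floor(yc - ri)),
        y1 = std::min(H - 1, (int)std::ceil(yc + ri));
    double r2 = ri * ri;
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        double dx = x - xc, dy = y - yc;
        if (dx * dx + dy * dy <= r2) out(x, y) = 1;
      }
  }
  return out;
}

// Grayscale variant: intensity from the elevation of a cylindrical body,
// max-combined across samples, so self-overlapping coils stay bright.
// [[Rcpp::export]]
NumericMatrix cpp_render_tube_gray(NumericVector cx, NumericVector cy,
                                   NumericVector r, int W, int H) {
  NumericMatrix out(W, H);
  const int n = cx.size();
  for (int i = 0; i < n; ++i) {
    double xc = cx[i] - 1.0, yc = cy[i] - 1.0, ri = r[i];
    if (ri <= 0) continue;
    int x0 = std::max(0, (int)std::floor(xc - ri)),
        x1 = std::min(W - 1, (int)std::ceil(xc + ri)),
        y0 = std::max(0, (int)std::floor(yc - ri)),
        y1 = std::min(H - 1, (int)std::ceil(yc + ri));
    double r2 = ri * ri;
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        double dx = x - xc, dy = y - yc, d2 = dx * dx + dy * dy;
        if (d2 <= r2) {
          double v = std::sqrt(1.0 - d2 / r2);
          if (v > out(x, y)) out(x, y) = v;
        }
      }
  }
  return out;
}

// ---- Zhang-Suen thinning --------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  const int W = mask.nrow(), H = mask.ncol();
  IntegerMatrix img(clone(mask));
  auto at = [&](int x, int y) -> int {
    if (x < 0 || y < 0 || x >= W || y >= H) return 0;
    return img(x, y) ? 1 : 0;
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int y = 0; y < H; ++y)
        for (int x = 0; x < W; ++x) {
          if (!img(x, y)) continue;
          // neighbors P2..P9 clockwise starting at north
          int p[8] = {at(x, y - 1), at(x + 1, y - 1), at(x + 1, y),
                      at(x + 1, y + 1), at(x, y + 1), at(x - 1, y + 1),
                      at(x - 1, y), at(x - 1, y - 1)};
          int bsum = 0, a = 0;
          for (int k = 0; k < 8; ++k) {
            bsum += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
          }
          if (bsum < 2 || bsum > 6 || a != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back({x, y});
        }
      if (!kill.empty()) changed = true;
      for (auto &q : kill) img(q.first, q.second) = 0;
    }
  }
  return img;
}

// ---- skeleton main path ---------------------------------------------------
// Double-BFS over the 8-connected skeleton pixel graph: the path between the
// two mutually farthest pixels is taken as the centerline. Also reports the
// degree-1 endpoints and, for endpoints off the main path, the graph distance
// from the endpoint to the nearest main-path pixel (branch length).

// [[Rcpp::export]]
List cpp_skeleton_path(IntegerMatrix skel) {
  const int W = skel.nrow(), H = skel.ncol();
  std::vector<int> px, py;
  IntegerMatrix id(W, H);
  std::fill(id.begin(), id.end(), -1);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (skel(x, y)) { id(x, y) = px.size(); px.push_back(x); py.push_back(y); }
  const int n = px.size();
  if (n == 0) return List::create(_["path"] = IntegerMatrix(0, 2),
                                  _["endpoints"] = 0,
                                  _["branch_lengths"] = NumericVector(0));
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy) continue;
        int nx = px[i] + dx, ny = py[i] + dy;
        if (nx < 0 || ny < 0 || nx >= W || ny >= H) continue;
        int j = id(nx, ny);
        if (j >= 0) adj[i].push_back(j);
      }
  auto bfs = [&](int src, std::vector<int> &dist, std::vector<int> &par) {
    dist.assign(n, -1); par.assign(n, -1);
    std::queue<int> q; q.push(src); dist[src] = 0;
    int far = src;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      if (dist[u] > dist[far]) far = u;
      for (int v : adj[u]) if (dist[v] < 0) { dist[v] = dist[u] + 1; par[v] = u; q.push(v); }
    }
    return far;
  };
  std::vector<int> dist, par;
  int a = bfs(0, dist, par);
  int b = bfs(a, dist, par);
  // path b -> a via parents, then reverse
  std::vector<int> path;
  for (int u = b; u != -1; u = par[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());
  std::vector<char> onpath(n, 0);
  for (int u : path) onpath[u] = 1;
  // endpoints: degree-1 pixels (isolated pixel counts as endpoint too)
  std::vector<int> eps;
  for (int i = 0; i < n; ++i)
    if (adj[i].size() <= 1) eps.push_back(i);
  // branch length: BFS distance from off-path endpoint to the main path
  std::vector<double> bl;
  for (int e : eps) {
    if (onpath[e]) continue;
    std::vector<int> d(n, -1);
    std::queue<int> q; q.push(e); d[e] = 0;
    int found = -1;
    while (!q.empty() && found < 0) {
      int u = q.front(); q.pop();
      for (int v : adj[u]) {
        if (d[v] >= 0) continue;
        d[v] = d[u] + 1;
        if (onpath[v]) { found = d[v]; break; }
        q.push(v);
      }
    }
    bl.push_back(found < 0 ? (double)n : (double)found);
  }
  IntegerMatrix pm(path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    pm(i, 0) = px[path[i]] + 1;  // 1-based for R
    pm(i, 1) = py[path[i]] + 1;
  }
  return List::create(_["path"] = pm,
                      _["endpoints"] = (int)eps.size(),
                      _["branch_lengths"] = wrap(bl));
}

// ---- Sobel gradient magnitude (replicated border) -------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sobel(NumericMatrix img) {
  const int W = img.nrow(), H = img.ncol();
  NumericMatrix out(W, H);
  auto at = [&](int x, int y) {
    x = std::min(std::max(x, 0), W - 1);
    y = std::min(std::max(y, 0), H - 1);
    return img(x, y);
  };
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double gx = -at(x - 1, y - 1) - 2 * at(x - 1, y) - at(x - 1, y + 1)
                  + at(x + 1, y - 1) + 2 * at(x + 1, y) + at(x + 1, y + 1);
      double gy = -at(x - 1, y - 1) - 2 * at(x, y - 1) - at(x + 1, y - 1)
                  + at(x - 1, y + 1) + 2 * at(x, y + 1) + at(x + 1, y + 1);
      out(x, y) = std::sqrt(gx * gx + gy * gy);
    }
  return out;
}

// ---- local standard deviation filter (box window, integral images) --------

// [[Rcpp::export]]
NumericMatrix cpp_stdfilt(NumericMatrix img, int w) {
  if (w < 1 || w % 2 == 0) stop("window must be odd and >= 1");
  const int W = img.nrow(), H = img.ncol(), h = w / 2;
  std::vector<double> s1((W + 1) * (H + 1), 0.0), s2((W + 1) * (H + 1), 0.0);
  auto I = [&](std::vector<double> &s, int x, int y) -> double & {
    return s[(size_t)y * (W + 1) + x];
  };
  for (int y = 1; y <= H; ++y)
    for (int x = 1; x <= W; ++x) {
      double v = img(x - 1, y - 1);
      I(s1, x, y) = v + I(s1, x - 1, y) + I(s1, x, y - 1) - I(s1, x - 1, y - 1);
      I(s2, x, y) = v * v + I(s2, x - 1, y) + I(s2, x, y - 1) - I(s2, x - 1, y - 1);
    }
  NumericMatrix out(W, H);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int x0 = std::max(0, x - h), x1 = std::min(W - 1, x + h);
      int y0 = std::max(0, y - h), y1 = std::min(H - 1, y + h);
      double nn = (double)(x1 - x0 + 1) * (y1 - y0 + 1);
      double a = I(s1, x1 + 1, y1 + 1) - I(s1, x0, y1 + 1) - I(s1, x1 + 1, y0) + I(s1, x0, y0);
      double b = I(s2, x1 + 1, y1 + 1) - I(s2, x0, y1 + 1) - I(s2, x1 + 1, y0) + I(s2, x0, y0);
      double var = b / nn - (a / nn) * (a / nn);
      out(x, y) = var > 0 ? std::sqrt(var) : 0.0;
    }
  return out;
}

// ---- rotation about the image center, same canvas, background 0 -----------
// bilinear = false gives mask-safe nearest-neighbor sampling (no intensity
// smearing across thin gaps or ragged boundaries)

// [[Rcpp::export]]
NumericMatrix cpp_rotate(NumericMatrix img, double degrees,
                         bool bilinear = true) {
  const int W = img.nrow(), H = img.ncol();
  NumericMatrix out(W, H);
  double th = degrees * M_PI / 180.0, c = std::cos(th), s = std::sin(th);
  double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      // inverse map
      double dx = x - cx, dy = y - cy;
      double sx = c * dx + s * dy + cx, sy = -s * dx + c * dy + cy;
      if (!bilinear) {
        int xi = (int)std::lround(sx), yi = (int)std::lround(sy);
        if (xi >= 0 && yi >= 0 && xi < W && yi < H) out(x, y) = img(xi, yi);
        continue;
      }
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      if (x0 < -1 || y0 < -1 || x0 > W - 1 || y0 > H - 1) continue;
      double fx = sx - x0, fy = sy - y0;
      auto at = [&](int xx, int yy) {
        if (xx < 0 || yy < 0 || xx >= W || yy >= H) return 0.0;
        return img(xx, yy);
      };
      out(x, y) = (1 - fx) * (1 - fy) * at(x0, y0) + fx * (1 - fy) * at(x0 + 1, y0)
                + (1 - fx) * fy * at(x0, y0 + 1) + fx * fy * at(x0 + 1, y0 + 1);
    }
  return out;
}

// ---- holes: background components not touching the border -----------------

static IntegerMatrix bg_labels(IntegerMatrix mask) {
  const int W = mask.nrow(), H = mask.ncol();
  IntegerMatrix inv(W, H);
  for (int i = 0; i < W * H; ++i) inv[i] = mask[i] ? 0 : 1;
  return cpp_label8(inv);
}

// [[Rcpp::export]]
int cpp_count_holes(IntegerMatrix mask) {
  const int W = mask.nrow(), H = mask.ncol();
  IntegerMatrix lab = bg_labels(mask);
  int n = lab.attr("n");
  std::vector<char> border(n + 1, 0);
  for (int x = 0; x < W; ++x) {
    if (lab(x, 0)) border[lab(x, 0)] = 1;
    if (lab(x, H - 1)) border[lab(x, H - 1)] = 1;
  }
  for (int y = 0; y < H; ++y) {
    if (lab(0, y)) border[lab(0, y)] = 1;
    if (lab(W - 1, y)) border[lab(W - 1, y)] = 1;
  }
  int holes = 0;
  for (int k = 1; k <= n; ++k) if (!border[k]) ++holes;
  return holes;
}

// Fill enclosed background components of area <= max_area (keeps worm-scale
// coil holes open while closing pinholes left by edge-based binarization).
// [[Rcpp::export]]
IntegerMatrix cpp_fill_small_holes(IntegerMatrix mask, int max_area) {
  const int W = mask.nrow(), H = mask.ncol();
  IntegerMatrix lab = bg_labels(mask);
  int n = lab.attr("n");
  std::vector<int> area(n + 1, 0);
  std::vector<char> border(n + 1, 0);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int l = lab(x, y);
      if (!l) continue;
      ++area[l];
      if (x == 0 || y == 0 || x == W - 1 || y == H - 1) border[l] = 1;
    }
  IntegerMatrix out(clone(mask));
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int l = lab(x, y);
      if (l && !border[l] && area[l] <= max_area) out(x, y) = 1;
    }
  return out;
}
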