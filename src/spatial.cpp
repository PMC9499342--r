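#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

// ---- k nearest neighbours, O(n^2 k) partial selection -----------------

static void knn_core(const std::vector<double> &x, const std::vector<double> &y,
                     int k, std::vector<int> &idx, std::vector<double> &d2out);

// [[Rcpp::export(name = ".knn_cpp")]]
List knn_cpp(NumericVector xin, NumericVector yin, int k) {
  const int n = xin.size();
  if (k >= n) stop("k must be smaller than the number of points");
  std::vector<double> x(xin.begin(), xin.end()), y(yin.begin(), yin.end());
  std::vector<int> id; std::vector<double> d2;
  knn_core(x, y, k, id, d2);
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < k; ++q) {
      idx(i, q) = id[(size_t)i * k + q] + 1;
      dst(i, q) = std::sqrt(d2[(size_t)i * k + q]);
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dst);
}

// insertion into a sorted best-k buffer
static inline void push_best(double d2, int j, int k, int &m,
                             std::vector<double> &bestd, std::vector<int> &besti) {
  if (m < k) {
    int p = m++;
    while (p > 0 && bestd[p - 1] > d2) {
      bestd[p] = bestd[p - 1]; besti[p] = besti[p - 1]; --p;
    }
    bestd[p] = d2; besti[p] = j;
  } else if (d2 < bestd[k - 1]) {
    int p = k - 1;
    while (p > 0 && bestd[p - 1] > d2) {
      bestd[p] = bestd[p - 1]; besti[p] = besti[p - 1]; --p;
    }
    bestd[p] = d2; besti[p] = j;
  }
}

// shared kNN core: uniform-grid cell lists with expanding ring search;
// falls back to the O(n^2) scan for tiny or degenerate inputs
static void knn_core(const std::vector<double> &x, const std::vector<double> &y,
                     int k, std::vector<int> &idx, std::vector<double> &d2out) {
  const int n = (int)x.size();
  idx.assign((size_t)n * k, 0);
  d2out.assign((size_t)n * k, 0.0);
  std::vector<double> bestd(k);
  std::vector<int> besti(k);

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double w = xmax - xmin, h = ymax - ymin;

  if (n < 256 || w <= 0 || h <= 0) { // brute force
    for (int i = 0; i < n; ++i) {
      int m = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dx = x[i] - x[j], dy = y[i] - y[j];
        push_best(dx * dx + dy * dy, j, k, m, bestd, besti);
      }
      for (int q = 0; q < k; ++q) {
        idx[(size_t)i * k + q] = besti[q];
        d2out[(size_t)i * k + q] = bestd[q];
      }
    }
    return;
  }

  // ~2 points per cell on average
  int ncells = std::max(1, n / 2);
  int ncx = std::max(1, (int)std::sqrt((double)ncells * w / h));
  int ncy = std::max(1, ncells / ncx);
  double cw = w / ncx, ch = h / ncy;
  double mincell = std::min(cw, ch);

  std::vector<int> cellof(n), count(ncx * ncy + 1, 0);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncx - 1, (int)((x[i] - xmin) / cw));
    int cy = std::min(ncy - 1, (int)((y[i] - ymin) / ch));
    cellof[i] = cy * ncx + cx;
    count[cellof[i] + 1]++;
  }
  for (int c = 0; c < ncx * ncy; ++c) count[c + 1] += count[c];
  std::vector<int> bucket(n);
  {
    std::vector<int> cur(count.begin(), count.end() - 1);
    for (int i = 0; i < n; ++i) bucket[cur[cellof[i]]++] = i;
  }

  int maxring = std::max(ncx, ncy);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    const double xi = x[i], yi = y[i];
    int cx = cellof[i] % ncx, cy = cellof[i] / ncx;
    for (int r = 0; r <= maxring; ++r) {
      // stop: every unvisited cell is at ring >= r, hence at distance
      // >= (r - 1) * mincell from the query point
      if (m == k && r >= 2 &&
          bestd[k - 1] <= (double)(r - 1) * (r - 1) * mincell * mincell) break;
      int x0 = cx - r, x1 = cx + r, y0 = cy - r, y1 = cy + r;
      for (int gy = y0; gy <= y1; ++gy) {
        if (gy < 0 || gy >= ncy) continue;
        bool edge_row = (gy == y0 || gy == y1);
        for (int gx = x0; gx <= x1; gx += (edge_row ? 1 : (x1 - x0 > 0 ? x1 - x0 : 1))) {
          if (gx < 0 || gx >= ncx) continue;
          int c = gy * ncx + gx;
          for (int b = count[c]; b < count[c + 1]; ++b) {
            int j = bucket[b];
            if (j == i) continue;
            double dx = xi - x[j], dy = yi - y[j];
            push_best(dx * dx + dy * dy, j, k, m, bestd, besti);
          }
        }
      }
    }
    for (int q = 0; q < k; ++q) {
      idx[(size_t)i * k + q] = besti[q];
      d2out[(size_t)i * k + q] = bestd[q];
    }
  }
}

// ---- union-kNN edge list, deduplicated ---------------------------------
// edge (i, j) exists iff i is among j's k nearest neighbours or vice versa

// [[Rcpp::export(name = ".knn_edges_cpp")]]
List knn_edges_cpp(NumericVector xin, NumericVector yin, int k) {
  const int n = xin.size();
  if (k >= n) stop("k must be smaller than the number of points");
  std::vector<double> x(xin.begin(), xin.end()), y(yin.begin(), yin.end());
  std::vector<int> idx; std::vector<double> d2;
  knn_core(x, y, k, idx, d2);
  std::unordered_map<long long, double> seen;
  seen.reserve((size_t)n * k);
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < k; ++q) {
      int j = idx[(size_t)i * k + q];
      long long a = std::min(i, j), b = std::max(i, j);
      seen.emplace(a * (long long)n + b, d2[(size_t)i * k + q]);
    }
  }
  const int m = (int)seen.size();
  IntegerVector from(m), to(m);
  NumericVector dist(m);
  int r = 0;
  for (auto &kv : seen) {
    from[r] = (int)(kv.first / n) + 1;
    to[r] = (int)(kv.first % n) + 1;
    dist[r] = std::sqrt(kv.second);
    ++r;
  }
  return List::create(_["i"] = from, _["j"] = to, _["dist"] = dist);
}

// ---- union-kNN node scores (sum of incident Gaussian edge weights) -----

// [[Rcpp::export(name = ".knn_scores_cpp")]]
NumericVector knn_scores_cpp(NumericVector xin, NumericVector yin, int k,
                             double r_o) {
  const int n = xin.size();
  if (k >= n) stop("k must be smaller than the number of points");
  std::vector<double> x(xin.begin(), xin.end()), y(yin.begin(), yin.end());
  std::vector<int> idx; std::vector<double> d2;
  knn_core(x, y, k, idx, d2);
  std::unordered_map<long long, double> seen;
  seen.reserve((size_t)n * k);
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < k; ++q) {
      int j = idx[(size_t)i * k + q];
      long long a = std::min(i, j), b = std::max(i, j);
      seen.emplace(a * (long long)n + b, d2[(size_t)i * k + q]);
    }
  }
  NumericVector score(n);
  const double inv = 1.0 / (r_o * r_o);
  for (auto &kv : seen) {
    double w = std::exp(-kv.second * inv);
    score[(int)(kv.first / n)] += w;
    score[(int)(kv.first % n)] += w;
  }
  return score;
}

// ---- median of K-th nearest-neighbour distances ------------------------

// [[Rcpp::export(name = ".kth_nn_dist_cpp")]]
NumericVector kth_nn_dist_cpp(NumericVector xin, NumericVector yin, int k) {
  const int n = xin.size();
  if (k >= n) stop("k must be smaller than the number of points");
  std::vector<double> x(xin.begin(), xin.end()), y(yin.begin(), yin.end());
  std::vector<int> idx; std::vector<double> d2;
  knn_core(x, y, k, idx, d2);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(d2[(size_t)i * k + k - 1]);
  return out;
}

// ---- nearest-neighbour distance per point ------------------------------

// [[Rcpp::export(name = ".nn_dist_cpp")]]
NumericVector nn_dist_cpp(NumericVector xin, NumericVector yin) {
  const int n = xin.size();
  std::vector<double> x(xin.begin(), xin.end()), y(yin.begin(), yin.end());
  std::vector<int> id; std::vector<double> d2;
  knn_core(x, y, 1, id, d2);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(d2[i]);
  return out;
}

// ---- Delaunay triangulation (Bowyer-Watson) ----------------------------

struct Tri {
  int a, b, c;       // vertex indices (0-based, super vertices are n..n+2)
  double cx, cy, r2; // circumcircle
  bool alive;
};

static inline bool circum(double ax, double ay, double bx, double by,
                          double cx, double cy,
                          double &ox, double &oy, double &r2) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-14) return false; // degenerate (collinear)
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
  return true;
}

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericVector xin, NumericVector yin) {
  const int n = xin.size();
  if (n < 3) stop("need at least 3 points");

  // scale into the unit square for numerical stability
  double xmin = min(xin), xmax = max(xin), ymin = min(yin), ymax = max(yin);
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate input: all points coincide");
  std::vector<double> x(n + 3), y(n + 3);
  for (int i = 0; i < n; ++i) {
    x[i] = (xin[i] - xmin) / span;
    y[i] = (yin[i] - ymin) / span;
  }
  // super-triangle comfortably containing the unit square
  x[n] = -50.0;  y[n] = -50.0;
  x[n + 1] = 50.0; y[n + 1] = -50.0;
  x[n + 2] = 0.5; y[n + 2] = 100.0;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  {
    Tri t{n, n + 1, n + 2, 0, 0, 0, true};
    if (!circum(x[t.a], y[t.a], x[t.b], y[t.b], x[t.c], y[t.c], t.cx, t.cy, t.r2))
      stop("internal: super-triangle degenerate");
    tris.push_back(t);
  }

  std::vector<int> bad;
  // boundary edge -> count
  std::unordered_map<long long, std::pair<int, int>> edges;

  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = x[p] - tris[t].cx, dy = y[p] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12)) bad.push_back((int)t);
    }
    if (bad.empty()) stop("degenerate configuration encountered (coincident points?)");
    edges.clear();
    for (int bi : bad) {
      Tri &t = tris[bi];
      t.alive = false;
      int vs[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (auto &e : vs) {
        int u = std::min(e[0], e[1]), v = std::max(e[0], e[1]);
        long long key = (long long)u * (n + 3) + v;
        auto it = edges.find(key);
        if (it == edges.end()) edges[key] = {1, 0};
        else it->second.first++;
      }
    }
    for (auto &kv : edges) {
      if (kv.second.first != 1) continue; // interior edge of the cavity
      int u = (int)(kv.first / (n + 3)), v = (int)(kv.first % (n + 3));
      Tri t;
      t.a = u; t.b = v; t.c = p; t.alive = true;
      if (!circum(x[u], y[u], x[v], y[v], x[p], y[p], t.cx, t.cy, t.r2)) {
        // collinear with cavity edge: skip (point lies on an existing edge line)
        continue;
      }
      tris.push_back(t);
    }
  }

  int m = 0;
  for (auto &t : tris)
    if (t.alive && t.a < n && t.b < n && t.c < n) ++m;
  if (m == 0) stop("degenerate input: points are collinear");
  IntegerMatrix out(m, 3);
  int r = 0;
  for (auto &t : tris) {
    if (!(t.alive && t.a < n && t.b < n && t.c < n)) continue;
    out(r, 0) = t.a + 1; out(r, 1) = t.b + 1; out(r, 2) = t.c + 1;
    ++r;
  }
  return out;
}
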