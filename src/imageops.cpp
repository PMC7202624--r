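#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Matrices are column-major (R convention); index = i + j*nr.

static inline int reflect_idx(int i, int n) {
  // reflect-101-style padding collapsed to simple mirror (edge repeated once)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int k = kernel.size(), r = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // convolve along rows (vertical direction, within each column)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = 0; t < k; ++t)
        s += kernel[t] * img(reflect_idx(i + t - r, nr), j);
      tmp(i, j) = s;
    }
  // convolve along columns (horizontal)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = 0; t < k; ++t)
        s += kernel[t] * tmp(i, reflect_idx(j + t - r, nc));
      out(i, j) = s;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  int w = 2 * radius + 1;
  std::vector<double> buf;
  buf.reserve((size_t)w * w);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -radius; di <= radius; ++di)
          buf.push_back(img(reflect_idx(i + di, nr), jj));
      }
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      // even count cannot occur (w*w odd) but keep exact middle anyway
      out(i, j) = med;
    }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (pixel units, center-to-center) from every
// pixel to the nearest TRUE pixel of `feature`. All-false input -> Inf.
// A large finite sentinel is used internally so parabola intersections
// stay finite; anything above it on output is reported as Inf.
static const double EDT_BIG = 1e15;

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix feature) {
  int nr = feature.nrow(), nc = feature.ncol();
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  // pass along columns (vertical)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i)
      f[i] = feature(i, j) ? 0.0 : EDT_BIG;
    dt1d(f, out, nr);
    for (int i = 0; i < nr; ++i) d(i, j) = out[i];
  }
  // pass along rows (horizontal)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    dt1d(f, out, nc);
    for (int j = 0; j < nc; ++j) d(i, j) = out[j];
  }
  for (int t = 0; t < nr * nc; ++t)
    if (d[t] >= EDT_BIG / 2) d[t] = R_PosInf;
  return d;
}

// Connected component labelling, column-major first-encounter label order.
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int dx4[] = {-1, 1, 0, 0}, dy4[] = {0, 0, -1, 1};
  int dx8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dy8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int *dx = connectivity == 8 ? dx8 : dx4;
  int *dy = connectivity == 8 ? dy8 : dy4;
  int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int t = 0; t < nn; ++t) {
          int ni = ci + dx[t], nj = cj + dy[t];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}

// 2D Euler number with 8-connected foreground / 4-connected background,
// by bit-quad counting over the zero-padded image (Gray's formula):
// E8 = (Q1 - Q3 - 2*Qd) / 4.
// [[Rcpp::export]]
int cpp_euler8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  long q1 = 0, q3 = 0, qd = 0;
  for (int j = -1; j < nc; ++j)
    for (int i = -1; i < nr; ++i) {
      int a = (i >= 0 && j >= 0 && mask(i, j)) ? 1 : 0;
      int b = (i + 1 < nr && j >= 0 && mask(i + 1, j)) ? 1 : 0;
      int c = (i >= 0 && j + 1 < nc && mask(i, j + 1)) ? 1 : 0;
      int d = (i + 1 < nr && j + 1 < nc && mask(i + 1, j + 1)) ? 1 : 0;
      int s = a + b + c + d;
      if (s == 1) ++q1;
      else if (s == 3) ++q3;
      else if (s == 2 && ((a && d && !b && !c) || (b && c && !a && !d))) ++qd;
    }
  long num = q1 - q3 - 2 * qd;
  return (int)(num / 4);
}

// ---- topology-preserving thinning ------------------------------------

// Simple-point lookup for (8,4) connectivity, built by brute force over all
// 256 neighbourhood configurations. Bit k of the config corresponds to
// neighbour offsets in the order:
//   0:(-1,-1) 1:(0,-1) 2:(1,-1) 3:(-1,0) 4:(1,0) 5:(-1,1) 6:(0,1) 7:(1,1)
// (di, dj) with column-major (row, col) offsets.
static bool simple_table[256];
static bool simple_table_ready = false;

static const int off_di[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int off_dj[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

static int count_components_3x3(const int grid[3][3], int target, int conn) {
  // count components of cells==target among the 8 neighbours (centre excluded)
  // that are conn-adjacent (transitively) — restricted to the 3x3 patch —
  // and require each counted component to touch the centre by conn-adjacency.
  bool seen[3][3] = {{false}};
  int comps = 0;
  int dx4[] = {-1, 1, 0, 0}, dy4[] = {0, 0, -1, 1};
  int dx8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dy8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dx = conn == 8 ? dx8 : dx4;
  const int *dy = conn == 8 ? dy8 : dy4;
  int nn = conn == 8 ? 8 : 4;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      if (i == 1 && j == 1) continue;
      if (grid[i][j] != target || seen[i][j]) continue;
      // flood this component
      std::vector<std::pair<int,int> > st;
      st.push_back(std::make_pair(i, j));
      seen[i][j] = true;
      bool touches = false;
      while (!st.empty()) {
        std::pair<int,int> p = st.back(); st.pop_back();
        // adjacency to centre (1,1) under conn
        int adi = p.first - 1, adj = p.second - 1;
        if (conn == 4) {
          if (std::abs(adi) + std::abs(adj) == 1) touches = true;
        } else {
          if (std::max(std::abs(adi), std::abs(adj)) == 1) touches = true;
        }
        for (int t = 0; t < nn; ++t) {
          int ni = p.first + dx[t], nj = p.second + dy[t];
          if (ni < 0 || ni > 2 || nj < 0 || nj > 2) continue;
          if (ni == 1 && nj == 1) continue;
          if (grid[ni][nj] == target && !seen[ni][nj]) {
            seen[ni][nj] = true;
            st.push_back(std::make_pair(ni, nj));
          }
        }
      }
      if (touches) ++comps;
    }
  return comps;
}

static void build_simple_table() {
  for (int cfg = 0; cfg < 256; ++cfg) {
    int grid[3][3];
    for (int k = 0; k < 8; ++k)
      grid[off_di[k] + 1][off_dj[k] + 1] = (cfg >> k) & 1;
    grid[1][1] = 1;
    // simple for (8,4): exactly one 8-connected fg component touching the
    // centre AND exactly one 4-connected bg component 4-adjacent to centre
    int fg = count_components_3x3(grid, 1, 8);
    int bg = count_components_3x3(grid, 0, 4);
    simple_table[cfg] = (fg == 1 && bg == 1);
  }
  simple_table_ready = true;
}

static inline int neigh_config(const std::vector<char> &m, int i, int j,
                               int nr, int nc) {
  int cfg = 0;
  for (int k = 0; k < 8; ++k) {
    int ni = i + off_di[k], nj = j + off_dj[k];
    if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
    if (m[ni + (size_t)nj * nr]) cfg |= (1 << k);
  }
  return cfg;
}

static inline int popcount8(int x) {
  int c = 0;
  for (int k = 0; k < 8; ++k) c += (x >> k) & 1;
  return c;
}

// Thinning to a one-pixel-wide, topology-preserved medial structure.
//
// Candidate border pixels are selected per pass with the Guo-Hall
// two-subiteration masks (which peel symmetric layers, keeping the
// result centered), and then deleted ONE AT A TIME, each deletion gated
// by the sequential simple-point test for the (8-fg, 4-bg) connectivity
// pair. Sequential simple-point removal provably never changes the
// component or hole count; the Guo-Hall masks only steer which simple
// pixels go first. Endpoints (<= 1 foreground neighbour) are kept.
static inline bool guo_hall_cond(const std::vector<char> &m, int i, int j,
                                 int nr, int nc, int sub) {
  // neighbours p2..p9 clockwise from north; out of bounds = background
  int p[10];
  const int ddi[8] = {-1, -1, 0, 1, 1, 1, 0, -1}; // N NE E SE S SW W NW
  const int ddj[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int k = 0; k < 8; ++k) {
    int ni = i + ddi[k], nj = j + ddj[k];
    p[k + 2] = (ni >= 0 && ni < nr && nj >= 0 && nj < nc &&
                m[ni + (size_t)nj * nr]) ? 1 : 0;
  }
  int C = ((!p[2]) & (p[3] | p[4])) + ((!p[4]) & (p[5] | p[6])) +
          ((!p[6]) & (p[7] | p[8])) + ((!p[8]) & (p[9] | p[2]));
  int N1 = (p[9] | p[2]) + (p[3] | p[4]) + (p[5] | p[6]) + (p[7] | p[8]);
  int N2 = (p[2] | p[3]) + (p[4] | p[5]) + (p[6] | p[7]) + (p[8] | p[9]);
  int N = N1 < N2 ? N1 : N2;
  int c3;
  if (sub == 0) c3 = (p[2] | p[3] | (!p[5])) & p[4];
  else          c3 = (p[6] | p[7] | (!p[9])) & p[8];
  return C == 1 && N >= 2 && N <= 3 && c3 == 0;
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  if (!simple_table_ready) build_simple_table();
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> m((size_t)nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[i + (size_t)j * nr] = mask(i, j) ? 1 : 0;

  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      cand.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          int idx = i + j * nr;
          if (m[idx] && guo_hall_cond(m, i, j, nr, nc, sub))
            cand.push_back(idx);
        }
      for (size_t t = 0; t < cand.size(); ++t) {
        int idx = cand[t];
        int i = idx % nr, j = idx / nr;
        int cfg = neigh_config(m, i, j, nr, nc);
        if (popcount8(cfg) <= 1) continue;  // endpoint: keep
        if (!simple_table[cfg]) continue;   // would change topology
        m[idx] = 0;
        changed = true;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = m[i + (size_t)j * nr] != 0;
  return out;
}

// Render ribbons: pixel (centre) is foreground if within halfwidth of any
// segment (x = row coordinate, y = column coordinate, in pixel units,
// 0-based centres). Returns logical mask.
// [[Rcpp::export]]
LogicalMatrix cpp_render_ribbons(int nr, int nc,
                                 NumericVector x0, NumericVector y0,
                                 NumericVector x1, NumericVector y1,
                                 NumericVector halfwidth) {
  LogicalMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), false);
  int ne = x0.size();
  for (int e = 0; e < ne; ++e) {
    double ax = x0[e], ay = y0[e], bx = x1[e], by = y1[e], hw = halfwidth[e];
    double lo_i = std::min(ax, bx) - hw - 1, hi_i = std::max(ax, bx) + hw + 1;
    double lo_j = std::min(ay, by) - hw - 1, hi_j = std::max(ay, by) + hw + 1;
    int i0 = std::max(0, (int)std::floor(lo_i));
    int i1 = std::min(nr - 1, (int)std::ceil(hi_i));
    int j0 = std::max(0, (int)std::floor(lo_j));
    int j1 = std::min(nc - 1, (int)std::ceil(hi_j));
    double vx = bx - ax, vy = by - ay;
    double len2 = vx * vx + vy * vy;
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double px = i - ax, py = j - ay;
        double t = len2 > 0 ? (px * vx + py * vy) / len2 : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double dx = px - t * vx, dy = py - t * vy;
        if (dx * dx + dy * dy <= hw * hw) out(i, j) = true;
      }
  }
  return out;
}
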