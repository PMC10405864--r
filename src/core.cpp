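#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Resampling (separable cubic convolution, Keys kernel a = -0.5, with
// kernel widening for antialiased downsampling)
// ---------------------------------------------------------------------------

static inline double cubic_keys(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0)  return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

struct ResampleWeights {
  std::vector<int> first;            // first source index per output index
  std::vector<std::vector<double> > w;
};

static ResampleWeights make_weights(int n_in, int n_out) {
  ResampleWeights rw;
  rw.first.resize(n_out);
  rw.w.resize(n_out);
  double scale = (double)n_out / (double)n_in;
  double kscale = scale < 1.0 ? scale : 1.0;   // widen kernel when shrinking
  double support = 2.0 / kscale;
  for (int i = 0; i < n_out; ++i) {
    double u = (i + 0.5) / scale - 0.5;        // source coordinate, 0-based
    int lo = (int)std::floor(u - support) + 1;
    int hi = (int)std::floor(u + support);
    std::vector<double> wts;
    double tot = 0.0;
    for (int j = lo; j <= hi; ++j) {
      double wj = cubic_keys((u - j) * kscale) * kscale;
      wts.push_back(wj);
      tot += wj;
    }
    if (tot != 0.0) for (size_t k = 0; k < wts.size(); ++k) wts[k] /= tot;
    rw.first[i] = lo;
    rw.w[i] = wts;
  }
  return rw;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bicubic(NumericMatrix img, int out_nrow, int out_ncol) {
  int nr = img.nrow(), nc = img.ncol();
  if (out_nrow < 1 || out_ncol < 1) stop("output size must be positive");
  ResampleWeights wr = make_weights(nr, out_nrow);
  ResampleWeights wc = make_weights(nc, out_ncol);
  // rows first
  NumericMatrix tmp(out_nrow, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < out_nrow; ++i) {
      double acc = 0.0;
      const std::vector<double>& w = wr.w[i];
      int f = wr.first[i];
      for (size_t k = 0; k < w.size(); ++k) {
        int src = f + (int)k;
        if (src < 0) src = 0; else if (src >= nr) src = nr - 1;
        acc += w[k] * img(src, j);
      }
      tmp(i, j) = acc;
    }
  }
  NumericMatrix out(out_nrow, out_ncol);
  for (int i = 0; i < out_nrow; ++i) {
    for (int j = 0; j < out_ncol; ++j) {
      double acc = 0.0;
      const std::vector<double>& w = wc.w[j];
      int f = wc.first[j];
      for (size_t k = 0; k < w.size(); ++k) {
        int src = f + (int)k;
        if (src < 0) src = 0; else if (src >= nc) src = nc - 1;
        acc += w[k] * tmp(i, src);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local mean (clamped square window) via integral image
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_local_mean(NumericMatrix img, int window) {
  int nr = img.nrow(), nc = img.ncol();
  if (window < 1) stop("window must be >= 1");
  int h1 = (window - 1) / 2, h2 = window - 1 - h1;
  std::vector<double> S((nr + 1) * (size_t)(nc + 1), 0.0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      S[(i + 1) + (size_t)(j + 1) * (nr + 1)] =
        img(i, j) + S[i + (size_t)(j + 1) * (nr + 1)] +
        S[(i + 1) + (size_t)j * (nr + 1)] - S[i + (size_t)j * (nr + 1)];
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int c0 = std::max(0, j - h1), c1 = std::min(nc - 1, j + h2);
    for (int i = 0; i < nr; ++i) {
      int r0 = std::max(0, i - h1), r1 = std::min(nr - 1, i + h2);
      double s = S[(r1 + 1) + (size_t)(c1 + 1) * (nr + 1)]
               - S[r0 + (size_t)(c1 + 1) * (nr + 1)]
               - S[(r1 + 1) + (size_t)c0 * (nr + 1)]
               + S[r0 + (size_t)c0 * (nr + 1)];
      out(i, j) = s / ((double)(r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected components (BFS), selectable 4/8 connectivity
// ---------------------------------------------------------------------------

// union-find over column runs (fast two-pass labeling); `invert` labels the
// complement of bw without materializing it
static void label_core_inv(const int* bw, int nr, int nc, int conn, bool invert,
                           std::vector<int>& lab, std::vector<double>& areas) {
  lab.assign((size_t)nr * nc, 0);
  areas.clear();
  struct Run { int a, b, id; };
  std::vector<Run> prev, cur;
  std::vector<int> parent;
  auto find = [&parent](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<std::vector<Run> > cols(nc);
  int slack = (conn == 8) ? 1 : 0;
  for (int j = 0; j < nc; ++j) {
    cur.clear();
    const int* col = bw + (size_t)j * nr;
    int i = 0;
    while (i < nr) {
      bool v = invert ? !col[i] : (col[i] != 0);
      if (!v) { ++i; continue; }
      int a = i;
      while (i < nr && (invert ? !col[i] : (col[i] != 0))) ++i;
      Run r; r.a = a; r.b = i - 1; r.id = (int)parent.size();
      parent.push_back(r.id);
      cur.push_back(r);
    }
    // union with overlapping runs of the previous column
    size_t pi = 0;
    for (size_t ci = 0; ci < cur.size(); ++ci) {
      int a = cur[ci].a - slack, b = cur[ci].b + slack;
      while (pi < prev.size() && prev[pi].b < a) ++pi;
      size_t pj = pi;
      while (pj < prev.size() && prev[pj].a <= b) {
        int ra = find(prev[pj].id), rb = find(cur[ci].id);
        if (ra != rb) parent[rb] = ra;
        ++pj;
      }
    }
    cols[j] = cur;
    prev.swap(cur);
  }
  // compact labels and areas
  std::vector<int> root_label(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (size_t t = 0; t < cols[j].size(); ++t) {
      int r = find(cols[j][t].id);
      if (!root_label[r]) { root_label[r] = ++next; areas.push_back(0.0); }
      int l = root_label[r];
      areas[l - 1] += cols[j][t].b - cols[j][t].a + 1;
      int* dst = lab.data() + (size_t)j * nr;
      for (int i = cols[j][t].a; i <= cols[j][t].b; ++i) dst[i] = l;
    }
}

static void label_core(const int* bw, int nr, int nc, int conn,
                       std::vector<int>& lab, std::vector<double>& areas) {
  label_core_inv(bw, nr, nc, conn, false, lab, areas);
}

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix bw, int conn) {
  int nr = bw.nrow(), nc = bw.ncol();
  std::vector<int> lab; std::vector<double> areas;
  label_core(LOGICAL(bw), nr, nc, conn, lab, areas);
  IntegerMatrix out(nr, nc);
  std::copy(lab.begin(), lab.end(), INTEGER(out));
  out.attr("areas") = NumericVector(areas.begin(), areas.end());
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_remove_small(LogicalMatrix bw, double min_keep, int conn) {
  int nr = bw.nrow(), nc = bw.ncol();
  std::vector<int> lab; std::vector<double> areas;
  label_core(LOGICAL(bw), nr, nc, conn, lab, areas);
  LogicalMatrix out(nr, nc);
  int* o = LOGICAL(out);
  for (size_t k = 0; k < (size_t)nr * nc; ++k)
    o[k] = lab[k] > 0 && areas[lab[k] - 1] >= min_keep;
  return out;
}

// ---------------------------------------------------------------------------
// Binary morphology with exact Euclidean disks {(dx,dy): dx^2+dy^2 <= r^2}
// ---------------------------------------------------------------------------

static void disk_offsets(int r, std::vector<int>& dr, std::vector<int>& dc) {
  dr.clear(); dc.clear();
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if (a * a + b * b <= r * r) { dr.push_back(a); dc.push_back(b); }
}

static void dilate_core(const int* in, int* out, int nr, int nc, int r) {
  std::vector<int> dr, dc;
  disk_offsets(r, dr, dc);
  std::fill(out, out + (size_t)nr * nc, 0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!in[i + (size_t)j * nr]) continue;
      for (size_t t = 0; t < dr.size(); ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out[ii + (size_t)jj * nr] = 1;
      }
    }
  }
}

// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disk(LogicalMatrix bw, int r) {
  int nr = bw.nrow(), nc = bw.ncol();
  LogicalMatrix out(nr, nc);
  if (r <= 0) { std::copy(LOGICAL(bw), LOGICAL(bw) + (size_t)nr * nc, LOGICAL(out)); return out; }
  dilate_core(LOGICAL(bw), LOGICAL(out), nr, nc, r);
  return out;
}

// erosion: out-of-image treated as foreground (border-preserving)
// [[Rcpp::export]]
LogicalMatrix cpp_erode_disk(LogicalMatrix bw, int r) {
  int nr = bw.nrow(), nc = bw.ncol();
  LogicalMatrix out(nr, nc);
  const int* in = LOGICAL(bw);
  int* o = LOGICAL(out);
  if (r <= 0) { std::copy(in, in + (size_t)nr * nc, o); return out; }
  // a pixel is eroded away iff a background pixel lies within disk r
  std::fill(o, o + (size_t)nr * nc, 1);
  std::vector<int> dr, dc;
  disk_offsets(r, dr, dc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (in[i + (size_t)j * nr]) continue;
      for (size_t t = 0; t < dr.size(); ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) o[ii + (size_t)jj * nr] = 0;
      }
    }
  for (size_t k = 0; k < (size_t)nr * nc; ++k) o[k] = o[k] && in[k];
  return out;
}

// grayscale opening (erosion then dilation) with disk r; replicate-style
// border handling (out-of-image ignored in min/max)
// [[Rcpp::export]]
NumericMatrix cpp_gray_open(NumericMatrix img, int r) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  disk_offsets(r, dr, dc);
  NumericMatrix er(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (size_t t = 0; t < dr.size(); ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = img(ii, jj);
        if (v < m) m = v;
      }
      er(i, j) = m;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (size_t t = 0; t < dr.size(); ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = er(ii, jj);
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

// 3x3 median filter (within-bounds neighborhood)
// [[Rcpp::export]]
NumericMatrix cpp_median3(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b) {
          int ii = i + a, jj = j + b;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          v[n++] = img(ii, jj);
        }
      std::sort(v, v + n);
      out(i, j) = (n % 2) ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
    }
  return out;
}

// ---------------------------------------------------------------------------
// Thinning (Zhang-Suen) to a 1-px skeleton; endpoint pruning; isolated-pixel
// removal
// ---------------------------------------------------------------------------

static inline int nb_state(const std::vector<int>& im, int nr, int nc, int i, int j,
                           int p[8]) {
  // neighbors clockwise: N, NE, E, SE, S, SW, W, NW
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int b = 0;
  for (int t = 0; t < 8; ++t) {
    int ii = i + dr[t], jj = j + dc[t];
    p[t] = (ii >= 0 && ii < nr && jj >= 0 && jj < nc) ? im[ii + (size_t)jj * nr] : 0;
    b += p[t];
  }
  return b;
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix bw) {
  int nr = bw.nrow(), nc = bw.ncol();
  std::vector<int> im(LOGICAL(bw), LOGICAL(bw) + (size_t)nr * nc);
  std::vector<int> kill;
  bool changed = true;
  int p[8];
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          size_t k = i + (size_t)j * nr;
          if (!im[k]) continue;
          int b = nb_state(im, nr, nc, i, j, p);
          if (b < 2 || b > 6) continue;
          int a = 0;
          for (int t = 0; t < 8; ++t) if (!p[t] && p[(t + 1) % 8]) ++a;
          if (a != 1) continue;
          // p[0]=N(P2) p[2]=E(P4) p[4]=S(P6) p[6]=W(P8)
          if (sub == 0) {
            if (p[0] && p[2] && p[4]) continue;
            if (p[2] && p[4] && p[6]) continue;
          } else {
            if (p[0] && p[2] && p[6]) continue;
            if (p[0] && p[4] && p[6]) continue;
          }
          kill.push_back((int)k);
        }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t) im[kill[t]] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  std::copy(im.begin(), im.end(), LOGICAL(out));
  return out;
}

// remove endpoint pixels (<= 1 foreground 8-neighbor) n_iter times
// [[Rcpp::export]]
LogicalMatrix cpp_prune_spurs(LogicalMatrix bw, int n_iter) {
  int nr = bw.nrow(), nc = bw.ncol();
  std::vector<int> im(LOGICAL(bw), LOGICAL(bw) + (size_t)nr * nc);
  int p[8];
  for (int it = 0; it < n_iter; ++it) {
    std::vector<int> kill;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        size_t k = i + (size_t)j * nr;
        if (!im[k]) continue;
        int b = nb_state(im, nr, nc, i, j, p);
        if (b == 1) kill.push_back((int)k);
      }
    if (kill.empty()) break;
    for (size_t t = 0; t < kill.size(); ++t) im[kill[t]] = 0;
  }
  LogicalMatrix out(nr, nc);
  std::copy(im.begin(), im.end(), LOGICAL(out));
  return out;
}

// remove isolated foreground pixels (no foreground 8-neighbor)
// [[Rcpp::export]]
LogicalMatrix cpp_remove_isolated(LogicalMatrix bw) {
  int nr = bw.nrow(), nc = bw.ncol();
  std::vector<int> im(LOGICAL(bw), LOGICAL(bw) + (size_t)nr * nc);
  LogicalMatrix out(nr, nc);
  int* o = LOGICAL(out);
  int p[8];
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      size_t k = i + (size_t)j * nr;
      o[k] = im[k] && nb_state(im, nr, nc, i, j, p) > 0;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Perimeter (8-connectivity: foreground pixel with a background 8-neighbor;
// image border counts as background)
// ---------------------------------------------------------------------------

static double perim_count_core(const int* im, int nr, int nc) {
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  double n = 0;
  for (int j = 0; j < nc; ++j) {
    const int* c0 = im + (size_t)j * nr;
    bool border_col = (j == 0 || j == nc - 1);
    if (!border_col) {
      const int* cl = c0 - nr;
      const int* cru = c0 + nr;
      for (int i = 1; i < nr - 1; ++i) {
        if (!c0[i]) continue;
        if (!c0[i - 1] || !c0[i + 1] ||
            !cl[i - 1] || !cl[i] || !cl[i + 1] ||
            !cru[i - 1] || !cru[i] || !cru[i + 1]) ++n;
      }
      if (c0[0]) ++n;
      if (nr > 1 && c0[nr - 1]) ++n;
    } else {
      for (int i = 0; i < nr; ++i) {
        if (!c0[i]) continue;
        bool edge = false;
        for (int t = 0; t < 8 && !edge; ++t) {
          int ii = i + dr[t], jj = j + dc[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || !im[ii + (size_t)jj * nr])
            edge = true;
        }
        if (edge) ++n;
      }
    }
  }
  return n;
}

// [[Rcpp::export]]
double cpp_perimeter_count(LogicalMatrix bw) {
  return perim_count_core(LOGICAL(bw), bw.nrow(), bw.ncol());
}

// [[Rcpp::export]]
LogicalMatrix cpp_perimeter_image(LogicalMatrix bw) {
  int nr = bw.nrow(), nc = bw.ncol();
  const int* im = LOGICAL(bw);
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  LogicalMatrix out(nr, nc);
  int* o = LOGICAL(out);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      size_t k = i + (size_t)j * nr;
      o[k] = 0;
      if (!im[k]) continue;
      for (int t = 0; t < 8; ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || !im[ii + (size_t)jj * nr]) {
          o[k] = 1; break;
        }
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// Box counting over dyadic box sizes, grid anchored at the image origin
// ---------------------------------------------------------------------------

static void boxcount_core(const int* im, int nr, int nc,
                          std::vector<double>& sizes, std::vector<double>& counts) {
  sizes.clear(); counts.clear();
  int smax = std::min(nr, nc);
  // pyramid of 2x2 OR-reductions: total work ~ 4/3 N
  std::vector<char> cur((size_t)nr * nc), nxt;
  for (size_t k = 0; k < (size_t)nr * nc; ++k) cur[k] = (char)(im[k] != 0);
  int cr = nr, cc = nc;
  for (int s = 1; s <= smax; s *= 2) {
    double n = 0;
    for (size_t k = 0; k < (size_t)cr * cc; ++k) n += cur[k];
    sizes.push_back((double)s);
    counts.push_back(n);
    if (2 * s > smax) break;
    int br = (cr + 1) / 2, bc = (cc + 1) / 2;
    nxt.assign((size_t)br * bc, 0);
    for (int j = 0; j < cc; ++j) {
      const char* src = cur.data() + (size_t)j * cr;
      char* dst = nxt.data() + (size_t)(j / 2) * br;
      for (int i = 0; i < cr; ++i) if (src[i]) dst[i / 2] = 1;
    }
    cur.swap(nxt);
    cr = br; cc = bc;
  }
}

// [[Rcpp::export]]
List cpp_boxcount(LogicalMatrix bw) {
  std::vector<double> s, n;
  boxcount_core(LOGICAL(bw), bw.nrow(), bw.ncol(), s, n);
  return List::create(_["size"] = NumericVector(s.begin(), s.end()),
                      _["count"] = NumericVector(n.begin(), n.end()));
}

static double fd_from_boxcount(const std::vector<double>& s,
                               const std::vector<double>& n) {
  int m = (int)s.size();
  if (m < 2) return NA_REAL;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  for (int i = 0; i < m; ++i) {
    double x = std::log(s[i]), y = std::log(n[i]);
    sx += x; sy += y; sxx += x * x; sxy += x * y;
  }
  double denom = m * sxx - sx * sx;
  if (denom == 0) return NA_REAL;
  return -(m * sxy - sx * sy) / denom;
}

// ---------------------------------------------------------------------------
// Skeleton graph: nodes are foreground pixels with != 2 foreground
// 8-neighbors; segments are the maximal degree-2 chains between nodes.
// Pure cycles get a designated break node. Returned indices are 1-based
// column-major linear indices.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_skeleton_graph(LogicalMatrix bw) {
  int nr = bw.nrow(), nc = bw.ncol();
  const int* im = LOGICAL(bw);
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  size_t N = (size_t)nr * nc;
  std::vector<signed char> deg(N, -1);
  std::vector<int> fg;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      size_t k = i + (size_t)j * nr;
      if (!im[k]) continue;
      int d = 0;
      for (int t = 0; t < 8; ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && im[ii + (size_t)jj * nr]) ++d;
      }
      deg[k] = (signed char)std::min(d, 120);
      fg.push_back((int)k);
    }
  std::vector<bool> is_node(N, false), visited(N, false);
  std::vector<int> nodes;
  for (size_t t = 0; t < fg.size(); ++t) {
    size_t k = fg[t];
    if (deg[k] != 2) { is_node[k] = true; nodes.push_back((int)k); }
  }
  std::vector<IntegerVector> segments;
  std::vector<double> lengths;

  // helper lambdas
  auto neighbors_of = [&](int k, int* out) {
    int i = k % nr, j = k / nr, n = 0;
    for (int t = 0; t < 8; ++t) {
      int ii = i + dr[t], jj = j + dc[t];
      if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) {
        int q = ii + jj * nr;
        if (im[q]) out[n++] = q;
      }
    }
    return n;
  };

  int nb[8];
  // trace chains emanating from nodes
  for (size_t t = 0; t < nodes.size(); ++t) {
    int p = nodes[t];
    int n = neighbors_of(p, nb);
    for (int q0i = 0; q0i < n; ++q0i) {
      int q = nb[q0i];
      if (is_node[q] || visited[q]) continue;
      std::vector<int> chain;
      int prev = p, cur = q;
      while (true) {
        visited[cur] = true;
        chain.push_back(cur + 1);
        int m = neighbors_of(cur, nb);
        int nxt = -1;
        for (int z = 0; z < m; ++z) if (nb[z] != prev) { nxt = nb[z]; break; }
        if (nxt < 0) break;               // dead end (shouldn't happen for deg 2)
        if (is_node[nxt]) break;          // reached a node
        prev = cur; cur = nxt;
      }
      segments.push_back(IntegerVector(chain.begin(), chain.end()));
      lengths.push_back((double)chain.size());
    }
  }
  // remaining unvisited degree-2 pixels form pure cycles
  for (size_t t = 0; t < fg.size(); ++t) {
    int k = fg[t];
    if (is_node[k] || visited[k]) continue;
    // designate k as a break node, trace the cycle from one neighbor
    is_node[k] = true; nodes.push_back(k);
    visited[k] = true;
    int n = neighbors_of(k, nb);
    if (n == 0) continue;
    std::vector<int> chain;
    int prev = k, cur = nb[0];
    while (!is_node[cur] && !visited[cur]) {
      visited[cur] = true;
      chain.push_back(cur + 1);
      int m = neighbors_of(cur, nb);
      int nxt = -1;
      for (int z = 0; z < m; ++z) if (nb[z] != prev) { nxt = nb[z]; break; }
      if (nxt < 0) break;
      prev = cur; cur = nxt;
    }
    if (!chain.empty()) {
      segments.push_back(IntegerVector(chain.begin(), chain.end()));
      lengths.push_back((double)chain.size());
    }
  }
  IntegerVector node_idx(nodes.size());
  for (size_t t = 0; t < nodes.size(); ++t) node_idx[t] = nodes[t] + 1;
  List seglist(segments.size());
  for (size_t t = 0; t < segments.size(); ++t) seglist[t] = segments[t];
  return List::create(_["nodes"] = node_idx,
                      _["segments"] = seglist,
                      _["lengths"] = NumericVector(lengths.begin(), lengths.end()),
                      _["total_px"] = (double)fg.size());
}

// ---------------------------------------------------------------------------
// Metric battery on a binary vessel raster
// ---------------------------------------------------------------------------

static NumericVector metrics_core(const int* im, int nr, int nc,
                                  int center_r, int center_c,   // 0-based
                                  double min_area_px, double px_area_mm2,
                                  double vci_norm, int bg_conn,
                                  int include_border, int sd_pop) {
  size_t N = (size_t)nr * nc;
  double fgn = 0;
  for (size_t k = 0; k < N; ++k) fgn += im[k];
  double vd = fgn / (double)N;
  double per = perim_count_core(im, nr, nc);
  double vpi = per / (double)N;
  double vci = fgn > 0 ? per * per / (4.0 * M_PI * fgn) / vci_norm : NA_REAL;
  double fd = NA_REAL;
  if (fgn >= 2) {
    std::vector<double> s, n;
    boxcount_core(im, nr, nc, s, n);
    fd = fd_from_boxcount(s, n);
  }
  // background components
  std::vector<int> lab; std::vector<double> areas;
  label_core_inv(im, nr, nc, bg_conn, true, lab, areas);
  int nreg = (int)areas.size();

  double faz_area = NA_REAL, faz_px = NA_REAL;
  int faz_lab = 0, fallback = 0;
  if (nreg > 0) {
    size_t ck = center_r + (size_t)center_c * nr;
    int clab = lab[ck];
    if (clab > 0) {
      // rank of clab among areas (descending); count strictly larger regions
      int larger = 0;
      for (int t = 0; t < nreg; ++t) if (areas[t] > areas[clab - 1]) ++larger;
      if (larger < 10) faz_lab = clab;
      else { faz_lab = clab; fallback = 1; }  // containing region outside top-10
    }
    if (clab == 0) {
      // center on vessel: nearest background pixel
      fallback = 1;
      double best = R_PosInf; int bestlab = 0;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          size_t k = i + (size_t)j * nr;
          if (!lab[k]) continue;
          double d = (double)(i - center_r) * (i - center_r) +
                     (double)(j - center_c) * (j - center_c);
          if (d < best) { best = d; bestlab = lab[k]; }
        }
      faz_lab = bestlab;
    }
    if (faz_lab > 0) {
      faz_px = areas[faz_lab - 1];
      faz_area = faz_px * px_area_mm2;
    }
  }

  // border-touching background regions (optionally excluded; FAZ exempt)
  std::vector<char> on_border((size_t)nreg + 1, 0);
  if (!include_border) {
    for (int j = 0; j < nc; ++j) {
      if (lab[0 + (size_t)j * nr]) on_border[lab[0 + (size_t)j * nr]] = 1;
      if (lab[(nr - 1) + (size_t)j * nr]) on_border[lab[(nr - 1) + (size_t)j * nr]] = 1;
    }
    for (int i = 0; i < nr; ++i) {
      if (lab[i]) on_border[lab[i]] = 1;
      if (lab[i + (size_t)(nc - 1) * nr]) on_border[lab[i + (size_t)(nc - 1) * nr]] = 1;
    }
  }

  // PICA statistics over qualifying background regions
  double s1 = 0, s2 = 0; int nq = 0;
  double s1x = 0, s2x = 0; int nqx = 0;  // excluding FAZ
  for (int t = 0; t < nreg; ++t) {
    double a = areas[t];
    if (a < min_area_px) continue;
    if (!include_border && on_border[t + 1] && t + 1 != faz_lab) continue;
    double amm = a * px_area_mm2;
    s1 += amm; s2 += amm * amm; ++nq;
    if (t + 1 != faz_lab) { s1x += amm; s2x += amm * amm; ++nqx; }
  }
  double pmean = nq > 0 ? s1 / nq : NA_REAL;
  double psum = nq > 0 ? s1 : NA_REAL;
  double xmean = nqx > 0 ? s1x / nqx : NA_REAL;
  double xsum = nqx > 0 ? s1x : NA_REAL;
  double psd = NA_REAL, xsd = NA_REAL;
  if (sd_pop) {
    if (nq > 0) psd = std::sqrt(std::max(0.0, (s2 - s1 * s1 / nq) / nq));
    if (nqx > 0) xsd = std::sqrt(std::max(0.0, (s2x - s1x * s1x / nqx) / nqx));
  } else {
    if (nq > 1) psd = std::sqrt(std::max(0.0, (s2 - s1 * s1 / nq) / (nq - 1)));
    if (nqx > 1) xsd = std::sqrt(std::max(0.0, (s2x - s1x * s1x / nqx) / (nqx - 1)));
  }
  double preg = (!ISNA(psd) && psd > 0) ? pmean / psd : NA_REAL;
  double xreg = (!ISNA(xsd) && xsd > 0) ? xmean / xsd : NA_REAL;

  NumericVector out = NumericVector::create(
    _["faz_area_mm2"] = faz_area,
    _["vessel_density"] = vd,
    _["vci"] = vci,
    _["vpi"] = vpi,
    _["fd"] = fd,
    _["pica_mean_mm2"] = pmean,
    _["pica_sum_mm2"] = psum,
    _["pica_regularity"] = preg,
    _["pica_sd_mm2"] = psd,
    _["nf_pica_mean_mm2"] = xmean,
    _["nf_pica_sum_mm2"] = xsum,
    _["nf_pica_regularity"] = xreg,
    _["nf_pica_sd_mm2"] = xsd,
    _["faz_px"] = faz_px,
    _["faz_fallback"] = (double)fallback,
    _["n_pica_regions"] = (double)nq);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_binary_metrics(LogicalMatrix bw, int center_r, int center_c,
                                 double min_area_px, double px_area_mm2,
                                 double vci_norm, int bg_conn,
                                 int include_border, int sd_pop) {
  return metrics_core(LOGICAL(bw), bw.nrow(), bw.ncol(),
                      center_r - 1, center_c - 1, min_area_px, px_area_mm2,
                      vci_norm, bg_conn, include_border, sd_pop);
}

// [[Rcpp::export]]
LogicalMatrix cpp_rebuild(LogicalMatrix full_skeleton, IntegerVector removed_idx,
                          LogicalMatrix large_mask, int dilate_radius) {
  int nr = full_skeleton.nrow(), nc = full_skeleton.ncol();
  if (large_mask.nrow() != nr || large_mask.ncol() != nc)
    stop("dimension mismatch between skeleton and mask");
  size_t N = (size_t)nr * nc;
  std::vector<int> skel(LOGICAL(full_skeleton), LOGICAL(full_skeleton) + N);
  for (int t = 0; t < removed_idx.size(); ++t) {
    int k = removed_idx[t] - 1;
    if (k < 0 || (size_t)k >= N) stop("removed index out of bounds");
    skel[k] = 0;
  }
  LogicalMatrix out(nr, nc);
  dilate_core(skel.data(), LOGICAL(out), nr, nc, dilate_radius);
  const int* m = LOGICAL(large_mask);
  int* o = LOGICAL(out);
  for (size_t k = 0; k < N; ++k) o[k] = o[k] || m[k];
  return out;
}

// fused rebuild + metrics (per-trial fast path)
// [[Rcpp::export]]
NumericVector cpp_rebuild_metrics(LogicalMatrix full_skeleton, IntegerVector removed_idx,
                                  LogicalMatrix large_mask, int dilate_radius,
                                  int center_r, int center_c,
                                  double min_area_px, double px_area_mm2,
                                  double vci_norm, int bg_conn,
                                  int include_border, int sd_pop) {
  int nr = full_skeleton.nrow(), nc = full_skeleton.ncol();
  if (large_mask.nrow() != nr || large_mask.ncol() != nc)
    stop("dimension mismatch between skeleton and mask");
  size_t N = (size_t)nr * nc;
  std::vector<int> skel(LOGICAL(full_skeleton), LOGICAL(full_skeleton) + N);
  for (int t = 0; t < removed_idx.size(); ++t) {
    int k = removed_idx[t] - 1;
    if (k < 0 || (size_t)k >= N) stop("removed index out of bounds");
    skel[k] = 0;
  }
  std::vector<int> img(N);
  dilate_core(skel.data(), img.data(), nr, nc, dilate_radius);
  const int* m = LOGICAL(large_mask);
  for (size_t k = 0; k < N; ++k) img[k] = img[k] || m[k];
  return metrics_core(img.data(), nr, nc, center_r - 1, center_c - 1,
                      min_area_px, px_area_mm2, vci_norm, bg_conn,
                      include_border, sd_pop);
}

// ---------------------------------------------------------------------------
// Nearest-site labeling for the synthetic capillary mesh (Voronoi cells of a
// relaxed point set, plus an optional additively weighted center site whose
// cell forms the avascular zone). Returns labels: 0 = center cell, 1..n = seeds.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_voronoi_labels(NumericVector sx, NumericVector sy,
                                 int nr, int nc,
                                 double center_x, double center_y, double faz_w) {
  int ns = sx.size();
  if (ns < 1) stop("need at least one seed");
  // bucket grid
  double bsz = std::max(4.0, std::sqrt((double)nr * nc / std::max(ns, 1)));
  int br = (int)std::ceil(nr / bsz), bc = (int)std::ceil(nc / bsz);
  if (br < 1) br = 1; if (bc < 1) bc = 1;
  std::vector<std::vector<int> > bucket((size_t)br * bc);
  for (int t = 0; t < ns; ++t) {
    int bi = (int)(sy[t] / bsz), bj = (int)(sx[t] / bsz);
    bi = std::max(0, std::min(br - 1, bi));
    bj = std::max(0, std::min(bc - 1, bj));
    bucket[bi + (size_t)bj * br].push_back(t);
  }
  IntegerMatrix out(nr, nc);
  double fw2 = faz_w * faz_w;
  for (int j = 0; j < nc; ++j) {
    double x = j + 1.0;
    int bj0 = (int)(x / bsz);
    for (int i = 0; i < nr; ++i) {
      double y = i + 1.0;
      int bi0 = (int)(y / bsz);
      double best = R_PosInf; int bestt = -1;
      for (int ring = 0; ring < std::max(br, bc) + 1; ++ring) {
        // scan buckets on the square ring at Chebyshev distance `ring`
        bool any = false;
        for (int a = -ring; a <= ring; ++a)
          for (int b = -ring; b <= ring; ++b) {
            if (std::max(std::abs(a), std::abs(b)) != ring) continue;
            int bi = bi0 + a, bj = bj0 + b;
            if (bi < 0 || bi >= br || bj < 0 || bj >= bc) continue;
            any = true;
            const std::vector<int>& v = bucket[bi + (size_t)bj * br];
            for (size_t z = 0; z < v.size(); ++z) {
              int t = v[z];
              double d = (sx[t] - x) * (sx[t] - x) + (sy[t] - y) * (sy[t] - y);
              if (d < best) { best = d; bestt = t; }
            }
          }
        // can stop once best distance is within the guaranteed-searched radius
        if (bestt >= 0) {
          double safe = (double)ring * bsz;
          if (best <= safe * safe) break;
        }
        if (!any && ring > std::max(br, bc)) break;
      }
      int lab = bestt + 1;
      if (faz_w > 0) {
        double dc2 = (x - center_x) * (x - center_x) + (y - center_y) * (y - center_y);
        if (dc2 - fw2 < best) lab = 0;
      }
      out(i, j) = lab;
    }
  }
  return out;
}

// boundary pixels between differently labeled cells (marks the pixel whose
// right or lower 4-neighbor carries a different label)
// [[Rcpp::export]]
LogicalMatrix cpp_label_boundaries(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool b = false;
      if (i + 1 < nr && lab(i, j) != lab(i + 1, j)) b = true;
      if (!b && j + 1 < nc && lab(i, j) != lab(i, j + 1)) b = true;
      out(i, j) = b;
    }
  return out;
}
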