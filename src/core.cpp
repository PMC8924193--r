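#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Shared 4-neighbourhood in lexicographic (row, col) order. The watershed
// tie-break contract (pop order (elevation, row, col); label taken from the
// lexicographically smallest labelled neighbour) depends on this ordering and
// is mirrored by the pure-R oracle used in the tests.
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {0, -1, 1, 0};

struct WsNode {
  double e;
  long long seq;
  int r, c;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.e != b.e) return a.e > b.e;
    return a.seq > b.seq;  // FIFO at equal elevation (immersion plateaus)
  }
};

// Seeded watershed by priority flooding. Pixels are popped in increasing
// elevation order; at equal elevation, first-in-first-out by insertion
// order, so plateaus flood as breadth-first waves from every labelled
// front (two markers on a flat ridge split at the equidistant column).
// Lexicographic (row, col) order fixes every remaining choice: the initial
// frontier is built by scanning marker pixels and their 4-neighbourhoods in
// (row, col) order, and a popped pixel takes the label of its
// lexicographically smallest labelled 4-neighbour. The pure-R oracle in the
// tests replays exactly this definition. `mask` restricts flooding; pass a
// matrix of all TRUE for an unmasked flood.
// [[Rcpp::export]]
IntegerMatrix cpp_priority_flood(NumericMatrix elev, IntegerMatrix markers,
                                 LogicalMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long seq = 0;

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      lab(r, c) = markers(r, c);

  // queue unlabelled masked neighbours of every marker pixel
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (lab(r, c) <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        int rr = r + DR4[k], cc = c + DC4[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (lab(rr, cc) <= 0 && mask(rr, cc))
          pq.push({elev(rr, cc), seq++, rr, cc});
      }
    }
  }

  while (!pq.empty()) {
    WsNode n = pq.top();
    pq.pop();
    if (lab(n.r, n.c) > 0) continue;  // stale entry
    int assigned = 0;
    for (int k = 0; k < 4 && assigned == 0; ++k) {
      int rr = n.r + DR4[k], cc = n.c + DC4[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) > 0) assigned = lab(rr, cc);
    }
    if (assigned == 0) continue;  // isolated stale entry
    lab(n.r, n.c) = assigned;
    for (int k = 0; k < 4; ++k) {
      int rr = n.r + DR4[k], cc = n.c + DC4[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) <= 0 && mask(rr, cc))
        pq.push({elev(rr, cc), seq++, rr, cc});
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance from every pixel to the nearest FALSE
// (background) pixel of `fg`. Pixels of an all-TRUE image get Inf.
// Internally a large finite sentinel replaces infinity: true infinities
// break the lower-envelope intersection test (s = -inf <= z[0] = -inf).
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  const double BIG = 1e12;  // >> max possible squared distance
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  // pass 1: columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = fg(r, c) ? BIG : 0.0;
    dt_1d(f, out, nr);
    for (int r = 0; r < nr; ++r) d(r, c) = std::min(out[r], BIG);
  }
  // pass 2: rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt_1d(f, out, nc);
    for (int c = 0; c < nc; ++c)
      d(r, c) = out[c] >= BIG / 2 ? INF : out[c];
  }
  return d;
}

// Connected-component labelling of a binary mask; labels assigned in raster
// scan order of each component's first pixel, so output is deterministic.
// connectivity = 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int nb = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? DR8 : DR4;
  const int* dc = (connectivity == 8) ? DC8 : DC4;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r * nc + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p / nc, pc = p % nc;
        for (int k = 0; k < nb; ++k) {
          int rr = pr + dr[k], cc = pc + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr * nc + cc);
          }
        }
      }
    }
  }
  return lab;
}

// Assign each TRUE pixel of `px` to the nearest positive label of `lab`
// (exact Euclidean distance; ties broken towards the lowest label).
// Unreachable pixels (no labelled pixel in the image) get 0.
// Returns the completed label matrix; attribute "dropped" = count unassigned.
// [[Rcpp::export]]
IntegerMatrix cpp_assign_nearest_label(IntegerMatrix lab, LogicalMatrix px) {
  int nr = lab.nrow(), nc = lab.ncol();
  LogicalMatrix not_lab(nr, nc);
  bool any_lab = false;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      not_lab(r, c) = lab(r, c) <= 0;
      if (lab(r, c) > 0) any_lab = true;
    }
  IntegerMatrix out = clone(lab);
  int dropped = 0;
  if (!any_lab) {
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c)
        if (px(r, c)) ++dropped;
    out.attr("dropped") = dropped;
    return out;
  }
  NumericMatrix d2 = cpp_edt_sq(not_lab);  // dist to nearest labelled pixel
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!px(r, c) || lab(r, c) > 0) continue;
      double dd = d2(r, c);
      if (!std::isfinite(dd)) { ++dropped; continue; }
      long long target = (long long)std::llround(dd);
      int R = (int)std::ceil(std::sqrt((double)target)) + 1;
      int best = 0;
      for (int rr = std::max(0, r - R); rr <= std::min(nr - 1, r + R); ++rr) {
        for (int cc = std::max(0, c - R); cc <= std::min(nc - 1, c + R); ++cc) {
          if (lab(rr, cc) <= 0) continue;
          long long dr_ = rr - r, dc_ = cc - c;
          if (dr_ * dr_ + dc_ * dc_ == target) {
            if (best == 0 || lab(rr, cc) < best) best = lab(rr, cc);
          }
        }
      }
      if (best == 0) ++dropped; else out(r, c) = best;
    }
  }
  out.attr("dropped") = dropped;
  return out;
}

// Symmetric Hausdorff distance between two point sets given as n x 2
// matrices (row, col). Brute-force double loop with early exit.
// [[Rcpp::export]]
double cpp_hausdorff(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  double h = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    const NumericMatrix& P = pass == 0 ? a : b;
    const NumericMatrix& Q = pass == 0 ? b : a;
    int np = P.nrow(), nq = Q.nrow();
    for (int i = 0; i < np; ++i) {
      double best = std::numeric_limits<double>::infinity();
      for (int j = 0; j < nq; ++j) {
        double dr = P(i, 0) - Q(j, 0), dc = P(i, 1) - Q(j, 1);
        double d = dr * dr + dc * dc;
        if (d < best) {
          best = d;
          if (best <= h) break;  // cannot raise the running max
        }
      }
      if (best > h) h = best;
    }
  }
  (void)na; (void)nb;
  return std::sqrt(h);
}

// Nearest-seed (Voronoi) partition: label each pixel by the seed minimising
// Euclidean distance (ties -> lowest seed label); pixels farther than
// max_radius from every seed get 0. seeds: n x 3 matrix (row, col, label),
// 0-based coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_voronoi(int nr, int nc, IntegerMatrix seeds,
                          double max_radius) {
  IntegerMatrix lab(nr, nc);
  int ns = seeds.nrow();
  double cap = max_radius * max_radius;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double best = std::numeric_limits<double>::infinity();
      int bl = 0;
      for (int s = 0; s < ns; ++s) {
        double dr = r - seeds(s, 0), dc = c - seeds(s, 1);
        double d = dr * dr + dc * dc;
        if (d < best || (d == best && bl != 0 && seeds(s, 2) < bl)) {
          best = d;
          bl = seeds(s, 2);
        }
      }
      if (best <= cap) lab(r, c) = bl;
    }
  }
  return lab;
}

// 4-connected flood from the image border through non-barrier pixels.
// Returns TRUE where reachable from outside.
// [[Rcpp::export]]
LogicalMatrix cpp_flood_outside(LogicalMatrix barrier) {
  int nr = barrier.nrow(), nc = barrier.ncol();
  LogicalMatrix reach(nr, nc);
  std::vector<int> stack;
  auto push = [&](int r, int c) {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return;
    if (reach(r, c) || barrier(r, c)) return;
    reach(r, c) = true;
    stack.push_back(r * nc + c);
  };
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int r = p / nc, c = p % nc;
    for (int k = 0; k < 4; ++k) push(r + DR4[k], c + DC4[k]);
  }
  return reach;
}
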