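#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas, applied to squared distances column- then row-wise).
// mask: integer matrix, 1 = foreground, 0 = background. Returns the distance
// from every pixel to the nearest background pixel (0 on background).
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_exact_edt(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix sq(nr, nc);
  const double INF = 1e18;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      sq(i, j) = mask(i, j) ? INF : 0.0;
  // columns
  {
    std::vector<double> f(nr), d(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = sq(i, j);
      dt1d(f, d, nr);
      for (int i = 0; i < nr; ++i) sq(i, j) = d[i];
    }
  }
  // rows
  {
    std::vector<double> f(nc), d(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = sq(i, j);
      dt1d(f, d, nc);
      for (int j = 0; j < nc; ++j) sq(i, j) = std::sqrt(d[j]);
    }
  }
  return sq;
}

// ---------------------------------------------------------------------------
// Connected component labelling (4- or 8-connectivity), labels 1..K in
// raster-scan discovery order (deterministic).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Moore boundary tracing of one labelled region (8-connected foreground).
// Returns an ordered closed contour as a matrix of 0-based (row, col) pairs,
// counter-clockwise in image coordinates (row axis pointing down).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(IntegerMatrix lab, int id) {
  int nr = lab.nrow(), nc = lab.ncol();
  // start: topmost, then leftmost pixel of the region
  int sr = -1, sc = -1;
  for (int i = 0; i < nr && sr < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (lab(i, j) == id) { sr = i; sc = j; break; }
  if (sr < 0) return IntegerMatrix(0, 2);
  // clockwise neighbour order starting at W
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  int cr = sr, cc = sc;
  int back = 0; // pretend we entered the start pixel from the W
  auto next_dir = [&](int r, int c, int b) {
    for (int k = 1; k <= 8; ++k) {
      int dir = (b + k) % 8;
      int qi = r + dr[dir], qj = c + dc[dir];
      if (qi >= 0 && qi < nr && qj >= 0 && qj < nc && lab(qi, qj) == id)
        return dir;
    }
    return -1;
  };
  int d0 = next_dir(sr, sc, back);
  if (d0 < 0) { // isolated pixel
    IntegerMatrix out(1, 2);
    out(0, 0) = sr; out(0, 1) = sc;
    return out;
  }
  cr = sr + dr[d0]; cc = sc + dc[d0];
  back = (d0 + 4) % 8;
  rows.push_back(cr); cols.push_back(cc);
  long guard = 0, maxsteps = 8L * (long)nr * nc + 16;
  while (guard++ < maxsteps) {
    int d = next_dir(cr, cc, back);
    if (d < 0) break;
    // stop when about to repeat the initial move out of the start pixel
    if (cr == sr && cc == sc && d == d0) break;
    cr += dr[d]; cc += dc[d];
    back = (d + 4) % 8;
    rows.push_back(cr); cols.push_back(cc);
  }
  // drop the cycle-closing re-entry of the start pixel
  int n = rows.size();
  if (n > 1 && rows[n - 1] == sr && cols[n - 1] == sc) --n;
  IntegerMatrix out(n, 2);
  for (int k = 0; k < n; ++k) { out(k, 0) = rows[k]; out(k, 1) = cols[k]; }
  return out;
}

// ---------------------------------------------------------------------------
// Persistence-based peak regions of a distance field. Foreground pixels are
// processed in decreasing distance order; each regional maximum seeds a
// region, and two regions meeting at a saddle of height s are merged when
// s >= saddle_ratio * (lower peak) or when the lower peak's prominence
// (peak - s) is below prominence_min. The result is a partition of the
// foreground into K peak regions plus the peak height of each.
// ---------------------------------------------------------------------------

struct UF {
  std::vector<int> parent;
  std::vector<double> peak;
  std::vector<double> maxsad; // highest saddle at which a merge was refused
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// [[Rcpp::export]]
List cpp_peak_regions(NumericMatrix dist, double saddle_ratio,
                      double prominence_min) {
  int nr = dist.nrow(), nc = dist.ncol();
  int n = nr * nc;
  std::vector<int> order;
  order.reserve(n);
  for (int p = 0; p < n; ++p)
    if (dist[p] > 0) order.push_back(p);
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (dist[a] != dist[b]) return dist[a] > dist[b];
    return a < b;
  });
  std::vector<int> region(n, -1); // union-find id per pixel, -1 = unprocessed
  UF uf;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (size_t t = 0; t < order.size(); ++t) {
    int p = order[t];
    int pi = p % nr, pj = p / nr;
    double h = dist[p];
    int target = -1;
    for (int k = 0; k < 8; ++k) {
      int qi = pi + dr[k], qj = pj + dc[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      int q = qi + qj * nr;
      if (region[q] < 0) continue;
      int rq = uf.find(region[q]);
      if (target < 0) { target = rq; continue; }
      int rt = uf.find(target);
      if (rq == rt) continue;
      // decide merge: lower-peak region absorbed if saddle high enough
      int hi = (uf.peak[rt] >= uf.peak[rq]) ? rt : rq;
      int lo = (hi == rt) ? rq : rt;
      if (h >= saddle_ratio * uf.peak[lo] || (uf.peak[lo] - h) < prominence_min) {
        uf.parent[lo] = hi;
        if (uf.peak[hi] < uf.peak[lo]) uf.peak[hi] = uf.peak[lo];
        if (uf.maxsad[hi] < uf.maxsad[lo]) uf.maxsad[hi] = uf.maxsad[lo];
        target = hi;
      } else {
        if (uf.maxsad[hi] < h) uf.maxsad[hi] = h;
        if (uf.maxsad[lo] < h) uf.maxsad[lo] = h;
        target = (uf.peak[rt] >= uf.peak[rq]) ? rt : rq; // stay with higher peak
      }
    }
    if (target < 0) {
      int id = uf.parent.size();
      uf.parent.push_back(id);
      uf.peak.push_back(h);
      uf.maxsad.push_back(0.0);
      region[p] = id;
    } else {
      region[p] = uf.find(target);
    }
  }
  // relabel surviving roots 1..K
  std::vector<int> newid(uf.parent.size(), 0);
  int K = 0;
  IntegerMatrix out(nr, nc);
  std::vector<double> peaks, maxsads;
  for (int p = 0; p < n; ++p) {
    if (region[p] < 0) { out[p] = 0; continue; }
    int r = uf.find(region[p]);
    if (!newid[r]) {
      newid[r] = ++K;
      peaks.push_back(uf.peak[r]);
      maxsads.push_back(uf.maxsad[r]);
    }
    out[p] = newid[r];
  }
  return List::create(_["labels"] = out,
                      _["peaks"] = NumericVector(peaks.begin(), peaks.end()),
                      _["maxsad"] = NumericVector(maxsads.begin(), maxsads.end()));
}

// ---------------------------------------------------------------------------
// Marker-controlled priority flood (Meyer's algorithm). Floods the height
// surface from labelled markers, restricted to mask; 4-connected frontier;
// ties broken by insertion order (deterministic). Pixels reached
// simultaneously by two basins get the boundary code -1.
// ---------------------------------------------------------------------------

struct QEntry {
  double h;
  long gen;
  long order;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.h != b.h) return a.h > b.h;     // min-heap on height
    if (a.gen != b.gen) return a.gen > b.gen; // fronts advance ring-by-ring
    return a.order > b.order;             // FIFO for determinism
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed_flood(NumericMatrix height, IntegerMatrix markers,
                                  IntegerMatrix mask) {
  int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr[4] = {-1, 0, 0, 1};
  const int dc[4] = {0, -1, 1, 0};
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long order = 0;
  int n = nr * nc;
  for (int p = 0; p < n; ++p)
    if (markers[p] > 0 && mask[p]) lab[p] = markers[p];
  // seed: unlabeled mask pixels adjacent to a marker
  for (int p = 0; p < n; ++p) {
    if (!mask[p] || lab[p]) continue;
    int pi = p % nr, pj = p / nr;
    for (int k = 0; k < 4; ++k) {
      int qi = pi + dr[k], qj = pj + dc[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (lab(qi, qj) > 0) {
        pq.push({height[p], 0, order++, p, lab(qi, qj)});
        break;
      }
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    if (lab[e.idx]) continue;
    int pi = e.idx % nr, pj = e.idx / nr;
    // distinct basin labels among 4-neighbours
    int l1 = 0;
    bool multi = false;
    for (int k = 0; k < 4; ++k) {
      int qi = pi + dr[k], qj = pj + dc[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      int lq = lab(qi, qj);
      if (lq > 0) {
        if (!l1) l1 = lq;
        else if (lq != l1) multi = true;
      }
    }
    if (!l1) l1 = e.label;
    lab[e.idx] = multi ? -1 : l1;
    if (!multi) {
      for (int k = 0; k < 4; ++k) {
        int qi = pi + dr[k], qj = pj + dc[k];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        int q = qi + qj * nr;
        if (mask[q] && !lab[q]) pq.push({height[q], e.gen + 1, order++, q, l1});
      }
    }
  }
  // sweep: any still-unlabeled mask pixel sits on a ridge -> boundary code
  for (int p = 0; p < n; ++p)
    if (mask[p] && !lab[p]) lab[p] = -1;
  return lab;
}

// ---------------------------------------------------------------------------
// Assign boundary-coded pixels (-1) to the adjacent basin with the lowest
// label so that basins are closed regions for contour extraction.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_merge_boundary(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out = clone(lab);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  bool changed = true;
  while (changed) {
    changed = false;
    IntegerMatrix cur = clone(out);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (cur(i, j) != -1) continue;
        int best = 0;
        for (int k = 0; k < 8; ++k) {
          int qi = i + dr[k], qj = j + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          int lq = cur(qi, qj);
          if (lq > 0 && (best == 0 || lq < best)) best = lq;
        }
        if (best > 0) { out(i, j) = best; changed = true; }
      }
    }
  }
  return out;
}
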