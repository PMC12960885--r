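#include <Rcpp.h>
#include <vector>
#include <deque>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f: input costs, d: output, n: length.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[1] = INF; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double fv = f[v[k]];
    d[q] = (fv == INF) ? INF : (q - v[k]) * (double)(q - v[k]) + fv;
  }
}

//' Exact Euclidean distance transform.
//'
//' Distance (in cell units, between cell centres) from every cell to the
//' nearest TRUE cell; Inf where the mask has no TRUE cell.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass 1: along columns (rows vary)
  std::vector<double> tmp((size_t)nr * nc);
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = mask(i, j) ? 0.0 : INF;
    dt1d(f, d, nr, v, z);
    for (int i = 0; i < nr; i++) tmp[(size_t)j * nr + i] = d[i];
  }
  // pass 2: along rows
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = tmp[(size_t)j * nr + i];
    dt1d(f, d, nc, v, z);
    for (int j = 0; j < nc; j++)
      out(i, j) = (d[j] == INF) ? INF : std::sqrt(d[j]);
  }
  return out;
}

//' Flood-fill reachability: cells of `open` reachable from any `seed` cell
//' through 4- or 8-connected paths of open cells. Seeds themselves are not
//' reported unless they are also open.
//' @noRd
// [[Rcpp::export]]
LogicalMatrix cpp_flood_reach(LogicalMatrix open, LogicalMatrix seeds, int conn) {
  int nr = open.nrow(), nc = open.ncol();
  LogicalMatrix vis(nr, nc);
  std::deque<std::pair<int,int> > q;
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (seeds(i, j)) q.push_back(std::make_pair(i, j));
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (conn == 8) ? 8 : 4;
  while (!q.empty()) {
    std::pair<int,int> p = q.front();
    q.pop_front();
    for (int k = 0; k < ndir; k++) {
      int ri = p.first + dr8[k], ci = p.second + dc8[k];
      if (ri < 0 || ri >= nr || ci < 0 || ci >= nc) continue;
      if (open(ri, ci) && !vis(ri, ci)) {
        vis(ri, ci) = true;
        q.push_back(std::make_pair(ri, ci));
      }
    }
  }
  return vis;
}

//' Connected-component labelling of a boolean mask. Components are numbered
//' 1..k in column-major scan order; background is 0.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (conn == 8) ? 8 : 4;
  int next = 0;
  std::deque<std::pair<int,int> > q;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      next++;
      lab(i, j) = next;
      q.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front();
        q.pop_front();
        for (int k = 0; k < ndir; k++) {
          int ri = p.first + dr8[k], ci = p.second + dc8[k];
          if (ri < 0 || ri >= nr || ci < 0 || ci >= nc) continue;
          if (mask(ri, ci) && lab(ri, ci) == 0) {
            lab(ri, ci) = next;
            q.push_back(std::make_pair(ri, ci));
          }
        }
      }
    }
  }
  return lab;
}

//' Nearest non-zero label: for each query cell (1-based row/col), the
//' Euclidean distance (cell units) to the nearest cell with labels != 0 and
//' that cell's label. Brute force over labelled cells.
//' @noRd
// [[Rcpp::export]]
List cpp_nearest_label(IntegerMatrix labels, IntegerVector qrow, IntegerVector qcol) {
  int nr = labels.nrow(), nc = labels.ncol();
  std::vector<int> lr, lc, lv;
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (labels(i, j) != 0) {
        lr.push_back(i);
        lc.push_back(j);
        lv.push_back(labels(i, j));
      }
  int nq = qrow.size();
  NumericVector dist(nq);
  IntegerVector lab(nq);
  for (int q = 0; q < nq; q++) {
    double best = INF;
    int bl = NA_INTEGER;
    int ri = qrow[q] - 1, ci = qcol[q] - 1;
    for (size_t t = 0; t < lr.size(); t++) {
      double dy = lr[t] - ri, dx = lc[t] - ci;
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bl = lv[t]; }
    }
    dist[q] = (best == INF) ? R_PosInf : std::sqrt(best);
    lab[q] = bl;
  }
  return List::create(_["distance"] = dist, _["label"] = lab);
}
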