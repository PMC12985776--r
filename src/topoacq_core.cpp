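#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Union-find with value-ordered elder rule, shared by both filtrations.
// ---------------------------------------------------------------------------

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n, -1) {}
  void make_set(int i) { parent[i] = i; }
  bool alive(int i) const { return parent[i] >= 0; }
  int find(int i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    while (parent[i] != r) { int nxt = parent[i]; parent[i] = r; i = nxt; }
    return r;
  }
};

// Cubical persistence of a 2D image under the superlevel-set filtration
// (vessels bright). Degree 0 uses 8-connected foreground; degree 1 is
// computed by planar duality as degree-0 of the 4-connected complement
// grown from a virtual border node. Diagrams are reported in the
// flipped (sublevel of the negated image) convention, so death >= birth
// and persistence = death - birth equals the intensity lifetime.
//
// Returns a list with matrices h0, h1; columns (birth, death).
// Zero-persistence pairs are always dropped; pairs with persistence
// <= min_persistence are pruned.
// [[Rcpp::export]]
List cube_persistence_cpp(NumericMatrix img, double min_persistence) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<double> v(n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) v[i + j * nr] = img(i, j);

  double vmin = *std::min_element(v.begin(), v.end());
  double vmax = *std::max_element(v.begin(), v.end());

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> b0, d0, b1, d1;

  // ---- degree 0: superlevel, 8-connectivity, process descending ----
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });
  {
    UnionFind uf(n);
    std::vector<double> birth(n, 0.0);
    const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
    const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
    for (int oi = 0; oi < n; ++oi) {
      int p = order[oi];
      int pr = p % nr, pc = p / nr;
      uf.make_set(p);
      birth[p] = v[p];
      for (int k = 0; k < 8; ++k) {
        int qr = pr + dr[k], qc = pc + dc[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int q = qr + qc * nr;
        if (!uf.alive(q)) continue;
        int ra = uf.find(p), rb = uf.find(q);
        if (ra == rb) continue;
        // elder = larger birth value (appeared earlier in descending sweep)
        int elder = (birth[ra] >= birth[rb]) ? ra : rb;
        int young = (elder == ra) ? rb : ra;
        double pers = birth[young] - v[p];
        if (pers > 0.0 && pers > min_persistence) {
          b0.push_back(-birth[young]);
          d0.push_back(-v[p]);
        }
        uf.parent[young] = elder;
      }
    }
    // essential class(es): grid is connected, so exactly one survives
    int r0 = uf.find(order[0]);
    b0.push_back(-birth[r0]);
    d0.push_back(-vmin);
    (void)vmax;
  }

  // ---- degree 1: dual sublevel of the complement, 4-connectivity ----
  // Virtual node n represents the unbounded outside, processed first.
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] < v[b];
    return a < b;
  });
  {
    UnionFind uf(n + 1);
    std::vector<double> birth(n + 1, 0.0);
    const double NEG_INF = -std::numeric_limits<double>::infinity();
    uf.make_set(n);
    birth[n] = NEG_INF;
    const int dr[4] = {-1, 1, 0, 0};
    const int dc[4] = {0, 0, -1, 1};
    for (int oi = 0; oi < n; ++oi) {
      int p = order[oi];
      int pr = p % nr, pc = p / nr;
      uf.make_set(p);
      birth[p] = v[p];
      bool on_border = (pr == 0 || pr == nr - 1 || pc == 0 || pc == nc - 1);
      for (int k = 0; k < 5; ++k) {
        int q;
        if (k < 4) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          q = qr + qc * nr;
          if (!uf.alive(q)) continue;
        } else {
          if (!on_border) continue;
          q = n;
        }
        int ra = uf.find(p), rb = uf.find(q);
        if (ra == rb) continue;
        int elder = (birth[ra] <= birth[rb]) ? ra : rb;
        int young = (elder == ra) ? rb : ra;
        // hole alive for thresholds in (min inside, saddle]; flipped pair
        double pers = v[p] - birth[young];
        if (pers > 0.0 && pers > min_persistence) {
          b1.push_back(-v[p]);
          d1.push_back(-birth[young]);
        }
        uf.parent[young] = elder;
      }
    }
  }

  NumericMatrix h0(b0.size(), 2), h1(b1.size(), 2);
  for (size_t i = 0; i < b0.size(); ++i) { h0(i, 0) = b0[i]; h0(i, 1) = d0[i]; }
  for (size_t i = 0; i < b1.size(); ++i) { h1(i, 0) = b1[i]; h1(i, 1) = d1[i]; }
  return List::create(_["h0"] = h0, _["h1"] = h1);
}

// ---------------------------------------------------------------------------
// Dense linear assignment (Hungarian algorithm with potentials, O(n^3)).
// Returns 1-based column assigned to each row and the total cost.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List lap_solve_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0)
    return List::create(_["assignment"] = IntegerVector(0), _["cost"] = 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), vpot(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - vpot[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; vpot[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector assignment(n);
  double total = 0.0;
  for (int j = 1; j <= n; ++j) {
    assignment[p[j] - 1] = j;
    total += cost(p[j] - 1, j - 1);
  }
  return List::create(_["assignment"] = assignment, _["cost"] = total);
}

// ---------------------------------------------------------------------------
// Zhang-Suen morphological thinning of a binary mask (8-connectivity
// preserving). Input/output: integer matrix of 0/1.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix zhang_suen_thin_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m = clone(mask);
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return m(r, c);
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<std::pair<int, int> > del;
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int bsum = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (bsum < 2 || bsum > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int a = 0;
          for (int k = 0; k < 8; ++k)
            if (seq[k] == 0 && seq[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k)
        m(del[k].first, del[k].second) = 0;
    }
  }
  return m;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary mask; connectivity 4 or 8.
// Returns an integer matrix of labels (0 = background), labelled 1..K.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  UnionFind uf(n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) uf.make_set(i + j * nr);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = connectivity;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int p = i + j * nr;
      for (int k = 0; k < nnb; ++k) {
        int qr = i + dr8[k], qc = j + dc8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (!mask(qr, qc)) continue;
        int q = qr + qc * nr;
        int ra = uf.find(p), rb = uf.find(q);
        if (ra != rb) uf.parent[std::max(ra, rb)] = std::min(ra, rb);
      }
    }
  }
  IntegerMatrix lab(nr, nc);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) { lab(i, j) = 0; continue; }
      int r = uf.find(i + j * nr);
      if (relabel[r] == 0) relabel[r] = ++next;
      lab(i, j) = relabel[r];
    }
  }
  return lab;
}
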