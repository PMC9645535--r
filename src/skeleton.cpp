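#include <Rcpp.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

// Distance-ordered homotopic thinning. A foreground voxel may be deleted if
// it is "simple" (deletion preserves topology) and not a curve endpoint.
// Candidates are processed in increasing distance-to-background order so the
// surviving curve stays medial. Simplicity follows the standard digital
// topology characterization for (26, 6) adjacency: exactly one 26-connected
// foreground component in the punctured 3x3x3 neighbourhood, and exactly one
// 6-connected background component in the 18-neighbourhood touching a face
// neighbour.

static int off_i[27], off_j[27], off_k[27];
static bool adj26[27][27], adj6[27][27];
static bool n18[27];
static bool init_done = false;

static void init_tables() {
  if (init_done) return;
  for (int p = 0; p < 27; ++p) {
    off_i[p] = p % 3 - 1;
    off_j[p] = (p / 3) % 3 - 1;
    off_k[p] = p / 9 - 1;
    int man = std::abs(off_i[p]) + std::abs(off_j[p]) + std::abs(off_k[p]);
    n18[p] = (man >= 1 && man <= 2);
  }
  for (int p = 0; p < 27; ++p)
    for (int q = 0; q < 27; ++q) {
      int di = std::abs(off_i[p] - off_i[q]);
      int dj = std::abs(off_j[p] - off_j[q]);
      int dk = std::abs(off_k[p] - off_k[q]);
      adj26[p][q] = (p != q && di <= 1 && dj <= 1 && dk <= 1);
      adj6[p][q]  = (p != q && di + dj + dk == 1);
    }
  init_done = true;
}

static bool is_simple(const bool nb[27]) {
  // nb: foreground flags of the 3x3x3 neighbourhood, centre at index 13
  // 1) exactly one 26-component of foreground in N26*
  int comp = 0;
  bool seen[27] = {false};
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !nb[p] || seen[p]) continue;
    ++comp;
    if (comp > 1) return false;
    int stack[27], top = 0;
    stack[top++] = p; seen[p] = true;
    while (top) {
      int v = stack[--top];
      for (int q = 0; q < 27; ++q)
        if (q != 13 && nb[q] && !seen[q] && adj26[v][q]) { seen[q] = true; stack[top++] = q; }
    }
  }
  if (comp != 1) return false;
  // 2) exactly one 6-component of background in N18 touching a face neighbour
  int bcomp = 0;
  bool bseen[27] = {false};
  for (int p = 0; p < 27; ++p) {
    if (!n18[p] || nb[p] || bseen[p]) continue;
    // flood this background component within N18 via 6-adjacency
    bool touches_face = false;
    int stack[27], top = 0;
    stack[top++] = p; bseen[p] = true;
    while (top) {
      int v = stack[--top];
      if (std::abs(off_i[v]) + std::abs(off_j[v]) + std::abs(off_k[v]) == 1)
        touches_face = true;
      for (int q = 0; q < 27; ++q)
        if (n18[q] && !nb[q] && !bseen[q] && adj6[v][q]) { bseen[q] = true; stack[top++] = q; }
    }
    if (touches_face) ++bcomp;
    if (bcomp > 1) return false;
  }
  return bcomp == 1;
}

// [[Rcpp::export]]
IntegerVector skeletonize_cpp(IntegerVector mask, NumericVector dist) {
  init_tables();
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector fg = clone(mask);

  auto neighbourhood = [&](int i, int j, int k, bool nb[27]) {
    for (int p = 0; p < 27; ++p) {
      int i2 = i + off_i[p], j2 = j + off_j[p], k2 = k + off_k[p];
      nb[p] = (i2 >= 0 && j2 >= 0 && k2 >= 0 && i2 < nx && j2 < ny && k2 < nz) &&
              fg[i2 + (R_xlen_t)nx * (j2 + (R_xlen_t)ny * k2)];
    }
  };
  auto n26_count = [&](const bool nb[27]) {
    int c = 0;
    for (int p = 0; p < 27; ++p) if (p != 13 && nb[p]) ++c;
    return c;
  };

  typedef std::tuple<double, R_xlen_t, R_xlen_t> Item;  // (dist, seq, voxel)
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  R_xlen_t seq = 0;
  bool nb[27];
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!fg[v]) continue;
    pq.push(Item(dist[v], seq++, v));
  }
  while (!pq.empty()) {
    R_xlen_t v = std::get<2>(pq.top());
    pq.pop();
    if (!fg[v]) continue;
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    neighbourhood(i, j, k, nb);
    int cnt = n26_count(nb);
    if (cnt <= 1) continue;          // endpoint (or isolated): keep
    if (!is_simple(nb)) continue;
    fg[v] = 0;                        // delete and requeue neighbours
    for (int p = 0; p < 27; ++p) {
      if (p == 13) continue;
      int i2 = i + off_i[p], j2 = j + off_j[p], k2 = k + off_k[p];
      if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz) continue;
      R_xlen_t w = i2 + (R_xlen_t)nx * (j2 + (R_xlen_t)ny * k2);
      if (fg[w]) pq.push(Item(dist[w], seq++, w));
    }
  }
  fg.attr("dim") = d;
  return fg;
}
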