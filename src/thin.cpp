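#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-neighbourhood ring offsets, fixed order: NW N NE W E SW S SE
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline bool inb(int r, int c, int H, int W) {
  return r >= 0 && r < H && c >= 0 && c < W;
}

static int uf_find(int *par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// Local topology of the 3x3 neighbourhood of (r, c), excluding the pixel
// itself. Out-of-image cells count as background.
//   fg8: number of 8-connected components of foreground ring cells
//   bg4: number of 4-connected components of background ring cells that
//        contain a 4-neighbour of (r, c)
//   nfg: number of foreground ring cells
static void local_topology(const LogicalMatrix &m, int r, int c,
                           int &fg8, int &bg4, int &nfg) {
  const int H = m.nrow(), W = m.ncol();
  bool fg[8];
  nfg = 0;
  for (int i = 0; i < 8; i++) {
    int rr = r + DR[i], cc = c + DC[i];
    fg[i] = inb(rr, cc, H, W) && m(rr, cc);
    if (fg[i]) nfg++;
  }
  int par[8];
  for (int i = 0; i < 8; i++) par[i] = i;
  // foreground components under 8-adjacency within the ring
  for (int i = 0; i < 8; i++) {
    if (!fg[i]) continue;
    for (int j = i + 1; j < 8; j++) {
      if (!fg[j]) continue;
      int dr = DR[i] - DR[j], dc = DC[i] - DC[j];
      if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1)
        par[uf_find(par, i)] = uf_find(par, j);
    }
  }
  fg8 = 0;
  for (int i = 0; i < 8; i++)
    if (fg[i] && uf_find(par, i) == i) fg8++;
  // background components under 4-adjacency within the ring
  for (int i = 0; i < 8; i++) par[i] = i;
  for (int i = 0; i < 8; i++) {
    if (fg[i]) continue;
    for (int j = i + 1; j < 8; j++) {
      if (fg[j]) continue;
      int dr = DR[i] - DR[j], dc = DC[i] - DC[j];
      if ((dr == 0 && (dc == 1 || dc == -1)) ||
          (dc == 0 && (dr == 1 || dr == -1)))
        par[uf_find(par, i)] = uf_find(par, j);
    }
  }
  // ring indices of the 4-neighbours: N=1 W=3 E=4 S=6
  static const int four[4] = {1, 3, 4, 6};
  bool counted[8] = {false, false, false, false, false, false, false, false};
  bg4 = 0;
  for (int k = 0; k < 4; k++) {
    int i = four[k];
    if (fg[i]) continue;
    int root = uf_find(par, i);
    if (!counted[root]) { counted[root] = true; bg4++; }
  }
}

//' @noRd
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix m = clone(mask);
  // border-side offsets for the four directional sub-passes; axes are
  // interleaved (N, E, S, W) so both dimensions erode at the same rate
  static const int BR[4] = {-1, 0, 1, 0};
  static const int BC[4] = {0, 1, 0, -1};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; d++) {
      // snapshot this direction's border pixels so only one layer peels per
      // sub-pass (deleting a pixel must not expose its inward neighbour
      // within the same sub-pass, or thinning would lose centering)
      cand.clear();
      for (int c = 0; c < W; c++) {
        for (int r = 0; r < H; r++) {
          if (!m(r, c)) continue;
          int rr = r + BR[d], cc = c + BC[d];
          if (inb(rr, cc, H, W) && m(rr, cc)) continue;
          cand.push_back(r + c * H);
        }
      }
      for (size_t i = 0; i < cand.size(); i++) {
        int r = cand[i] % H, c = cand[i] / H;
        if (!m(r, c)) continue;
        int fg8, bg4, nfg;
        local_topology(m, r, c, fg8, bg4, nfg);
        // delete only simple points that are not endpoints (sequential
        // deletion of simple points preserves homotopy)
        if (nfg >= 2 && fg8 == 1 && bg4 == 1) {
          m(r, c) = false;
          changed = true;
        }
      }
    }
  }
  return m;
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int nn = (connectivity == 8) ? 8 : 4;
  static const int DR4[4] = {-1, 1, 0, 0};
  static const int DC4[4] = {0, 0, -1, 1};
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < W; c++) {
    for (int r = 0; r < H; r++) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(r + c * H);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int cr = idx % H, cc = idx / H;
        for (int i = 0; i < nn; i++) {
          int rr = cr + (nn == 8 ? DR[i] : DR4[i]);
          int ccn = cc + (nn == 8 ? DC[i] : DC4[i]);
          if (!inb(rr, ccn, H, W)) continue;
          if (mask(rr, ccn) && !lab(rr, ccn)) {
            lab(rr, ccn) = next;
            q.push(rr + ccn * H);
          }
        }
      }
    }
  }
  return lab;
}
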