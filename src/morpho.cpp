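#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Clockwise Moore neighborhood, starting West.
static const int DR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
static const int DC[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

static int find_root(std::vector<int> &par, int x) {
  while (par[x] != x) {
    par[x] = par[par[x]];
    x = par[x];
  }
  return x;
}

static void unite(std::vector<int> &par, int a, int b) {
  a = find_root(par, a);
  b = find_root(par, b);
  if (a != b) par[b] = a;
}

// 8-connected component labeling. Labels are assigned 1..n in row-major
// scan order of each component's first pixel (origin top-left).
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> par((size_t)H * W);
  IntegerMatrix out(H, W);

  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j)) continue;
      int id = j * H + i;  // column-major linear index
      par[id] = id;
      // neighbors already visited in row-major scan: NW, N, NE, W
      if (i > 0) {
        if (j > 0 && mask(i - 1, j - 1)) unite(par, (j - 1) * H + (i - 1), id);
        if (mask(i - 1, j)) unite(par, j * H + (i - 1), id);
        if (j < W - 1 && mask(i - 1, j + 1)) unite(par, (j + 1) * H + (i - 1), id);
      }
      if (j > 0 && mask(i, j - 1)) unite(par, (j - 1) * H + i, id);
    }
  }

  std::vector<int> lab((size_t)H * W, 0);
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j)) continue;
      int r = find_root(par, j * H + i);
      if (lab[r] == 0) lab[r] = ++next;
      out(i, j) = lab[r];
    }
  }
  return out;
}

// Outer-boundary perimeter per labeled object by clockwise Moore tracing.
// Step weights: 1 for isothetic moves, sqrt(2) for diagonal moves. Single
// pixels get perimeter 0 (roundness is clamped to 1 downstream).
// [[Rcpp::export(name = ".objectPerimeters")]]
NumericVector objectPerimeters(IntegerMatrix labels, int nlab) {
  const int H = labels.nrow(), W = labels.ncol();
  const double LEN[8] = {1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2};
  NumericVector per(nlab, 0.0);
  std::vector<int> sr(nlab, -1), sc(nlab, -1);
  std::vector<long> area(nlab, 0);

  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int l = labels(i, j);
      if (l > 0) {
        ++area[l - 1];
        if (sr[l - 1] < 0) { sr[l - 1] = i; sc[l - 1] = j; }
      }
    }

  for (int l = 0; l < nlab; ++l) {
    if (area[l] <= 1) continue;
    const int lab = l + 1;
    int cr = sr[l], cc = sc[l];
    // start pixel is first in row-major scan, so its West neighbor is
    // outside the object: valid initial backtrack
    int prev = 0;
    int firstdir = -1;
    bool started = false;
    double p = 0.0;
    long guard = 8L * area[l] + 16;

    while (guard-- > 0) {
      int d = -1, bk = -1;
      for (int k = 1; k <= 8; ++k) {
        int dd = (prev + k) & 7;
        int nr = cr + DR[dd], nc = cc + DC[dd];
        if (nr >= 0 && nr < H && nc >= 0 && nc < W && labels(nr, nc) == lab) {
          d = dd;
          break;
        }
        bk = dd;
      }
      if (d < 0) break;  // no neighbor (cannot happen for area >= 2)
      if (cr == sr[l] && cc == sc[l]) {
        if (!started) { firstdir = d; started = true; }
        else if (d == firstdir) break;  // back at start, about to repeat
      }
      p += LEN[d];
      int nr = cr + DR[d], nc = cc + DC[d];
      // backtrack for the next scan: the background cell checked just
      // before the hit (or the previous backtrack if the hit came first)
      int br, bc;
      if (bk >= 0) { br = cr + DR[bk]; bc = cc + DC[bk]; }
      else { br = cr + DR[prev]; bc = cc + DC[prev]; }
      int ddr = br - nr, ddc = bc - nc, nb = 0;
      for (int t = 0; t < 8; ++t)
        if (DR[t] == ddr && DC[t] == ddc) { nb = t; break; }
      cr = nr; cc = nc; prev = nb;
    }
    per[l] = p;
  }
  return per;
}

// Fill holes: background regions (4-connected) not reachable from the
// image border become foreground.
// [[Rcpp::export(name = ".fillHoles")]]
LogicalMatrix fillHoles(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<char> reach((size_t)H * W, 0);
  std::queue<int> q;
  auto push = [&](int i, int j) {
    int id = j * H + i;
    if (!mask(i, j) && !reach[id]) { reach[id] = 1; q.push(id); }
  };
  for (int j = 0; j < W; ++j) { push(0, j); push(H - 1, j); }
  for (int i = 0; i < H; ++i) { push(i, 0); push(i, W - 1); }
  while (!q.empty()) {
    int id = q.front(); q.pop();
    int i = id % H, j = id / H;
    if (i > 0) push(i - 1, j);
    if (i < H - 1) push(i + 1, j);
    if (j > 0) push(i, j - 1);
    if (j < W - 1) push(i, j + 1);
  }
  LogicalMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      out(i, j) = mask(i, j) || !reach[(size_t)j * H + i];
  return out;
}
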