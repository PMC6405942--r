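#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Max-tree based MSER detector for bright-on-dark regions.
//
// The component tree of the upper level sets is built with the union-find
// max-tree algorithm (pixels processed in decreasing gray order, neighbours
// merged, one canonical element per (component, level) node after the
// canonicalization pass).  Region moments are accumulated along the tree so
// every node carries the area, centroid and second central moments of its
// component.  Stability follows the usual MSER rule: the relative area
// growth towards the ancestor delta gray levels down must be a local
// minimum along the branch and below max_variation; nested detections
// closer than min_diversity in relative area are reduced to the most
// stable one.

static inline int find_root(std::vector<int> &zpar, int p) {
  int r = p;
  while (zpar[r] != r) r = zpar[r];
  while (zpar[p] != r) { int n = zpar[p]; zpar[p] = r; p = n; }
  return r;
}

// [[Rcpp::export(name = ".mser_cpp")]]
List mser_cpp(IntegerMatrix img, int delta, int min_area, int max_area,
              double max_variation, double min_diversity) {
  const int nr = img.nrow(), nc = img.ncol();
  const int N = nr * nc;

  // counting sort, decreasing gray level (levels assumed 0..255)
  const int L = 256;
  std::vector<int> hist(L, 0);
  for (int i = 0; i < N; ++i) hist[img[i]]++;
  std::vector<int> start(L + 1, 0);
  // order[] holds pixels from brightest to dimmest
  for (int l = L - 1; l >= 0; --l) start[l] = (l == L - 1 ? 0 : start[l + 1] + hist[l + 1]);
  std::vector<int> order(N);
  {
    std::vector<int> cur(start.begin(), start.begin() + L);
    for (int i = 0; i < N; ++i) order[cur[img[i]]++] = i;
  }

  std::vector<int> parent(N, -1), zpar(N, -1), rank_pos(N, -1);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  for (int k = 0; k < N; ++k) {
    int p = order[k];
    parent[p] = p; zpar[p] = p; rank_pos[p] = k;
    int pr = p % nr, pc = p / nr;
    for (int d = 0; d < 8; ++d) {
      int r = pr + dr8[d], c = pc + dc8[d];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      int n = r + c * nr;
      if (zpar[n] < 0) continue;          // not processed yet
      int root = find_root(zpar, n);
      if (root != p) { parent[root] = p; zpar[root] = p; }
    }
  }

  // canonicalization: every parent pointer targets a canonical element
  for (int k = N - 1; k >= 0; --k) {
    int p = order[k];
    int q = parent[p];
    if (img[parent[q]] == img[q]) parent[p] = parent[q];
  }

  // accumulate moments child -> parent (children precede parents in order)
  std::vector<double> area(N, 1.0), sx(N), sy(N), sxx(N), syy(N), sxy(N);
  for (int i = 0; i < N; ++i) {
    // x = column, y = row, 0-based pixel-center coordinates
    double x = (double)(i / nr), y = (double)(i % nr);
    sx[i] = x; sy[i] = y; sxx[i] = x * x; syy[i] = y * y; sxy[i] = x * y;
  }
  for (int k = 0; k < N; ++k) {
    int p = order[k], q = parent[p];
    if (q == p) continue;
    area[q] += area[p]; sx[q] += sx[p]; sy[q] += sy[p];
    sxx[q] += sxx[p]; syy[q] += syy[p]; sxy[q] += sxy[p];
  }

  // canonical nodes
  std::vector<int> nodes;
  std::vector<char> is_node(N, 0);
  for (int i = 0; i < N; ++i) {
    if (parent[i] == i || img[parent[i]] != img[i]) { nodes.push_back(i); is_node[i] = 1; }
  }

  // variation: relative area growth to the ancestor >= delta levels below
  std::vector<double> variation(N, R_PosInf);
  for (size_t t = 0; t < nodes.size(); ++t) {
    int n = nodes[t];
    int lev = img[n], a = n;
    while (parent[a] != a && img[parent[a]] > lev - delta) a = parent[a];
    if (parent[a] != a) a = parent[a];   // first node at level <= lev - delta (or root)
    variation[n] = (area[a] - area[n]) / area[n];
  }

  // local-minimum test along parent links
  std::vector<char> maximal(N, 0);
  for (size_t t = 0; t < nodes.size(); ++t) maximal[nodes[t]] = 1;
  for (size_t t = 0; t < nodes.size(); ++t) {
    int n = nodes[t];
    if (parent[n] == n) { maximal[n] = 0; continue; }  // root: whole image
    int p = parent[n];
    if (variation[n] < variation[p]) maximal[p] = 0;
    if (variation[p] < variation[n]) maximal[n] = 0;
  }

  std::vector<int> cand;
  for (size_t t = 0; t < nodes.size(); ++t) {
    int n = nodes[t];
    if (!maximal[n]) continue;
    if (area[n] < min_area || area[n] > max_area) continue;
    if (variation[n] > max_variation) continue;
    cand.push_back(n);
  }

  // nested-duplicate suppression: keep the most stable of close nested pairs
  std::vector<char> keep(N, 0);
  for (size_t t = 0; t < cand.size(); ++t) keep[cand[t]] = 1;
  std::sort(cand.begin(), cand.end(),
            [&](int a, int b) { return area[a] < area[b]; });
  for (size_t t = 0; t < cand.size(); ++t) {
    int n = cand[t];
    if (!keep[n]) continue;
    int a = parent[n];
    while (true) {
      if (keep[a] && a != n) {
        double rel = (area[a] - area[n]) / area[n];
        if (rel < min_diversity) {
          if (variation[n] <= variation[a]) keep[a] = 0; else { keep[n] = 0; break; }
        } else break;  // far enough apart: both stay
      }
      if (parent[a] == a) break;
      a = parent[a];
    }
  }

  std::vector<int> sel;
  for (size_t t = 0; t < cand.size(); ++t) if (keep[cand[t]]) sel.push_back(cand[t]);

  // collect member pixels per selected node
  std::vector<int> sel_id(N, -1);
  for (size_t t = 0; t < sel.size(); ++t) sel_id[sel[t]] = (int)t;
  std::vector<std::vector<int> > members(sel.size());
  if (!sel.empty()) {
    for (int q = 0; q < N; ++q) {
      int n = is_node[q] ? q : parent[q];  // canonical node of pixel q
      while (true) {
        if (sel_id[n] >= 0) members[sel_id[n]].push_back(q);
        if (parent[n] == n) break;
        n = parent[n];
      }
    }
  }

  List out(sel.size());
  for (size_t t = 0; t < sel.size(); ++t) {
    int n = sel[t];
    double a = area[n];
    double cx = sx[n] / a, cy = sy[n] / a;
    double p = sxx[n] / a - cx * cx;
    double r = syy[n] / a - cy * cy;
    double q = sxy[n] / a - cx * cy;
    std::vector<int> &mem = members[t];
    IntegerMatrix px((int)mem.size(), 2);
    for (size_t m = 0; m < mem.size(); ++m) {
      px(m, 0) = mem[m] / nr;   // x (column)
      px(m, 1) = mem[m] % nr;   // y (row)
    }
    out[t] = List::create(
      _["level"] = img[n], _["area"] = a,
      _["cx"] = cx, _["cy"] = cy,
      _["p"] = p, _["q"] = q, _["r"] = r,
      _["variation"] = variation[n],
      _["pixels"] = px);
  }
  return out;
}
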