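#include <Rcpp.h>
using namespace Rcpp;

// Nearest occupied source within the offset neighborhood, for every cell.
// sites: 1-based cell indices (idx = row + (col-1)*n_rows); offsets are the
// precomputed (dr, dc, dist) triples within the capped kernel radius.
// Returns dmin (km, Inf where unreached) and the 1-based position of the
// nearest source in `sites` (0 where unreached).
// [[Rcpp::export]]
List cpp_nearest_source(IntegerVector sites, int n_rows, int n_cols,
                        IntegerVector dr, IntegerVector dc,
                        NumericVector dist) {
  int ncell = n_rows * n_cols;
  NumericVector dmin(ncell, R_PosInf);
  IntegerVector src(ncell, 0);
  int n = sites.size(), m = dr.size();
  for (int i = 0; i < n; ++i) {
    int idx = sites[i] - 1;
    int r = idx % n_rows, c = idx / n_rows;
    for (int j = 0; j < m; ++j) {
      int tr = r + dr[j], tc = c + dc[j];
      if (tr < 0 || tr >= n_rows || tc < 0 || tc >= n_cols) continue;
      int t = tr + tc * n_rows;
      if (dist[j] < dmin[t]) {
        dmin[t] = dist[j];
        src[t] = i + 1;
      }
    }
  }
  return List::create(_["dmin"] = dmin, _["src"] = src);
}

// Connected components of occupied sites under a planar contact distance,
// via union-find over the offset neighborhood. Components are numbered in
// order of their smallest member site index.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector sites, int n_rows, int n_cols,
                             IntegerVector dr, IntegerVector dc) {
  int n = sites.size(), m = dr.size();
  std::vector<int> lut((size_t)n_rows * n_cols, -1);
  for (int i = 0; i < n; ++i) lut[sites[i] - 1] = i;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };
  for (int i = 0; i < n; ++i) {
    int idx = sites[i] - 1;
    int r = idx % n_rows, c = idx / n_rows;
    for (int j = 0; j < m; ++j) {
      int tr = r + dr[j], tc = c + dc[j];
      if (tr < 0 || tr >= n_rows || tc < 0 || tc >= n_cols) continue;
      int hit = lut[tr + tc * n_rows];
      if (hit < 0) continue;
      int a = find(i), b = find(hit);
      if (a != b) parent[b] = a;
    }
  }
  // label components by smallest member site (sites need not be sorted)
  std::vector<int> smallest(n, INT_MAX);
  for (int i = 0; i < n; ++i) {
    int rt = find(i);
    if (sites[i] < smallest[rt]) smallest[rt] = sites[i];
  }
  std::vector<std::pair<int, int> > roots;  // (smallest site, root)
  for (int i = 0; i < n; ++i)
    if (find(i) == i) roots.push_back(std::make_pair(smallest[i], i));
  std::sort(roots.begin(), roots.end());
  std::vector<int> label(n, 0);
  for (size_t k = 0; k < roots.size(); ++k) label[roots[k].second] = k + 1;
  IntegerVector comp(n);
  for (int i = 0; i < n; ++i) comp[i] = label[find(i)];
  return comp;
}
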