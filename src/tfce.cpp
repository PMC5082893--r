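#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Disjoint-set with path halving; used per height step in TFCE and for
// component labelling of masks.
static int ds_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void ds_union(std::vector<int> &parent, std::vector<int> &sz, int a, int b) {
  a = ds_find(parent, a);
  b = ds_find(parent, b);
  if (a == b) return;
  if (sz[a] < sz[b]) std::swap(a, b);
  parent[b] = a;
  sz[a] += sz[b];
}

// Build a CSR neighbour structure over an arbitrary voxel set.
// coords: n x 3 integer matrix of 1-based grid coordinates.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full cube).
// Returns 0-based idx/ptr vectors.
// [[Rcpp::export]]
List build_neighbors_cpp(IntegerMatrix coords, int connectivity) {
  int n = coords.nrow();
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  // hash voxel coordinate -> node index
  std::unordered_map<long long, int> lut;
  lut.reserve(n * 2);
  long long K = 1 << 20;  // grids are far smaller than 2^20 per axis
  for (int i = 0; i < n; i++) {
    long long key = (long long)coords(i, 0) + K * ((long long)coords(i, 1) + K * (long long)coords(i, 2));
    lut[key] = i;
  }
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; dx++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dz = -1; dz <= 1; dz++) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; i++) {
    for (auto &o : offs) {
      long long key = (long long)(coords(i, 0) + o[0]) +
                      K * ((long long)(coords(i, 1) + o[1]) + K * (long long)(coords(i, 2) + o[2]));
      auto it = lut.find(key);
      if (it != lut.end()) nb[i].push_back(it->second);
    }
  }
  IntegerVector ptr(n + 1);
  int total = 0;
  for (int i = 0; i < n; i++) {
    ptr[i] = total;
    total += (int)nb[i].size();
  }
  ptr[n] = total;
  IntegerVector idx(total);
  int k = 0;
  for (int i = 0; i < n; i++)
    for (int j : nb[i]) idx[k++] = j;
  return List::create(_["idx"] = idx, _["ptr"] = ptr, _["n"] = n);
}

// Threshold-free cluster enhancement of a non-negative statistic map defined
// on an arbitrary node set with CSR neighbours. Heights are the right
// endpoints h = s * dh, s = 1..nsteps, dh = max(stat)/nsteps; voxels with
// stat >= h belong to the suprathreshold set (so the global maximum
// contributes at every step including the last).
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector nbr_idx, IntegerVector nbr_ptr,
                       double E, double H, int nsteps) {
  int n = stat.size();
  NumericVector out(n);
  double hmax = 0.0;
  for (int i = 0; i < n; i++) {
    if (NumericVector::is_na(stat[i])) stop("statistic map contains NA");
    if (stat[i] > hmax) hmax = stat[i];
  }
  if (hmax <= 0.0) return out;
  double dh = hmax / nsteps;
  // process heights descending so components only merge; voxels activate
  // once, in decreasing-stat order
  std::vector<int> ord(n);
  for (int i = 0; i < n; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });
  std::vector<int> parent(n), sz(n, 1);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; i++) parent[i] = i;
  int done = 0;
  for (int s = nsteps; s >= 1; s--) {
    double h = s * dh;
    while (done < n && stat[ord[done]] >= h) {
      int i = ord[done++];
      active[i] = 1;
      for (int k = nbr_ptr[i]; k < nbr_ptr[i + 1]; k++) {
        int j = nbr_idx[k];
        if (active[j]) ds_union(parent, sz, i, j);
      }
    }
    double hH = std::pow(h, H) * dh;
    int last_root = -1;
    double last_val = 0.0;
    for (int a = 0; a < done; a++) {
      int i = ord[a];
      int r = ds_find(parent, i);
      if (r != last_root) {             // components are contiguous runs only
        last_root = r;                  // sometimes; cache still cuts pow calls
        last_val = std::pow((double)sz[r], E) * hH;
      }
      out[i] += last_val;
    }
  }
  return out;
}

// Connected-component labels (1-based, 0 = outside) for a logical mask over
// the node set; components numbered by order of first node appearance.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector nbr_idx, IntegerVector nbr_ptr) {
  int n = mask.size();
  std::vector<int> parent(n), sz(n, 1);
  for (int i = 0; i < n; i++) parent[i] = i;
  for (int i = 0; i < n; i++) {
    if (!mask[i]) continue;
    for (int k = nbr_ptr[i]; k < nbr_ptr[i + 1]; k++) {
      int j = nbr_idx[k];
      if (j > i && mask[j]) ds_union(parent, sz, i, j);
    }
  }
  IntegerVector lab(n);
  std::unordered_map<int, int> seen;
  int next = 0;
  for (int i = 0; i < n; i++) {
    if (!mask[i]) { lab[i] = 0; continue; }
    int r = ds_find(parent, i);
    auto it = seen.find(r);
    if (it == seen.end()) { seen[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
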