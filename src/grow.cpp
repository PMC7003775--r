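#include <Rcpp.h>
#include <queue>
#include <vector>
#include <functional>
#include <cmath>
using namespace Rcpp;

// Neighbor offsets for 26-connectivity (3-D) or 8-connectivity restricted to
// the seed's slice (2-D mode). Offsets are in (x,y,z) voxel steps.
static inline void neighbor_offsets(bool slice_mode,
                                    std::vector<std::array<int,3> > &offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz) {
    if (slice_mode && dz != 0) continue;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs.push_back({dx, dy, dz});
      }
  }
}

// Seeded region growing with a running-mean acceptance band.
// Frontier voxels are evaluated exactly once, in increasing linear-index order
// (lexicographic over (x,y,z) with x fastest), which makes the result
// deterministic. A frontier voxel v is accepted iff
//   |I(v) - mu_R| <= max(tol_frac * |mu_R|, eps_abs)
// where mu_R is the mean intensity of the voxels accepted so far.
// [[Rcpp::export(name = ".rg_core")]]
LogicalVector rg_core(NumericVector vol, IntegerVector dim,
                      int seed_linear, double tol_frac, double eps_abs,
                      bool slice_mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (seed_linear < 0 || seed_linear >= n) stop("seed index out of range");
  if (!R_finite(vol[seed_linear])) stop("seed lies on a non-finite voxel");

  std::vector<char> state(n, 0); // 0 unseen, 1 queued/evaluated, 2 accepted
  std::vector<std::array<int,3> > offs;
  neighbor_offsets(slice_mode, offs);

  std::priority_queue<R_xlen_t, std::vector<R_xlen_t>,
                      std::greater<R_xlen_t> > frontier;

  double sum = vol[seed_linear];
  R_xlen_t cnt = 1;
  state[seed_linear] = 2;

  const int sx = seed_linear % nx;
  const int sy = (seed_linear / nx) % ny;
  const int sz = seed_linear / (nx * ny);

  // push neighbours of one accepted voxel
  std::function<void(int,int,int)> push_nb = [&](int x, int y, int z) {
    for (size_t k = 0; k < offs.size(); ++k) {
      const int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const R_xlen_t li = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (state[li] == 0) { state[li] = 1; frontier.push(li); }
    }
  };
  push_nb(sx, sy, sz);

  while (!frontier.empty()) {
    const R_xlen_t v = frontier.top();
    frontier.pop();
    const double iv = vol[v];
    if (!R_finite(iv)) continue; // evaluated once, rejected
    const double mu = sum / cnt;
    const double band = std::max(tol_frac * std::fabs(mu), eps_abs);
    if (std::fabs(iv - mu) <= band) {
      state[v] = 2;
      sum += iv; cnt += 1;
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      push_nb(x, y, z);
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (state[i] == 2);
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling of a logical 3-D mask.
// Returns an integer volume: 0 outside the mask, components numbered 1..K
// in order of first (smallest linear index) occurrence.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3> > offs;
  neighbor_offsets(false, offs);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (size_t k = 0; k < offs.size(); ++k) {
        const int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t li = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[li] && lab[li] == 0) { lab[li] = next; stack.push_back(li); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
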