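#include <Rcpp.h>
#include <unordered_set>
#include <array>
#include <vector>
using namespace Rcpp;

// Pack a lattice site into a 64-bit key; collision-free for |coord| < 2^20.
static inline long long site_key(int x, int y, int z) {
  const long long mask = (1LL << 21) - 1;
  return (((long long)x & mask) << 42) |
         (((long long)y & mask) << 21) |
         ((long long)z & mask);
}

// Pivot Monte Carlo for a self-avoiding walk on the cubic lattice.
// Starts from a straight rod along x; each attempt picks an interior pivot
// monomer and a random non-identity element of the octahedral group, applies
// it to the shorter arm, and accepts iff no lattice site is occupied twice.
// Uses R's RNG, so set.seed() reproducibility carries through.
// [[Rcpp::export]]
List saw_pivot_cpp(int n, int attempts) {
  IntegerMatrix coords(n, 3);
  for (int i = 0; i < n; ++i) coords(i, 0) = i;

  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  // persistent occupancy set: only the moving arm is removed/re-inserted
  std::unordered_set<long long> occ;
  occ.reserve(8 * n);
  occ.max_load_factor(0.5f);
  for (int i = 0; i < n; ++i)
    occ.insert(site_key(coords(i, 0), coords(i, 1), coords(i, 2)));
  std::vector<std::array<int, 3>> seg;
  seg.reserve(n);
  int accepted = 0;

  for (int a = 0; a < attempts; ++a) {
    int j = 1 + (int)(unif_rand() * (n - 2));
    if (j > n - 2) j = n - 2;
    int s = 1 + (int)(unif_rand() * 47.0);  // 1..47: never the identity
    if (s > 47) s = 47;
    const int *pm = perms[s / 8];
    int sg = s % 8;
    int sgn[3] = {(sg & 1) ? -1 : 1, (sg & 2) ? -1 : 1, (sg & 4) ? -1 : 1};

    bool move_tail = (n - 1 - j) <= j;
    int lo_mv = move_tail ? j + 1 : 0;
    int hi_mv = move_tail ? n - 1 : j - 1;

    for (int i = lo_mv; i <= hi_mv; ++i)
      occ.erase(site_key(coords(i, 0), coords(i, 1), coords(i, 2)));

    int px = coords(j, 0), py = coords(j, 1), pz = coords(j, 2);
    bool ok = true;
    seg.clear();
    for (int i = lo_mv; i <= hi_mv; ++i) {
      int d[3] = {coords(i, 0) - px, coords(i, 1) - py, coords(i, 2) - pz};
      int nx = px + sgn[0] * d[pm[0]];
      int ny = py + sgn[1] * d[pm[1]];
      int nz = pz + sgn[2] * d[pm[2]];
      if (occ.count(site_key(nx, ny, nz))) { ok = false; break; }
      seg.push_back({nx, ny, nz});
    }
    if (ok) {
      int idx = 0;
      for (int i = lo_mv; i <= hi_mv; ++i, ++idx) {
        coords(i, 0) = seg[idx][0];
        coords(i, 1) = seg[idx][1];
        coords(i, 2) = seg[idx][2];
      }
      ++accepted;
    }
    // re-insert the (possibly updated) arm; rigid motion keeps it
    // internally self-avoiding, so insertion cannot collide
    for (int i = lo_mv; i <= hi_mv; ++i)
      occ.insert(site_key(coords(i, 0), coords(i, 1), coords(i, 2)));
  }
  return List::create(_["coords"] = coords, _["accepted"] = accepted);
}
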