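#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-list neighbour search: all atom pairs (i < j) from distinct residues
// with Euclidean distance <= cutoff (closed bound, exact double comparison),
// identical by construction to the all-pairs scan. `res` gives a residue
// index per atom; pairs within one residue are self-contacts and excluded.
// [[Rcpp::export]]
DataFrame contact_pairs_cpp(NumericMatrix coords, IntegerVector res,
                            double cutoff) {
  const int n = coords.nrow();
  const double c2 = cutoff * cutoff;
  std::unordered_map<long long, std::vector<int>> cells;
  std::vector<long long> key(n);
  auto cell_key = [](long long cx, long long cy, long long cz) {
    return ((cx + 1048576) << 42) | ((cy + 1048576) << 21) | (cz + 1048576);
  };
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor(coords(i, 0) / cutoff);
    long long cy = (long long)std::floor(coords(i, 1) / cutoff);
    long long cz = (long long)std::floor(coords(i, 2) / cutoff);
    key[i] = cell_key(cx, cy, cz);
    cells[key[i]].push_back(i);
  }
  std::vector<int> ia, ja;
  std::vector<double> dist;
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor(coords(i, 0) / cutoff);
    long long cy = (long long)std::floor(coords(i, 1) / cutoff);
    long long cz = (long long)std::floor(coords(i, 2) / cutoff);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= i || res[j] == res[i]) continue;
            double ddx = coords(i, 0) - coords(j, 0);
            double ddy = coords(i, 1) - coords(j, 1);
            double ddz = coords(i, 2) - coords(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= c2) {
              ia.push_back(i + 1);
              ja.push_back(j + 1);
              dist.push_back(std::sqrt(d2));
            }
          }
        }
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ja, _["distance"] = dist);
}
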