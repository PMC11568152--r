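#include <Rcpp.h>
using namespace Rcpp;

// Fixed-margin randomization of a binary matrix (rows = species,
// columns = plots). Both algorithms preserve row sums, column sums and
// total fill exactly; each call starts from the supplied matrix and
// performs n_steps trades, so independent restarts give non-sequential
// null draws.

// Curveball: pick two rows, pool the columns where exactly one of them
// has a presence, and redistribute that pool at random between the rows.
// [[Rcpp::export(name = ".curveball_cpp")]]
IntegerMatrix curveball_cpp(IntegerMatrix m, int n_steps) {
  IntegerMatrix x = clone(m);
  int nr = x.nrow(), nc = x.ncol();
  if (nr < 2 || nc < 2) return x;
  std::vector<int> diff_ab, diff_ba;
  diff_ab.reserve(nc);
  diff_ba.reserve(nc);
  for (int step = 0; step < n_steps; ++step) {
    int a = (int)(unif_rand() * nr);
    int b = (int)(unif_rand() * nr);
    while (b == a) b = (int)(unif_rand() * nr);
    diff_ab.clear();
    diff_ba.clear();
    for (int j = 0; j < nc; ++j) {
      int xa = x(a, j), xb = x(b, j);
      if (xa == 1 && xb == 0) diff_ab.push_back(j);
      else if (xa == 0 && xb == 1) diff_ba.push_back(j);
    }
    int na = diff_ab.size(), nb = diff_ba.size(), tot = na + nb;
    if (na == 0 || nb == 0) continue;
    // merge the symmetric difference and shuffle; first na columns go to a
    diff_ab.insert(diff_ab.end(), diff_ba.begin(), diff_ba.end());
    for (int j = tot - 1; j > 0; --j) {
      int k = (int)(unif_rand() * (j + 1));
      std::swap(diff_ab[j], diff_ab[k]);
    }
    for (int j = 0; j < tot; ++j) {
      int col = diff_ab[j];
      int give_a = (j < na) ? 1 : 0;
      x(a, col) = give_a;
      x(b, col) = 1 - give_a;
    }
  }
  return x;
}

// Trial swap: pick a random 2x2 submatrix; if it is a checkerboard,
// swap its diagonal; every pick counts as one trial.
// [[Rcpp::export(name = ".trialswap_cpp")]]
IntegerMatrix trialswap_cpp(IntegerMatrix m, int n_steps) {
  IntegerMatrix x = clone(m);
  int nr = x.nrow(), nc = x.ncol();
  if (nr < 2 || nc < 2) return x;
  for (int step = 0; step < n_steps; ++step) {
    int a = (int)(unif_rand() * nr);
    int b = (int)(unif_rand() * nr);
    while (b == a) b = (int)(unif_rand() * nr);
    int i = (int)(unif_rand() * nc);
    int j = (int)(unif_rand() * nc);
    while (j == i) j = (int)(unif_rand() * nc);
    int s = x(a, i) + x(b, j);
    int t = x(a, j) + x(b, i);
    if (s == 2 && t == 0) {
      x(a, i) = 0; x(b, j) = 0; x(a, j) = 1; x(b, i) = 1;
    } else if (s == 0 && t == 2) {
      x(a, i) = 1; x(b, j) = 1; x(a, j) = 0; x(b, i) = 0;
    }
  }
  return x;
}
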