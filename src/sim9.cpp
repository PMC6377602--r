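#include <Rcpp.h>
using namespace Rcpp;

// Elementary SIM9 step: draw a random 2x2 submatrix; if it is one of the two
// checkerboard configurations, flip it to the other. Non-checkerboard draws
// are no-ops that still count toward the attempt total, so the chain is a
// correct Metropolis sampler on the fixed-fixed matrix set (uniform target:
// every matrix has the same number of checkerboard neighbours counted with
// proposal multiplicity, and the proposal is symmetric).
static inline void sim9_attempt(IntegerMatrix &m, int nr, int nc) {
  int i1 = (int)(unif_rand() * nr);
  int i2 = (int)(unif_rand() * nr);
  if (i1 == i2 || i1 >= nr || i2 >= nr) return;
  int j1 = (int)(unif_rand() * nc);
  int j2 = (int)(unif_rand() * nc);
  if (j1 == j2 || j1 >= nc || j2 >= nc) return;
  int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
  if (a == d && b == c && a != b) {
    m(i1, j1) = b; m(i1, j2) = a;
    m(i2, j1) = d; m(i2, j2) = c;
  }
}

// [[Rcpp::export(name = ".sim9_swap_cpp")]]
IntegerMatrix sim9_swap_cpp(IntegerMatrix m, double n_swaps) {
  IntegerMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  if (nr < 2 || nc < 2) return out;
  GetRNGstate();
  for (double s = 0; s < n_swaps; s += 1.0) sim9_attempt(out, nr, nc);
  PutRNGstate();
  return out;
}

// Run one chain: burn_in attempts, then n_iter samples taken every `thin`
// attempts. Samples are returned flattened, one matrix per row (column-major
// cell order), so any R-level statistic can be applied afterwards.
// [[Rcpp::export(name = ".sim9_chain_cpp")]]
List sim9_chain_cpp(IntegerMatrix m, int n_iter, double burn_in, double thin) {
  IntegerMatrix cur = clone(m);
  int nr = cur.nrow(), nc = cur.ncol();
  IntegerMatrix samples(n_iter, nr * nc);
  GetRNGstate();
  for (double s = 0; s < burn_in; s += 1.0) sim9_attempt(cur, nr, nc);
  for (int k = 0; k < n_iter; ++k) {
    for (double s = 0; s < thin; s += 1.0) sim9_attempt(cur, nr, nc);
    int idx = 0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        samples(k, idx++) = cur(i, j);
  }
  PutRNGstate();
  return List::create(_["samples"] = samples, _["final"] = cur);
}

// True if the matrix contains at least one swappable 2x2 checkerboard.
// [[Rcpp::export(name = ".has_checkerboard_cpp")]]
bool has_checkerboard_cpp(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  for (int i1 = 0; i1 < nr; ++i1)
    for (int i2 = i1 + 1; i2 < nr; ++i2)
      for (int j1 = 0; j1 < nc; ++j1)
        for (int j2 = j1 + 1; j2 < nc; ++j2) {
          int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
          if (a == d && b == c && a != b) return true;
        }
  return false;
}
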