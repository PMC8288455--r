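#include <Rcpp.h>
using namespace Rcpp;

// Occupancy codes: 0 empty, 1 r cell, 2 K cell.
// Moore neighborhood, reflecting boundary: out-of-bounds sites are wall,
// never candidates for placement; in the crowding score they contribute
// nothing to the numerator while the denominator stays 8.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// crowding felt by the cell at (i, j): (own-type neighbors +
// gamma * other-type neighbors) / 8, gamma = alpha for r, beta for K.
static double crowding_at(const IntegerMatrix &occ, int i, int j,
                          int type, double gamma) {
  int nr = occ.nrow(), nc = occ.ncol();
  double num = 0.0;
  for (int k = 0; k < 8; ++k) {
    int ii = i + DR[k], jj = j + DC[k];
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    int v = occ(ii, jj);
    if (v == 0) continue;
    num += (v == type) ? 1.0 : gamma;
  }
  return num / 8.0;
}

// uniform integer in [0, n)
static int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// [[Rcpp::export]]
double local_crowding_cpp(IntegerMatrix occ, int i, int j,
                          double alpha, double beta) {
  int type = occ(i, j);
  if (type == 0) stop("site is empty");
  return crowding_at(occ, i, j, type, type == 1 ? alpha : beta);
}

// One asynchronous update sweep. Cells present at sweep start are visited
// in a fresh uniform random order; per cell the mutually exclusive events
// death -> division -> migration are attempted. Daughters and migrants
// placed this sweep are not revisited (tracked via the `placed` flags).
// Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix step_lattice_cpp(IntegerMatrix occ,
                               double alpha, double beta,
                               double birth_r, double death0_r,
                               double ddc_r, double mot_r,
                               double birth_k, double death0_k,
                               double ddc_k, double mot_k,
                               double dt) {
  RNGScope scope;
  IntegerMatrix grid = clone(occ);
  int nr = grid.nrow(), nc = grid.ncol();

  std::vector<int> cells;
  cells.reserve(1024);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (grid(i, j) != 0) cells.push_back(j * nr + i);
  int n = (int)cells.size();
  if (n == 0) return grid;

  // Fisher-Yates shuffle
  for (int k = n - 1; k > 0; --k) {
    int m = runif_int(k + 1);
    std::swap(cells[k], cells[m]);
  }

  // sites that received a new occupant during this sweep
  std::vector<char> placed((size_t)nr * nc, 0);

  int empties[8];
  for (int c = 0; c < n; ++c) {
    int idx = cells[c];
    int i = idx % nr, j = idx / nr;
    int type = grid(i, j);
    if (type == 0) continue;              // original occupant already gone
    if (placed[(size_t)idx]) continue;    // newcomer moved in; not this cell

    double gamma = (type == 1) ? alpha : beta;
    double death0 = (type == 1) ? death0_r : death0_k;
    double ddc = (type == 1) ? ddc_r : ddc_k;
    double birth = (type == 1) ? birth_r : birth_k;
    double mot = (type == 1) ? mot_r : mot_k;

    double crowd = crowding_at(grid, i, j, type, gamma);
    double p_death = (death0 + ddc * crowd) * dt;
    if (p_death > 1.0) p_death = 1.0;
    if (unif_rand() < p_death) {
      grid(i, j) = 0;
      continue;
    }

    int n_empty = 0;
    for (int k = 0; k < 8; ++k) {
      int ii = i + DR[k], jj = j + DC[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (grid(ii, jj) == 0) empties[n_empty++] = jj * nr + ii;
    }
    if (n_empty == 0) continue;  // fully enclosed: no division, no migration

    double p_div = birth * dt;
    if (p_div > 1.0) p_div = 1.0;
    if (unif_rand() < p_div) {
      int dest = empties[runif_int(n_empty)];
      grid(dest % nr, dest / nr) = type;
      placed[(size_t)dest] = 1;
      continue;
    }

    double p_mig = mot * dt;
    if (p_mig > 1.0) p_mig = 1.0;
    if (unif_rand() < p_mig) {
      int dest = empties[runif_int(n_empty)];
      grid(dest % nr, dest / nr) = type;
      placed[(size_t)dest] = 1;
      grid(i, j) = 0;
    }
  }
  return grid;
}

// [[Rcpp::export]]
IntegerVector count_types_cpp(IntegerMatrix occ) {
  int n1 = 0, n2 = 0;
  for (int k = 0; k < occ.length(); ++k) {
    if (occ[k] == 1) ++n1;
    else if (occ[k] == 2) ++n2;
  }
  return IntegerVector::create(_["n_r"] = n1, _["n_K"] = n2);
}
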