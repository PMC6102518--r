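#include <Rcpp.h>
using namespace Rcpp;

// Beta phylogenetic metrics over a cophenetic matrix D (1-based index
// vectors). betaMPD averages all ordered cross pairs, so taxa shared by
// both communities contribute zero distances (comdist convention).

// [[Rcpp::export]]
double cpp_beta_mpd(const NumericMatrix& D, const IntegerVector& ia,
                    const IntegerVector& ib) {
  const int na = ia.size(), nb = ib.size();
  double s = 0.0;
  for (int i = 0; i < na; ++i) {
    const int ri = ia[i] - 1;
    for (int j = 0; j < nb; ++j) s += D(ri, ib[j] - 1);
  }
  return s / (double(na) * double(nb));
}

// betaMNTD: mean over taxa of both communities of the distance to the
// nearest taxon in the opposite community (zero for shared taxa).

// [[Rcpp::export]]
double cpp_beta_mntd(const NumericMatrix& D, const IntegerVector& ia,
                     const IntegerVector& ib) {
  const int na = ia.size(), nb = ib.size();
  double s = 0.0;
  for (int i = 0; i < na; ++i) {
    const int ri = ia[i] - 1;
    double m = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double d = D(ri, ib[j] - 1);
      if (d < m) m = d;
    }
    s += m;
  }
  for (int j = 0; j < nb; ++j) {
    const int rj = ib[j] - 1;
    double m = R_PosInf;
    for (int i = 0; i < na; ++i) {
      const double d = D(rj, ia[i] - 1);
      if (d < m) m = d;
    }
    s += m;
  }
  return s / double(na + nb);
}

// Null distribution for a community pair under the unconstrained
// (pool-wide) label shuffle. Each randomization draws na + nb - s
// distinct labels from `pool` (a vector of 1-based indices into D) by
// partial Fisher-Yates using R's RNG: the first `s` are shared by both
// communities, the next na - s complete community a, the rest complete
// community b. Community sizes and shared-taxon structure are thereby
// preserved. Returns an nrand x 2 matrix (betaMPD, betaMNTD).

// [[Rcpp::export]]
NumericMatrix cpp_null_beta(const NumericMatrix& D,
                            const IntegerVector& pool,
                            const int na, const int nb, const int s,
                            const int nrand) {
  const int np = pool.size();
  const int need = na + nb - s;
  if (need > np) stop("pool smaller than the union of the two communities");
  std::vector<int> bag(pool.begin(), pool.end());
  NumericMatrix out(nrand, 2);
  IntegerVector ia(na), ib(nb);
  RNGScope rng;
  for (int r = 0; r < nrand; ++r) {
    for (int k = 0; k < need; ++k) {
      int j = k + (int)(unif_rand() * (np - k));
      if (j >= np) j = np - 1;
      std::swap(bag[k], bag[j]);
    }
    for (int k = 0; k < na; ++k) ia[k] = bag[k];
    for (int k = 0; k < s; ++k) ib[k] = bag[k];
    for (int k = s; k < nb; ++k) ib[k] = bag[na + (k - s)];
    out(r, 0) = cpp_beta_mpd(D, ia, ib);
    out(r, 1) = cpp_beta_mntd(D, ia, ib);
  }
  return out;
}
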