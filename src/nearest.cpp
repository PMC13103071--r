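#include <Rcpp.h>

// Directed nearest-neighbour distances between two 3D point sets (mm).
// Brute force O(n*m); the point sets are mask surfaces (thousands of
// points), for which this is faster and simpler than tree structures.
// [[Rcpp::export]]
Rcpp::NumericVector nearest_distances_cpp(Rcpp::NumericMatrix a,
                                          Rcpp::NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  Rcpp::NumericVector out(na);
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int j = 0; j < nb; ++j) {
    bx[j] = b(j, 0);
    by[j] = b(j, 1);
    bz[j] = b(j, 2);
  }
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - bx[j], dy = ay - by[j], dz = az - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
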