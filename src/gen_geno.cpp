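#include <Rcpp.h>
using namespace Rcpp;

// Biallelic genotype dosages G_ij ~ Binomial(2, maf_j), sampled from a single
// uniform per cell via the cumulative genotype probabilities. Uses R's RNG so
// set.seed() gives bit-identical matrices. Returns doubles: every downstream
// consumer (crossprod, %*%) needs the numeric coercion anyway.
// [[Rcpp::export]]
NumericMatrix gen_geno(int n_individuals, NumericVector maf) {
  int n_snps = maf.size();
  NumericMatrix G(n_individuals, n_snps);
  for (int j = 0; j < n_snps; ++j) {
    double p = maf[j];
    double q1 = (1.0 - p) * (1.0 - p); // P(G = 0)
    double q2 = 1.0 - p * p;           // P(G <= 1)
    double *col = &G(0, j);
    for (int i = 0; i < n_individuals; ++i) {
      double u = unif_rand();
      col[i] = (u > q1) + (u > q2);
    }
  }
  return G;
}
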