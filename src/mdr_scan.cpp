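#include <Rcpp.h>
using namespace Rcpp;

// Tabulate case/control counts per multi-locus genotype cell for every
// candidate locus combination in one pass over the data.
//
// geno:   n x K integer matrix, codes in {0,1,2} (validated on the R side)
// pheno:  length-n integer vector, 1 = case, 0 = control
// combos: C x k matrix of 1-based column indices, each row one combination
//
// Returns a C x (2 * 3^k) integer matrix: columns [0, 3^k) hold case counts
// per cell (base-3 cell index, first locus most significant), columns
// [3^k, 2*3^k) hold control counts.
// [[Rcpp::export]]
IntegerMatrix cell_counts_scan(const IntegerMatrix& geno,
                               const IntegerVector& pheno,
                               const IntegerMatrix& combos) {
  const int n = geno.nrow();
  const int C = combos.nrow();
  const int k = combos.ncol();
  if (pheno.size() != n)
    stop("phenotype length does not match genotype rows");
  int M = 1;
  for (int j = 0; j < k; ++j) M *= 3;

  // base-3 place values, first locus most significant
  std::vector<int> pw(k);
  pw[k - 1] = 1;
  for (int j = k - 2; j >= 0; --j) pw[j] = pw[j + 1] * 3;

  IntegerMatrix out(C, 2 * M);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < n; ++i) {
      int idx = 0;
      for (int j = 0; j < k; ++j) idx += geno(i, combos(c, j) - 1) * pw[j];
      out(c, pheno[i] == 1 ? idx : M + idx)++;
    }
  }
  return out;
}
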