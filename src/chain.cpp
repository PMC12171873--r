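#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete-time Markov chain of length n_frames from cumulative
// row probabilities.  Uses R's RNG so results are governed by set.seed().
// States are 1-based.
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix cum_tpm, int n_frames, int start) {
  int n = cum_tpm.nrow();
  if (start < 1 || start > n) stop("start state out of range");
  IntegerVector out(n_frames);
  int s = start - 1;
  out[0] = s + 1;
  for (int t = 1; t < n_frames; ++t) {
    double u = unif_rand();
    int j = 0;
    while (j < n - 1 && u > cum_tpm(s, j)) ++j;
    s = j;
    out[t] = s + 1;
  }
  return out;
}
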