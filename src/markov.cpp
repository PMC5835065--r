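#include <Rcpp.h>
using namespace Rcpp;

// Sample a base sequence from an order-k Markov chain over {A,C,G,T}.
//
// cumprob: (4^order) x 4 matrix of cumulative next-base probabilities per
//          context (each row non-decreasing, last entry 1).
// init:    0-based integer codes of the first `order` bases (the seed
//          context, not returned).
// u:       pre-drawn uniforms, one per emitted base; drawing them in R keeps
//          the generator tied to R's RNG stream and seed.
//
// [[Rcpp::export]]
IntegerVector markov_sample_bases(NumericMatrix cumprob, IntegerVector init,
                                  NumericVector u) {
  const int order = init.size();
  const int n = u.size();
  int ncontext = cumprob.nrow();
  int submod = ncontext / 4;  // 4^(order-1)
  IntegerVector out(n);

  int ctx = 0;
  for (int i = 0; i < order; ++i) ctx = ctx * 4 + init[i];
  if (ctx >= ncontext) stop("initial context out of range");

  for (int i = 0; i < n; ++i) {
    const double uu = u[i];
    int b = 0;
    while (b < 3 && uu > cumprob(ctx, b)) ++b;
    out[i] = b;
    ctx = (ctx % submod) * 4 + b;
  }
  return out;
}
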