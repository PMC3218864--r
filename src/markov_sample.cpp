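#include <Rcpp.h>
using namespace Rcpp;

// Sequential sampler for a k-th order Markov chain over {A,C,G,T}.
//
// cum:  (4^k) x 4 matrix of cumulative conditional probabilities, row i
//       corresponding to context code i (0-based, base-4 big-endian of the
//       preceding k bases), columns cumulative over A,C,G,T (last col == 1).
// init: integer vector of k initial base codes (1..4); may be empty if k==0.
// n:    total length of the output (including the initial context).
//
// Uses R's RNG (unif_rand), so results are reproducible under set.seed().
// [[Rcpp::export(name = ".sampleMarkovCpp")]]
IntegerVector sampleMarkovCpp(NumericMatrix cum, IntegerVector init, int n) {
    int k = init.size();
    IntegerVector out(n);
    int nctx = cum.nrow();
    int ctx = 0;
    for (int i = 0; i < k; ++i) {
        out[i] = init[i];
        ctx = (ctx * 4 + (init[i] - 1)) % nctx;
    }
    RNGScope scope;
    for (int i = k; i < n; ++i) {
        double u = unif_rand();
        int b = 0;
        while (b < 3 && u > cum(ctx, b)) ++b;
        out[i] = b + 1;
        if (nctx > 1) {
            ctx = (ctx * 4 + b) % nctx;
        }
    }
    return out;
}
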