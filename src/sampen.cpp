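#include <Rcpp.h>
#include <cmath>

// Template match counting for sample entropy.
//
// Counts pairs (i, j), i < j, over the N - m templates of length m whose
// Chebyshev distance is within the tolerance (B), and among those the pairs
// that still match when extended by one point (A). Only the first N - m
// templates are used so every length-m template has an (m+1)-th point,
// which keeps the ratio A/B a conditional probability. Self-matches are
// excluded by construction (i < j).
//
// The scan runs over pair lags d = j - i, tracking the run length of
// consecutive point matches at that lag: a template pair of length m ends
// wherever the run reaches m. This keeps memory access sequential and the
// cost a flat O(N^2) regardless of how often early points match.
//
// `strict` selects "< r" instead of the default "<= r" comparison.
//
// [[Rcpp::export]]
Rcpp::NumericVector sampen_counts(Rcpp::NumericVector x, int m, double r_abs,
                                  bool strict = false) {
    const int N = x.size();
    if (m < 1) Rcpp::stop("m must be >= 1");
    if (r_abs < 0) Rcpp::stop("tolerance must be non-negative");
    const int nt = N - m;  // number of usable templates
    if (nt < 2) Rcpp::stop("series too short for template length m");

    double B = 0.0, A = 0.0;
    const double* v = REAL(x);

    // For a lag d, length-m templates ending at pos start at pos - m + 1 and
    // are admissible while pos <= N - 2 - d; the (m+1)-extension check is
    // admissible through pos = N - 1 - d. Only the final position differs,
    // so it is peeled out of the loop.
    for (int d = 1; d <= nt - 1; ++d) {
        const int pos_end = N - 1 - d;
        const double* lo = v;
        const double* hi = v + d;
        int run = 0;
        long bB = 0, aA = 0;  // branchless per-lag accumulators
        if (strict) {
            for (int pos = 0; pos < pos_end; ++pos) {
                const int ok = std::fabs(lo[pos] - hi[pos]) < r_abs;
                run = ok * (run + 1);
                bB += run >= m;
                aA += run > m;
            }
            run = (std::fabs(lo[pos_end] - hi[pos_end]) < r_abs) * (run + 1);
        } else {
            for (int pos = 0; pos < pos_end; ++pos) {
                const int ok = std::fabs(lo[pos] - hi[pos]) <= r_abs;
                run = ok * (run + 1);
                bB += run >= m;
                aA += run > m;
            }
            run = (std::fabs(lo[pos_end] - hi[pos_end]) <= r_abs) * (run + 1);
        }
        aA += run > m;
        B += static_cast<double>(bB);
        A += static_cast<double>(aA);
    }

    return Rcpp::NumericVector::create(B, A);
}
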