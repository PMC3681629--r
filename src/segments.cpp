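#include <Rcpp.h>
using namespace Rcpp;

// Maximal high-scoring segments of a real-valued score vector.
//
// A segment [m, n) (0-based half-open) qualifies when
//   (1) its score sum S is strictly positive,
//   (2) no strictly containing interval has a larger sum, and
//   (3) no strictly contained interval attains a sum >= S
// (condition 3 breaks zero-sum-extension ties toward the shortest
// interval).  In terms of the prefix-sum walk P this is equivalent to:
// P[m] is a running minimum of P[0..m], P[n] is a running maximum of
// P[n..len], and every interior prefix value lies strictly between
// P[m] and P[n].  Qualifying segments are pairwise disjoint, so one
// left-to-right sweep pairing eligible starts with eligible ends
// recovers all of them in linear time.
// [[Rcpp::export(name = ".hss_cpp")]]
DataFrame hss_cpp(NumericVector y) {
    R_xlen_t n = y.size();
    std::vector<double> P(n + 1);
    P[0] = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) P[i + 1] = P[i] + y[i];

    // start eligibility: P[m] equals the minimum of P[0..m]
    std::vector<bool> isStart(n + 1, false);
    double mn = R_PosInf;
    for (R_xlen_t i = 0; i <= n; ++i) {
        if (P[i] <= mn) { isStart[i] = true; mn = P[i]; }
    }
    // end eligibility: P[e] equals the maximum of P[e..n]
    std::vector<bool> isEnd(n + 1, false);
    double mx = R_NegInf;
    for (R_xlen_t i = n; i >= 0; --i) {
        if (P[i] >= mx) { isEnd[i] = true; mx = P[i]; }
    }

    std::vector<int> starts, ends;
    std::vector<double> scores;
    R_xlen_t cur = -1;          // latest live eligible start
    R_xlen_t prev_end = 0;
    for (R_xlen_t pos = 0; pos <= n; ++pos) {
        if (pos > 0 && isEnd[pos] && cur >= 0 && P[cur] < P[pos]) {
            starts.push_back((int)cur);
            ends.push_back((int)pos);
            scores.push_back(P[pos] - P[cur]);
            prev_end = pos;
            cur = -1;
        }
        if (isStart[pos] && pos >= prev_end) cur = pos;
    }
    return DataFrame::create(_["start"] = starts, _["end"] = ends,
                             _["score"] = scores);
}
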