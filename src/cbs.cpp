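#include <Rcpp.h>
using namespace Rcpp;

// Maximal two-sample arc statistic for circular binary segmentation.
//
// Arcs are enumerated in linear index space: arc (i, j] covers positions
// i+1..j (0-based i, 1 <= j - i <= n-1).  Wraparound arcs are covered by
// their complementary linear splits because the statistic is symmetric in
// group exchange.  min_width constrains both group sizes so the pooled
// t-statistic is defined on at least min_width observations per side.
static double arc_t_stat(double arc_sum, int k, double total_sum,
                         double total_ss, int n, double tol) {
    double m1 = arc_sum / k;
    double m2 = (total_sum - arc_sum) / (n - k);
    double ss_within = total_ss - k * m1 * m1 - (n - k) * m2 * m2;
    if (ss_within < 0.0) ss_within = 0.0;
    double diff = m1 - m2;
    if (ss_within <= tol) {
        return (std::fabs(diff) <= std::sqrt(tol)) ? 0.0 : R_PosInf;
    }
    double sp2 = ss_within / (n - 2);
    return std::fabs(diff) / std::sqrt(sp2 * (1.0 / k + 1.0 / (n - k)));
}

static double max_arc_stat(const double *x, int n, int min_width,
                           int *best_i, int *best_j) {
    if (best_i) *best_i = -1;
    if (best_j) *best_j = -1;
    if (n < 2 || n < 2 * min_width) return -1.0;
    std::vector<double> cs(n + 1, 0.0);
    double total_ss = 0.0;
    for (int t = 0; t < n; ++t) {
        cs[t + 1] = cs[t] + x[t];
        total_ss += x[t] * x[t];
    }
    double total_sum = cs[n];
    double tol = 1e-12 * (1.0 + std::fabs(total_ss));
    double best = -1.0;
    for (int i = 0; i <= n - min_width; ++i) {
        // group sizes k = j - i and n - k must both be >= min_width
        int j_lo = i + min_width;
        int j_hi = std::min(n, i + n - min_width);
        for (int j = j_lo; j <= j_hi; ++j) {
            int k = j - i;
            double s = arc_t_stat(cs[j] - cs[i], k, total_sum, total_ss, n, tol);
            if (s > best) {
                best = s;
                if (best_i) *best_i = i;
                if (best_j) *best_j = j;
            }
        }
    }
    return best;
}

// [[Rcpp::export]]
List cbs_max_arc_cpp(NumericVector x, int min_width = 2) {
    int n = x.size(), bi = -1, bj = -1;
    double best = max_arc_stat(REAL(x), n, min_width, &bi, &bj);
    return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = best);
}

// Permutation reference for the observed max arc statistic.  Uses R's RNG
// (so set.seed() in R controls the stream).  Stops early once `stop_count`
// exceedances are seen: at that point the add-one p-value can no longer
// drop below the significance level the caller derived stop_count from.
// [[Rcpp::export]]
List cbs_perm_count_cpp(NumericVector x, double stat_obs, int n_perm,
                        int min_width, int stop_count) {
    RNGScope scope;
    int n = x.size();
    std::vector<double> y(REAL(x), REAL(x) + n);
    int count = 0, done = 0;
    for (int b = 0; b < n_perm; ++b) {
        if (stop_count >= 0 && count >= stop_count) break;
        for (int k = n - 1; k > 0; --k) {
            int idx = (int)(unif_rand() * (k + 1));
            if (idx > k) idx = k;
            std::swap(y[k], y[idx]);
        }
        double s = max_arc_stat(y.data(), n, min_width, NULL, NULL);
        ++done;
        if (s >= stat_obs) ++count;
    }
    return List::create(_["count"] = count, _["n_done"] = done);
}
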