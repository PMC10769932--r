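#include <Rcpp.h>
using namespace Rcpp;

// Jaro match/transposition count on integer-coded sequences.
// w = floor(max(|a|,|b|)/2) - 1 (floored at 0); matches assigned greedily
// left-to-right within the window; t = half the number of matched symbols
// that appear out of order.
static void jaro_core(const int* a, int la, const int* b, int lb,
                      int& m, double& t, double& sim, double winkler_p) {
    int w = std::max(la, lb) / 2 - 1;
    if (w < 0) w = 0;
    std::vector<char> am(la, 0), bm(lb, 0);
    m = 0;
    for (int i = 0; i < la; ++i) {
        int lo = std::max(0, i - w), hi = std::min(lb - 1, i + w);
        for (int j = lo; j <= hi; ++j) {
            if (!bm[j] && a[i] == b[j]) {
                am[i] = bm[j] = 1;
                ++m;
                break;
            }
        }
    }
    if (m == 0) { t = 0.0; sim = 0.0; return; }
    int k = 0, half = 0;
    for (int i = 0; i < la; ++i) {
        if (!am[i]) continue;
        while (!bm[k]) ++k;
        if (a[i] != b[k]) ++half;
        ++k;
    }
    t = half / 2.0;
    sim = ((double)m / la + (double)m / lb + (m - t) / m) / 3.0;
    if (winkler_p > 0.0) {
        int l = 0, lim = std::min(4, std::min(la, lb));
        while (l < lim && a[l] == b[l]) ++l;
        sim += l * winkler_p * (1.0 - sim);
    }
}

// [[Rcpp::export]]
List jaro_int_cpp(IntegerVector a, IntegerVector b, double winkler_p) {
    int m; double t, sim;
    jaro_core(a.begin(), a.size(), b.begin(), b.size(), m, t, sim, winkler_p);
    return List::create(_["similarity"] = sim, _["matches"] = m,
                        _["transpositions"] = t);
}

// [[Rcpp::export]]
NumericMatrix jaro_matrix_cpp(List seqs, double winkler_p) {
    int n = seqs.size();
    std::vector<IntegerVector> v(n);
    for (int i = 0; i < n; ++i) v[i] = as<IntegerVector>(seqs[i]);
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        out(i, i) = 1.0;
        for (int j = i + 1; j < n; ++j) {
            int m; double t, sim;
            jaro_core(v[i].begin(), v[i].size(), v[j].begin(), v[j].size(),
                      m, t, sim, winkler_p);
            out(i, j) = sim;
            out(j, i) = sim;
        }
    }
    return out;
}
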