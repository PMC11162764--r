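#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Unit-cost Levenshtein distance, optionally capped at `k` (Ukkonen band).
// With k >= 0 the return value is exact when <= k and k + 1 otherwise.
static int lev_core(const std::string &a, const std::string &b, int k) {
    const int n = (int) a.size(), m = (int) b.size();
    if (k >= 0 && std::abs(n - m) > k) return k + 1;
    if (n == 0) return m;
    if (m == 0) return n;
    const int INF = n + m + 1;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j)
        prev[j] = (k >= 0 && j > k) ? INF : j;
    for (int i = 1; i <= n; ++i) {
        int lo = 1, hi = m;
        if (k >= 0) {
            lo = std::max(1, i - k);
            hi = std::min(m, i + k);
        }
        cur[0] = i;
        if (lo > 1) cur[lo - 1] = INF;
        int rowmin = INF;
        for (int j = lo; j <= hi; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            int v = sub < del ? sub : del;
            if (ins < v) v = ins;
            cur[j] = v;
            if (v < rowmin) rowmin = v;
        }
        if (hi < m) cur[hi + 1] = INF;
        if (k >= 0 && rowmin > k) return k + 1;  // early abandon
        std::swap(prev, cur);
    }
    int d = prev[m];
    if (k >= 0 && d > k) return k + 1;
    return d;
}

//' @noRd
// [[Rcpp::export(name = ".levDistance")]]
IntegerVector lev_distance(CharacterVector x, std::string y, int cap = -1) {
    const int n = x.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        if (CharacterVector::is_na(x[i])) { out[i] = NA_INTEGER; continue; }
        out[i] = lev_core(as<std::string>(x[i]), y, cap);
    }
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".levDistMatrix")]]
IntegerMatrix lev_dist_matrix(CharacterVector x) {
    const int n = x.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            int d = lev_core(s[i], s[j], -1);
            out(i, j) = d;
            out(j, i) = d;
        }
    return out;
}

// Greedy count-ordered clustering: sequences arrive sorted by descending count
// (ties already broken lexicographically upstream); each joins the first
// existing cluster whose centroid is within `maxDist`, else founds one.
// Returns the 1-based founding index of each sequence's cluster.
//' @noRd
// [[Rcpp::export(name = ".greedyCluster")]]
IntegerVector greedy_cluster(CharacterVector seqs, int maxDist) {
    const int n = seqs.size();
    IntegerVector out(n);
    std::vector<std::string> centroids;
    std::vector<int> founder;
    centroids.reserve(256);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        int hit = -1;
        for (size_t c = 0; c < centroids.size(); ++c) {
            if (lev_core(s, centroids[c], maxDist) <= maxDist) { hit = (int) c; break; }
        }
        if (hit < 0) {
            centroids.push_back(s);
            founder.push_back(i + 1);
            out[i] = i + 1;
        } else {
            out[i] = founder[hit];
        }
    }
    return out;
}
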