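// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Brute-force k-nearest-neighbour search by Euclidean distance, computed in
// row blocks so the full n x n distance matrix is never materialized.
// Ties are broken by cell index (smaller index first); the query point itself
// is excluded. Returns 1-based neighbour indices and distances, both n x k,
// each row ordered from nearest to farthest.
// [[Rcpp::export(name = ".knn_brute")]]
List knn_brute(const arma::mat& X, const int k, const int chunk = 1024) {
    const arma::uword n = X.n_rows;
    if (k <= 0 || (arma::uword)k >= n)
        stop("k must satisfy 0 < k < n");
    arma::vec sq = arma::sum(arma::square(X), 1);
    IntegerMatrix idx(n, k);
    NumericMatrix dst(n, k);
    std::vector<std::pair<double, arma::uword>> cand(n - 1);
    for (arma::uword start = 0; start < n; start += (arma::uword)chunk) {
        arma::uword end = std::min(n, start + (arma::uword)chunk);
        // squared distances for this block: |x|^2 + |y|^2 - 2 x.y
        arma::mat G = X.rows(start, end - 1) * X.t();
        for (arma::uword i = start; i < end; ++i) {
            arma::uword m = 0;
            for (arma::uword j = 0; j < n; ++j) {
                if (j == i) continue;
                double d2 = sq[i] + sq[j] - 2.0 * G(i - start, j);
                if (d2 < 0) d2 = 0;
                cand[m++] = std::make_pair(d2, j);
            }
            std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
            for (int l = 0; l < k; ++l) {
                idx(i, l) = (int)cand[l].second + 1;
                dst(i, l) = std::sqrt(cand[l].first);
            }
        }
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["index"] = idx, _["distance"] = dst);
}

// For each cell, count how many of its first k neighbours (k over a vector of
// scales) carry label 1. nn_index is 1-based, n x max(ks); ks must be
// increasing and <= ncol(nn_index).
// [[Rcpp::export(name = ".label_counts_at_scales")]]
IntegerMatrix label_counts_at_scales(const IntegerMatrix& nn_index,
                                     const IntegerVector& y01,
                                     const IntegerVector& ks) {
    const int n = nn_index.nrow();
    const int nk = ks.size();
    if (nk == 0) stop("ks is empty");
    if (ks[nk - 1] > nn_index.ncol())
        stop("max(ks) exceeds the number of stored neighbours");
    IntegerMatrix out(n, nk);
    for (int i = 0; i < n; ++i) {
        int acc = 0, col = 0;
        for (int j = 0; j < ks[nk - 1]; ++j) {
            acc += y01[nn_index(i, j) - 1];
            while (col < nk && j + 1 == ks[col]) {
                out(i, col) = acc;
                ++col;
            }
        }
    }
    return out;
}

// Cells within radius r of each centre row; returns a list of 1-based index
// vectors, one per centre.
// [[Rcpp::export(name = ".radius_members")]]
List radius_members(const arma::mat& centers, const arma::mat& X,
                    const double r) {
    const arma::uword nc = centers.n_rows, n = X.n_rows;
    arma::vec sqx = arma::sum(arma::square(X), 1);
    arma::vec sqc = arma::sum(arma::square(centers), 1);
    const double r2 = r * r;
    List out(nc);
    arma::mat G = centers * X.t();
    for (arma::uword c = 0; c < nc; ++c) {
        std::vector<int> mem;
        for (arma::uword j = 0; j < n; ++j) {
            double d2 = sqc[c] + sqx[j] - 2.0 * G(c, j);
            if (d2 <= r2) mem.push_back((int)j + 1);
        }
        out[c] = wrap(mem);
    }
    return out;
}
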