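#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// splitmix64 finalizer: well-mixed 64-bit hash of the packed k-mer.
static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// fixed hash seed so sketches are comparable across sessions
static const uint64_t HASH_SEED = 0x53474232303236ULL;

static inline int baseCode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Bottom-s sketch of canonical k-mers over a set of contigs.
// Hash values are reduced to 53 bits (exact in an R double).
// Non-ACGT characters break the k-mer window; k must be odd and <= 31.
// [[Rcpp::export]]
NumericVector cpp_sketch(CharacterVector contigs, int k, int s) {
    if (k < 1 || k > 31) stop("k must be in [1, 31]");
    if (k % 2 == 0) stop("k must be odd");
    if (s < 1) stop("sketch size must be positive");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    std::vector<uint64_t> hashes;
    for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
        const char* seq = CHAR(STRING_ELT(contigs, ci));
        uint64_t fwd = 0, rev = 0;
        int run = 0;
        for (const char* p = seq; *p; ++p) {
            int code = baseCode(*p);
            if (code < 0) { run = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)code) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - code) << shift);
            if (++run >= k) {
                uint64_t canon = fwd < rev ? fwd : rev;
                hashes.push_back(splitmix64(canon ^ HASH_SEED) >> 11);
            }
        }
    }
    if (hashes.empty()) stop("no k-mers: all contigs shorter than k");
    std::sort(hashes.begin(), hashes.end());
    hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
    size_t keep = std::min(hashes.size(), (size_t)s);
    NumericVector out(keep);
    for (size_t i = 0; i < keep; ++i) out[i] = (double)hashes[i];
    return out;
}

// Mash-style Jaccard estimate from two sorted bottom-s sketches:
// walk the merged union in ascending order, keep the bottom min(s, |union|)
// values, and count how many occur in both sketches.
// [[Rcpp::export]]
double cpp_bottom_jaccard(NumericVector a, NumericVector b, int s) {
    R_xlen_t i = 0, j = 0;
    int taken = 0, shared = 0;
    while ((i < a.size() || j < b.size()) && taken < s) {
        if (i < a.size() && (j >= b.size() || a[i] < b[j])) {
            ++i;
        } else if (j < b.size() && (i >= a.size() || b[j] < a[i])) {
            ++j;
        } else {
            ++shared; ++i; ++j;
        }
        ++taken;
    }
    if (taken == 0) return 0.0;
    return (double)shared / (double)taken;
}

// All-versus-all Jaccard estimates for a list of sorted sketches.
// [[Rcpp::export]]
NumericMatrix cpp_jaccard_matrix(List sketches, int s) {
    int n = sketches.size();
    NumericMatrix out(n, n);
    std::vector<NumericVector> sk(n);
    for (int i = 0; i < n; ++i) sk[i] = as<NumericVector>(sketches[i]);
    for (int i = 0; i < n; ++i) {
        out(i, i) = 1.0;
        for (int j = i + 1; j < n; ++j) {
            double v = cpp_bottom_jaccard(sk[i], sk[j], s);
            out(i, j) = v;
            out(j, i) = v;
        }
    }
    return out;
}
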