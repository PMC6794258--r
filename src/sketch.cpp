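#include <Rcpp.h>
#include <queue>
#include <unordered_set>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3 (monotone in lexicographic base order,
// so numeric comparison of encoded k-mers equals string comparison).
static inline int encode_base(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// splitmix64 finalizer: well-mixed 64-bit hash.
static inline uint64_t mix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// Hashes are truncated to 53 bits so they round-trip exactly through R
// doubles; ordering and collision behaviour are unaffected at sketch scales.
static const uint64_t HASH_MASK = (1ULL << 53) - 1;

static inline uint64_t hash_kmer(uint64_t kmer, uint64_t seed) {
    return mix64(kmer ^ mix64(seed)) & HASH_MASK;
}

// Bottom-s MinHash sketch over canonical k-mers (lexicographic minimum of a
// k-mer and its reverse complement). K-mers containing non-ACGT characters
// are skipped and counted. Returns sorted ascending hash values.
// [[Rcpp::export]]
List cpp_sketch(std::string seq, int k, int s, double seed) {
    if (k < 1 || k > 31) stop("k must be in [1, 31]");
    if (s < 1) stop("sketch size must be >= 1");
    const size_t n = seq.size();
    if (n < (size_t)k) stop("sequence shorter than k");
    const uint64_t useed = (uint64_t)seed;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);

    uint64_t fwd = 0, rev = 0;
    int valid = 0;           // length of current run of valid bases
    long long skipped = 0;   // windows lost to ambiguous bases
    std::unordered_set<uint64_t> seen;
    std::priority_queue<uint64_t> heap; // max-heap of current bottom-s

    for (size_t i = 0; i < n; ++i) {
        int b = encode_base(seq[i]);
        if (b < 0) {
            // every window covering this base is skipped
            size_t win_start_min = (i + 1 >= (size_t)k) ? i + 1 - k : 0;
            size_t win_start_max = std::min(i, n - (size_t)k);
            if (win_start_max >= win_start_min)
                skipped += (long long)(win_start_max - win_start_min + 1);
            valid = 0; fwd = 0; rev = 0;
            continue;
        }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        if (++valid < k) continue;
        uint64_t canon = std::min(fwd, rev);
        uint64_t h = hash_kmer(canon, useed);
        if (seen.count(h)) continue;
        if ((int)heap.size() < s) {
            seen.insert(h);
            heap.push(h);
        } else if (h < heap.top()) {
            seen.erase(heap.top());
            heap.pop();
            seen.insert(h);
            heap.push(h);
        }
    }

    NumericVector hashes(heap.size());
    for (int i = (int)heap.size() - 1; i >= 0; --i) {
        hashes[i] = (double)heap.top();
        heap.pop();
    }
    return List::create(_["hashes"] = hashes,
                        _["n_skipped"] = (double)skipped);
}

// Shared-hash count among the s smallest distinct values of the merged
// sketch (the Mash union-sketch Jaccard estimator). Inputs must be sorted
// ascending. Returns the shared count and the union sample size used.
// [[Rcpp::export]]
List cpp_union_jaccard(NumericVector a, NumericVector b, int s) {
    int i = 0, j = 0, taken = 0, shared = 0;
    const int na = a.size(), nb = b.size();
    while (taken < s && (i < na || j < nb)) {
        if (i < na && j < nb && a[i] == b[j]) {
            ++shared; ++i; ++j;
        } else if (j >= nb || (i < na && a[i] < b[j])) {
            ++i;
        } else {
            ++j;
        }
        ++taken;
    }
    return List::create(_["shared"] = shared, _["taken"] = taken);
}
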