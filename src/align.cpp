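#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <string>
using namespace Rcpp;

static inline int baseCode2(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline char compBase(char c) {
    switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
    }
}

// Seed index over the concatenated subject. Seeds never span contig
// boundaries (contig id is checked at lookup time).
struct SubjectIndex {
    std::string seq;                 // concatenated contigs
    std::vector<int> contigOf;       // contig id per position
    std::vector<int> contigStart, contigEnd; // [start, end) per contig
    std::unordered_map<uint64_t, std::vector<int>> seeds;
    int seedLen;
};

static void buildIndex(SubjectIndex& idx, CharacterVector contigs, int seedLen) {
    idx.seedLen = seedLen;
    for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
        const char* s = CHAR(STRING_ELT(contigs, ci));
        idx.contigStart.push_back((int)idx.seq.size());
        idx.seq.append(s);
        idx.contigEnd.push_back((int)idx.seq.size());
        idx.contigOf.resize(idx.seq.size(), (int)ci);
    }
    const uint64_t mask = (1ULL << (2 * seedLen)) - 1;
    uint64_t w = 0;
    int run = 0;
    for (size_t p = 0; p < idx.seq.size(); ++p) {
        // restart the window at contig boundaries
        if (p > 0 && idx.contigOf[p] != idx.contigOf[p - 1]) { run = 0; w = 0; }
        int code = baseCode2(idx.seq[p]);
        if (code < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint64_t)code) & mask;
        if (++run >= seedLen)
            idx.seeds[w].push_back((int)p - seedLen + 1);
    }
}

struct Hit { int matches = -1; int alignedLen = 0; double identity = 0.0; };

// Ungapped evaluation of one fragment orientation against the index:
// exact seeds every `step` bases vote for diagonals; each candidate
// diagonal is scored by ungapped identity over the fragment window
// clipped to the contig holding the seed.
static void scanOrientation(const SubjectIndex& idx, const std::string& frag,
                            int step, Hit& best) {
    int fl = (int)frag.size();
    int sl = idx.seedLen;
    if (fl < sl) return;
    const uint64_t mask = (1ULL << (2 * sl)) - 1;
    std::vector<int> starts;
    for (int q = 0; q + sl <= fl; q += step) starts.push_back(q);
    if (starts.empty() || starts.back() != fl - sl) starts.push_back(fl - sl);
    std::unordered_map<int64_t, int> diagSeen; // (contig, diag) -> flag
    for (int q : starts) {
        uint64_t w = 0;
        bool ok = true;
        for (int t = 0; t < sl; ++t) {
            int code = baseCode2(frag[q + t]);
            if (code < 0) { ok = false; break; }
            w = ((w << 2) | (uint64_t)code) & mask;
        }
        if (!ok) continue;
        auto it = idx.seeds.find(w);
        if (it == idx.seeds.end()) continue;
        for (int pos : it->second) {
            int diag = pos - q; // subject offset of fragment position 0
            int ctg = idx.contigOf[pos];
            int64_t key = ((int64_t)ctg << 32) ^ (int64_t)(diag + 1000000000);
            if (diagSeen.count(key)) continue;
            diagSeen[key] = 1;
            int lo = std::max(diag, idx.contigStart[ctg]);
            int hi = std::min(diag + fl, idx.contigEnd[ctg]);
            int alen = hi - lo;
            if (alen <= 0) continue;
            int matches = 0;
            for (int p = lo; p < hi; ++p) {
                char a = frag[p - diag], b = idx.seq[p];
                int ca = baseCode2(a), cb = baseCode2(b);
                if (ca >= 0 && ca == cb) ++matches;
            }
            if (matches > best.matches ||
                (matches == best.matches && alen > best.alignedLen)) {
                best.matches = matches;
                best.alignedLen = alen;
                best.identity = 100.0 * matches / alen;
            }
        }
    }
}

// Best ungapped local placement (either strand) of each fragment against
// the subject contigs. Returns per-fragment identity (%), aligned length,
// and whether any placement was found at all; acceptance filtering
// (minimum aligned fraction / identity) is applied by the caller.
// [[Rcpp::export]]
DataFrame cpp_align_fragments(CharacterVector fragments, CharacterVector subject,
                              int seedLen, int seedStep) {
    if (seedLen < 4 || seedLen > 31) stop("seedLen must be in [4, 31]");
    SubjectIndex idx;
    buildIndex(idx, subject, seedLen);
    R_xlen_t nf = fragments.size();
    NumericVector identity(nf), alignedLen(nf);
    LogicalVector found(nf);
    for (R_xlen_t i = 0; i < nf; ++i) {
        std::string frag = as<std::string>(fragments[i]);
        Hit best;
        scanOrientation(idx, frag, seedStep, best);
        std::string rc(frag.rbegin(), frag.rend());
        for (auto& c : rc) c = compBase(c);
        scanOrientation(idx, rc, seedStep, best);
        if (best.matches >= 0) {
            found[i] = true;
            identity[i] = best.identity;
            alignedLen[i] = best.alignedLen;
        } else {
            found[i] = false;
            identity[i] = NA_REAL;
            alignedLen[i] = 0;
        }
    }
    return DataFrame::create(_["identity"] = identity,
                             _["aligned_length"] = alignedLen,
                             _["found"] = found);
}
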