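#include "fp_common.h"
#include <functional>
#include <vector>

using namespace Rcpp;

// Build a Singlebit or Multibit tree over the given database members
// (1-based column indices into bits). Returns flat preorder arrays; bit
// positions are 1-based. Singlebit recursion stops when all fingerprints in
// a node are identical; Multibit stops below leafLimit or when no informative
// unclaimed bit remains. Split bit: 1-count closest to half the node size,
// ties to the lowest position. Match-bits (Multibit, internal nodes only):
// unclaimed positions on which every fingerprint in the subtree agrees.
// [[Rcpp::export]]
List buildTreeC(RawMatrix bits, int nBits, IntegerVector members,
                int leafLimit, bool singlebit) {
    const unsigned char* base = (const unsigned char*)RAW(bits);
    const int nBytes = bits.nrow();

    std::vector<int> splitPos, left, right, matchPos, matchVal, leafItems;
    std::vector<int> matchOff(1, 0), leafOff(1, 0);
    std::vector<char> claimed(nBits, 0);
    std::vector<int> counts(nBits);

    std::function<int(std::vector<int>&)> build =
        [&](std::vector<int>& mem) -> int {
        const int sz = (int)mem.size();
        std::fill(counts.begin(), counts.end(), 0);
        for (int m : mem) {
            const unsigned char* col = base + (size_t)(m - 1) * nBytes;
            for (int byte = 0; byte < nBytes; ++byte) {
                unsigned v = col[byte];
                while (v) {
                    counts[byte * 8 + __builtin_ctz(v)]++;
                    v &= v - 1;
                }
            }
        }

        int best = -1;
        double bestDiff = 1e18;
        for (int p = 0; p < nBits; ++p) {
            if (claimed[p] || counts[p] == 0 || counts[p] == sz) continue;
            double diff = std::fabs(counts[p] - sz / 2.0);
            if (diff < bestDiff - 1e-9) {
                bestDiff = diff;
                best = p;
            }
        }

        const int id = (int)left.size() + 1;
        left.push_back(0);
        right.push_back(0);
        splitPos.push_back(NA_INTEGER);

        const bool isLeaf = singlebit ? (best < 0)
                                      : (sz < leafLimit || best < 0);
        if (isLeaf) {
            for (int m : mem) leafItems.push_back(m);
            leafOff.push_back((int)leafItems.size());
            matchOff.push_back((int)matchPos.size());
            return id;
        }

        std::vector<int> myMatch;
        if (!singlebit) {
            for (int p = 0; p < nBits; ++p) {
                if (claimed[p]) continue;
                if (counts[p] == 0 || counts[p] == sz) {
                    matchPos.push_back(p + 1);
                    matchVal.push_back(counts[p] == sz ? 1 : 0);
                    claimed[p] = 1;
                    myMatch.push_back(p);
                }
            }
        }
        matchOff.push_back((int)matchPos.size());
        leafOff.push_back((int)leafItems.size());
        splitPos[id - 1] = best + 1;

        std::vector<int> zeros, ones;
        zeros.reserve(sz);
        ones.reserve(sz);
        for (int m : mem) {
            const unsigned char* col = base + (size_t)(m - 1) * nBytes;
            (get_bit(col, best) ? ones : zeros).push_back(m);
        }
        { std::vector<int>().swap(mem); }
        left[id - 1] = build(zeros);
        { std::vector<int>().swap(zeros); }
        right[id - 1] = build(ones);
        for (int p : myMatch) claimed[p] = 0;
        return id;
    };

    std::vector<int> mem(members.begin(), members.end());
    build(mem);

    return List::create(
        _["splitPos"] = IntegerVector(splitPos.begin(), splitPos.end()),
        _["left"] = IntegerVector(left.begin(), left.end()),
        _["right"] = IntegerVector(right.begin(), right.end()),
        _["matchOff"] = IntegerVector(matchOff.begin(), matchOff.end()),
        _["matchPos"] = IntegerVector(matchPos.begin(), matchPos.end()),
        _["matchVal"] = IntegerVector(matchVal.begin(), matchVal.end()),
        _["leafOff"] = IntegerVector(leafOff.begin(), leafOff.end()),
        _["leafItems"] = IntegerVector(leafItems.begin(), leafItems.end()));
}
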