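#ifndef FPSCREEN_FP_COMMON_H
#define FPSCREEN_FP_COMMON_H

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>

// Fingerprints are packed LSB-first: bit position p (0-based) lives in byte
// p >> 3 at bit p & 7, matching R's packBits() and the FPS hex convention.

static inline int popcount_bytes(const unsigned char* p, int nBytes) {
    int c = 0, i = 0;
    for (; i + 8 <= nBytes; i += 8) {
        uint64_t w;
        std::memcpy(&w, p + i, 8);
        c += __builtin_popcountll(w);
    }
    for (; i < nBytes; ++i) c += __builtin_popcount((unsigned)p[i]);
    return c;
}

static inline int popcount_and(const unsigned char* a, const unsigned char* b,
                               int nBytes) {
    int c = 0, i = 0;
    for (; i + 8 <= nBytes; i += 8) {
        uint64_t wa, wb;
        std::memcpy(&wa, a + i, 8);
        std::memcpy(&wb, b + i, 8);
        c += __builtin_popcountll(wa & wb);
    }
    for (; i < nBytes; ++i) c += __builtin_popcount((unsigned)(a[i] & b[i]));
    return c;
}

static inline int popcount_xor(const unsigned char* a, const unsigned char* b,
                               int nBytes) {
    int c = 0, i = 0;
    for (; i + 8 <= nBytes; i += 8) {
        uint64_t wa, wb;
        std::memcpy(&wa, a + i, 8);
        std::memcpy(&wb, b + i, 8);
        c += __builtin_popcountll(wa ^ wb);
    }
    for (; i < nBytes; ++i) c += __builtin_popcount((unsigned)(a[i] ^ b[i]));
    return c;
}

static inline int get_bit(const unsigned char* p, int pos) {
    return (p[pos >> 3] >> (pos & 7)) & 1;
}

// Threshold predicate for numer/denom >= s, with a relative guard in the
// sound direction (a tie is never pruned and always counts as a hit).
// denom == 0 only for the all-zero-vs-all-zero pair, taken as similarity 1.
static inline bool pass_threshold(double numer, double denom, double s) {
    if (denom <= 0) return true;
    return numer >= s * denom - 1e-12 * denom;
}

// Upper bound on the Tanimoto coefficient from popcounts a, b and d, any
// lower bound on |A xor B| (folded XOR weight or folded-popcount difference).
static inline bool xor_pretest(int a, int b, int d, double s) {
    int cmax = (a + b - d) / 2;
    int mn = a < b ? a : b;
    if (cmax > mn) cmax = mn;
    if (cmax < 0) cmax = 0;
    return pass_threshold((double)cmax, (double)(a + b - cmax), s);
}

struct Interval {
    int lo, hi;
    bool ok;
};

// Maximal integer interval of fragment popcounts n_i in [0, Ni] for which the
// partial grid bound (pAnd + min(ai, n) + R) / (pOr + max(ai, n) + R) >= s.
// The bound is unimodal with its peak at n = ai, so a closed-form guess for
// each endpoint is corrected by +-1 steps against the exact predicate.
static inline Interval level_interval(double pAnd, double pOr, double R,
                                      int ai, int Ni, double s) {
    int peak = ai < Ni ? ai : Ni;
    if (peak < 0) peak = 0;
    auto pass = [&](int v) {
        double mn = ai < v ? ai : v, mx = ai > v ? ai : v;
        return pass_threshold(pAnd + mn + R, pOr + mx + R, s);
    };
    Interval out = {1, 0, false};
    if (!pass(peak)) return out;
    int nl = 0;
    if (!pass(0)) {
        double g = std::ceil(s * (pOr + ai + R) - pAnd - R);
        nl = (int)g;
        if (nl < 1) nl = 1;
        if (nl > peak) nl = peak;
        while (!pass(nl)) ++nl;
        while (nl > 0 && pass(nl - 1)) --nl;
    }
    int nu = Ni;
    if (!pass(Ni)) {
        double g = s > 0 ? std::floor((pAnd + ai + R) / s - pOr - R) : Ni;
        nu = (int)g;
        if (nu > Ni - 1) nu = Ni - 1;
        if (nu < peak) nu = peak;
        while (!pass(nu)) --nu;
        while (nu < Ni && pass(nu + 1)) ++nu;
    }
    out.lo = nl;
    out.hi = nu;
    out.ok = true;
    return out;
}

// Shared state for one query against one database.
struct SearchCtx {
    const unsigned char* bits;     // nBytes x n column-packed fingerprints
    int nBytes;
    const int* pops;               // per-fingerprint popcounts
    const unsigned char* xorBits;  // wBytes x n folded summaries
    int wBytes;
    const unsigned char* q;        // query fingerprint
    const unsigned char* qXor;     // folded query
    int qPop;
    double sMin;
    std::vector<int> hitIdx;       // 1-based database indices
    std::vector<double> hitCoef;
    long coefComputed = 0;   // records inspected individually (the cost metric)
    long exactComputed = 0;  // exact |A & B| popcounts actually evaluated
    long nodesVisited = 0;
    long bucketsVisited = 0;
};

// Per-record candidate inspection: XOR pre-test, then the exact coefficient
// for survivors.  coefComputed counts every record that reaches this stage
// (the structural-pruning survivors); the folded pre-test only saves the
// exact popcount, it does not reduce the metric.
static inline void leaf_check(SearchCtx& ctx, int i) {
    ctx.coefComputed++;
    int b = ctx.pops[i - 1];
    int d = popcount_xor(ctx.qXor, ctx.xorBits + (size_t)(i - 1) * ctx.wBytes,
                         ctx.wBytes);
    if (!xor_pretest(ctx.qPop, b, d, ctx.sMin)) return;
    int c = popcount_and(ctx.q, ctx.bits + (size_t)(i - 1) * ctx.nBytes,
                         ctx.nBytes);
    ctx.exactComputed++;
    double denom = (double)ctx.qPop + b - c;
    double coef = denom > 0 ? c / denom : 1.0;
    if (pass_threshold((double)c, denom, ctx.sMin)) {
        ctx.hitIdx.push_back(i);
        ctx.hitCoef.push_back(coef);
    }
}

// Flattened tree as built by buildTreeC(): 1-based node ids in preorder,
// child id 0 marks a leaf, bit positions 1-based.
struct TreeView {
    const int* splitPos;
    const int* left;
    const int* right;
    const int* matchOff;  // length nNodes + 1, 0-based offsets
    const int* matchPos;
    const int* matchVal;
    const int* leafOff;   // length nNodes + 1
    const int* leafItems; // 1-based database indices
};

void multibit_dfs(const TreeView& t, int node, int b, int m00, int m01,
                  int m10, int m11, SearchCtx& ctx);
void singlebit_dfs(const TreeView& t, int node, int b, int m00, int m01,
                   int m10, int m11, SearchCtx& ctx);
TreeView tree_view(const Rcpp::List& tree);

#endif
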