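#include "fp_common.h"
#include <functional>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector fpPopcountsC(RawMatrix bits) {
    const unsigned char* base = (const unsigned char*)RAW(bits);
    const int nBytes = bits.nrow();
    const int n = bits.ncol();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = popcount_bytes(base + (size_t)i * nBytes, nBytes);
    return out;
}

// Tanimoto of one query against database columns idx (1-based); NA idx not
// allowed. Both all-zero -> 1.0.
// [[Rcpp::export]]
NumericVector tanimotoManyC(RawMatrix bits, IntegerVector pops, RawVector q,
                            int qPop, IntegerVector idx) {
    const unsigned char* base = (const unsigned char*)RAW(bits);
    const unsigned char* qp = (const unsigned char*)RAW(q);
    const int nBytes = bits.nrow();
    NumericVector out(idx.size());
    for (int j = 0; j < idx.size(); ++j) {
        const int i = idx[j];
        const int c = popcount_and(qp, base + (size_t)(i - 1) * nBytes, nBytes);
        const double denom = (double)qPop + pops[i - 1] - c;
        out[j] = denom > 0 ? c / denom : 1.0;
    }
    return out;
}

// Fold each column to width bits: summary bit j is the parity of all
// fingerprint bits at positions p with p mod width == j.
// [[Rcpp::export]]
RawMatrix xorFoldMatrixC(RawMatrix bits, int nBits, int width) {
    const unsigned char* base = (const unsigned char*)RAW(bits);
    const int nBytes = bits.nrow();
    const int n = bits.ncol();
    const int wBytes = (width + 7) / 8;
    RawMatrix out(wBytes, n);
    unsigned char* obase = (unsigned char*)RAW(out);
    for (int i = 0; i < n; ++i) {
        const unsigned char* col = base + (size_t)i * nBytes;
        unsigned char* ocol = obase + (size_t)i * wBytes;
        for (int p = 0; p < nBits; ++p) {
            if (get_bit(col, p)) {
                const int j = p % width;
                ocol[j >> 3] ^= (unsigned char)(1u << (j & 7));
            }
        }
    }
    return out;
}

static List ctx_result(SearchCtx& ctx) {
    return List::create(
        _["idx"] = IntegerVector(ctx.hitIdx.begin(), ctx.hitIdx.end()),
        _["coef"] = NumericVector(ctx.hitCoef.begin(), ctx.hitCoef.end()),
        _["coefficientsComputed"] = (double)ctx.coefComputed,
        _["exactCoefficients"] = (double)ctx.exactComputed,
        _["nodesVisited"] = (double)ctx.nodesVisited,
        _["bucketsVisited"] = (double)ctx.bucketsVisited);
}

static SearchCtx make_ctx(RawMatrix& bits, IntegerVector& pops,
                          RawMatrix& xorBits, RawVector& q, RawVector& qXor,
                          int qPop, double sMin) {
    SearchCtx ctx;
    ctx.bits = (const unsigned char*)RAW(bits);
    ctx.nBytes = bits.nrow();
    ctx.pops = INTEGER(pops);
    ctx.xorBits = (const unsigned char*)RAW(xorBits);
    ctx.wBytes = xorBits.nrow();
    ctx.q = (const unsigned char*)RAW(q);
    ctx.qXor = (const unsigned char*)RAW(qXor);
    ctx.qPop = qPop;
    ctx.sMin = sMin;
    return ctx;
}

// Linear scan: XOR-fold pre-test on every record, exact coefficient only for
// survivors.
// [[Rcpp::export]]
List linearSearchC(RawMatrix bits, IntegerVector pops, RawMatrix xorBits,
                   RawVector q, RawVector qXor, int qPop, double sMin) {
    SearchCtx ctx = make_ctx(bits, pops, xorBits, q, qXor, qPop, sMin);
    const int n = bits.ncol();
    for (int i = 1; i <= n; ++i) leaf_check(ctx, i);
    return ctx_result(ctx);
}

// Three-stage pruning: popcount (bit-bound) buckets first, then the
// folded-popcount difference bound, then the full folded-XOR bound; exact
// coefficients for stage-3 survivors only.
// [[Rcpp::export]]
List baldiSearchC(List byPopcount, RawMatrix bits, IntegerVector pops,
                  RawMatrix xorBits, IntegerVector xorPops, RawVector q,
                  RawVector qXor, int qPop, int qXorPop, double sMin,
                  int nBits) {
    SearchCtx ctx = make_ctx(bits, pops, xorBits, q, qXor, qPop, sMin);
    Interval iv = level_interval(0.0, 0.0, 0.0, qPop, nBits, sMin);
    double s1 = 0, s2 = 0, s3 = 0;
    if (iv.ok) {
        for (int b = iv.lo; b <= iv.hi; ++b) {
            SEXP bucket = byPopcount[b];
            if (Rf_isNull(bucket)) continue;
            ctx.bucketsVisited++;
            IntegerVector mem(bucket);
            for (int j = 0; j < mem.size(); ++j) {
                const int i = mem[j];
                s1++;
                const int dlow = std::abs(qXorPop - xorPops[i - 1]);
                if (!xor_pretest(qPop, b, dlow, sMin)) continue;
                s2++;
                // stage 3 inspects the record's full-width summary: this is
                // the per-record work the cost metric counts
                ctx.coefComputed++;
                const int d = popcount_xor(
                    ctx.qXor, ctx.xorBits + (size_t)(i - 1) * ctx.wBytes,
                    ctx.wBytes);
                if (!xor_pretest(qPop, b, d, sMin)) continue;
                s3++;
                const int c = popcount_and(
                    ctx.q, ctx.bits + (size_t)(i - 1) * ctx.nBytes,
                    ctx.nBytes);
                ctx.exactComputed++;
                const double denom = (double)qPop + b - c;
                if (pass_threshold((double)c, denom, sMin)) {
                    ctx.hitIdx.push_back(i);
                    ctx.hitCoef.push_back(denom > 0 ? c / denom : 1.0);
                }
            }
        }
    }
    List out = ctx_result(ctx);
    out["stageSurvivors"] = NumericVector::create(s1, s2, s3);
    return out;
}

// [[Rcpp::export]]
IntegerVector levelIntervalC(double pAnd, double pOr, double R, int ai,
                             int Ni, double s) {
    Interval iv = level_interval(pAnd, pOr, R, ai, Ni, s);
    if (!iv.ok) return IntegerVector(0);
    return IntegerVector::create(iv.lo, iv.hi);
}

// Depth-first traversal of the kD grid. bucketCoords rows must be sorted
// lexicographically; payloads[i] is an integer vector of members (list
// buckets) or a flat tree (singlebit/multibit buckets).
// [[Rcpp::export]]
List gridSearchC(IntegerMatrix bucketCoords, IntegerVector bucketPop,
                 List payloads, IntegerVector lengths, IntegerVector aCounts,
                 int kind, RawMatrix bits, IntegerVector pops,
                 RawMatrix xorBits, RawVector q, RawVector qXor, int qPop,
                 double sMin) {
    SearchCtx ctx = make_ctx(bits, pops, xorBits, q, qXor, qPop, sMin);
    const int k = bucketCoords.ncol();
    const int B = bucketCoords.nrow();
    std::vector<double> suffix(k + 1, 0.0);
    for (int j = k - 1; j >= 0; --j) suffix[j] = suffix[j + 1] + aCounts[j];

    std::function<void(int, int, int, double, double)> rec =
        [&](int level, int lo, int hi, double pAnd, double pOr) {
        if (level == k) {
            for (int bi = lo; bi < hi; ++bi) {
                ctx.bucketsVisited++;
                if (kind == 0) {
                    IntegerVector mem(((SEXP)payloads[bi]));
                    for (int j = 0; j < mem.size(); ++j)
                        leaf_check(ctx, mem[j]);
                } else {
                    List tr(((SEXP)payloads[bi]));
                    TreeView t = tree_view(tr);
                    if (kind == 1)
                        singlebit_dfs(t, 1, bucketPop[bi], 0, 0, 0, 0, ctx);
                    else
                        multibit_dfs(t, 1, bucketPop[bi], 0, 0, 0, 0, ctx);
                }
            }
            return;
        }
        Interval iv = level_interval(pAnd, pOr, suffix[level + 1],
                                     aCounts[level], lengths[level], sMin);
        if (!iv.ok) return;
        int i = lo;
        while (i < hi) {
            const int v = bucketCoords(i, level);
            int j = i;
            while (j < hi && bucketCoords(j, level) == v) ++j;
            if (v >= iv.lo && v <= iv.hi) {
                const double ai = aCounts[level];
                rec(level + 1, i, j, pAnd + (ai < v ? ai : v),
                    pOr + (ai > v ? ai : v));
            }
            i = j;
        }
    };
    rec(0, 0, B, 0.0, 0.0);
    return ctx_result(ctx);
}

// Per-fragment popcounts (grid coordinates): k x n matrix of 1-bit counts of
// the concatenation split given by lengths.
// [[Rcpp::export]]
IntegerMatrix fragPopcountsC(RawMatrix bits, int nBits,
                             IntegerVector lengths) {
    const unsigned char* base = (const unsigned char*)RAW(bits);
    const int nBytes = bits.nrow();
    const int n = bits.ncol();
    const int k = lengths.size();
    IntegerMatrix out(k, n);
    for (int i = 0; i < n; ++i) {
        const unsigned char* col = base + (size_t)i * nBytes;
        int p = 0;
        for (int j = 0; j < k; ++j) {
            int c = 0;
            for (int t = 0; t < lengths[j]; ++t, ++p) c += get_bit(col, p);
            out(j, i) = c;
        }
    }
    return out;
}
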