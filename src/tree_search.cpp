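#include "fp_common.h"

using namespace Rcpp;

TreeView tree_view(const List& tree) {
    TreeView t;
    t.splitPos = INTEGER(((SEXP)tree["splitPos"]));
    t.left = INTEGER(((SEXP)tree["left"]));
    t.right = INTEGER(((SEXP)tree["right"]));
    t.matchOff = INTEGER(((SEXP)tree["matchOff"]));
    t.matchPos = INTEGER(((SEXP)tree["matchPos"]));
    t.matchVal = INTEGER(((SEXP)tree["matchVal"]));
    t.leafOff = INTEGER(((SEXP)tree["leafOff"]));
    t.leafItems = INTEGER(((SEXP)tree["leafItems"]));
    return t;
}

// Descend a Multibit tree. At each node the match-bits refine the lower
// limits m_ij; the subtree bound c/(a + b - c) with c = min(a - m10, b - m01)
// prunes whole branches. b is the shared popcount of the grid bucket.
void multibit_dfs(const TreeView& t, int node, int b, int m00, int m01,
                  int m10, int m11, SearchCtx& ctx) {
    ctx.nodesVisited++;
    const int i0 = t.matchOff[node - 1], i1 = t.matchOff[node];
    for (int j = i0; j < i1; ++j) {
        const int p = t.matchPos[j] - 1;
        const int v = t.matchVal[j];
        if (get_bit(ctx.q, p)) {
            if (v) m11++; else m10++;
        } else {
            if (v) m01++; else m00++;
        }
    }
    int c = ctx.qPop - m10;
    if (b - m01 < c) c = b - m01;
    if (c < 0) c = 0;
    if (!pass_threshold((double)c, (double)ctx.qPop + b - c, ctx.sMin)) return;
    if (t.left[node - 1] == 0) {
        const int l0 = t.leafOff[node - 1], l1 = t.leafOff[node];
        for (int j = l0; j < l1; ++j) leaf_check(ctx, t.leafItems[j]);
        return;
    }
    multibit_dfs(t, t.left[node - 1], b, m00, m01, m10, m11, ctx);
    multibit_dfs(t, t.right[node - 1], b, m00, m01, m10, m11, ctx);
}

// Descend a Singlebit tree: each branch taken contributes one
// (position, value) observation. Leaves hold identical fingerprints, so the
// exact coefficient is computed once per surviving leaf.
void singlebit_dfs(const TreeView& t, int node, int b, int m00, int m01,
                   int m10, int m11, SearchCtx& ctx) {
    ctx.nodesVisited++;
    if (t.left[node - 1] == 0) {
        const int l0 = t.leafOff[node - 1], l1 = t.leafOff[node];
        if (l0 >= l1) return;
        ctx.coefComputed += l1 - l0;
        const int i = t.leafItems[l0];
        const int bi = ctx.pops[i - 1];
        const int d = popcount_xor(
            ctx.qXor, ctx.xorBits + (size_t)(i - 1) * ctx.wBytes, ctx.wBytes);
        if (!xor_pretest(ctx.qPop, bi, d, ctx.sMin)) return;
        const int c = popcount_and(
            ctx.q, ctx.bits + (size_t)(i - 1) * ctx.nBytes, ctx.nBytes);
        ctx.exactComputed++;
        const double denom = (double)ctx.qPop + bi - c;
        if (!pass_threshold((double)c, denom, ctx.sMin)) return;
        const double coef = denom > 0 ? c / denom : 1.0;
        for (int j = l0; j < l1; ++j) {
            ctx.hitIdx.push_back(t.leafItems[j]);
            ctx.hitCoef.push_back(coef);
        }
        return;
    }
    const int p = t.splitPos[node - 1] - 1;
    const int abit = get_bit(ctx.q, p);
    {   // zero child: observed (p, 0)
        const int M10 = m10 + (abit ? 1 : 0), M00 = m00 + (abit ? 0 : 1);
        int c = ctx.qPop - M10;
        if (b - m01 < c) c = b - m01;
        if (c < 0) c = 0;
        if (pass_threshold((double)c, (double)ctx.qPop + b - c, ctx.sMin))
            singlebit_dfs(t, t.left[node - 1], b, M00, m01, M10, m11, ctx);
    }
    {   // one child: observed (p, 1)
        const int M01 = m01 + (abit ? 0 : 1), M11 = m11 + (abit ? 1 : 0);
        int c = ctx.qPop - m10;
        if (b - M01 < c) c = b - M01;
        if (c < 0) c = 0;
        if (pass_threshold((double)c, (double)ctx.qPop + b - c, ctx.sMin))
            singlebit_dfs(t, t.right[node - 1], b, m00, M01, m10, M11, ctx);
    }
}

// Standalone bucket-tree search used by treeSearch(); grid traversal calls
// the dfs routines directly.
// [[Rcpp::export]]
List treeSearchC(List tree, RawMatrix bits, IntegerVector pops,
                 RawMatrix xorBits, RawVector q, RawVector qXor, int qPop,
                 int b, double sMin, bool singlebit) {
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
    TreeView t = tree_view(tree);
    if (singlebit)
        singlebit_dfs(t, 1, b, 0, 0, 0, 0, ctx);
    else
        multibit_dfs(t, 1, b, 0, 0, 0, 0, ctx);
    return List::create(
        _["idx"] = IntegerVector(ctx.hitIdx.begin(), ctx.hitIdx.end()),
        _["coef"] = NumericVector(ctx.hitCoef.begin(), ctx.hitCoef.end()),
        _["coefficientsComputed"] = (double)ctx.coefComputed,
        _["exactCoefficients"] = (double)ctx.exactComputed,
        _["nodesVisited"] = (double)ctx.nodesVisited);
}
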