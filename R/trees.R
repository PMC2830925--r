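## Singlebit and Multibit bucket trees: construction heuristics, the m_ij
## descent bookkeeping and the subtree bound.  Trees are stored flat: all
## node attributes are parallel vectors indexed by 1-based preorder node id,
## with child id 0 marking a leaf.  Bit positions are 1-based.

#' Choose the split bit for a tree node
#'
#' Returns the bit position (1-based) whose 1-count over the fingerprints is
#' closest to half the set size, in the hope of producing a balanced tree;
#' ties are broken by the lowest position.  Positions in \code{excluded} and
#' uninformative positions (all fingerprints equal) are skipped.
#'
#' @param x a \code{\link{FingerprintSet}} or character vector of bit
#'   strings.
#' @param excluded integer positions to skip (e.g. ancestors' match-bits).
#' @return Integer position, or an error when no informative bit exists
#'   (the caller must stop splitting).
#' @export
chooseSplitBit <- function(x, excluded = integer(0)) {
    if (is.character(x)) x <- fingerprintSet(x)
    stopifnot(is(x, "FingerprintSet"))
    if (length(x) == 0L) stop("'x' must be nonempty")
    counts <- integer(x@nBits)
    for (i in seq_len(length(x)))
        counts <- counts + as.integer(.unpackColumn(x@bits, i, x@nBits))
    ok <- counts > 0L & counts < length(x)
    if (length(excluded)) ok[excluded] <- FALSE
    if (!any(ok))
        stop("no informative bit available: stop splitting")
    cand <- which(ok)
    diff <- abs(counts[cand] - length(x) / 2)
    cand[which.min(diff)]  # which.min keeps the lowest position on ties
}

#' Build a Singlebit tree
#'
#' A binary tree over the fingerprints of one grid bucket: each node stores
#' a single split position, fingerprints with a zero there go left and with
#' a one go right, recursively until all fingerprints in a node are
#' identical.  Leaves therefore hold one distinct fingerprint (with
#' duplicates kept at their multiplicity).
#'
#' @param x a \code{\link{FingerprintSet}} (nonempty).
#' @return A list of parallel vectors (class \code{"fpTree"}):
#'   \code{splitPos} (NA at leaves), \code{left}/\code{right} child ids
#'   (0 at leaves), \code{leafOff}/\code{leafItems} (indices into \code{x}),
#'   and empty match-bit slots shared with the Multibit layout.
#' @export
buildSinglebitTree <- function(x) {
    stopifnot(is(x, "FingerprintSet"), length(x) > 0L)
    tr <- buildTreeC(x@bits, x@nBits, seq_len(length(x)), 1L, TRUE)
    structure(tr, class = "fpTree", kind = "singlebit", n = length(x))
}

#' Build a Multibit tree
#'
#' Like the Singlebit tree, but every internal node also stores its
#' \emph{match-bits}: all positions, not claimed by any ancestor, on which
#' every fingerprint in the subtree agrees (with the shared value).  During
#' a search the match-bits of each visited node refine the lower limits
#' \eqn{m_{ij}} and hence tighten the subtree bound.  Splitting stops when a
#' node holds fewer than \code{leafLimit} fingerprints (or no informative
#' bit remains), creating a plain leaf.
#'
#' @param x a \code{\link{FingerprintSet}} (nonempty).
#' @param leafLimit leaf limit \eqn{l}; nodes with fewer fingerprints become
#'   leaves.  Default 6.
#' @return A list of parallel vectors (class \code{"fpTree"}) as in
#'   \code{\link{buildSinglebitTree}}, plus \code{matchOff} /
#'   \code{matchPos} / \code{matchVal}: node \code{i}'s match-bits are
#'   positions \code{matchPos[(matchOff[i]+1):matchOff[i+1]]} with values
#'   \code{matchVal[...]}.
#' @export
buildMultibitTree <- function(x, leafLimit = 6L) {
    stopifnot(is(x, "FingerprintSet"), length(x) > 0L)
    leafLimit <- as.integer(leafLimit)
    if (leafLimit < 1L) stop("'leafLimit' must be >= 1")
    tr <- buildTreeC(x@bits, x@nBits, seq_len(length(x)), leafLimit, FALSE)
    structure(tr, class = "fpTree", kind = "multibit", n = length(x))
}

#' @export
print.fpTree <- function(x, ...) {
    leaves <- sum(x$left == 0L)
    cat(sprintf("%s tree: %d nodes (%d leaves) over %d fingerprints\n",
                attr(x, "kind"), length(x$left), leaves, attr(x, "n")))
    invisible(x)
}

#' Match-bits of a tree node
#'
#' @param tree a tree from \code{\link{buildMultibitTree}}.
#' @param node 1-based node id.
#' @return Integer matrix with columns \code{pos} (1-based) and
#'   \code{value}; zero rows when the node has no match-bits.
#' @export
matchBits <- function(tree, node) {
    i0 <- tree$matchOff[node] + 1L
    i1 <- tree$matchOff[node + 1L]
    idx <- if (i1 >= i0) i0:i1 else integer(0)
    cbind(pos = tree$matchPos[idx], value = tree$matchVal[idx])
}

#' Initial descent bookkeeping state
#'
#' The four counters \eqn{m_{ij}}: lower limits, accumulated along a
#' root-to-node path, on the number of positions where the query has bit
#' \eqn{i} and every fingerprint in the subtree has bit \eqn{j}.
#'
#' @return Named integer vector \code{c(m00, m01, m10, m11)}, all zero.
#' @export
boundState <- function() {
    c(m00 = 0L, m01 = 0L, m10 = 0L, m11 = 0L)
}

#' Update the descent state with a node's match-bits
#'
#' For each match-bit \code{(p, v)} the counter \eqn{m_{A[p], v}} is
#' incremented.  The update is path-local: callers keep the parent state for
#' the sibling branch.
#'
#' @param state a state from \code{\link{boundState}}.
#' @param A the query fingerprint (bit string or length-1
#'   \code{\link{FingerprintSet}}).
#' @param matchBits integer matrix with columns \code{pos} (1-based) and
#'   \code{value}, e.g. from \code{\link{matchBits}}.
#' @return The updated state.
#' @export
updateState <- function(state, A, matchBits) {
    A <- .asFp1(A)
    if (nrow(matchBits) == 0L) return(state)
    pos <- matchBits[, 1L]
    if (anyDuplicated(pos))
        stop("duplicate match-bit position on one path")
    abits <- as.integer(.unpackColumn(A@bits, 1L, A@nBits)[pos])
    key <- paste0("m", abits, matchBits[, 2L])
    for (j in seq_along(key)) state[key[j]] <- state[key[j]] + 1L
    state
}

#' Subtree upper bound on the Tanimoto coefficient
#'
#' Every fingerprint \eqn{B} below the current node has at least
#' \code{m10} positions where the query has a one and \eqn{B} a zero, and at
#' least \code{m01} positions the other way around, so its intersection with
#' the query is at most \eqn{c = \min(a - m_{10}, b - m_{01})} and
#' \eqn{S_T(A,B) \le c / (a + b - c)}.  With \eqn{m_{10} = m_{01} = 0} this
#' reduces to \code{\link{swamidassBound}}.  \eqn{b} is known exactly
#' because all fingerprints in one grid bucket share their popcount.
#'
#' @param state a state vector \code{c(m00, m01, m10, m11)}.
#' @param a query popcount.
#' @param b bucket popcount.
#' @return Numeric bound in \[0, 1\]; 1 when \code{a = b = 0}.
#'
#' @examples
#' treeBound(c(m00 = 0, m01 = 0, m10 = 1, m11 = 0), 4, 4)  # 3/5
#' @export
treeBound <- function(state, a, b) {
    m10 <- state[["m10"]]
    m01 <- state[["m01"]]
    if (m10 > a || m01 > b)
        stop("inconsistent state: m10 > a or m01 > b")
    cc <- max(0, min(a - m10, b - m01))
    denom <- a + b - cc
    if (denom == 0) 1 else cc / denom
}

#' Search one bucket tree
#'
#' Depth-first search of a Singlebit or Multibit tree built over (a subset
#' of) \code{x}: the descent maintains the \eqn{m_{ij}} state, prunes every
#' subtree whose \code{\link{treeBound}} falls below \code{sMin}, and at the
#' leaves applies the XOR-fold pre-test before computing exact coefficients.
#'
#' @param tree a tree from \code{\link{buildSinglebitTree}} or
#'   \code{\link{buildMultibitTree}} whose leaf items index into \code{x}.
#' @param x the \code{\link{FingerprintSet}} the tree was built over.
#' @param A the query fingerprint.
#' @param sMin threshold in \[0, 1\].
#' @param xorWidth XOR fold width for the leaf pre-test.
#' @return A \code{\link{SearchResult}}.
#' @export
treeSearch <- function(tree, x, A, sMin, xorWidth = 128L) {
    stopifnot(inherits(tree, "fpTree"), is(x, "FingerprintSet"))
    if (sMin < 0 || sMin > 1) stop("'sMin' must be in [0, 1]")
    q <- .asQuery(.asFp1(A), x@nBits)
    pops <- unique(x@popcounts[tree$leafItems])
    if (length(pops) > 1L)
        stop("bucket trees require fingerprints of equal popcount")
    b <- if (length(pops)) pops else 0L
    xorWidth <- min(as.integer(xorWidth), x@nBits)
    xb <- xorFoldMatrixC(x@bits, x@nBits, xorWidth)
    qx <- xorFoldMatrixC(matrix(q$bits, ncol = 1L), x@nBits, xorWidth)[, 1L]
    res <- treeSearchC(tree, x@bits, x@popcounts, xb, q$bits, qx, q$pop, b,
                       sMin, identical(attr(tree, "kind"), "singlebit"))
    .makeResult(res, x@ids, length(x))
}
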