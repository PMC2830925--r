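## kD grid plumbing: fragmenting fingerprints, bucket coordinates, and the
## per-level popcount interval that drives the grid traversal.

#' Fragment lengths for the kD grid
#'
#' Splits a fingerprint of \code{nBits} bits into \code{k} near-equal
#' fragments.  When \code{nBits} is not divisible by \code{k} the first
#' \code{nBits \%\% k} fragments are one bit longer, so lengths differ by at
#' most one and the scheme is deterministic.
#'
#' @param nBits fingerprint length.
#' @param k number of fragments, \code{1 <= k <= nBits}.
#' @return Integer vector of \code{k} fragment lengths summing to
#'   \code{nBits}.
#'
#' @examples
#' fragmentLengths(1024, 4)  # 256 256 256 256
#' fragmentLengths(1024, 3)  # 342 341 341
#' @export
fragmentLengths <- function(nBits, k) {
    nBits <- as.integer(nBits)
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > nBits)
        stop("'k' must satisfy 1 <= k <= nBits")
    base <- nBits %/% k
    rep(base, k) + as.integer(seq_len(k) <= nBits %% k)
}

#' Per-fragment popcounts (grid coordinates)
#'
#' Splits each fingerprint into the concatenation fragments given by
#' \code{lengths} (in position order) and counts the 1-bits of each
#' fragment.  These counts are the fingerprint's bucket coordinates in the
#' kD grid; they sum to the total popcount.
#'
#' @param x a fingerprint (bit string) or a \code{\link{FingerprintSet}}.
#' @param lengths integer fragment lengths, e.g. from
#'   \code{\link{fragmentLengths}}; must sum to \code{nBits}.
#' @return For a single fingerprint an integer vector of length \code{k};
#'   for a set a \code{k x n} integer matrix.
#'
#' @examples
#' fragmentPopcounts("110100", fragmentLengths(6, 2))  # 2 1
#' @export
fragmentPopcounts <- function(x, lengths) {
    single <- is.character(x) && length(x) == 1L
    x <- .asFp1(x)
    lengths <- as.integer(lengths)
    if (sum(lengths) != x@nBits)
        stop("fragment lengths must sum to the fingerprint length")
    n <- length(x)
    out <- fragPopcountsC(x@bits, x@nBits, lengths)
    colnames(out) <- x@ids
    if (single || n == 1L) out[, 1L] else out
}

#' Qualifying popcount interval at one grid level
#'
#' During the grid traversal the coordinates \code{prefix} of levels
#' \code{1..i-1} are fixed and the coordinates of levels below \code{i} are
#' unknown.  Writing \eqn{P_\wedge = \sum_{j<i} \min(a_j, n_j)},
#' \eqn{P_\vee = \sum_{j<i} \max(a_j, n_j)} and
#' \eqn{R = \sum_{j>i} a_j} (the most favourable contribution of the unseen
#' levels), the Tanimoto coefficient of the query against anything in a
#' bucket with level-\code{i} coordinate \eqn{n_i} is at most
#' \deqn{(P_\wedge + \min(a_i, n_i) + R) / (P_\vee + \max(a_i, n_i) + R).}
#' The bound is unimodal in \eqn{n_i} (peaking at \eqn{n_i = a_i}), so the
#' coordinates meeting the threshold form an integer interval.  Endpoints
#' are found in closed form and corrected against the exact predicate so
#' float rounding can never prune a qualifying bucket.
#'
#' @param aCounts integer vector \code{(a_1, ..., a_k)} of the query's
#'   fragment popcounts.
#' @param sMin threshold in \[0, 1\].
#' @param level the level \code{i} being expanded (1-based).
#' @param prefix integer coordinates already fixed for levels
#'   \code{1..i-1} (length \code{level - 1}).
#' @param lengths fragment lengths \code{(N_1, ..., N_k)}.
#' @return Integer vector \code{c(lower, upper)}, or \code{integer(0)} when
#'   no coordinate at this level can reach the threshold.
#'
#' @examples
#' levelInterval(100, 0.9, 1, integer(0), 1024)  # 90 111
#' @export
levelInterval <- function(aCounts, sMin, level = 1L, prefix = integer(0),
                          lengths) {
    aCounts <- as.integer(aCounts)
    lengths <- as.integer(lengths)
    k <- length(lengths)
    if (length(aCounts) != k)
        stop("'aCounts' and 'lengths' must have equal length")
    level <- as.integer(level)
    if (level < 1L || level > k) stop("invalid 'level'")
    if (length(prefix) != level - 1L)
        stop("'prefix' must have length level - 1")
    if (sMin < 0 || sMin > 1) stop("'sMin' must be in [0, 1]")
    if (any(prefix < 0L) || any(prefix > lengths[seq_len(level - 1L)]))
        stop("'prefix' coordinates out of range")
    pAnd <- sum(pmin(aCounts[seq_len(level - 1L)], prefix))
    pOr <- sum(pmax(aCounts[seq_len(level - 1L)], prefix))
    R <- if (level < k) sum(aCounts[(level + 1L):k]) else 0L
    levelIntervalC(pAnd, pOr, R, aCounts[level], lengths[level], sMin)
}

# Internal: build the sparse grid skeleton for a database.  Returns bucket
# coordinates (rows sorted lexicographically), per-bucket total popcount and
# the member indices of each bucket (in database order).
.buildGridSkeleton <- function(db, lengths) {
    n <- length(db)
    k <- length(lengths)
    if (n == 0L)
        return(list(coords = matrix(0L, 0L, k), pop = integer(0),
                    members = list()))
    fc <- fragmentPopcounts(db, lengths)
    fc <- matrix(fc, nrow = k)  # k x n even when n == 1
    key <- apply(fc, 2L, paste, collapse = ",")
    members <- split(seq_len(n), key)
    coords <- do.call(rbind, lapply(strsplit(names(members), ",", fixed = TRUE),
                                    as.integer))
    ord <- do.call(order, lapply(seq_len(k), function(j) coords[, j]))
    list(coords = coords[ord, , drop = FALSE],
         pop = as.integer(rowSums(coords[ord, , drop = FALSE])),
         members = unname(members[ord]))
}
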