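## The Tanimoto coefficient and the closed-form upper bounds shared by all
## search strategies.  Every bound is *sound*: it never underestimates the
## true coefficient, so pruning against it preserves exactness.

#' Number of 1-bits
#'
#' @param x a \code{"0"}/\code{"1"} character vector, a logical vector, a raw
#'   vector of packed bits, a \code{\link{FingerprintSet}} or an
#'   \code{\link{XorSummary}}.
#' @return Integer popcount(s).
#'
#' @examples
#' popcount("101101")  # 4
#' @export
popcount <- function(x) {
    if (is(x, "FingerprintSet")) return(x@popcounts)
    if (is(x, "XorSummary")) return(x@popcount)
    if (is.character(x)) {
        bad <- grepl("[^01]", x)
        if (any(bad)) stop("bitstrings may only contain '0' and '1'")
        return(vapply(x, function(s) sum(strsplit(s, "", fixed = TRUE)[[1L]] == "1"),
                      integer(1), USE.NAMES = FALSE))
    }
    if (is.logical(x)) return(sum(x))
    if (is.raw(x)) return(sum(as.integer(rawToBits(x))))
    stop("unsupported input for popcount()")
}

# coerce bit-string / length-1 FingerprintSet arguments to length-1 sets
.asFp1 <- function(x) {
    if (is.character(x)) x <- fingerprintSet(x)
    stopifnot(is(x, "FingerprintSet"))
    x
}

#' Tanimoto coefficient
#'
#' \eqn{S_T(A,B) = |A \wedge B| / |A \vee B|}, the fraction of set bits the
#' two fingerprints share.  When both fingerprints are all-zero the
#' coefficient is defined as 1 (identical strings match themselves), so
#' that a self-query at threshold 1 always returns the record.
#'
#' @param A a single fingerprint: a \code{"0101..."} string or a length-1
#'   \code{\link{FingerprintSet}}.
#' @param B a fingerprint or a \code{FingerprintSet}; with several
#'   fingerprints the coefficient of \code{A} against each is returned.
#' @return Numeric in \[0, 1\] (vector when \code{B} holds several records),
#'   named by the ids of \code{B}.
#'
#' @examples
#' tanimoto("101101", "110100")  # 2/5
#' @export
tanimoto <- function(A, B) {
    A <- .asFp1(A)
    B <- .asFp1(B)
    if (length(A) != 1L) stop("'A' must be a single fingerprint")
    if (A@nBits != B@nBits)
        stop("fingerprints have incompatible lengths (", A@nBits, " vs ",
             B@nBits, ")")
    out <- tanimotoManyC(B@bits, B@popcounts, A@bits[, 1L], A@popcounts[1L],
                         seq_len(length(B)))
    names(out) <- B@ids
    if (length(out) == 1L) unname(out) else out
}

#' Popcount (min/max) upper bound on the Tanimoto coefficient
#'
#' For any fingerprints with \code{a = |A|} and \code{b = |B|} set bits,
#' \eqn{S_T(A,B) \le \min(a,b)/\max(a,b)}.  Returns 1 when both are zero.
#'
#' @param a,b non-negative integer popcounts (vectorised).
#' @return Numeric bound(s) in \[0, 1\].
#'
#' @examples
#' swamidassBound(2, 4)  # 0.5
#' @export
swamidassBound <- function(a, b) {
    if (any(a < 0) || any(b < 0)) stop("popcounts must be non-negative")
    ifelse(pmax(a, b) == 0, 1, pmin(a, b) / pmax(a, b))
}

#' XOR-fold a fingerprint
#'
#' Compresses a fingerprint to \code{width} bits; summary bit \eqn{j}
#' (0-based) is the XOR of all fingerprint bits at positions \eqn{p} with
#' \eqn{p \equiv j \pmod{width}} (positions 0-based).  With
#' \code{width = nBits} the summary equals the fingerprint.
#'
#' @param x a single fingerprint (bit string or length-1
#'   \code{\link{FingerprintSet}}).
#' @param width fold width in bits, between 1 and \code{nBits};
#'   default 128.
#' @return An \code{\link{XorSummary}}.
#' @export
xorFold <- function(x, width = 128L) {
    x <- .asFp1(x)
    if (length(x) != 1L) stop("'x' must be a single fingerprint")
    width <- as.integer(width)
    if (width < 1L || width > x@nBits)
        stop("'width' must be between 1 and nBits")
    m <- xorFoldMatrixC(x@bits, x@nBits, width)
    new("XorSummary", width = width, bits = m[, 1L],
        popcount = fpPopcountsC(m)[1L])
}

setMethod("show", "XorSummary", function(object) {
    cat("XorSummary: width", object@width, "bits, popcount",
        object@popcount, "\n")
    invisible(object)
})

#' XOR-folding upper bound on the Tanimoto coefficient
#'
#' The folded Hamming distance \eqn{|s_A \oplus s_B|} never exceeds the full
#' distance \eqn{|A \oplus B| = a + b - 2|A \wedge B|}, so
#' \eqn{c_{max} = \lfloor (a + b - |s_A \oplus s_B|)/2 \rfloor}, clamped to
#' \eqn{[0, \min(a,b)]}, upper-bounds the intersection and
#' \eqn{c_{max}/(a + b - c_{max})} upper-bounds the coefficient.  At
#' \code{width = nBits} the bound is exact.
#'
#' @param a,b popcounts of the two full fingerprints.
#' @param sa,sb their \code{\link{XorSummary}} objects (equal widths).
#' @return Numeric bound in \[0, 1\]; 1 when \code{a = b = 0}.
#' @export
xorBound <- function(a, b, sa, sb) {
    stopifnot(is(sa, "XorSummary"), is(sb, "XorSummary"))
    if (sa@width != sb@width)
        stop("summaries have different widths (", sa@width, " vs ",
             sb@width, ")")
    d <- sum(as.integer(rawToBits(as.raw(bitwXor(as.integer(sa@bits),
                                                 as.integer(sb@bits))))))
    .xorBoundFromDistance(a, b, d)
}

.xorBoundFromDistance <- function(a, b, d) {
    cmax <- max(0, min((a + b - d) %/% 2, min(a, b)))
    denom <- a + b - cmax
    if (denom == 0) 1 else cmax / denom
}

#' Folded-popcount difference bound
#'
#' A cheaper relaxation of \code{\link{xorBound}}: the folded Hamming
#' distance is itself at least \eqn{||s_A| - |s_B||}, so substituting that
#' difference gives a (weaker) sound bound requiring only two cached
#' integers.
#'
#' @param a,b popcounts of the full fingerprints.
#' @param pa,pb popcounts of their XOR summaries.
#' @return Numeric bound in \[0, 1\]; always \code{>= xorBound} for the same
#'   pair.
#'
#' @examples
#' xorPopcountDiffBound(4, 4, 4, 0)  # 1/3
#' @export
xorPopcountDiffBound <- function(a, b, pa, pb) {
    .xorBoundFromDistance(a, b, abs(pa - pb))
}

#' XOR summary as a character bitstring
#'
#' @param x an \code{\link{XorSummary}}.
#' @return A \code{"0"}/\code{"1"} string of length \code{width}.
#' @export
asXorString <- function(x) {
    stopifnot(is(x, "XorSummary"))
    paste(as.integer(rawToBits(x@bits))[seq_len(x@width)], collapse = "")
}
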