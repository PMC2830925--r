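#' FingerprintSet: a database of binary molecular fingerprints
#'
#' Stores fixed-length bitstrings column-packed into a raw matrix
#' (\code{ceiling(nBits/8)} rows, one column per fingerprint; bit position
#' \eqn{p} of a fingerprint, 1-based, is bit \code{(p-1) \%\% 8} of byte
#' \code{(p-1) \%/\% 8 + 1}, i.e. least-significant bit first as produced by
#' \code{\link[base]{packBits}}).  Popcounts are cached on construction.
#'
#' @slot bits raw matrix of packed fingerprints, one column per record.
#' @slot ids character vector of unique record identifiers.
#' @slot nBits integer, fingerprint length in bits.
#' @slot popcounts integer vector, number of 1-bits per fingerprint.
#'
#' @seealso \code{\link{fingerprintSet}}, \code{\link{readFPS}},
#'   \code{\link{generateFingerprints}}
#' @exportClass FingerprintSet
setClass("FingerprintSet",
    representation(bits = "matrix", ids = "character", nBits = "integer",
                   popcounts = "integer"))

setValidity("FingerprintSet", function(object) {
    msg <- character()
    if (!is.raw(object@bits))
        msg <- c(msg, "'bits' must be a raw matrix")
    nb <- object@nBits
    if (length(nb) != 1L || is.na(nb) || nb < 1L)
        msg <- c(msg, "'nBits' must be a single positive integer")
    if (length(msg)) return(msg)
    if (nrow(object@bits) != (nb + 7L) %/% 8L)
        msg <- c(msg, "'bits' has the wrong number of rows for 'nBits'")
    if (ncol(object@bits) != length(object@ids))
        msg <- c(msg, "'ids' length must equal the number of fingerprints")
    if (anyDuplicated(object@ids))
        msg <- c(msg, "fingerprint ids must be unique")
    if (length(object@popcounts) != length(object@ids))
        msg <- c(msg, "'popcounts' length must equal the number of fingerprints")
    if (length(msg)) return(msg)
    # padding bits beyond nBits must be zero so byte-level popcounts are exact
    pad <- nrow(object@bits) * 8L - nb
    if (pad > 0L && ncol(object@bits) > 0L) {
        mask <- as.raw(bitwAnd(255L, bitwShiftL(255L, 8L - pad)))
        if (any(bitwAnd(as.integer(object@bits[nrow(object@bits), ]),
                        as.integer(mask)) != 0L))
            msg <- c(msg, "padding bits beyond 'nBits' must be zero")
    }
    if (ncol(object@bits) > 0L &&
        !identical(object@popcounts, fpPopcountsC(object@bits)))
        msg <- c(msg, "'popcounts' do not match 'bits'")
    if (length(msg)) msg else TRUE
})

#' XorSummary: an XOR-folded fingerprint
#'
#' A fingerprint compressed to \code{width} bits: summary bit \eqn{j}
#' (0-based) is the parity of all fingerprint bits at positions congruent to
#' \eqn{j} modulo \code{width}.  The Hamming weight of the XOR of two folded
#' summaries lower-bounds the Hamming distance of the full fingerprints,
#' which yields a sound upper bound on their Tanimoto coefficient
#' (\code{\link{xorBound}}).
#'
#' @slot width integer fold width in bits.
#' @slot bits raw vector of packed summary bits.
#' @slot popcount integer, number of 1-bits in the summary.
#'
#' @seealso \code{\link{xorFold}}
#' @exportClass XorSummary
setClass("XorSummary",
    representation(width = "integer", bits = "raw", popcount = "integer"))

setValidity("XorSummary", function(object) {
    if (object@width < 1L) return("'width' must be >= 1")
    if (length(object@bits) != (object@width + 7L) %/% 8L)
        return("'bits' length inconsistent with 'width'")
    TRUE
})

#' FingerprintIndex: a search-ready fingerprint database
#'
#' The result of \code{\link{buildIndex}}: the database plus the
#' strategy-specific acceleration structures (kD-grid bucket coordinates and
#' payloads, popcount buckets for the staged baseline) and the cached
#' XOR-folded summaries used by every strategy's pre-test.
#'
#' @slot db the indexed \code{FingerprintSet}.
#' @slot strategy one of \code{"linear"}, \code{"baldi"}, \code{"list"},
#'   \code{"singlebit"}, \code{"multibit"}.
#' @slot k integer number of grid dimensions (grid strategies).
#' @slot lengths integer fragment lengths (grid strategies).
#' @slot leafLimit integer Multibit leaf limit.
#' @slot xorWidth integer XOR fold width.
#' @slot bucketCoords integer matrix of bucket coordinates, rows sorted
#'   lexicographically.
#' @slot bucketPop integer total popcount per bucket.
#' @slot payloads list of bucket payloads (member indices or flat trees).
#' @slot byPopcount list mapping popcount to member indices (baldi).
#' @slot xorBits raw matrix of folded summaries, one column per record.
#' @slot xorPops integer popcounts of the folded summaries.
#'
#' @seealso \code{\link{buildIndex}}, \code{\link{runQuery}}
#' @exportClass FingerprintIndex
setClass("FingerprintIndex",
    representation(db = "FingerprintSet", strategy = "character",
                   k = "integer", lengths = "integer", leafLimit = "integer",
                   xorWidth = "integer", bucketCoords = "matrix",
                   bucketPop = "integer", payloads = "list",
                   byPopcount = "list", xorBits = "matrix",
                   xorPops = "integer"))

#' SearchResult: hits and instrumentation from one query
#'
#' @slot hits data.frame with columns \code{id} and \code{coefficient},
#'   sorted by descending coefficient, ties by id.
#' @slot stats named list of counters: \code{coefficientsComputed},
#'   \code{nodesVisited}, \code{bucketsVisited}, \code{dbSize}, and for the
#'   staged baseline \code{stageSurvivors} (candidates after each of the
#'   three pruning stages).
#'
#' @seealso \code{\link{runQuery}}, \code{\link{hits}},
#'   \code{\link{searchStats}}
#' @exportClass SearchResult
setClass("SearchResult",
    representation(hits = "data.frame", stats = "list"))
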