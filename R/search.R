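## Running queries against an index and packaging results.

# turn a C++ result list into a SearchResult: sort hits by descending
# coefficient, ties by id, attach counters
.makeResult <- function(res, ids, dbSize, extra = list()) {
    id <- ids[res$idx]
    coef <- res$coef
    ord <- order(-coef, id)
    stats <- c(list(coefficientsComputed = res$coefficientsComputed,
                    exactCoefficients = res$exactCoefficients %||% 0,
                    nodesVisited = res$nodesVisited %||% 0,
                    bucketsVisited = res$bucketsVisited %||% 0,
                    dbSize = dbSize), extra)
    new("SearchResult",
        hits = data.frame(id = id[ord], coefficient = coef[ord],
                          stringsAsFactors = FALSE),
        stats = stats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one threshold query against an index
#'
#' Returns every database fingerprint whose Tanimoto coefficient to the
#' query is at least \code{sMin} (threshold comparisons are inclusive; a
#' record at exactly \code{sMin} is returned).  All strategies produce the
#' identical hit set; the instrumentation counters in
#' \code{\link{searchStats}} show how much work each pruned.
#'
#' @param index a \code{\link{FingerprintIndex}}.
#' @param A the query fingerprint: a bit string or a length-1
#'   \code{\link{FingerprintSet}} (e.g. one record of the database).
#' @param sMin threshold in \[0, 1\]; default 0.9, the usual operating point
#'   for similarity screening.
#' @return A \code{\link{SearchResult}}.
#'
#' @examples
#' db <- fingerprintSet(c(A = "101101", B = "110100"))
#' idx <- buildIndex(db, "multibit", k = 1)
#' hits(runQuery(idx, db["A"], sMin = 0.4))
#' @export
runQuery <- function(index, A, sMin = 0.9) {
    stopifnot(is(index, "FingerprintIndex"))
    if (!is.numeric(sMin) || length(sMin) != 1L || sMin < 0 || sMin > 1)
        stop("'sMin' must be a single value in [0, 1]")
    db <- index@db
    q <- .asQuery(.asFp1(A), db@nBits)
    qRaw <- matrix(q$bits, ncol = 1L)
    qXor <- xorFoldMatrixC(qRaw, db@nBits, index@xorWidth)[, 1L]
    if (length(db) == 0L)
        return(new("SearchResult",
                   hits = data.frame(id = character(0),
                                     coefficient = numeric(0)),
                   stats = list(coefficientsComputed = 0,
                                exactCoefficients = 0, nodesVisited = 0,
                                bucketsVisited = 0, dbSize = 0)))
    res <- switch(index@strategy,
        linear = linearSearchC(db@bits, db@popcounts, index@xorBits,
                               q$bits, qXor, q$pop, sMin),
        baldi = baldiSearchC(index@byPopcount, db@bits, db@popcounts,
                             index@xorBits, index@xorPops, q$bits, qXor,
                             q$pop, popcount(as.raw(qXor)), sMin, db@nBits),
        gridSearchC(index@bucketCoords, index@bucketPop, index@payloads,
                    index@lengths, fragmentPopcounts(.asFp1(A),
                                                     index@lengths),
                    match(index@strategy, .gridStrategies) - 1L,
                    db@bits, db@popcounts, index@xorBits, q$bits, qXor,
                    q$pop, sMin))
    extra <- if (index@strategy == "baldi")
        list(stageSurvivors = res$stageSurvivors) else list()
    .makeResult(res, db@ids, length(db), extra)
}

#' Linear scan of a fingerprint database
#'
#' Convenience wrapper: builds a linear index on the fly and runs one query.
#' Each record gets the XOR-fold pre-test; the exact coefficient is computed
#' only for records the pre-test cannot exclude.
#'
#' @param db a \code{\link{FingerprintSet}}.
#' @param A the query fingerprint.
#' @param sMin threshold in \[0, 1\].
#' @param xorWidth XOR fold width (default 128).
#' @return A \code{\link{SearchResult}}.
#' @export
linearSearch <- function(db, A, sMin = 0.9, xorWidth = 128L) {
    runQuery(buildIndex(db, "linear", xorWidth = xorWidth), A, sMin)
}

#' Hits of a search
#'
#' @param x a \code{\link{SearchResult}}.
#' @return data.frame with columns \code{id} and \code{coefficient}, sorted
#'   by descending coefficient then id.
#' @export
hits <- function(x) {
    stopifnot(is(x, "SearchResult"))
    x@hits
}

#' Instrumentation counters of a search
#'
#' @param x a \code{\link{SearchResult}}.
#' @return Named list: \code{coefficientsComputed} (database records the
#'   strategy's structural pruning could not exclude, i.e. records whose
#'   fingerprint or full-width XOR summary had to be compared against the
#'   query individually -- the implementation-independent cost metric; a
#'   linear scan always scores \code{dbSize}), \code{exactCoefficients}
#'   (records whose exact coefficient was evaluated after the folded-XOR
#'   shortcut), \code{nodesVisited}, \code{bucketsVisited}, \code{dbSize},
#'   and for the staged baseline \code{stageSurvivors} (candidates left
#'   after each of its three pruning stages).
#' @export
searchStats <- function(x) {
    stopifnot(is(x, "SearchResult"))
    x@stats
}

setMethod("show", "SearchResult", function(object) {
    st <- object@stats
    cat("SearchResult:", nrow(object@hits), "hit(s) over",
        st$dbSize, "fingerprints\n")
    cat(sprintf("  coefficients computed: %d (%.3f of database)\n",
                as.integer(st$coefficientsComputed),
                if (st$dbSize > 0) st$coefficientsComputed / st$dbSize
                else 0))
    if (nrow(object@hits)) {
        print(head(object@hits, 10L), row.names = FALSE)
        if (nrow(object@hits) > 10L)
            cat("  ...", nrow(object@hits) - 10L, "more\n")
    }
    invisible(object)
})
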