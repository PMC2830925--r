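## Building search indexes and dumping/rebuilding them as JSON-lines.

.strategies <- c("linear", "baldi", "list", "singlebit", "multibit")
.gridStrategies <- c("list", "singlebit", "multibit")

#' Build a search index over a fingerprint database
#'
#' Prepares one of five interchangeable exact search strategies:
#' \describe{
#'   \item{\code{"linear"}}{instrumented scan of every record with the
#'     XOR-fold pre-test.}
#'   \item{\code{"baldi"}}{staged pruning: popcount (bit-bound) buckets,
#'     then the folded-popcount difference bound, then the full folded-XOR
#'     bound.}
#'   \item{\code{"list"}, \code{"singlebit"}, \code{"multibit"}}{a sparse
#'     kD grid keyed by per-fragment popcounts, whose buckets hold plain
#'     member lists, Singlebit trees or Multibit trees.}
#' }
#' Every strategy returns the identical hit set; they differ only in how
#' much work they prune.  The defaults (\code{k = 1} with Multibit buckets,
#' XOR width 128, leaf limit 6) are the configuration that screens large
#' drug-discovery databases fastest.
#'
#' @param db a \code{\link{FingerprintSet}}.
#' @param strategy one of \code{"multibit"}, \code{"list"},
#'   \code{"singlebit"}, \code{"baldi"}, \code{"linear"}.
#' @param k number of grid dimensions (grid strategies only), typically
#'   1--4.
#' @param leafLimit Multibit leaf limit \eqn{l} (default 6).
#' @param xorWidth XOR fold width in bits (default 128, capped at
#'   \code{nBits}).
#' @return A \code{\link{FingerprintIndex}}.
#'
#' @examples
#' db <- generateFingerprints(200, nBits = 128, seed = 1)
#' idx <- buildIndex(db, "multibit", k = 1)
#' runQuery(idx, db[1], sMin = 0.7)
#' @export
buildIndex <- function(db, strategy = c("multibit", "list", "singlebit",
                                        "baldi", "linear"),
                       k = 1L, leafLimit = 6L, xorWidth = 128L) {
    strategy <- match.arg(strategy)
    stopifnot(is(db, "FingerprintSet"))
    k <- as.integer(k)
    leafLimit <- as.integer(leafLimit)
    if (leafLimit < 1L) stop("'leafLimit' must be >= 1")
    xorWidth <- min(as.integer(xorWidth), db@nBits)
    if (xorWidth < 1L) stop("'xorWidth' must be >= 1")

    xorBits <- xorFoldMatrixC(db@bits, db@nBits, xorWidth)
    xorPops <- fpPopcountsC(xorBits)

    lengths <- integer(0)
    coords <- matrix(0L, 0L, max(k, 1L))
    pop <- integer(0)
    payloads <- list()
    byPopcount <- list()

    if (strategy %in% .gridStrategies) {
        lengths <- fragmentLengths(db@nBits, k)
        skel <- .buildGridSkeleton(db, lengths)
        coords <- skel$coords
        pop <- skel$pop
        payloads <- if (strategy == "list") skel$members
            else lapply(skel$members, function(mem)
                buildTreeC(db@bits, db@nBits, mem,
                           if (strategy == "singlebit") 1L else leafLimit,
                           strategy == "singlebit"))
    } else if (strategy == "baldi") {
        byPopcount <- vector("list", db@nBits + 1L)
        grp <- split(seq_len(length(db)), db@popcounts)
        byPopcount[as.integer(names(grp)) + 1L] <- grp
    }

    new("FingerprintIndex", db = db, strategy = strategy, k = k,
        lengths = lengths, leafLimit = leafLimit, xorWidth = xorWidth,
        bucketCoords = coords, bucketPop = pop, payloads = payloads,
        byPopcount = byPopcount, xorBits = xorBits, xorPops = xorPops)
}

setMethod("show", "FingerprintIndex", function(object) {
    cat("FingerprintIndex (", object@strategy, ")\n", sep = "")
    cat("  database:", length(object@db), "fingerprints,",
        object@db@nBits, "bits\n")
    if (object@strategy %in% .gridStrategies)
        cat("  grid: k =", object@k, "with", nrow(object@bucketCoords),
            "occupied buckets\n")
    cat("  XOR fold width:", object@xorWidth, "bits\n")
    invisible(object)
})

#' Dump an index as a versioned JSON-lines file
#'
#' Writes one header record (format version, bit length, strategy and its
#' parameters) followed by one record per fingerprint (id + hex bits).  Only
#' the database and configuration are stored; \code{\link{loadIndex}}
#' rebuilds the acceleration structures deterministically.
#'
#' @param index a \code{\link{FingerprintIndex}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveIndex <- function(index, path) {
    stopifnot(is(index, "FingerprintIndex"))
    header <- jsonlite::toJSON(list(
        format = "fpscreen-index", version = 1L,
        num_bits = index@db@nBits, strategy = index@strategy, k = index@k,
        leaf_limit = index@leafLimit, xor_width = index@xorWidth),
        auto_unbox = TRUE)
    hex <- apply(index@db@bits, 2L, function(col)
        paste(as.character(col), collapse = ""))
    if (length(index@db) == 0L) hex <- character(0)
    recs <- vapply(seq_along(hex), function(i)
        as.character(jsonlite::toJSON(list(id = index@db@ids[i],
                                           hex = hex[i]),
                                      auto_unbox = TRUE)), character(1))
    writeLines(c(as.character(header), recs), path)
    invisible(path)
}

#' Rebuild an index from a JSON-lines dump
#'
#' @param path a file written by \code{\link{saveIndex}}.
#' @return A \code{\link{FingerprintIndex}} equivalent to the saved one.
#' @export
loadIndex <- function(path) {
    lines <- readLines(path)
    if (length(lines) == 0L) stop("empty index file")
    header <- jsonlite::fromJSON(lines[1L])
    if (!identical(header$format, "fpscreen-index"))
        stop("not an fpscreen index file")
    if (!identical(as.integer(header$version), 1L))
        stop("unsupported index format version ", header$version)
    n <- length(lines) - 1L
    ids <- character(n)
    nBits <- as.integer(header$num_bits)
    nBytes <- (nBits + 7L) %/% 8L
    bits <- matrix(as.raw(0L), nBytes, n)
    for (i in seq_len(n)) {
        rec <- jsonlite::fromJSON(lines[i + 1L])
        ids[i] <- rec$id
        bits[, i] <- .hexToRaw(rec$hex, nBytes, nBits, i + 1L)
    }
    db <- if (n == 0L) fingerprintSet(character(0), nBits = nBits)
          else fingerprintSet(as.vector(bits), ids = ids, nBits = nBits)
    buildIndex(db, strategy = header$strategy, k = as.integer(header$k),
               leafLimit = as.integer(header$leaf_limit),
               xorWidth = as.integer(header$xor_width))
}
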