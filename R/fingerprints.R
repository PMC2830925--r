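## Construction of FingerprintSet objects and low-level bit plumbing.
## Bit order everywhere: position 1 is the least-significant bit of byte 1
## (packBits order), so character "101101" has its first character at
## position 1.

# pack one logical/integer 0-1 vector of length nBits into raw bytes
.packBitVector <- function(v, nBits) {
    pad <- (-length(v)) %% 8L
    packBits(c(as.logical(v), logical(pad)), type = "raw")
}

# character "0101..." strings -> raw matrix (nBytes x n)
.packBitStrings <- function(x, nBits) {
    nBytes <- (nBits + 7L) %/% 8L
    out <- matrix(as.raw(0L), nrow = nBytes, ncol = length(x))
    for (i in seq_along(x)) {
        v <- strsplit(x[[i]], "", fixed = TRUE)[[1L]]
        bad <- !(v %in% c("0", "1"))
        if (any(bad))
            stop("fingerprint strings may only contain '0' and '1'")
        out[, i] <- .packBitVector(v == "1", nBits)
    }
    out
}

# raw matrix column -> logical vector of length nBits
.unpackColumn <- function(bits, i, nBits) {
    as.logical(rawToBits(bits[, i]))[seq_len(nBits)]
}

#' Create a set of binary fingerprints
#'
#' @param x fingerprints, as a character vector of \code{"0"}/\code{"1"}
#'   strings (all the same length), a logical or 0/1 numeric matrix with one
#'   fingerprint per row, or a raw matrix of packed bits with one fingerprint
#'   per column (then \code{nBits} is required).
#' @param ids character identifiers, one per fingerprint; defaults to
#'   \code{names(x)}/\code{rownames(x)} or \code{"fp1"}, \code{"fp2"}, ...
#'   Must be unique.
#' @param nBits fingerprint length in bits; inferred except for raw input.
#'
#' @return A \code{\link{FingerprintSet}}.
#'
#' @examples
#' fps <- fingerprintSet(c(A = "101101", B = "110100"))
#' fpPopcounts(fps)
#' tanimoto(fps[1], fps[2])
#' @export
fingerprintSet <- function(x, ids = NULL, nBits = NULL) {
    if (is.character(x)) {
        if (length(x) > 0L) {
            lens <- unique(nchar(x))
            if (length(lens) > 1L)
                stop("all fingerprints must have the same length")
            inferred <- lens
        } else inferred <- 0L
        if (is.null(nBits)) nBits <- inferred
        if (length(x) > 0L && nBits != inferred)
            stop("'nBits' disagrees with the string lengths")
        if (is.null(ids)) ids <- names(x)
        bits <- .packBitStrings(x, nBits)
    } else if (is.logical(x) || (is.numeric(x) && !is.raw(x))) {
        x <- as.matrix(x)
        if (is.null(nBits)) nBits <- ncol(x)
        if (ncol(x) != nBits) stop("'nBits' disagrees with the matrix width")
        if (is.null(ids)) ids <- rownames(x)
        storage.mode(x) <- "logical"
        nBytes <- (nBits + 7L) %/% 8L
        bits <- matrix(as.raw(0L), nrow = nBytes, ncol = nrow(x))
        for (i in seq_len(nrow(x))) bits[, i] <- .packBitVector(x[i, ], nBits)
    } else if (is.raw(x)) {
        if (is.null(nBits)) stop("'nBits' is required for raw input")
        bits <- matrix(x, nrow = (nBits + 7L) %/% 8L)
    } else stop("unsupported fingerprint input type")
    if (is.null(ids)) ids <- sprintf("fp%d", seq_len(ncol(bits)))
    nBits <- as.integer(nBits)
    if (nBits < 1L && ncol(bits) > 0L)
        stop("'nBits' must be a positive integer")
    if (nBits < 1L) nBits <- 1L  # empty set still needs a valid length
    new("FingerprintSet", bits = bits, ids = as.character(ids),
        nBits = nBits, popcounts = fpPopcountsC(bits))
}

#' @describeIn fingerprintSet number of fingerprints in the set.
#' @param x a \code{FingerprintSet}.
#' @export
setMethod("length", "FingerprintSet", function(x) ncol(x@bits))

#' Fingerprint identifiers
#'
#' @param x a \code{\link{FingerprintSet}}.
#' @return Character vector of record ids.
#' @export
fpIds <- function(x) x@ids

#' Cached popcounts of a fingerprint set
#'
#' @param x a \code{\link{FingerprintSet}}.
#' @return Integer vector: the number of 1-bits of each fingerprint.
#' @export
fpPopcounts <- function(x) x@popcounts

#' Fingerprint length in bits
#'
#' @param x a \code{\link{FingerprintSet}} or \code{\link{FingerprintIndex}}.
#' @return Integer number of bits per fingerprint.
#' @export
nBits <- function(x) {
    if (is(x, "FingerprintIndex")) x@db@nBits else x@nBits
}

#' Fingerprints as character bitstrings
#'
#' @param x a \code{\link{FingerprintSet}}.
#' @return Named character vector of \code{"0"}/\code{"1"} strings.
#' @export
asBitStrings <- function(x) {
    stopifnot(is(x, "FingerprintSet"))
    n <- length(x)
    out <- character(n)
    for (i in seq_len(n))
        out[i] <- paste(as.integer(.unpackColumn(x@bits, i, x@nBits)),
                        collapse = "")
    names(out) <- x@ids
    out
}

#' @export
setMethod("[", "FingerprintSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) {
        i <- match(i, x@ids)
        if (anyNA(i)) stop("unknown fingerprint id")
    }
    idx <- seq_len(length(x))[i]
    new("FingerprintSet", bits = x@bits[, idx, drop = FALSE],
        ids = x@ids[idx], nBits = x@nBits, popcounts = x@popcounts[idx])
})

setMethod("show", "FingerprintSet", function(object) {
    cat("FingerprintSet of", length(object), "fingerprints,",
        object@nBits, "bits\n")
    if (length(object)) {
        pc <- object@popcounts
        cat("  popcount range:", min(pc), "-", max(pc),
            sprintf("(mean %.1f)\n", mean(pc)))
        shown <- head(object@ids, 5L)
        cat("  ids:", paste(shown, collapse = ", "),
            if (length(object) > 5L) "..." else "", "\n")
    }
    invisible(object)
})

# internal: coerce a query given as string / length-1 set into (raw, pop)
.asQuery <- function(A, nBits) {
    if (is.character(A) && length(A) == 1L)
        A <- fingerprintSet(A, ids = "query")
    stopifnot(is(A, "FingerprintSet"))
    if (length(A) != 1L) stop("the query must be a single fingerprint")
    if (A@nBits != nBits)
        stop("query length (", A@nBits, ") does not match the database (",
             nBits, ")")
    list(bits = A@bits[, 1L], pop = A@popcounts[1L], id = A@ids[1L])
}
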