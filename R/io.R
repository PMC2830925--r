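## FPS fingerprint-file I/O.  Line-oriented exchange format: '#'-prefixed
## key=value header lines (num_bits is required), then one record per line:
## hex-encoded fingerprint, a tab, and the identifier.  Hex convention: bytes
## left to right, least-significant bit of each byte is the lowest position.

# decode one hex field to nBytes raw, validating length and padding bits
.hexToRaw <- function(hex, nBytes, nBits, lineNo) {
    if (!grepl("^[0-9a-fA-F]*$", hex))
        stop("line ", lineNo, ": invalid hex fingerprint")
    if (nchar(hex) != 2L * nBytes)
        stop("line ", lineNo, ": expected ", 2L * nBytes,
             " hex digits, got ", nchar(hex))
    bytes <- strtoi(substring(hex, seq(1L, nchar(hex), 2L),
                              seq(2L, nchar(hex), 2L)), 16L)
    pad <- nBytes * 8L - nBits
    if (pad > 0L) {
        mask <- bitwAnd(255L, bitwShiftL(255L, 8L - pad))
        if (bitwAnd(bytes[nBytes], mask) != 0L)
            stop("line ", lineNo,
                 ": bits set beyond num_bits in fingerprint")
    }
    as.raw(bytes)
}

#' Read an FPS fingerprint file
#'
#' @param path path to an FPS file (or connection).  Header lines start with
#'   \code{#}; a \code{#num_bits=<N>} line is required before the first
#'   record.  Each record is \code{<hex fingerprint>\\t<id>}.  Records whose
#'   hex encodes bits beyond \code{num_bits}, malformed hex, and duplicate
#'   ids are rejected with the offending line number.
#' @return A \code{\link{FingerprintSet}}.
#' @seealso \code{\link{writeFPS}}
#' @export
readFPS <- function(path) {
    lines <- readLines(path)
    isHeader <- grepl("^#", lines)
    body <- which(!isHeader & nzchar(lines))
    nBits <- NA_integer_
    for (h in lines[isHeader]) {
        m <- regmatches(h, regexec("^#\\s*num_bits\\s*=\\s*([0-9]+)", h))[[1L]]
        if (length(m) == 2L) nBits <- as.integer(m[2L])
    }
    if (is.na(nBits))
        stop("FPS header is missing a num_bits=<N> line")
    nBytes <- (nBits + 7L) %/% 8L
    n <- length(body)
    bits <- matrix(as.raw(0L), nBytes, n)
    ids <- character(n)
    for (j in seq_len(n)) {
        lineNo <- body[j]
        parts <- strsplit(lines[lineNo], "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 2L || !nzchar(parts[2L]))
            stop("line ", lineNo, ": expected <hex><tab><id>")
        bits[, j] <- .hexToRaw(parts[1L], nBytes, nBits, lineNo)
        ids[j] <- parts[2L]
    }
    if (anyDuplicated(ids)) {
        dup <- which(duplicated(ids))[1L]
        stop("line ", body[dup], ": duplicate id '", ids[dup], "'")
    }
    if (n == 0L) return(fingerprintSet(character(0), nBits = nBits))
    fingerprintSet(as.vector(bits), ids = ids, nBits = nBits)
}

#' Write an FPS fingerprint file
#'
#' @param x a \code{\link{FingerprintSet}}.
#' @param path output file path (or connection).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readFPS}}
#' @export
writeFPS <- function(x, path) {
    stopifnot(is(x, "FingerprintSet"))
    header <- c("#FPS1",
                paste0("#num_bits=", x@nBits),
                "#software=fpscreen")
    recs <- character(length(x))
    for (i in seq_len(length(x)))
        recs[i] <- paste0(paste(as.character(x@bits[, i]), collapse = ""),
                          "\t", x@ids[i])
    writeLines(c(header, recs), path)
    invisible(path)
}
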