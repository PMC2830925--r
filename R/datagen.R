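## Seeded synthetic fingerprint generator.  Emulates the statistical shape
## of 1024-bit structural fingerprints of drug-like molecules: a unimodal
## popcount distribution, plus a clustered mode producing families of
## near-duplicates so that high-threshold queries have non-trivial hit sets.

# run code with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(seed)
        return(code)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
}

# draw one fingerprint: target popcount from N(mean, sd), rounded and
# clamped to [1, nBits - 1], bits placed uniformly without replacement
.drawUniformColumn <- function(nBits, mean, sd) {
    pc <- max(1L, min(nBits - 1L, as.integer(round(rnorm(1L, mean, sd)))))
    v <- logical(nBits)
    v[sample.int(nBits, pc)] <- TRUE
    v
}

#' Generate synthetic binary fingerprints
#'
#' Two modes:
#' \describe{
#'   \item{\code{"uniform"}}{\code{n} independent fingerprints.  Each draws
#'     a target popcount from a normal distribution (rounded, clamped to
#'     \code{[1, nBits - 1]}) and sets that many bits uniformly at random,
#'     giving direct control over the unimodal popcount profile the grid
#'     index keys on.}
#'   \item{\code{"clustered"}}{\code{nSeeds} uniform "parent" fingerprints,
#'     each emitting \code{variantsPerSeed} copies with every bit flipped
#'     independently with probability \code{flipProb}.  Families of
#'     near-duplicates guarantee non-empty hit sets at high thresholds; ids
#'     encode family membership (\code{fam0001.v01}, ...).}
#' }
#' Output is fully reproducible from \code{seed} and leaves the caller's
#' RNG state untouched.
#'
#' @param n number of fingerprints (uniform mode).
#' @param nBits fingerprint length; default 1024, the standard structural
#'   fingerprint size.
#' @param mode \code{"uniform"} or \code{"clustered"}.
#' @param popcountMean,popcountSd popcount distribution parameters; the
#'   defaults (300, 60 at \code{nBits = 1024}, scaled proportionally for
#'   other lengths) give a unimodal occupancy profile over the grid axis
#'   resembling real drug-like databases.
#' @param nSeeds,variantsPerSeed clustered mode: number of families and
#'   members per family; defaults \code{ceiling(n / variantsPerSeed)} and
#'   50.
#' @param flipProb clustered mode per-bit flip probability; the default
#'   0.002 keeps within-family Tanimoto coefficients near 0.99.
#' @param seed integer seed; \code{NULL} uses (and advances) the caller's
#'   RNG state.
#' @return A \code{\link{FingerprintSet}} (\code{nSeeds * variantsPerSeed}
#'   records in clustered mode).
#'
#' @examples
#' db <- generateFingerprints(100, nBits = 256, seed = 1)
#' summary(fpPopcounts(db))
#' @export
generateFingerprints <- function(n, nBits = 1024L,
                                 mode = c("uniform", "clustered"),
                                 popcountMean = round(nBits * 300 / 1024),
                                 popcountSd = nBits * 60 / 1024,
                                 nSeeds = NULL, variantsPerSeed = 50L,
                                 flipProb = 0.002, seed = NULL) {
    mode <- match.arg(mode)
    nBits <- as.integer(nBits)
    if (nBits < 2L) stop("'nBits' must be >= 2")
    if (popcountMean <= 0 || popcountMean >= nBits)
        stop("'popcountMean' must be in (0, nBits)")
    if (popcountSd < 0) stop("'popcountSd' must be >= 0")
    if (flipProb < 0 || flipProb > 1)
        stop("'flipProb' must be in [0, 1]")
    nBytes <- (nBits + 7L) %/% 8L
    .withSeed(seed, {
        if (mode == "uniform") {
            n <- as.integer(n)
            if (is.na(n) || n < 0L) stop("'n' must be a non-negative count")
            bits <- matrix(as.raw(0L), nBytes, n)
            for (i in seq_len(n))
                bits[, i] <- .packBitVector(
                    .drawUniformColumn(nBits, popcountMean, popcountSd),
                    nBits)
            ids <- sprintf("fp%06d", seq_len(n))
            if (n == 0L) return(fingerprintSet(character(0), nBits = nBits))
            fingerprintSet(as.vector(bits), ids = ids, nBits = nBits)
        } else {
            variantsPerSeed <- as.integer(variantsPerSeed)
            if (variantsPerSeed < 1L) stop("'variantsPerSeed' must be >= 1")
            if (is.null(nSeeds)) nSeeds <- ceiling(n / variantsPerSeed)
            nSeeds <- as.integer(nSeeds)
            if (is.na(nSeeds) || nSeeds < 0L) stop("invalid 'nSeeds'")
            total <- nSeeds * variantsPerSeed
            bits <- matrix(as.raw(0L), nBytes, total)
            ids <- character(total)
            col <- 0L
            for (f in seq_len(nSeeds)) {
                parent <- .drawUniformColumn(nBits, popcountMean, popcountSd)
                for (v in seq_len(variantsPerSeed)) {
                    child <- parent
                    nFlips <- rbinom(1L, nBits, flipProb)
                    if (nFlips > 0L) {
                        at <- sample.int(nBits, nFlips)
                        child[at] <- !child[at]
                    }
                    col <- col + 1L
                    bits[, col] <- .packBitVector(child, nBits)
                    ids[col] <- sprintf("fam%04d.v%02d", f, v)
                }
            }
            if (total == 0L) return(fingerprintSet(character(0),
                                                   nBits = nBits))
            fingerprintSet(as.vector(bits), ids = ids, nBits = nBits)
        }
    })
}
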