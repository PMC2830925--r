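## Strategy benchmarking: the implementation-independent performance metric
## is the fraction of the database for which the exact Tanimoto coefficient
## had to be computed.

#' Benchmark search strategies on one database
#'
#' Runs a grid of strategies, grid dimensions and thresholds over a set of
#' query fingerprints and records per-query instrumentation.  By default
#' the first \code{nQueries} fingerprints of the database itself are used
#' as queries, the standard protocol for screening benchmarks.
#'
#' @param db a \code{\link{FingerprintSet}}.
#' @param strategies character subset of
#'   \code{c("linear", "baldi", "list", "singlebit", "multibit")}.
#' @param ks integer grid dimensions to try for the grid strategies
#'   (ignored for \code{"linear"}/\code{"baldi"}, reported as \code{k = 1}).
#' @param thresholds numeric thresholds to try.
#' @param nQueries number of leading database records used as queries when
#'   \code{queries} is not given.
#' @param queries optional \code{FingerprintSet} of query fingerprints.
#' @param leafLimit,xorWidth index parameters, see \code{\link{buildIndex}}.
#' @return data.frame with one row per (strategy, k, threshold, query):
#'   columns \code{strategy}, \code{k}, \code{s_min}, \code{db_size},
#'   \code{query_id}, \code{n_hits}, \code{coefficients_computed},
#'   \code{nodes_visited}, \code{wall_ms}.
#'
#' @examples
#' db <- generateFingerprints(300, nBits = 256, seed = 7)
#' b <- benchStrategies(db, strategies = c("linear", "multibit"),
#'                      ks = 1, thresholds = 0.9, nQueries = 5)
#' aggregate(coefficients_computed / db_size ~ strategy, b, mean)
#' @export
benchStrategies <- function(db,
                            strategies = c("linear", "baldi", "list",
                                           "singlebit", "multibit"),
                            ks = 1:4, thresholds = seq(0.5, 0.9, by = 0.1),
                            nQueries = 100L, queries = NULL,
                            leafLimit = 6L, xorWidth = 128L) {
    stopifnot(is(db, "FingerprintSet"))
    strategies <- match.arg(strategies, several.ok = TRUE)
    if (is.null(queries))
        queries <- db[seq_len(min(nQueries, length(db)))]
    stopifnot(is(queries, "FingerprintSet"))
    rows <- list()
    for (strategy in strategies) {
        kGrid <- if (strategy %in% .gridStrategies) ks else 1L
        for (k in kGrid) {
            index <- buildIndex(db, strategy, k = k, leafLimit = leafLimit,
                                xorWidth = xorWidth)
            for (s in thresholds) {
                for (qi in seq_len(length(queries))) {
                    t0 <- proc.time()[["elapsed"]]
                    res <- runQuery(index, queries[qi], sMin = s)
                    ms <- (proc.time()[["elapsed"]] - t0) * 1000
                    st <- searchStats(res)
                    rows[[length(rows) + 1L]] <- data.frame(
                        strategy = strategy, k = as.integer(k), s_min = s,
                        db_size = length(db),
                        query_id = fpIds(queries)[qi],
                        n_hits = nrow(hits(res)),
                        coefficients_computed = st$coefficientsComputed,
                        nodes_visited = st$nodesVisited,
                        wall_ms = ms, stringsAsFactors = FALSE)
                }
            }
        }
    }
    do.call(rbind, rows)
}
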