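# Pure-R oracles, independent of the package's C++ search paths.

# random bitstrings as character vectors; densities chosen per-call
rndBitStrings <- function(n, nBits, density = 0.3) {
  vapply(seq_len(n), function(i)
    paste(ifelse(runif(nBits) < density, "1", "0"), collapse = ""),
    character(1))
}

# popcount by character inspection
oraclePopcount <- function(s) {
  sum(strsplit(s, "", fixed = TRUE)[[1L]] == "1")
}

# Tanimoto from first principles on character bitstrings
oracleTanimoto <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1L]] == "1"
  vb <- strsplit(b, "", fixed = TRUE)[[1L]] == "1"
  stopifnot(length(va) == length(vb))
  or <- sum(va | vb)
  if (or == 0) 1 else sum(va & vb) / or
}

# the package-wide inclusive threshold predicate (never exclude on a tie)
oraclePasses <- function(numer, denom, s) {
  if (denom <= 0) return(TRUE)
  numer >= s * denom - 1e-12 * denom
}

# brute-force hit list: ids of all database strings with coefficient >= s
oracleSearch <- function(dbStrings, ids, query, s) {
  coef <- vapply(dbStrings, oracleTanimoto, numeric(1), a = query,
                 USE.NAMES = FALSE)
  keep <- coef >= s - 1e-12
  data.frame(id = ids[keep], coefficient = coef[keep],
             stringsAsFactors = FALSE)
}

# sorted the way SearchResult sorts: descending coefficient, ties by id
sortHits <- function(h) {
  h[order(-h$coefficient, h$id), , drop = FALSE]
}

expectSameHits <- function(got, want, tol = 1e-12) {
  want <- sortHits(want)
  expect_identical(got$id, want$id)
  if (nrow(want) > 0)
    expect_lt(max(abs(got$coefficient - want$coefficient)), tol)
  else expect_identical(nrow(got), 0L)
}

# flip each bit of a 0/1 string with probability p (for clustered fixtures)
flipBits <- function(s, p) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  at <- runif(length(v)) < p
  v[at] <- ifelse(v[at] == "1", "0", "1")
  paste(v, collapse = "")
}
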