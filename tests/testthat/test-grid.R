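# kD grid: fragmentation, bucket coordinates, the per-level interval and
# the grid traversal.

test_that("fragmentLengths splits into near-equal fragments, longest first", {
  expect_identical(fragmentLengths(1024, 4), rep(256L, 4))
  expect_identical(fragmentLengths(1024, 3), c(342L, 341L, 341L))
  expect_identical(fragmentLengths(6, 1), 6L)
  expect_identical(fragmentLengths(7, 3), c(3L, 2L, 2L))
  expect_error(fragmentLengths(10, 0), "k")
  expect_error(fragmentLengths(10, 11), "k")
})

test_that("fragmentPopcounts gives coordinates that conserve the popcount", {
  expect_identical(fragmentPopcounts("110100", fragmentLengths(6, 2)),
                   c(2L, 1L))
  expect_identical(fragmentPopcounts(strrep("0", 12), fragmentLengths(12, 3)),
                   c(0L, 0L, 0L))
  expect_error(fragmentPopcounts("1101", c(2L, 3L)), "sum")

  set.seed(31)
  ss <- rndBitStrings(100, 60, 0.4)
  fps <- fingerprintSet(ss)
  for (k in c(1, 3, 5)) {
    fc <- fragmentPopcounts(fps, fragmentLengths(60, k))
    fc <- matrix(fc, nrow = k)
    expect_identical(as.integer(colSums(fc)), fpPopcounts(fps))
  }
})

test_that("grid construction stores every fingerprint at its coordinates", {
  db <- fingerprintSet(c(A = "101101", B = "110100"))
  idx <- buildIndex(db, "list", k = 1)
  expect_identical(as.vector(idx@bucketCoords), c(3L, 4L))  # sorted coords
  # bucket members are the records with that popcount
  members <- lapply(idx@payloads, function(m) fpIds(db)[m])
  expect_identical(members, list("B", "A"))

  set.seed(17)
  big <- fingerprintSet(rndBitStrings(400, 64, 0.3))
  for (k in 1:4) {
    idx <- buildIndex(big, "list", k = k)
    stored <- sort(unlist(idx@payloads))
    expect_identical(stored, seq_len(400L))  # conservation, no duplicates
    # every fingerprint sits at its fragment-popcount coordinates
    fc <- t(matrix(fragmentPopcounts(big, idx@lengths), nrow = k))
    for (b in seq_along(idx@payloads))
      for (m in idx@payloads[[b]])
        expect_identical(fc[m, ], idx@bucketCoords[b, ])
    # all fingerprints in one bucket share their total popcount
    expect_identical(idx@bucketPop, as.integer(rowSums(idx@bucketCoords)))
  }

  empty <- buildIndex(fingerprintSet(character(0), nBits = 16), "list")
  expect_identical(nrow(empty@bucketCoords), 0L)
})

test_that("levelInterval inverts the k = 1 popcount bound", {
  expect_identical(levelInterval(100, 0.9, 1, integer(0), 1024),
                   c(90L, 111L))
  expect_identical(levelInterval(100, 0, 1, integer(0), 1024), c(0L, 1024L))
  # s = 1 with a prefix exactly matching the query pins the coordinate
  expect_identical(levelInterval(c(3L, 5L), 1, 2, 3L, c(8L, 8L)), c(5L, 5L))
  # k = 1 endpoints equal the inverted min/max bound for every popcount
  N <- 256L
  for (s in c(0.5, 0.9)) {
    for (a in c(0L, 1L, 7L, 100L, 200L, 256L)) {
      iv <- levelInterval(a, s, 1, integer(0), N)
      pass <- vapply(0:N, function(n)
        oraclePasses(min(a, n), max(a, n), s), logical(1))
      expect_identical(iv, range(which(pass)) - 1L)
    }
  }
})

test_that("levelInterval equals brute-force enumeration on random configs", {
  set.seed(2024)
  for (rep in 1:200) {
    k <- sample(1:4, 1)
    lengths <- fragmentLengths(64L * k, k)
    aCounts <- vapply(lengths, function(L) sample(0:L, 1), integer(1))
    level <- sample(seq_len(k), 1)
    prefix <- if (level > 1)
      vapply(lengths[seq_len(level - 1)], function(L) sample(0:L, 1),
             integer(1)) else integer(0)
    s <- sample(c(0.5, 0.7, 0.9), 1)
    iv <- levelInterval(aCounts, s, level, prefix, lengths)
    pAnd <- sum(pmin(aCounts[seq_len(level - 1)], prefix))
    pOr <- sum(pmax(aCounts[seq_len(level - 1)], prefix))
    R <- if (level < k) sum(aCounts[(level + 1):k]) else 0
    Ni <- lengths[level]; ai <- aCounts[level]
    pass <- vapply(0:Ni, function(n)
      oraclePasses(pAnd + min(ai, n) + R, pOr + max(ai, n) + R, s),
      logical(1))
    if (!any(pass)) expect_identical(iv, integer(0))
    else {
      qualifying <- which(pass) - 1L
      # the qualifying set must be the contiguous interval returned
      expect_identical(iv, range(qualifying))
      expect_identical(qualifying, iv[1]:iv[2])
    }
  }
})

test_that("grid search never prunes a bucket containing a hit", {
  # exhaustive check on a small grid: every bucket outside the interval
  # chain contains no fingerprint at or above the threshold
  set.seed(9)
  db <- fingerprintSet(rndBitStrings(150, 16, 0.4))
  idx <- buildIndex(db, "list", k = 2)
  q <- db[3]
  aCounts <- fragmentPopcounts(q, idx@lengths)
  for (s in c(0.5, 0.8)) {
    iv1 <- levelInterval(aCounts, s, 1, integer(0), idx@lengths)
    for (b in seq_len(nrow(idx@bucketCoords))) {
      co <- idx@bucketCoords[b, ]
      visited <- length(iv1) > 0 && co[1] >= iv1[1] && co[1] <= iv1[2]
      if (visited) {
        iv2 <- levelInterval(aCounts, s, 2, co[1], idx@lengths)
        visited <- length(iv2) > 0 && co[2] >= iv2[1] && co[2] <= iv2[2]
      }
      if (!visited) {
        coef <- tanimoto(q, db[idx@payloads[[b]]])
        expect_true(all(coef < s))
      }
    }
  }
})

test_that("grid searches reproduce the naive scan for all k and buckets", {
  set.seed(4242)
  for (seedIdx in 1:2) {
    ss <- c(rndBitStrings(150, 128, 0.3),
            unlist(lapply(rndBitStrings(10, 128, 0.3), function(p)
              vapply(1:15, function(i) flipBits(p, 0.01), character(1)))))
    ids <- sprintf("m%04d", seq_along(ss))
    db <- fingerprintSet(ss, ids = ids)
    queries <- c(3, 151, 299)
    for (k in 1:4) {
      for (kind in c("list", "singlebit", "multibit")) {
        idx <- buildIndex(db, kind, k = k)
        for (qi in queries) for (s in c(0.3, 0.7, 0.9, 1.0)) {
          got <- hits(runQuery(idx, db[qi], s))
          expectSameHits(got, oracleSearch(ss, ids, ss[qi], s))
        }
      }
    }
  }
})
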