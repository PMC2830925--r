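# Singlebit and Multibit bucket trees: construction, match-bits, the m_ij
# bookkeeping, the subtree bound and the pruned descent.

test_that("chooseSplitBit balances and breaks ties at the lowest position", {
  expect_identical(chooseSplitBit(c("00", "01", "11")), 1L)
  expect_identical(chooseSplitBit(c("10", "01")), 1L)
  expect_identical(chooseSplitBit(c("10", "11")), 2L)  # only informative bit
})

test_that("chooseSplitBit errors when no informative bit remains", {
  expect_error(chooseSplitBit(c("1010", "1010")), "stop splitting")
  expect_error(chooseSplitBit(c("0011", "0111"), excluded = 2L),
               "stop splitting")
})

test_that("Singlebit trees isolate identical fingerprints in leaves", {
  dup <- fingerprintSet(c(x = "1010", y = "1010"))
  tr <- buildSinglebitTree(dup)
  expect_identical(length(tr$left), 1L)           # single leaf
  expect_identical(sort(leafMembers(tr, 1L)), 1:2)

  two <- fingerprintSet(c(x = "00", y = "11"))
  tr2 <- buildSinglebitTree(two)
  expect_identical(tr2$splitPos[1L], 1L)
  expect_identical(sum(tr2$left == 0L), 2L)       # two leaves

  set.seed(55)
  bucket <- rndBucket(120, 48, 14)
  tr3 <- buildSinglebitTree(bucket)
  ss <- asBitStrings(bucket)
  seen <- integer(0)
  walkTree(tr3, function(node, mb, claimed) {
    if (tr3$left[node] == 0L) {
      mem <- leafMembers(tr3, node)
      expect_identical(length(unique(ss[mem])), 1L)  # leaves identical
      seen <<- c(seen, mem)
    }
  })
  expect_identical(sort(seen), seq_len(120L))       # each fp exactly once
})

test_that("Multibit leaf rule and match-bits follow the construction", {
  # below the leaf limit: no split at all
  five <- rndBucket(5, 32, 10)
  tr <- buildMultibitTree(five, leafLimit = 6)
  expect_identical(length(tr$left), 1L)
  expect_identical(sort(leafMembers(tr, 1L)), 1:5)

  single <- fingerprintSet("10110")
  expect_identical(length(buildMultibitTree(single)$left), 1L)

  # root match-bits of {1100, 1010}: positions 1 (both 1) and 4 (both 0)
  pair <- fingerprintSet(c(p = "1100", q = "1010"))
  tr2 <- buildMultibitTree(pair, leafLimit = 1)
  mb <- matchBits(tr2, 1L)
  expect_identical(mb[order(mb[, "pos"]), "pos"], c(1L, 4L))
  expect_identical(mb[order(mb[, "pos"]), "value"], c(1L, 0L))
})

test_that("match-bits are path-disjoint and consistent with all leaves", {
  set.seed(66)
  bucket <- rndBucket(200, 64, 20)
  ss <- asBitStrings(bucket)
  bits <- do.call(rbind, lapply(strsplit(ss, "", fixed = TRUE), as.integer))
  tr <- buildMultibitTree(bucket, leafLimit = 6)
  walkTree(tr, function(node, mb, claimed) {
    # no position claimed twice along a path
    expect_identical(anyDuplicated(c(claimed, mb[, "pos"])), 0L)
    if (nrow(mb) > 0) {
      below <- subtreeMembers(tr, node)
      for (j in seq_len(nrow(mb)))
        expect_true(all(bits[below, mb[j, "pos"]] == mb[j, "value"]))
    }
    # nodes holding fewer than the leaf limit are leaves
    if (length(subtreeMembers(tr, node)) < 6)
      expect_identical(tr$left[node], 0L)
  })
})

test_that("updateState increments the matching m_ij counters", {
  s <- boundState()
  expect_identical(s, c(m00 = 0L, m01 = 0L, m10 = 0L, m11 = 0L))
  A <- "1010"
  expect_identical(updateState(s, A, cbind(pos = 1L, value = 1L))[["m11"]], 1L)
  expect_identical(updateState(s, A, cbind(pos = 1L, value = 0L))[["m10"]], 1L)
  expect_identical(updateState(s, A, cbind(pos = 2L, value = 1L))[["m01"]], 1L)
  expect_identical(updateState(s, A, cbind(pos = 2L, value = 0L))[["m00"]], 1L)
  expect_identical(updateState(s, A, cbind(pos = integer(0),
                                           value = integer(0))), s)
  expect_error(updateState(s, A, cbind(pos = c(1L, 1L), value = c(1L, 0L))),
               "duplicate")
})

test_that("treeBound reduces to the popcount bound and is sound", {
  st0 <- boundState()
  for (ab in list(c(4, 7), c(10, 10), c(0, 5))) {
    expect_equal(treeBound(st0, ab[1], ab[2]),
                 swamidassBound(ab[1], ab[2]))
  }
  expect_equal(treeBound(c(m00 = 0L, m01 = 0L, m10 = 1L, m11 = 0L), 4, 4),
               0.6)
  expect_equal(treeBound(st0, 0, 0), 1)
  expect_error(treeBound(c(m00 = 0L, m01 = 0L, m10 = 5L, m11 = 0L), 4, 4),
               "inconsistent")
})

test_that("treeBound dominates every consistent fingerprint exhaustively", {
  # N = 8 universe: reveal a random subset of positions of B, build the
  # state against a random A, and check the bound covers every completion
  set.seed(88)
  allB <- vapply(0:255, function(x)
    paste(rev(as.integer(intToBits(x))[1:8]), collapse = ""), character(1))
  for (rep in 1:60) {
    A <- rndBitStrings(1, 8, runif(1, 0.2, 0.8))
    va <- strsplit(A, "", fixed = TRUE)[[1L]] == "1"
    revealed <- sample(1:8, sample(0:8, 1))
    vals <- sample(0:1, length(revealed), replace = TRUE)
    st <- boundState()
    if (length(revealed))
      st <- updateState(st, A, cbind(pos = revealed, value = vals))
    consistent <- allB[vapply(allB, function(b) {
      vb <- strsplit(b, "", fixed = TRUE)[[1L]] == "1"
      all(vb[revealed] == (vals == 1))
    }, logical(1))]
    a <- sum(va)
    for (b in unique(popcount(consistent))) {
      grp <- consistent[popcount(consistent) == b]
      maxCoef <- max(vapply(grp, oracleTanimoto, numeric(1), a = A))
      expect_gte(treeBound(st, a, b) + 1e-12, maxCoef)
    }
  }
})

test_that("tree searches equal a linear scan of the bucket", {
  set.seed(99)
  bucket <- rndBucket(180, 64, 20)
  ss <- asBitStrings(bucket)
  q <- fingerprintSet(flipBits(ss[[1]], 0.03), ids = "q")
  for (s in c(0, 0.4, 0.7, 1.0)) {
    want <- oracleSearch(ss, fpIds(bucket), asBitStrings(q)[[1]], s)
    sb <- treeSearch(buildSinglebitTree(bucket), bucket, q, s)
    mb <- treeSearch(buildMultibitTree(bucket), bucket, q, s)
    expectSameHits(hits(sb), want)
    expectSameHits(hits(mb), want)
    # multibit candidate inspections never exceed the bucket size and at
    # threshold zero nothing can be pruned
    st <- searchStats(mb)
    expect_lte(st$coefficientsComputed, length(bucket))
    if (s == 0)
      expect_identical(st$coefficientsComputed, as.numeric(length(bucket)))
  }
  # a self-exclusive exact query: threshold 1 with the query absent
  probe <- fingerprintSet(paste(rev(strsplit(ss[[1]], "")[[1]]),
                                collapse = ""), ids = "probe")
  if (!asBitStrings(probe) %in% ss) {
    r <- treeSearch(buildMultibitTree(bucket), bucket, probe, 1)
    expect_identical(nrow(hits(r)), 0L)
  }
})

test_that("Multibit with leaf limit 1 matches Singlebit hit sets", {
  set.seed(111)
  bucket <- rndBucket(90, 48, 15)
  q <- fingerprintSet(flipBits(asBitStrings(bucket)[[5]], 0.05), ids = "q")
  sb <- buildSinglebitTree(bucket)
  m1 <- buildMultibitTree(bucket, leafLimit = 1)
  for (s in c(0.3, 0.6, 0.9)) {
    expect_identical(hits(treeSearch(sb, bucket, q, s)),
                     hits(treeSearch(m1, bucket, q, s)))
  }
})

test_that("the subtree bound never increases along a descent", {
  set.seed(123)
  bucket <- rndBucket(150, 64, 20)
  tr <- buildMultibitTree(bucket)
  A <- rndBitStrings(1, 64, 0.3)
  a <- popcount(A); b <- 20
  boundsOk <- TRUE
  recurse <- function(node, st, parentBound) {
    st <- updateState(st, A, matchBits(tr, node))
    bd <- tryCatch(treeBound(st, a, b), error = function(e) 0)
    if (bd > parentBound + 1e-12) boundsOk <<- FALSE
    if (tr$left[node] != 0L) {
      recurse(tr$left[node], st, bd)
      recurse(tr$right[node], st, bd)
    }
  }
  recurse(1L, boundState(), 1)
  expect_true(boundsOk)
})

test_that("treeSearch enforces the equal-popcount bucket contract", {
  mixed <- fingerprintSet(c(A = "101101", B = "110100"))
  expect_error(treeSearch(buildMultibitTree(mixed), mixed, mixed[1], 0.4),
               "equal popcount")
})
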