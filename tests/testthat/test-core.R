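# Bitstring primitives, the Tanimoto coefficient, and the closed-form
# pruning bounds.

test_that("popcount counts 1-bits across input types", {
  expect_identical(popcount("101101"), 4L)
  expect_identical(popcount(strrep("0", 64)), 0L)
  expect_identical(popcount(strrep("1", 64)), 64L)
  expect_identical(popcount(c("11", "00", "10")), c(2L, 0L, 1L))
  expect_identical(popcount(packBits(c(rep(TRUE, 5), rep(FALSE, 3)),
                                     "raw")), 5L)
  fps <- fingerprintSet(c(a = "101101", b = "000000"))
  expect_identical(popcount(fps), c(4L, 0L))
  expect_error(popcount("10a1"), "only contain")
})

test_that("tanimoto matches hand computation and the brute-force oracle", {
  expect_equal(tanimoto("101101", "110100"), 0.4)
  expect_equal(tanimoto("110100", "101101"), 0.4)  # symmetric
  expect_equal(tanimoto("101101", "101101"), 1)
  expect_equal(tanimoto("1100", "0011"), 0)
  expect_equal(tanimoto("0000", "0000"), 1)  # all-zero convention
  expect_error(tanimoto("1100", "110011"), "incompatible length")

  set.seed(101)
  ss <- rndBitStrings(40, 96, density = 0.25)
  fps <- fingerprintSet(ss, ids = sprintf("s%02d", seq_along(ss)))
  for (i in c(1, 7, 23)) {
    got <- tanimoto(fps[i], fps)
    want <- vapply(ss, oracleTanimoto, numeric(1), a = ss[i],
                   USE.NAMES = FALSE)
    expect_equal(unname(got), want, tolerance = 1e-14)
  }
})

test_that("tanimoto agrees with an independent cheminformatics library", {
  skip_if_not_installed("ChemmineR")
  set.seed(5)
  m <- matrix(runif(30 * 512) < 0.3, nrow = 30)
  rownames(m) <- sprintf("cmp%02d", 1:30)
  fps <- fingerprintSet(m)
  fpset <- methods::as(m * 1, "FPset")
  for (i in c(1, 12, 30)) {
    ours <- tanimoto(fps[i], fps)
    theirs <- ChemmineR::fpSim(fpset[i], fpset, method = "Tanimoto",
                               sorted = FALSE, top = "all", addone = 0)
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
  }
})

test_that("swamidassBound is min/max with the zero convention", {
  expect_equal(swamidassBound(2, 4), 0.5)
  expect_equal(swamidassBound(7, 7), 1)
  expect_equal(swamidassBound(0, 0), 1)
  expect_equal(swamidassBound(0, 3), 0)
  expect_error(swamidassBound(-1, 2), "non-negative")
})

test_that("xorFold implements modular parity folding", {
  expect_identical(asXorString(xorFold("1000", 2)), "10")
  expect_identical(asXorString(xorFold("1111", 2)), "00")
  s <- "10110100"
  expect_identical(asXorString(xorFold(s, 8)), s)  # w = N is the identity
  expect_error(xorFold(s, 0), "width")
  expect_error(xorFold(s, 9), "width")
})

test_that("xorBound is exact at full width and 1 for identical inputs", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(c(16L, 40L, 64L), 1)
    a <- rndBitStrings(1, n, runif(1, 0.1, 0.6))
    b <- rndBitStrings(1, n, runif(1, 0.1, 0.6))
    bd <- xorBound(oraclePopcount(a), oraclePopcount(b),
                   xorFold(a, n), xorFold(b, n))
    expect_equal(bd, oracleTanimoto(a, b), tolerance = 1e-12)
  }
  a <- "110010"
  expect_equal(xorBound(3, 3, xorFold(a, 3), xorFold(a, 3)), 1)
  expect_error(xorBound(3, 3, xorFold(a, 3), xorFold(a, 2)),
               "different widths")
})

test_that("xorPopcountDiffBound has the stated closed forms", {
  # pa = pb collapses to c_max = floor((a+b)/2) clamped at min(a, b)
  expect_equal(xorPopcountDiffBound(3, 5, 2, 2), 3 / 5)
  expect_equal(xorPopcountDiffBound(4, 4, 1, 1), 1)
  expect_equal(xorPopcountDiffBound(4, 4, 4, 0), 1 / 3)
})

test_that("the bound chain is sound on 10^4 random pairs", {
  # swamidass >= tanimoto and diff-bound >= xor-bound >= tanimoto,
  # at both a short and the standard fingerprint length
  for (cfg in list(list(n = 64L, w = 16L, reps = 5000L),
                   list(n = 1024L, w = 128L, reps = 5000L))) {
    set.seed(cfg$n)
    A <- fingerprintSet(rndBitStrings(cfg$reps, cfg$n, 0.3),
                        ids = sprintf("a%05d", seq_len(cfg$reps)))
    B <- fingerprintSet(rndBitStrings(cfg$reps, cfg$n, 0.3),
                        ids = sprintf("b%05d", seq_len(cfg$reps)))
    pa <- fpPopcounts(A); pb <- fpPopcounts(B)
    coef <- vapply(seq_len(cfg$reps),
                   function(i) tanimoto(A[i], B[i]), numeric(1))
    sw <- swamidassBound(pa, pb)
    xb <- numeric(cfg$reps); xd <- numeric(cfg$reps)
    for (i in seq_len(cfg$reps)) {
      sa <- xorFold(A[i], cfg$w); sb <- xorFold(B[i], cfg$w)
      xb[i] <- xorBound(pa[i], pb[i], sa, sb)
      xd[i] <- xorPopcountDiffBound(pa[i], pb[i], popcount(sa),
                                    popcount(sb))
    }
    expect_true(all(sw >= coef - 1e-12))
    expect_true(all(xd >= xb - 1e-12))
    expect_true(all(xb >= coef - 1e-12))
  }
})
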