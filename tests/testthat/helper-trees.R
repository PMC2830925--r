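# Helpers for inspecting flat bucket trees in tests.

# equal-popcount random bucket: every member has `pop` bits set
rndBucket <- function(n, nBits, pop) {
  ss <- vapply(seq_len(n), function(i) {
    v <- rep("0", nBits); v[sample.int(nBits, pop)] <- "1"
    paste(v, collapse = "")
  }, character(1))
  fingerprintSet(ss, ids = sprintf("b%03d", seq_len(n)))
}

# walk every root-to-node path, applying fun(node, matchBits, claimed)
walkTree <- function(tree, fun, node = 1L, claimed = integer(0)) {
  mb <- matchBits(tree, node)
  fun(node, mb, claimed)
  claimed <- c(claimed, mb[, "pos"])
  if (tree$left[node] != 0L) {
    walkTree(tree, fun, tree$left[node], claimed)
    walkTree(tree, fun, tree$right[node], claimed)
  }
}

leafMembers <- function(tree, node) {
  idx <- seq_len(tree$leafOff[node + 1L] - tree$leafOff[node]) +
    tree$leafOff[node]
  tree$leafItems[idx]
}

# all leaf items below a node
subtreeMembers <- function(tree, node) {
  if (tree$left[node] == 0L) return(leafMembers(tree, node))
  c(subtreeMembers(tree, tree$left[node]),
    subtreeMembers(tree, tree$right[node]))
}
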