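---
title: "Exact threshold screening of binary fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact threshold screening of binary fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpscreen)
```

## The screening problem

A molecular fingerprint is a bitstring of fixed length $N$ summarising a
molecule's structure, built so that structurally similar molecules get
similar fingerprints. Writing $|A|$ for the number of set bits
(popcount), similarity is measured by the Tanimoto coefficient

$$S_T(A, B) \;=\; \frac{|A \wedge B|}{|A \vee B|}
           \;=\; \frac{c}{|A| + |B| - c}, \qquad c = |A \wedge B|,$$

and the screening problem is: given a query $A$ and a threshold
$S_{\min}$, return *every* database fingerprint $B$ with
$S_T(A,B) \ge S_{\min}$. `fpscreen` solves this exactly. Speed comes
entirely from *sound upper bounds*: a cheap overestimate of $S_T$ for a
whole group of fingerprints. If the bound falls below $S_{\min}$ the
group is skipped; because the bound never underestimates, no hit can be
lost. Every strategy in the package is therefore interchangeable — they
return identical hit sets and differ only in how much of the database
they must inspect.

Two conventions used uniformly:

* **Zero versus zero.** $S_T(\vec0, \vec0) := 1$, and every bound also
  returns 1 in this case. Identical strings match themselves, so a
  self-query at $S_{\min} = 1$ always returns its record.
* **Inclusive thresholds with a guarded comparison.** Hits at exactly
  $S_{\min}$ are returned. All bound-versus-threshold tests compare an
  integer numerator/denominator pair against the floating-point
  threshold as `numer >= s*denom - 1e-12*denom`: the relative guard acts
  only in the sound direction, so a tie is never pruned. Since exact
  coefficients are rationals with denominators at most $2N$, the guard
  is far smaller than any genuine gap and can only rescue
  floating-point boundary cases, never admit a wrong hit — strategies
  all use the same predicate, which is why their hit sets agree bit for
  bit.

## The bounds

**Popcount (min/max) bound.** For any $A, B$:
$S_T(A,B) \le \min(|A|,|B|) / \max(|A|,|B|)$. Inverting it at
$S_{\min}$ shows only database popcounts in
$[\,\lceil S_{\min}|A|\rceil,\ \lfloor |A|/S_{\min}\rfloor\,]$ can ever
qualify (e.g. $|A| = 100$, $S_{\min} = 0.9$ gives $[90, 111]$; see
`levelInterval()`).

**kD grid.** Split every fingerprint into $k$ near-equal fragments
$B = B_1 \cdot B_2 \cdots B_k$ and store it at coordinates
$n_i = |B_i|$ in a sparse grid (`buildIndex(..., k = k)`). While
descending the grid with levels $1..i{-}1$ fixed, the coefficient of
anything below is at most

$$\frac{P_\wedge + \min(a_i, n_i) + R}
       {P_\vee + \max(a_i, n_i) + R},
\qquad
\begin{aligned}
P_\wedge &= \textstyle\sum_{j<i} \min(a_j, n_j), &
P_\vee &= \textstyle\sum_{j<i} \max(a_j, n_j), \\
R &= \textstyle\sum_{j>i} a_j, &
a_j &= |A_j|,
\end{aligned}$$

because the unseen deeper fragments can at best contribute $a_j$ to both
the intersection and the union. The bound is unimodal in $n_i$ (peak at
$n_i = a_i$), so the qualifying coordinates form an integer interval.
`levelInterval()` computes the endpoints in closed form by setting the
bound equal to $S_{\min}$ and then corrects each endpoint by $\pm 1$
against the exact predicate — soundness over elegance; the closed form
is only a starting guess and float rounding can never exclude a
qualifying bucket. At $k = 1$ the grid is exactly the popcount bucket
list; at $k = N$ it would degenerate into a binary trie over the
fingerprint (not built here, as a pure trie carries no popcount
information within buckets).

**XOR folding.** `xorFold()` compresses a fingerprint to $w$ bits;
summary bit $j$ is the parity of all positions $p \equiv j \pmod w$
(0-based). Any fixed partition of positions yields a sound fold; the
modular mapping is the simplest and is cache-friendly. Folding can only
cancel differences, so
$|s_A \oplus s_B| \le |A \oplus B| = |A| + |B| - 2c$, giving
$c \le c_{\max} = \lfloor (|A|+|B|-|s_A \oplus s_B|)/2 \rfloor$ (clamped
to $[0, \min(|A|,|B|)]$) and the bound
$c_{\max}/(|A|+|B|-c_{\max})$ (`xorBound()`). At $w = N$ the algebra
collapses and the bound *equals* $S_T$. Replacing
$|s_A \oplus s_B|$ by its own lower bound
$\bigl||s_A| - |s_B|\bigr|$ gives the still-cheaper
`xorPopcountDiffBound()`, which needs only two cached integers. The
chain `diffBound >= xorBound >= tanimoto` holds pairwise and is
property-tested on tens of thousands of seeded random pairs.

**Subtree (tree) bound.** Within one grid bucket all fingerprints share
$|B|$ (their coordinates sum to it), which the tree bound exploits. Let
$M_{ij}$ count positions where the query has bit $i$ and a database
fingerprint has bit $j$. A root-to-node path reveals positions with
known values for every fingerprint below, accumulating lower limits
$m_{ij} \le M_{ij}$. Then $c = M_{11} \le \min(|A| - m_{10},\ |B| -
m_{01})$ and

$$S_T(A,B) \;\le\; \frac{c}{|A| + |B| - c}$$

for every $B$ in the subtree (`treeBound()`). With no information
($m_{10} = m_{01} = 0$) this is exactly the popcount bound, and it can
only tighten along a descent since the $m_{ij}$ never decrease. All four
counters are tracked (`boundState()`, `updateState()`) even though only
$m_{10}$ and $m_{01}$ enter the bound — the extra two cost nothing and
make descents easy to audit.

## The tree structures

**Singlebit tree** (`buildSinglebitTree()`): each node picks one bit
position; zeros go left, ones go right, until all fingerprints in a node
are identical (duplicates stay together in one leaf). Each branch taken
contributes one $(p, v)$ observation to the $m_{ij}$ state. A balanced
tree over even 40,000 fingerprints is only ~15 levels deep, so a
descent learns at most ~15 of 1024 bits — too little to prune well,
which motivates:

**Multibit tree** (`buildMultibitTree()`): the same recursive split, but
every internal node stores its *match-bits* — all positions not claimed
by an ancestor on which *all* fingerprints below agree, with the shared
value. A visited node can reveal many positions at once (in clustered
data, the node covering one family of near-duplicates reveals most of
the fingerprint), so the state tightens much faster. Splitting stops
when a node holds fewer than $l$ fingerprints (leaf limit, default
$l = 6$: it roughly halves memory against $l = 1$ with no practical
pruning loss) or when no informative unclaimed bit remains.

Construction choices, fixed for determinism where the mathematics is
indifferent:

* split bit: the position whose 1-count is closest to half the node
  (aiming at balance), ties to the lowest position;
* fragments when $k \nmid N$: longer fragments first;
* leaf payloads keep insertion order; descents visit the zero child
  first; grid levels ascend in index order.

None of these affect the hit set (property-tested); they make trees and
outputs reproducible. With $l = 1$ the Multibit tree prunes at least as
well as the Singlebit tree and returns the same hits.

## Search strategies and the cost metric

`buildIndex()` prepares one of five strategies; `runQuery()` executes a
query:

* `linear` — scan everything;
* `baldi` — staged pruning: popcount buckets via the inverted min/max
  bound, then the folded-popcount difference bound, then the full
  folded-XOR bound, then exact coefficients;
* `list` / `singlebit` / `multibit` — the kD grid with plain-list or
  tree buckets.

Every strategy additionally applies the folded-XOR comparison
immediately before each exact coefficient (width 128 by default — a
good trade-off between pre-test cost and discrimination at standard
fingerprint lengths; `xorWidth = nBits` would make the pre-test exact
but as expensive as the coefficient itself).

`searchStats()` reports an implementation-independent cost metric:
`coefficientsComputed` counts the database records the strategy's
*structural* pruning (buckets, intervals, tree bounds, the staged
popcount/difference filters) could not exclude — records that had to be
inspected individually, whether by the folded-XOR comparison or the
exact coefficient. The per-record XOR shortcut does not reduce this
metric (a linear scan always scores `dbSize`); it only converts exact
evaluations into cheaper folded ones, reported separately as
`exactCoefficients`. Counting only exact evaluations would make every
strategy look identical whenever the folded pre-test dominates, hiding
precisely the structural differences the metric exists to compare.

## Synthetic data: what it emulates and what it does not

Real screening databases of drug-like molecules have a unimodal
popcount distribution over 1024-bit structural fingerprints, leaving
most popcount buckets empty. `generateFingerprints()` reproduces that
shape directly: each fingerprint draws a target popcount from
$\mathcal N(\mu, \sigma)$ (rounded, clamped to $[1, N-1]$; defaults
$\mu = 300$, $\sigma = 60$ at $N = 1024$, scaled proportionally for
other lengths — plausible-looking values chosen once for this package,
not measurements of any particular database) and places that many bits
uniformly. Normal-then-place was chosen over per-bit Bernoulli because
the grid keys on popcounts, so the popcount profile is the property
worth controlling directly.

The clustered mode adds what uniform sampling cannot: hits. It emits
families of `variantsPerSeed` copies of a parent (default 50), each bit
flipped independently with probability `flipProb` (default 0.002, which
keeps within-family coefficients near 0.986 ± 0.007 — comfortably above
the usual 0.9 operating point, while unrelated pairs sit far below;
measured bands are frozen as regression tests). Ids encode family
membership.

What the generator does **not** emulate: the correlated, structured bit
patterns of real substructure fingerprints (shared scaffolds switch
whole groups of bits together), heavy-tailed family-size distributions,
or any particular database's popcount parameters. Consequences for
interpreting results: exactness claims transfer to real data unchanged
(they are proven by the soundness of the bounds, not by the data), but
the measured *pruning fractions* are indicative only — real data's bit
correlations tend to make Multibit match-bits even more informative, so
synthetic numbers are, if anything, conservative about the tree's
relative advantage, and absolute fractions should not be quoted as
expectations for any specific database.

## The benchmark study point

The shipped acceptance computation uses a clustered database of
$n = 100{,}000$ fingerprints of $N = 1024$ bits (2,000 families × 50
variants), $S_{\min} = 0.9$, and the first 100 records of the database
as queries — an in-database query protocol standard for screening
benchmarks. On one CPU this runs in well under a minute per strategy;
the exactness sweep uses databases of 1,000 fingerprints at
$N \in \{256, 1024\}$ across seeds, modes, all five strategies and
$k \in 1..4$, sizes chosen so the full suite completes in minutes while
still exercising byte-boundary and clustering behaviour. The observed
ordering of mean inspected fractions — multibit ($k{=}1$) far below the
$k{=}3$ list grid, below the staged baseline, below the linear scan's
1.0 — is reproduced by `scripts/acceptance.R` and asserted only
qualitatively: absolute wall-clock times and memory are
hardware-dependent and deliberately out of scope.

## Numerical and degenerate cases

* Fingerprint bits are packed least-significant-bit-first per byte
  (`packBits()` order); FPS hex follows the same convention, and bits
  set beyond `num_bits` in a hex record are rejected. Any fixed
  convention is algorithm-neutral; this one round-trips through base R.
* Empty databases build valid indexes and return empty results; all-zero
  fingerprints follow the $S_T = 1$ self-match convention throughout.
* Interval endpoints are always verified against the exact guarded
  predicate, so the closed forms can be freely refactored without
  soundness risk.
* `treeSearch()` requires an equal-popcount bucket (the bound needs
  $|B|$); mixed-popcount collections are handled by the grid, which
  never builds such a bucket.

## Known limitations

* Only the Tanimoto coefficient; Dice/Tversky and approximate search are
  out of scope.
* Multibit trees store per-node match-bit lists and are the most
  memory-hungry index here (mirroring their known trade-off); the
  $k = N$ trie variant and clustering-based tree construction
  (e.g. neighbour-joining) are noted alternatives, not implemented.
* The package generates or reads fingerprints; computing fingerprints
  from molecular structure files is out of scope.
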