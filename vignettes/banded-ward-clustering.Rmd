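---
title: "Banded Ward clustering: methods and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Banded Ward clustering: methods and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandclust)
```

# Why adjacency-constrained clustering

Loci along a chromosome are *ordered*, and the biological units one wants
to recover from locus-level similarity — linkage-disequilibrium (LD)
blocks from SNP panels, topologically associating domains (TADs) from
Hi-C contact maps — are *contiguous* runs of loci. Imposing that
constraint during clustering does two things: it makes the output directly
interpretable as a segmentation of the chromosome, and it removes the
quadratic search over cluster pairs, because only *adjacent* clusters can
ever fuse. `bandclust` implements agglomerative clustering with Ward's
linkage under this adjacency constraint, on similarities restricted to a
diagonal band.

# The linkage, in similarity form

A cluster is a half-open interval $C = [i, j)$ of the $p$ ordered objects.
With $S(C) = \sum_{(a,b)\in C^2} s_{ab}$ the similarity mass of $C$,
Ward's linkage between adjacent clusters $C = [i, m)$ and $C' = [m, j)$ is

$$\delta(C, C') \;=\; \frac{S(C)}{|C|} + \frac{S(C')}{|C'|} -
\frac{S(C \cup C')}{|C \cup C'|}.$$

When $s_{ab} = \langle x_a, x_b \rangle$ for points $x_a$ in some
(implicit) Euclidean space, expanding the inner products shows that
$\delta$ equals the classical Ward criterion: the increase in
within-cluster error sum of squares,
$\frac{|C||C'|}{|C|+|C'|}\,\lVert \bar x_C - \bar x_{C'} \rVert^2$. So on
kernel or inner-product data the algorithm *is* Ward's method, merely
reparameterised. The test suite checks this identity to $10^{-8}$ against
an independent ESS computation.

Two algebraic facts extend the method beyond positive-semidefinite
similarities, and both are verified exhaustively in the tests:

- **Offset invariance.** Adding $f(a) + f(b)$ to every $s_{ab}$ leaves
  every linkage unchanged (the three mass terms cancel exactly). This is
  why `bandFromDissimilarity()` can convert a dissimilarity $d$ through
  $s = (\max d^2 - d^2)/2$ and reproduce Euclidean Ward exactly, and why
  adding a constant to the whole matrix changes nothing.
- **Diagonal shift.** Adding $\lambda$ to every *diagonal* entry adds
  exactly $\lambda$ to every linkage, for any similarity. Consequently a
  non-PSD similarity such as $r^2$ needs no preprocessing: the merge
  *order* produced on the raw matrix is identical to the order after any
  "PSD-restoring" shift. `bandClust()` therefore clusters raw
  similarities and simply warns when negative heights occur
  (`shiftDiagonal()` is available when nonnegative heights are wanted for
  display).

One caveat follows from the constraint itself: adjacency-constrained Ward
is *not* guaranteed monotone. Reducibility, which guarantees
nondecreasing heights in unconstrained Ward, fails when a cluster may
only fuse with its two neighbours, so height reversals can occur even on
Euclidean data. `isMonotone()` reports this, the `Dendrogram` show method
flags it, and `dendrogramToNewick()` clamps negative branch lengths (with
a warning) only at export time — the stored heights are never altered.

# The two O(p h) primitives

## Pencil cumulative sums

The band stores $s_{i,i+d}$ for $0 \le d < h$ as a $p \times h$ matrix.
The *forward pencil* $P(r, l)$ is the sum of all $s_{ab}$ with
$a, b \le r$ and $|a - b| < l$; the *backward pencil* $\bar P(r, l)$ is
its mirror from the other end. Both tables fill in a single pass: row $r$
contributes $s_{rr} + 2\sum_{d=1}^{l-1} s_{r-d,r}$ (built incrementally in
$l$), and a cumulative sum over $r$ finishes the job, so construction is
$O(ph)$ with at most $2ph$ stored values. For any interval of length
$k = j - i$, taking $l = \min(h, k)$ gives

$$S([i,j)) = P(j-1, l) + \bar P(i, l) - P(p, l),$$

because the two pencils double-count exactly the full-matrix pencil while
every excluded pair lies more than $l$ off the diagonal. Any Ward linkage
is then three $O(1)$ lookups. The identity is exact, not approximate —
the only approximation in the whole method is the user's choice to
truncate the similarity at bandwidth $h$ in the first place; within-band
arithmetic is plain floating point with cumulative sums accumulated in
extended precision. The construction is implemented in C++ for speed, and
every table entry and interval sum is compared against brute-force double
summation in the tests.

## Fusion heap with lazy invalidation

The $p - 1$ candidate fusions between adjacent clusters live in a binary
min-heap keyed by `(linkage, left boundary)`; the secondary key makes tie
resolution deterministic — among equal linkages the *leftmost* candidate
merges first, so exchangeable inputs cascade left to right. A merge
invalidates at most two neighbouring candidates; rather than deleting them
from the middle of the heap, a side array flags them and they are
discarded if and when they surface at the root ("lazy invalidation").
Each of the $p - 1$ steps inserts at most two fresh candidates and
invalidates at most two, so lazy discards are bounded by $2p$ across a
run — an invariant asserted on every clustering the test suite performs.
Total engine cost is $O(p \log p)$ heap operations on top of the $O(ph)$
precomputation. The engine is written in C++; a quadratic R reference
implementation (`naiveClust()`) recomputing every candidate from dense
partial sums at every step is shipped alongside, and the central
correctness property — merge-for-merge equivalence of the two on random
mixed-sign instances — is tested on hundreds of seeded instances.

# Choosing the bandwidth and the number of clusters

**Bandwidth.** $h$ trades fidelity for cost; similarity decays with
genomic distance, so there is usually a point beyond which enlarging $h$
changes nothing. `selectBandwidth()` operationalises this: it walks an
increasing schedule of bandwidths, clusters at each, and returns the
first $h$ whose dendrogram agrees with the next larger one (agreement
measured by `firstDifferenceIndex()`, the fraction of initial merges
shared before the first discrepancy; the threshold `stability = 1`
demands exact agreement). When the underlying similarity truly is banded
at $h_0$, runs at any $h \ge h_0$ are bit-identical — the extra stored
values are exact zeros that cancel from every pencil — which the tests
assert as `identical()`, not merely near-equality.

**Number of clusters.** Two standard rules act on the root decreases
$d_k$ (heights read from the root down):

- *Broken stick* (`selectBrokenStick()`): compare each $d_k$ with its
  expectation $b_k = \frac{T}{p-1}\sum_{i=k}^{p-1} 1/i$ under a uniform
  random partition of the total $T = \sum d_k$; stop at the first
  $k$ with $d_k \le b_k$. Parameter-free and fast; sensible for a first
  look.
- *Slope heuristic* (`selectSlopeHeuristic()`): treat the clustering
  contrast $C(K) = T - \sum_{k<K} d_k$ as a penalised model-selection
  problem with penalty shape $\mathrm{pen}(K) = \log\binom{p-1}{K-1}$
  (the log of the number of contiguous partitions into $K$ blocks),
  estimate the slope $\hat\kappa$ of $C$ against pen on
  $K \in [\lceil K_{\max}/2 \rceil, K_{\max}]$ by a Theil–Sen median
  slope, and minimise $C(K) + 2\hat\kappa\,\mathrm{pen}(K)$. Two choices
  here are deliberate: the *logarithm* of the binomial shape is used
  because the raw binomial overflows double precision for genomic $p$
  while preserving the ordering and curvature the slope fit needs, and
  the robust median-based fit avoids sensitivity to the exact fitting
  range. The default $K_{\max} = \min(p, 20)$ only caps the search range;
  on planted data the selection is stable when $K_{\max}$ is varied (a
  property the tests check at $K_{\max} = 50$ vs $100$).

Both return a `ClusterSelection` carrying the full per-$K$ trace, so the
decision can be inspected rather than trusted.

# The synthetic generators, and how realistic they are

The generators exist to provide seeded, assumption-transparent inputs
whose ground truth is known; defaults are the conditions under which the
package's own recovery claims are computed.

- `simBlockSimilarity()`: within-block similarity `within = 1`,
  between-block `between = 0.1`, additive Gaussian noise `noise = 0.1`,
  truncated to the band. This is the idealised "blocks plus noise" regime;
  real similarities decay smoothly rather than stepping, so treat it as a
  best case for contrast.
- `simGenotypes()`: haplotypes are built by a first-order copying chain —
  each SNP copies its left neighbour's allele with probability `rho = 0.9`
  and is redrawn at allele frequency `maf = 0.25` otherwise, with the
  chain restarting at block boundaries; dosages are sums of two
  haplotypes, with optional missingness. This reproduces the two features
  that matter for LD-based segmentation (within-block decay of $r^2$ with
  distance and independence across boundaries) but not recombination
  hotspot fine structure or population stratification.
- `simContactMap()`: Poisson counts with mean
  $\mathrm{base}\,(1+d)^{-\alpha}$ at bin distance $d$, multiplied by
  `boost = 5` within planted TADs — a power-law decay plus block
  enrichment, the standard first-order model of intra-chromosomal
  contacts; it omits coverage biases and hierarchical (nested) TADs.

All generators draw from private RNG streams derived from their `seed`
argument, so they are bit-reproducible and never perturb the caller's
random state.

# Adapters and I/O conventions

`ldBand()` computes $r^2$ as the squared Pearson correlation of dosages,
pairwise-complete over missing genotypes, one band diagonal at a time
(never forming the $p \times p$ matrix). Monomorphic SNPs have undefined
correlation; their pairs are set to 0 with a message. `hicBand()` uses
$\log(1 + \text{count})$, mapping absent (zero-count) pairs to exactly 0.
Cluster exports follow the native conventions of each format: `GRanges`
are 1-based closed, BED is 0-based half-open; with a bin size the
intervals tile the binned region exactly. Merge tables serialise with
`hclust`-style signed references (negative = leaf), and round-trip through
`writeMergeTable()`/`readMergeTable()` exactly. The command-line wrapper
(`inst/scripts/bandclust`) stamps every table it writes with the run
configuration in a `#` header comment and removes partial outputs on
failure.

# Limitations

- The adjacency constraint is an assumption, not an inference: if the
  biological signal is not contiguous in the given ordering, the
  segmentation is meaningless. The ordering itself is taken as given.
- Bandwidth truncation is the one approximation; similarity mass outside
  the band is treated as zero. `selectBandwidth()` detects when this
  stops mattering but cannot certify it for similarities with heavy
  long-range tails.
- Heights from non-PSD similarities can be negative and the hierarchy
  non-monotone; both are reported, and downstream consumers that assume
  ultrametricity (some tree viewers) should use the clamped Newick
  export with that caveat in mind.
- The model selectors assume a "signal then noise" shape of the root
  decreases. Strong distance decay alone (e.g. an unenriched contact
  map) produces genuinely nested structure that the broken stick will
  report as multiple clusters; that is a property of the data, not an
  error, but it means the selectors should not be read as hypothesis
  tests for the *existence* of blocks.
- Memory is $O(ph)$ and a single core is used; p in the millions with
  large h will be bound by the $2ph$ pencil storage.

# A complete run

```{r example, eval = FALSE}
ps  <- plantedStructure(p = 500, K = 5, seed = 1)
sim <- simBlockSimilarity(ps, h = 150)
D   <- bandClust(sim$similarity)
sel <- selectSlopeHeuristic(D)
selectedK(sel)
head(selectionTrace(sel))
clustersToGRanges(clusterLabels(sel), binSize = 40000, chromosome = "chr1")
```
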