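---
title: "Selecting reference sequences for planted (l,d) motif search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting reference sequences for planted (l,d) motif search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refselect)
```

## The model

Pattern-driven solvers for the planted (l, d) motif problem enumerate
candidate motifs from h-tuples of l-mers drawn from k reference
sequences, and their cost is essentially proportional to the number of
candidates generated. For a pair of l-mers x, x′, the number of common
candidates |M_d(x, x′)| — l-length strings within Hamming distance d of
both — depends only on l, d, the alphabet size σ and d_H(x, x′), and it
grows steeply as the pair distance shrinks: for (l, d) = (13, 6) over a
20-letter alphabet it spans eight orders of magnitude between distance
2d and distance 0. Under a uniform random background the probability of
a pair at distance i is binomial,

$$p_i = \binom{l}{i}\frac{(\sigma-1)^i}{\sigma^l},$$

so the expected number of window pairs at distance i between two
length-n sequences is $E_i = (n-l+1)^2 p_i$. Pairs with $E_i < 1$ almost
never arise by chance — but implanted motif instances produce them
systematically, and each one multiplies the candidate load. Selecting
references therefore means avoiding sequence pairs that share
small-distance windows.

`refselect` scores a candidate reference set D′ by the total
$N_r(D') = \sum_{i<j} N_r(s_i, s_j)$ with
$N_r(s_i,s_j) = \sum_{x,x'} |M_d(x,x')|$ over all window pairs, and
seeks a k-set with small total.

### Exact counting

The intersection count is evaluated by classifying each position of a
candidate y relative to the pair (x, x′): at the `dist` disagreeing
positions y matches x, matches x′, or matches neither (σ − 2 ways); at
m of the agreeing positions it differs from both (σ − 1 ways). Summing
the multinomial terms under the two distance constraints gives

$$|M_d| = \sum_{\substack{a+b+c=\mathrm{dist}\\ b+c+m\le d,\; a+c+m\le d}}
\frac{\mathrm{dist}!}{a!\,b!\,c!}\,(\sigma-2)^c\binom{l-\mathrm{dist}}{m}(\sigma-1)^m .$$

The package validates this formula in two independent ways: exhaustive
enumeration over all σ^l strings for every small instance (l ≤ 7,
d ≤ 3, σ ∈ {2, 3, 4}), and the published two-significant-figure table
cells for the challenging instances (13, 4), (15, 5), (13, 6), (19, 9).
Protein-scale counts exceed 2^53, past exact double precision, so the
sum is accumulated in a small base-10⁶ big-integer representation
(`R/bignum.R`); no arbitrary-precision package is available in the
supported environment, and the operations needed (add, multiply,
compare, render) are minimal.

### The O(n²) distance dynamic program

All (n − l + 1)² window-pair distances for a sequence pair are obtained
from a running match count along each diagonal of the (conceptual)
n × n match matrix M, where M[a, b] counts agreeing positions in the
aligned prefixes ending at a and b; the window distance is
l − (M[a, b] − M[a − l, b − l]). The kernel (Rcpp) keeps O(n) working
storage per diagonal, so the per-pair cost is O(n²) time and O(n) extra
space, and the pipeline's space contract is O(tn + n² + t²). Only the
distance *histogram* (length l + 1) is retained per pair — all
downstream aggregation is a dot product with the count table.

## Similarity and clustering

Raw totals feed the objective, but for clustering the package uses the
distance-weighted count $N_r' = \sum |M_d|/(d_H+1)$, which further
amplifies the rare small-distance pairs that dominate solver cost, and
converts it to a similarity
$sim(s_i,s_j) = \max_{i<j} N_r' \,/\, N_r'(s_i,s_j) \ge 1$: sequence
pairs that generate *few* candidates are *similar* and should land in
one cluster. The max is computed once over all pairs and never
recomputed.

**Zero denominators.** For tiny d, dissimilar sequences can have
$N_r' = 0$. The similarity model assumes positive counts; here such a
pair is capped at the largest finite similarity (max / smallest positive
weighted count), and if every pair is zero all similarities are set
to 1. A zero-count pair is the most desirable pairing, and Markov
clustering needs finite weights.

**Markov clustering.** Only the inflation value (1.8) is prescribed by
the method; the remaining choices are the package's own, following
standard MCL practice: column-stochastic normalization; expansion by
matrix squaring; per-node self-loops equal to the node's maximum
incident similarity (damping); entries below 10⁻¹⁴ pruned after each
inflation; convergence when the largest absolute entry change drops
below 10⁻⁸, capped at 100 iterations (non-convergence is a warning, not
an error — the current matrix is interpreted as-is). Attractors are
nodes with positive diagonal in the limit matrix; overlapping attractor
systems are merged; every other node joins the system receiving the
largest flow, ties to the lowest attractor index. These choices are
cross-checked in the tests against an independent plain-loop MCL
implementation on planted two-group matrices.

**Refinement.** Clusters rarely have exactly k members. A singleton
cluster is invalid (its node is similar to nothing). With |C| = k the
cluster is the answer; with |C| > k a greedy selection starts from the
most similar pair in C and repeatedly adds the member maximizing the
summed similarity to the current set; with |C| < k the cluster is grown
the same way over the whole graph. Every tie — initial pair, greedy
additions, best-set choice — breaks to the lowest index, making the
whole pipeline deterministic. Each refined set is scored by its summed
internal similarity (unordered pairs counted once; the displayed form
of the score sums ordered pairs, but a global factor of two cannot
change an argmax) and the best set wins. If no valid cluster exists,
the shrink-from-pair greedy runs on the whole node set as a fallback,
so every legal input yields an output.

**k edge cases.** The contract is 1 < k < t. k = t is accepted with a
warning and returns the identity ordering (convenient, outside the
model). When (q, h) is supplied instead of k, k = t − q + h is derived
and reported.

## The synthetic benchmark

`generate_planted_dataset()` reproduces the standard protocol: i.i.d.
uniform background, uniform random motif m, q sequences chosen without
replacement, one instance implanted per chosen sequence at a uniform
position, overwriting the background (n stays fixed). The mismatch law
in `at_most_d` mode is: mismatch count uniform on {0..d}, positions
uniform without replacement, substituted characters uniform over the
σ − 1 alternatives — the simplest law consistent with "differs in at
most d positions"; `exact_d` mode fixes the count at d (the regime used
by older benchmark suites, which is precisely the regime that masks
solver instability). Whether the original generator drew the mismatch
count uniformly is not documented anywhere; the law is confined to one
function so alternatives can be added. A single seed drives one R RNG
stream, and the generator restores the caller's RNG state.

What the generator does *not* emulate: positional bias, composition
bias (GC content, amino-acid frequencies), correlated backgrounds, or
multiple motif occurrences per sequence. A green selection-quality test
therefore establishes correctness of the machinery on the stated random
model, not performance on real ChIP-seq data.

**Defaults in the evaluation tests.** The large-dataset direction-of-
effect check uses protein data with t = 50, k = 3, n = 200,
(l, d) = (13, 6), q = t: the published large-data assessment fixes
n = 200 and k = 5% of t but does not state its (l, d) or q, so these
are stand-ins chosen from the challenging-instance regime, and only the
qualitative claim (mean N_original/N_improved > 1) is asserted — the
published ratio values are not reproducible without the original random
datasets.

## Numerical choices

- Raw counts are exact integers; they are stored as doubles in the
  matrices (protein magnitudes ≤ ~10¹⁶ per pair; relative error of the
  aggregated weighted counts ≤ ~10⁻¹⁰, far below anything that could
  flip a comparison decided by orders of magnitude). The count *table*
  additionally carries exact decimal strings.
- Probabilities are evaluated in log space (`lchoose`), keeping full
  relative precision for large-l tails; the binomial normalization is
  tested to 10⁻¹² up to l = 30.
- The pairwise stage chunks the C(t, 2) pair list and writes results
  into preassigned slots, so the output is bitwise identical for any
  worker count (forked workers on unix, serial elsewhere).
- Window positions and sequence indices are 1-based throughout the API,
  following R convention.

## Known limitations

- The design envelope is t ≲ 2000, n ≲ 1000 (dense t × t similarity
  matrix, complete graph; no sparsification).
- Ambiguity codes (N, X) are rejected, not randomized: silent
  substitution would perturb candidate counts invisibly.
- Joint candidate counts of three or more l-mers have no closed form
  here; the brute-force enumerator covers them for analysis only.
- MCL granularity is fixed at inflation 1.8; no parameter search is
  attempted.
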