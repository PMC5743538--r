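---
title: "Natural-vector phylogenetics: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural-vector phylogenetics: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvphylo)
```

## The model

`nvphylo` compares organisms without aligning anything. Each sequence is
summarized by a fixed-length **natural vector**; each organism (taxon) is
the finite set of its sequences' vectors; taxa are compared with the
Hausdorff distance between those sets; the resulting distance matrix is
clustered by single linkage.

For a sequence $S = s_1 \dots s_N$ over an alphabet of $K$ symbols, with
indicator $w_k(s_i) = \mathbf 1[s_i = k]$, the basic vector stacks, in
fixed alphabet order,

$$n_k = \sum_i w_k(s_i), \qquad
  \mu_k = \frac{1}{n_k}\sum_i i\, w_k(s_i), \qquad
  D_2^k = \frac{\sum_i (i-\mu_k)^2 w_k(s_i)}{n_k\,N},$$

the count, mean position, and normalized second central moment of each
symbol's position distribution ($2K$ + $K$ = $3K$ components: 12 for DNA,
60 for protein). The general moment
$D_j^k = \sum_i (i-\mu_k)^j w_k(s_i) / (n_k^{\,j-1} N^{\,j-1})$ is exposed
by `nv_central_moment()`; $D_1^k \equiv 0$ (the deviations from the mean
sum to zero), and orders $j \ge 3$ are accepted but not placed in vectors
— the method uses $j = 2$ throughout.

### The covariance extension

The basic vector treats each symbol's positions marginally. The extension
adds, for every unordered symbol pair, the covariance of their position
distributions. With position sets $A = a_1 < \dots < a_n$ and
$B = b_1 < \dots < b_m$, $n \ge m$:

* equal counts: rank pairing,
  $\mathrm{Cov}(A,B) = \frac1m \sum_i (a_i - \mu_A)(b_i - \mu_B)$;
* unequal counts: the average of the equal-count covariance over **all**
  $\binom{n}{m}$ increasing subsets of the larger set (each subset paired
  by rank with $B$ and centered on its own subset mean).

The feature stored in the vector is $\mathrm{Cov}(A,B)/N$. Enumeration is
exponential, but the average collapses to the closed form

$$I = \frac{1}{m\binom{n}{m}} B\, D\, A^{\mathsf T} - \mu_A \mu_B,$$

where $D_{ij}$ counts the subsets in which $a_j$ receives rank $i$. The
normalized weight

$$w_{ij} = \frac{D_{ij}}{\binom{n}{m}}
         = \frac{\binom{j-1}{i-1}\binom{n-j}{m-i}}{\binom{n}{m}}$$

is the probability that the $i$-th order statistic of a uniformly random
size-$m$ subset of $\{1,\dots,n\}$ equals $j$ — each row of $w$ is a
hypergeometric-style probability distribution (a property asserted in the
test suite). `nv_covariance_closed()` evaluates $w_{ij}$ via `lchoose` in
log space, so no binomial coefficient is ever materialized and the
computation is $O(nm)$ and stable for counts up to $10^5$.
`nv_covariance_brute()` enumerates the subsets literally (capped at $10^5$
subsets) and exists so that the closed form can be checked against an
implementation that shares no code with it; the suite sweeps all
$1 \le m \le n \le 8$ and requires agreement within $10^{-9}$. Note the
two paths even center differently (subset mean vs. full-set mean $\mu_A$)
— their agreement is a theorem, not a shared convention.

With the $\binom{4}{2} = 6$ or $\binom{20}{2} = 190$ pair covariances
appended (lexicographic pair order in the fixed alphabet order — the
method defines no order, so we fix one for determinism), the vector has
**18 (DNA) or 250 (protein) dimensions**.

### Set comparison and trees

$$H(X,Y) = \max\Big\{\max_{x\in X}\min_{y\in Y} d(x,y),\;
                      \max_{y\in Y}\min_{x\in X} d(x,y)\Big\}$$

with $d$ Euclidean or Manhattan. $H$ is a true metric on non-empty finite
sets; symmetry, identity, and the triangle inequality are property-tested
on random sets. Single-linkage agglomeration then merges the two clusters
with the smallest minimum cross-pair distance; its merge heights equal the
sorted MST edge weights of the distance graph, which the tests verify
against an independent Prim's-algorithm oracle and `stats::hclust`.
Bootstrap support resamples each taxon's sequences with replacement
(within-taxon, to the original count), rebuilds the tree, and reports for
every internal clade the fraction of replicate trees containing exactly
that leaf set.

Classification is leave-one-out nearest neighbor in the 250-dimensional
space: a query is assigned to the taxon with the smallest minimum
Euclidean distance to its vectors, the query *instance* itself excluded.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `extended` | `TRUE` | 18/250-dim vectors; `FALSE` gives the basic 12/60 |
| `base_metric` | `"euclidean"` | or `"manhattan"`; applied to raw vectors |
| `set_metric` | `"hausdorff"` | `"direct"` for one-sequence-per-taxon data (rRNA mode) |
| `policy` | `"skip"` | non-canonical residues kept as positional placeholders; `"strict"` rejects |
| `n_replicates` | 100 | bootstrap replicates; seed mandatory |
| `k` | 3 | k-mer baseline word length (8000 words for protein) |

No standardization or rescaling is applied before distances: the method
operates on raw natural vectors, whose blocks (counts, positions, moments,
covariances) intentionally live on different scales; rescaling would
change every distance and is not part of the method.

## The synthetic generator, and what a green test means

`simulate_strains()` plants a two-level hierarchy: one random root
sequence; per clade, an ancestor obtained by i.i.d. substitution of the
root at `between_divergence`; per strain, sequences that are independent
i.i.d.-substitution copies of the clade ancestor at `within_divergence`.
Defaults used in the validation suite — 2 clades x 3 strains, 8 protein
sequences of length 300 per strain, 0.3 between vs 0.02 within — put the
clades far apart relative to within-clade scatter, the regime the method
is designed for, at roughly ribosomal-protein length scale.

Two honest limitations of this stated world:

* **Strains within a clade carry no individual signal.** They are
  exchangeable draws around one ancestor, so only the clade partition is
  recoverable. Accordingly the pipeline check asks for exact recovery of
  the planted clades, support $\ge 0.9$ for them, and leave-one-out
  accuracy scored at the clade level (assignment to any strain of the
  correct clade); sub-clade topology and sub-clade support are expected to
  be arbitrary, and strain-level accuracy is tested on separate fixtures
  whose taxa have distinct ancestors.
* **Real proteomes are not noisy copies of one protein.** A real strain's
  ribosomal proteins are ~100+ unrelated sequences; the generator's
  profiles are far more homogeneous. A green planted-clade test
  establishes that the geometry and the pipeline plumbing are correct, not
  that the method resolves any particular real phylogeny.

Mutation draws a uniformly random *different* symbol, so
`within_divergence = 0` yields byte-identical strains within a clade and
zero within-clade Hausdorff distance — both asserted.

## Numerical choices, tie-breaks, degenerate inputs

* Zero-count symbols contribute 0 to their mean, moment, and every
  covariance involving them, keeping dimensions fixed (required for the
  Hausdorff/classification geometry). A singleton symbol has $D_2 = 0$ by
  the formula, no special case.
* Covariance weights in log space; row sums checked to $10^{-12}$ in the
  tests; equal counts short-circuit to the direct rank-paired formula.
* Single-linkage ties: among equal-distance merges, the pair whose
  lexicographically smallest member label is smallest wins (then the
  other cluster's smallest label). Classification ties go to the
  lexicographically smallest taxon label. Duplicate sequences across taxa
  are resolved *only* by this tie-break — the degenerate case is asserted
  in the tests, not hidden. With instance-level self-exclusion, a taxon
  duplicated under two labels classifies with accuracy exactly 0 (every
  query finds its identical twin in the other label at distance 0); this
  is the rule's true consequence, verified by enumeration.
* Ingest: sequences upper-cased, exactly one trailing `*` stripped,
  internal `*` non-canonical. Non-canonical characters occupy positions
  (counting toward $N$) but join no symbol class, preserving the
  positional indices of everything downstream.
* Newick output is ultrametric (branch length = parent merge height minus
  child height, leaves at height 0); labels with unsafe characters are
  single-quoted; support values become internal node labels.

## Design decisions that were genuinely open

* **Bootstrap unit.** There are no alignment columns to resample in an
  alignment-free method; the resampling unit is the whole sequence,
  within each taxon independently (per-strain, not global), default
  $B = 100$. Since a sequence's vector does not depend on the rest of the
  data, replicates resample precomputed vectors — identical results, much
  faster.
* **Clade identity for support** is exact leaf-set equality; all trees
  share one leaf set and the dendrogram is rooted, so unrooted bipartition
  matching would add complexity without changing anything.
* **rRNA mode.** With one 16s-23s sequence per taxon the Hausdorff
  distance degenerates to the base metric anyway; `set_metric = "direct"`
  makes that explicit and refuses multi-sequence profiles.
* **k-mer pooling.** How ~100 proteins per strain become one comparable
  composition vector is not specified by the baseline's description;
  pooled counts per taxon, then normalization, is the standard k-mer
  convention and the default. A Hausdorff-over-per-sequence-k-mer variant
  is offered (`pool = "hausdorff"`).
* **Self-exclusion scope.** The classification rule excludes the query
  instance only (the constraint is written per-instance), not the query's
  whole taxon; other identical vectors remain legitimate candidates.

## Known limitations

* Single linkage chains: with $B$ bridges between clusters the tree can
  concatenate them; this is inherent to the published pipeline, not a
  tunable.
* The brute-force covariance is exponential by design and guarded by a
  subset cap; production code always uses the closed form.
* The injectivity of the basic vector map is spot-checked ($10^4$ random
  distinct sequences, no collisions), not proven here.
* No approximate Hausdorff algorithms, no $j \ge 3$ moment vectors, no
  background-corrected k-mer statistics, no sequence retrieval from NCBI.

## A worked check

```{r}
rec <- nv_record("example", "ACACACGTGT", "DNA")
ps <- position_sets(rec)
c(mu_A = nv_mean_position(ps$A), mu_G = nv_mean_position(ps$G))
c(brute = nv_covariance_brute(ps$A, ps$G, 10),
  closed = nv_covariance_closed(ps$A, ps$G, 10), exact = 2/15)
```
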