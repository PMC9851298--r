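---
title: "The delta rank matrix: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The delta rank matrix: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarank)
```

This vignette records the model behind `deltarank`, the tunable
parameters and their defaults, the numerical conventions the package
commits to, and what the synthetic-data generator does and does not
emulate. It is the place where design choices that were genuinely open
are written down.

## The model

Measured single-cell expression values are only weakly comparable
across cells: amplification noise, library size and platform effects
act, to a good approximation, as cell-specific monotone distortions of
the underlying abundances. The within-cell *relative expression
ordering* of two genes is invariant under every such distortion, which
makes it a natural primitive for cross-cell, cross-dataset features.

Given an expression matrix with $m$ genes and $n$ cells and a
background network of $l$ gene–gene edges, the package computes, per
cell $c$:

1. ranks $r_{i,c}$ of all $m$ genes (smallest value $\to$ lowest rank,
   average ranks on ties);
2. per edge $e = (g_i, g_j)$ the **delta rank**
   $\Delta_{e,c} = r_{i,c} - r_{j,c}$, bounded by $\pm(m-1)$;
3. a per-cell z-score of the $l$ delta ranks,
   $(X - \bar X)/\sigma$.

The resulting $l \times n$ **delta rank matrix (DRM)** carries
edge-level features. The raw layer (before z-scoring) is *exactly*
invariant to strictly increasing per-cell transformations of the
input — this is an algebraic fact about ranks, not an approximation,
and the test suite asserts it bitwise.

Two further algebraic properties pin the construction down and are
tested exactly: reversing an edge's stored orientation negates its row
(so an orientation convention is mandatory; see below), and delta ranks
telescope around cycles — for edges $(a,b), (b,c), (c,a)$ the three
rows sum to zero in every cell.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `ties_method` | `rank_transform()` | `"average"` | The only convention under which two co-zero (undetected) genes give $\Delta = 0$: no ordering information maps to no signal. scRNA-seq columns are zero-dominated, so this choice is load-bearing. `min`/`max`/`first` are available but not default. |
| $\sigma$ divisor | `zscore_columns()` | sample ($l-1$) | Either convention is defensible; the sample estimator matches common statistical practice and is recorded in the object (`sd_divisor`). Zero-variance columns map to zeros. |
| `k` | `top_variance_features()` | 500 | Clustering quality as a function of feature count typically saturates around a few hundred features; 500 is the conventional operating point. |
| `k_per_type`, `q_threshold` | `select_marker_edges()` | 7, 0.01 | Top-$k$ FDR-significant edges per type, ordered by fold difference $FD_{e,t} = \lvert\bar\Delta_{e,c=t} - \bar\Delta_{e,c\neq t}\rvert$; FD ties break by edge order for determinism. |
| `n_shuffles` | `empirical_null()` | 10{,}000 | Monte-Carlo resolution of the per-cell null; the smallest attainable p is $1/(N+1) \approx 10^{-4}$. |
| `alpha` | `cell_specific_network()` | 0.05 | Raw (uncorrected) per-edge threshold within a cell; see below. |

## Numerical and procedural conventions

**Edge orientation.** Edges are undirected for uniqueness (an unordered
pair appears once) but orientation-bearing for $\Delta$'s sign. The
first orientation encountered in the source file is canonical and is
preserved through cleaning, restriction and serialization. Cleaned
networks are written with a comment header stating this.

**Welch tests.** Marker-edge tests are two-sided unequal-variance
t-tests with Welch–Satterthwaite degrees of freedom, vectorized across
edges and cross-checked against `stats::t.test` in the suite. Edges
with zero variance in both groups get $p = 1$ when the group means
agree (no information) and $p = 0$ when two constant groups differ
(complete separation). FDR control is Benjamini–Hochberg step-up via
`stats::p.adjust`; the suite verifies it against a from-definition
oracle on all permutations of five p-values.

**Test layer.** Marker tests default to the normalized DRM, the
package's default analysis layer. Within one cell z-scoring is an
affine map, so per-cell normalization does not change the structure of
a one-vs-rest contrast; it does equalize cells' overall spread.

**Cell-specific-network null.** The null for one cell draws ordered
pairs of two distinct gene positions uniformly from that cell's own
rank vector and records their rank difference. This is equivalent to
shuffling gene labels and reading a fixed edge, so one shared null
serves all edges of the cell, with the cell's ties (dropout block
included) represented faithfully. Significance is computed on **raw**
$\Delta$: per cell, z-scoring is monotone affine, so p-values would be
identical, and raw $\Delta$ lets the tie-free closed form
$P(\Delta = d) = (m - \lvert d\rvert)/(m(m-1))$ act as an exact oracle.
The estimator is the add-one rule
$p = (\#\{\lvert s\rvert \ge \lvert\Delta_{obs}\rvert\} + 1)/(N+1)$,
which never returns 0. The test is two-sided (rewiring arguments
concern magnitude), and no within-cell multiple-testing correction is
applied — the cell-specific network is defined by a raw $p < 0.05$.

**Clustering and indices.** Cells are observations (columns). K-means
uses 10 restarts under a fixed seed; hierarchical clustering uses Ward
linkage (`ward.D2`) on Euclidean distances; the spectral backend
delegates to `kernlab::specc`. NMI is normalized by the arithmetic mean
of the two label entropies, with the $0/0$ case (both partitions
trivial) defined as 1. ARI uses the pair-counting contingency formula.
Purity is reported alongside the other two, never alone, because fine
partitions inflate it (all singletons give purity 1). ARI and NMI are
verified against brute-force pair-counting/entropy implementations over
exhaustive partition enumerations.

**Degenerate inputs.** Duplicate gene IDs, negative or non-finite
values and dimension/sidecar mismatches are rejected at read time with
classed conditions; a single-edge matrix cannot be z-scored; a
coefficient of variation with $\lvert\text{mean}\rvert < 10^{-12}$ is
flagged and excluded from rankings (normalized DRM rows can have
legitimately negative means, hence CV uses $\lvert\text{mean}\rvert$).

## The synthetic generator

`simulate_gem()` exists so that every downstream claim is testable
without external data. It emulates exactly one mechanism — cell-type
identity encoded in within-cell orderings:

- baseline per-gene levels are log-normal (heavy-tailed, positive),
  shared by all cells;
- each planted marker edge receives endpoint levels at baseline
  quantiles $\text{centre} \pm 0.45\,\text{effect}$, so `effect` is the
  fraction of the rank range the pair spans; in the edge's assigned
  type the two levels are swapped. The pair's *value set* is identical
  in every type — only the ordering flips;
- planted edges are gene-disjoint across types, and filler network
  edges avoid marker genes entirely, because any edge touching a
  swapped gene would itself be differential: the planted set is exactly
  the truth set;
- multiplicative log-normal noise (sd 0.3) perturbs every entry; at
  `effect = 1` a planted ordering flips in well under 1% of cells;
- uniform random dropout zeroes entries last, producing the tied-at-zero
  rank block typical of scRNA-seq.

Defaults (3 types × 30 cells, 200 genes, 400 edges, 20 planted edges
per type, `effect = 1`, `dropout_rate = 0.3`) are the package's
standard study conditions and are used as-is by the test suite.

What the generator does **not** emulate: expression-dependent dropout
(an option flag exists for uniform only by design — realistic dropout
preferentially hits low expression, which is *gentler* on high-signal
pairs than the uniform model), UMI counting noise, library-size
gradients, batch structure, correlated gene programs, or doublets.
Passing tests on this generator therefore demonstrate the algebraic and
statistical machinery under its stated mechanism; they do not by
themselves establish performance on real tissues.

A deliberate consequence of uniform dropout worth knowing: at 60%
dropout only ~16% of cells retain both endpoints of an edge, and a
single dropped endpoint throws $\Delta$ from its signal value to
$\pm(r - \text{tie block})$. With 30 cells per type this mixture keeps
one-vs-rest Welch statistics for planted edges around
$\lvert t\rvert \approx 2.5\text{–}4$, which is below what BH-FDR
$< 0.01$ over 400 edges requires, so q-filtered marker recovery
collapses under that stress although it is essentially perfect at the
default 30% dropout. Detecting ordering signal under heavy uniform
dropout at this sample size is a power problem, not a bookkeeping one.

## Problem sizes used in the checks

The suite runs entirely on generated data at desk scale: matrices up to
300 genes × 210 cells and networks up to 700 edges for end-to-end
pipelines; exhaustive oracles run on all instances up to 6 genes/items;
Monte-Carlo checks use 10,000 draws. These sizes were chosen so the
full suite exercises every code path in about a minute while keeping
every statistical check adequately powered.

## Known limitations

- Ranking densifies: sparse inputs are expanded to dense matrices, so
  very large atlases need chunking outside this package.
- The DRM inherits the background network's coverage; genes absent from
  the network contribute nothing, and edge features are only as
  meaningful as the prior interactions.
- Heavy dropout plus small groups limits marker power (see above).
- The CSN p-values are per-cell and uncorrected by design; across many
  cells and edges, significant edges include the expected false-positive
  share.
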