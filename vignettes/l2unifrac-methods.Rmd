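---
title: "L2-UniFrac: model, algorithms, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{L2-UniFrac: model, algorithms, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A metagenomic sample on a rooted tree $T$ with $N$ nodes is a probability
vector $P \in \Delta^{N-1}$, indexed in a fixed post-order; entry $P_i$ is
the relative abundance assigned to node $i$ (leaves for 16S OTU profiles;
internal taxonomic ranks may also carry mass for shotgun profiles). Let
$w_j$ be the 0/1 indicator of the subtree rooted at $j$, $l(j)$ the length
of the branch above $j$, and build the matrices

$$W = \big(l(j)\, w_j\big)_j, \qquad
  \dot W = \big(\sqrt{l(j)}\, w_j\big)_j,$$

with the root row left unscaled (the root has no branch; its entry is the
total mass and cancels in every distance between valid profiles). Then

$$\mathrm{UniFrac}(P, Q) = \lVert W(P - Q)\rVert_1, \qquad
  \mathrm{L2UniFrac}(P, Q) = \lVert \dot W(P - Q)\rVert_2 .$$

The L1 form is the classical metric and coincides with the 1-Wasserstein
distance between $P$ and $Q$ under tree-path costs; the test suite checks
this against an explicit transport linear program solved by an independent
LP solver. The L2 form keeps the phylogeny-aware structure — entries of
$\dot W(P-Q)$ are per-edge fluxes — but lives in a Euclidean geometry.

Why that matters: the barycenter of a cohort $\{P_i\}_{i=1}^M$, defined as
the profile minimizing $\sum_i \mathrm{L2UniFrac}(P_i, x)^2$, is the
preimage of the component-wise mean of the aggregated vectors, and because
aggregation is linear and invertible this equals the plain component-wise
mean $\bar P = \tfrac1M \sum_i P_i$ — a valid probability vector, since the
simplex is closed under means. The analogous L1 construction takes a
component-wise *median* in aggregated space; medians of subtree sums need
not be consistent across nesting levels, so the inverse image routinely
has negative entries. `l1_median_demo()` exhibits this on the default
synthetic cohort, and the package never offers it as an average.

### A note on the barycenter definition

The barycenter is defined here as the minimizer of the sum of **squared**
distances (the Fréchet mean). A sum-of-distances objective would instead
define a geometric median, for which the component-wise mean is not
optimal and no closed form exists; only the squared form is consistent
with the mean identity above, which the implementation re-verifies at run
time on every call. This was a genuinely open corner of the design and the
squared form was adopted as the only self-consistent reading.

## Algorithms

**Aggregation** is a single post-order pass: for each non-root node $i$,
add the running subtree mass to the ancestor, then scale entry $i$ by
$l(i)^{1/p}$. This is $O(N)$ time and memory per sample and equals the
matrix product $W^{(p)} P$ exactly; the explicit matrix is built only as a
brute-force oracle in the tests. The scaling exponent follows the metric
definitions ($l$ for $p=1$, $\sqrt l$ for $p=2$); a published pseudocode
variant that scales by $l(i)$ for the L2 case was set aside in favor of
the definitions, which carry the metric's meaning.

**Inversion** undoes the forward pass in reverse post-order: unscale entry
$i$, subtract it from the ancestor. The binding contract is the round-trip
identity `inverse_aggregate(aggregate_profile(P)) == P` to $10^{-10}$,
checked on a thousand random instances, rather than any printed pseudocode
(a published variant omits the unscaling of the node's own entry).
Non-image inputs are returned unclamped with a negativity count — that
behavior is load-bearing for the L1-median demonstration.

**Distances and cohorts.** `pairwise_unifrac()` aggregates each sample
once (one linear pass over the cohort) and then takes plain Lp norms of
differences. `cluster_l2_space()` runs Lloyd's k-means with k-means++
seeding directly on aggregated vectors — Euclidean distance there *is*
L2-UniFrac — so no pairwise matrix is ever materialized; internal
operation counters expose the $O(M)$ vs $O(M^2)$ distinction and the test
suite asserts it as a complexity property, not as wall-clock timing.
k-means is implemented in-package because the contract requires k-means++
initialization, a caller seed with 10 restarts (best objective kept), and
a deterministic empty-cluster rule (re-seed at the farthest point);
`stats::kmeans` exposes none of these. The conventional route,
`cluster_dmat()`, delegates to PAM (build + swap) from the `cluster`
package; `k == n` is handled directly since PAM requires `k < n`.

**Classification.** `classify_nearest_representative()` builds one
barycenter per training environment and assigns each test sample to the
nearest one in L2-UniFrac; ties break to the alphabetically first
environment. The majority-vote labeling of unsupervised clusters is
provided for comparison, and its known failure mode — two clusters voting
the same label, leaving an environment unrepresented — is surfaced in a
`missing_labels` field.

**Taxonomic trees.** For shotgun profiles the tree may be a taxonomy
rather than a phylogeny. `tree_from_lineages()` deduplicates lineage
paths and assigns a node at depth $d$ (root children at $d=1$) branch
length $1/d$ — the reciprocal convention for taxonomic UniFrac. The exact
depth convention is not uniquely fixed by the literature this follows, so
the rule is a pluggable function argument; $1/d$ is the default.

**Differential abundance.** `differential_abundance()` is
$\dot W P - \dot W Q$; its norm is the metric and its root entry is zero
by conservation. `top_taxa_at_rank()` reports *unscaled* subtree-mass
differences (flow entry divided by $\sqrt l$), because bars of "difference
in total subtree abundance" are the interpretable quantity; the scaled
entries remain available behind a flag since their squares decompose the
metric.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p` | 2 | Lp space; only 1 and 2 are accepted (internally parameterized, untested p rejected) |
| sum-to-one tolerance | 1e-8 | rows further from 1 are rejected unless `renormalize = TRUE`; never silently fixed |
| negativity threshold | −1e-12 | separates true negative entries from float noise |
| `n_leaves` | 64 | synthetic tree size (127 nodes) |
| `branch_mean` | 1.0 | exponential branch-length mean, truncated below at 1e-6 |
| `n_environments` × `samples_per_environment` | 4 × 50 | cohort shape, body-site-like |
| `alpha` | 50 | Dirichlet concentration about the environment base profile |
| `sparsity` | 0.2 | fraction of leaves in each environment's support |
| `internal_mass_fraction` | 0 | fraction of mass moved to internal nodes (taxonomic pathway) |

Branch lengths must be strictly positive: the inverse transform divides by
$l(i)^{1/p}$, and a zero-length edge would make aggregation
non-invertible. Trees with zero or negative branch lengths are rejected at
parse time rather than clamped.

## What the synthetic generator does and does not establish

The generator emulates environment-structured cohorts: a random
bifurcating tree (sequential leaf attachment, exponential branch lengths),
one sparse base profile per environment (uniform over a random leaf
support), samples drawn $\mathrm{Dirichlet}(\alpha\,\mathrm{base} +
10^{-3})$ on the support, optional relocation of a mass fraction to
internal nodes to exercise the taxonomic pathway. One global seed is split
into per-component streams, so fixtures are bit-reproducible and adding a
generator never shifts existing draws.

Defaults were fixed once as the stated test world. The support sparsity
deserves a note: it was initially set to 0.5, under which four
environments on 64 leaves overlap in roughly half their taxa and k-means
recovers them imperfectly (Fowlkes–Mallows ≈ 0.68) — an interesting
regime, but not the "well-separated environments" the acceptance fixture
is defined to be. It was corrected once to 0.2, matching how distinct
body-site communities share few dominant taxa; all separation-dependent
properties then hold with margin, and no further adjustment was made.

A green suite on this world establishes the *algebraic* contracts
unconditionally (they hold instance-by-instance at $10^{-10}$–$10^{-12}$)
but only establishes the *statistical* claims — clustering quality,
classification accuracy, L1/L2 correlation, the negativity phenomenon —
for well-separated Dirichlet environments. Real 16S or shotgun cohorts
have compositional noise, copy-number variation, rank-incomplete
classifications and far larger trees; none of that is modeled, so the
statistical results here are qualitative analogs of the real-data
behavior, not reproductions of it.

## Numerical choices

- All accumulation in double precision; test tolerances are absolute
  (1e-12 oracle equivalence, 1e-10 round trips, 1e-9 slack on triangle
  inequalities).
- Post-order ties follow input order (Newick children as written; lineage
  children by first appearance); unnamed internal nodes get ids by
  post-order index, so orderings are reproducible byte-for-byte.
- The L1 median uses the *lower* median for even cohort sizes — any point
  between the two middle values is a valid median, and a deterministic
  choice makes negativity counts reproducible.
- k-means restarts derive their seeds from the caller's seed through a
  fixed integer mix; PAM is deterministic given the matrix and ignores the
  seed it accepts.
- Newick output uses `%.17g` so write/read round-trips are exact; TSV
  output uses R's default 15-significant-digit formatting, round-tripping
  to 1e-12.

## Known limitations

- Only $p \in \{1, 2\}$ is exposed; the machinery is parameterized for
  general Lp but untested values are rejected rather than silently
  accepted.
- No significance testing for differential abundance (no permutation or
  FDR machinery): flows rank clades, they do not test hypotheses.
- BIOM input is not parsed natively; tables arrive as TSV (the canonical
  test format). Reading BIOM via `biomformat` and passing the data frame
  in works unchanged.
- PCoA and bar-plot visualization are out of scope; outputs are TSVs
  designed to be plotted by external tools.
- The L1-median negativity demonstration is constructive on the synthetic
  world; per-environment negative-entry *counts* on real cohorts depend on
  the data and are not reproduced here.
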