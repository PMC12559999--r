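---
title: "Models and methods behind radils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radils)
```

`radils` quantifies phylogenomic conflict in rapid radiations and separates
incomplete lineage sorting (ILS) from reticulate evolution. This vignette
is the package's account of the models it implements, the conventions and
tunable parameters that matter, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was open.

## The multispecies coalescent and the simulator

Under the multispecies coalescent (MSC), a gene tree is generated inside a
species tree whose internal branch lengths are measured in coalescent units
(generations divided by effective population size). `simulate_gene_trees()`
samples one haploid lineage per tip; within each species-tree branch of
length $t$, the $k$ lineages present coalesce pairwise at rate
$\binom{k}{2}$ until the branch is exhausted, and lineages reaching the
root population coalesce with unlimited time. Population sizes are absorbed
into the coalescent-unit branch lengths — there is no separate $N_e$
parameter — and gene-tree branch lengths are retained in coalescent units.

The closed-form check used throughout the package is the quartet
concordance factor (CF): for a species quartet whose unrooted internal edge
has length $t$, the gene-tree quartet matching the species tree has
probability $1 - \tfrac{2}{3}e^{-t}$ and each discordant resolution
$\tfrac{1}{3}e^{-t}$ (`expected_quartet_cf()`). One subtlety worth stating:
for a rooted quartet $((AB)\!:\!x,(CD)\!:\!y)$ the relevant $t$ is $x + y$,
the unrooted edge spanning the root. The package's tests calibrate the
simulator against this closed form at $t \in \{0.1, 1\}$ with 10,000 loci
(a three-Monte-Carlo-standard-error band), and verify the defining
anomaly-zone prediction end-to-end (below) with 50,000 loci — sizes chosen
so that Monte-Carlo error is far below the effect sizes being checked while
a full test run stays in the minutes range on one CPU.

### The estimation-error and pseudo-support model

Empirical gene trees are estimates, and short internodes are estimated
badly. `apply_estimation_error()` emulates this with two components, both
driven by the gene tree's own branch lengths:

* **Topology error.** Each internal branch is hit by a random
  nearest-neighbour interchange (NNI) with probability
  $p_0 e^{-\ell/\lambda}$ (defaults $p_0 = 0.5$, $\lambda = 0.3$ cu), the
  two alternative configurations chosen uniformly. Error therefore
  concentrates on very short branches, which is where real tree-search
  error lives; with these defaults a typical simulated locus receives one
  or two NNIs, not a wholesale scramble.
* **Pseudo-supports.** Every internal branch gets a support value in
  $[0, 100]$ with mean $100(1 - e^{-\ell/s})$ ($s = 0.4$ cu), multiplied by
  0.4 on branches involved in an NNI, plus Gaussian noise (sd 10),
  truncated to the scale. Long branches saturate near 100 (so genuinely
  resolved splits usually clear a 95 threshold) while short and perturbed
  branches rarely do.

The true error process of any given empirical pipeline is unknown; these
defaults were set once so that the simulator reproduces the qualitative
signature the model is meant to emulate — the proportions of both weakly
and strongly supported conflicting gene trees rise as internodes shorten,
and weak conflicts dominate strong ones at the shortest internodes — and
the package's acceptance tests assert exactly that signature (significantly
negative regression slopes of both conflict percentages on log internode
length at $\alpha = 0.01$, on an 18-internode caterpillar with lengths
log-spaced over 0.05–2.5 cu and 400 loci). The error model is a stand-in
calibrated qualitatively, not an estimate of any specific inference
pipeline's error.

## Conflict classification and regression

`classify_gene_tree_vs_branch()` scores one gene tree against one
species-tree bipartition:

1. Restrict the species split to the taxa shared with the gene tree
   (mirroring the practice of pruning missing taxa before evaluating
   conflict). If either restricted side has fewer than two taxa the gene
   tree is **missing** for that branch.
2. If the gene tree displays the restricted split: **strong_support** when
   the gene tree's support for it reaches the threshold (default 95 on the
   0–100 ultrafast-bootstrap scale), otherwise **weak_support**.
3. Otherwise: **strong_conflict** when any gene-tree split incompatible
   with the restricted split (all four pairwise side intersections
   non-empty) carries support at or above the threshold, otherwise
   **weak_conflict**. Absent supports count as 0; a gene tree that is
   simply unresolved around the branch is thus scored as weak conflict.

`conflict_proportions()` exposes both denominator conventions: the
five-way percentages including the missing category (the pie-chart view)
and percentages over scored gene trees only, which is what
`conflict_regressions()` uses. Regressions are ordinary least squares of a
percentage on the **natural** logarithm of branch length with a two-sided
t-test on the slope; the log base only rescales the slope and leaves the
p-value untouched. Non-positive lengths are an error in `fit_loglinear()`
(no silent dropping); the wrapper `conflict_regressions()` drops
length-less branches with a message, since species-tree methods often
leave terminal or root branch lengths undefined. A constant response
returns slope 0 and p = 1 exactly rather than whatever floating-point
noise `lm` would produce at zero residual variance.

## The anomaly zone

For a species-tree internal branch of length $x$ with a descendant internal
branch of length $y$ (both in coalescent units), the pair is in the anomaly
zone iff $y < a(x)$ with

$$a(x) = \log\!\left[\frac{2}{3} +
  \frac{3e^{2x} - 2}{18\,(e^{3x} - e^{2x})}\right].$$

In the zone, the most probable gene-tree topology differs from the species
tree — the regime where concatenation-style reasoning fails.
`anomaly_boundary()` evaluates the algebraically identical stable form
$\log(2/3 + (3 - 2e^{-2x})/(18(e^x - 1)))$, avoiding $e^{3x}$ overflow;
`detect_anomaly_pairs()` additionally short-circuits $x > 30$ to
`in_zone = FALSE` (where $a(x) < 0$ anyway). $a$ uses the natural log,
matching its coalescent-unit derivation; it is strictly decreasing,
diverges as $x \to 0^+$, and tends to $\log(2/3) < 0$, so long parent
branches admit no anomalous descendant.

Conventions for the scan: terminal branches never participate; the tree is
treated as unrooted for adjacency, and with a binary root the two
root-incident edges count as a single branch whose length is their sum —
coalescent-unit lengths from quartet-based species-tree methods are defined
on the unrooted topology, so splitting that branch at an arbitrary root
would halve $x$ artificially. `cluster_anomaly_internodes()` groups the
branches of in-zone pairs into maximal components under tree adjacency
(sharing a node of the unrooted topology, which includes sibling branches),
numbered deterministically by preorder position.

## Quartet hypothesis tests and the NANUQ distance

`count_quartet_topologies()` tallies, for each 4-taxon subset, how many
gene trees display each of the three resolved quartet topologies after
restriction; gene trees missing a taxon contribute nothing, and quartets
left unresolved by a multifurcation are recorded separately. Quartets are
keyed by sorted taxon labels, making results invariant to input order.
Enumeration is exhaustive up to a configurable cap (default 500,000
quartets) with seeded uniform sampling beyond it; the package's tests run
at ≤ 20 taxa, where enumeration is always exhaustive.

Per quartet with counts $(n_1, n_2, n_3)$, $n = \sum n_i$:

* **Star test** — likelihood ratio against H0: $(p_1,p_2,p_3) =
  (\tfrac13,\tfrac13,\tfrac13)$ (a hard polytomy), statistic
  $2\sum n_i \log(3 n_i/n)$ (zero counts contribute 0), chi-squared with
  2 df.
* **T3 test** — H0 is the one-parameter model of *some* resolved species
  quartet under the MSC: largest probability $\ge 1/3$, minors equal. The
  constrained MLE sets $\hat p_{maj} = \max(m/n, 1/3)$ ($m$ the largest
  count) with equal minors; the statistic $2\sum n_i \log(n_i/(n\hat p_i))$
  is referred to chi-squared with 1 df. Near the simplex centre
  ($|\hat p_{maj} - 1/3| < 2/\sqrt{n}$) the chi-squared approximation is
  unreliable — the centre is a boundary-singular point of the model — so
  the default switches to a parametric bootstrap there; the bootstrap can
  also be forced or disabled. The test suite holds the chi-squared route to
  within 0.02 of a 10,000-replicate bootstrap away from the centre, and the
  combined procedure to its nominal type-I error (three binomial standard
  errors at $\alpha = 0.01$ over 2,000 simulated quartets of 300 loci).

`classify_quartets()` applies the decision rule: **reticulate** iff the T3
test rejects at level $\alpha$ (default $10^{-6}$ — a small $\alpha$ is
appropriate when weakly supported conflict indicates much gene-tree error,
as larger levels misread noise as reticulation); otherwise **starlike**
iff the star test fails to reject at level $\beta$ (default 0.1); otherwise
**treelike** with the argmax topology. Argmax ties are classified starlike
(conservative). The summary reports class fractions across the sensitivity
grid $\alpha \in \{10^{-2}, 10^{-3}, 10^{-5}, 10^{-6}\}$ alongside the
requested level, since headline "treelike" fractions depend visibly on
$\alpha$.

`nanuq_distance_matrix()` converts the per-quartet decisions into an
inter-taxon distance: a treelike quartet $ab|cd$ contributes 0 to its two
cherry pairs and 1 to the four separated pairs; starlike and reticulate
quartets contribute a flat weight (default $1/2$, configurable) to all six
pairs. This flat weight is an approximation of the published NANUQ
weighting, stated as such and kept configurable rather than guessed as
ground truth. The matrix is symmetric with zero diagonal and exports as a
lower-triangular nexus DISTANCES block (`write_nanuq_nexus()`) for
splits-network software; network layout itself is out of scope.

## ANI clustering and gap detection

`symmetrize_ani()` averages the two directions of each genome pair (ANI
tools report asymmetric values), warns on one-direction-only pairs and on
asymmetries above one percentage point, and fixes the diagonal at 100.
`cluster_genomes()` uses single-linkage (connected components of the
ANI ≥ threshold graph) because threshold clustering is usually described
without a linkage rule and single linkage is the minimal rule consistent
with "pairs above the threshold belong together"; complete linkage is
available via a flag for users who want chains broken. Cluster ids are
deterministic (numbered by smallest member label). Raising the threshold
can only refine clusters, a property the tests check on random matrices.

`detect_ani_gaps()` reports maximal open intervals containing no observed
pairwise value, at least `min_width` wide (default 0.5 percentage points);
`resolution` (default 0.1) sets the granularity below which neighbouring
values count as contiguous coverage. Bounds are reported at the flanking
observed values. The biological use is checking whether a discontinuity in
genomic similarity — e.g. a gap around 86% ANI — coincides with the
conventional 95% species threshold or falls elsewhere.

## Partner-sharing co-occurrence statistics

`partner_sharing_table()` enumerates specimen pairs per OTU pair: all
cross pairs for distinct OTUs ($n_A n_B$), unordered pairs within an OTU
($n(n-1)/2$). A pair is co-occurring iff both specimens carry the same
site id (exact string match; sites are discrete survey plots, so no
distance-based notion is used) and shares a partner iff both partner labels
are present and equal. Percentages are **truncated** to two decimals —
$\lfloor 10^4 \cdot k/n \rfloor / 10^2$ — because published tables of this
kind print truncated values (26/107 prints 24.29, not 24.30); full-precision
columns are emitted alongside. Specimens lacking a partner identification
are excluded from all counts by default, with a flag to retain them in the
pair universe while still excluding them from sharing counts — published
analyses rarely state which convention they used, so both are available and
the default is the stricter one. Empty categories yield `NA` percentages,
never 0. `partner_sharing_from_counts()` recomputes the derived cells of a
published summary directly from printed pair counts.

The specimen generator (`simulate_specimen_table()`) places specimens
uniformly across sites and draws partners uniformly from per-OTU pools,
except that with probability `sharing_elevation` a specimen copies the
partner of a co-occurring specimen — a minimal model of vertical
transmission through asexual propagation at local scales. At elevation 0,
sharing is provably independent of co-occurrence, which the tests verify
over > 10,000 pairs; at positive elevation, co-occurring sharing exceeds
non-co-occurring sharing for every OTU pair.

## What the synthetic generators do not emulate

The MSC simulator produces topologies and coalescent-unit lengths but no
sequences: there is no substitution model, no alignment uncertainty, and
the estimation-error model is a phenomenological stand-in, not a model of
any specific tree-search pipeline. There is no migration or hybridization
generator — the package tests reticulation *detection* power only against
simple two-tree mixtures, not against an explicit network-MSC generative
model. The ANI generator maps divergence time to expected identity by
piecewise-linear interpolation with Gaussian noise; real ANI distributions
have heavier tails, alignment-fraction covariates and recombination
structure it does not attempt. Passing tests therefore demonstrate that the
*methods* behave correctly under their own model assumptions, not that any
particular empirical dataset satisfies those assumptions.

## Numerical choices and degenerate inputs

* Supports are stored on the 0–100 scale; inputs that look like
  proportions are rescaled with a warning.
* Zero-length branches are permitted and treated as length 0, never
  silently collapsed.
* `truncate_percent()` adds 1e-9 before flooring to guard against exact
  hundredths landing epsilon low in binary floating point.
* The T3 bootstrap p-value uses the $(1 + \#\{T^* \ge T\})/(B + 1)$
  convention, never returning exactly 0.
* Gene trees sharing fewer than four taxa with the species tree are
  missing for every branch; quartets with $n = 0$ return NA-marked test
  results rather than errors.
* Random draws are confined to explicitly seeded calls; every simulator
  records its seed in its output attributes.

## Known limitations

The conflict tally is quadratic in (branches × gene trees) and intended
for desk-scale analyses (tens of taxa, thousands of loci); the 151-taxon,
1,519-locus scale of a full phylogenomic study is cluster work and out of
scope here, as is splits-graph layout, species-tree inference itself,
divergence dating and gene-flow clustering, which dedicated external tools
perform. The T3 test's exact boundary asymptotics are intricate; the
package treats the parametric bootstrap as the authority near the centre
and the chi-squared approximation elsewhere, and documents the 2/√n
switching band rather than claiming exactness.
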