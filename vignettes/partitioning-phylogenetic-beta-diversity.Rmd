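---
title: "Partitioning phylogenetic beta diversity into lineage turnover and PD-difference components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning phylogenetic beta diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdpart)
```

## The problem

Phylogenetic beta diversity (PBD) measures how much evolutionary history two
communities do *not* share. The two workhorse indices, PhyloSor and UniFrac,
compare the branch length unique to each community against the branch length
spanned jointly on a rooted regional phylogeny. Both are "broad-sense"
dissimilarities: a pair of communities can score high either because lineages
are genuinely *replaced* between them, or merely because one community spans
much more of the tree than the other (a phylogenetic diversity gradient, as
arises between a species-rich biogeographic center and a depauperate outpost).
Ecological inferences differ radically between those two situations, yet the
raw indices conflate them.

`pbdpart` implements the additive resolution of this conflation: each index
is split into a *'true' lineage-turnover* component and a *PD-difference*
component, exactly mirroring the turnover/nestedness partition of the
Sørensen and Jaccard indices for species composition.

## The decomposition

Every pairwise index here is a function of a partition $(a, b, c)$. For
compositional beta diversity (CBD), $a$ is the number of shared species and
$b, c$ the numbers unique to each site. For PBD, $a$ is the branch length
shared by the two communities and $b, c$ the branch lengths unique to each,
where a community's branch set contains every edge on a root-to-tip path of
one of its species ("root-inclusive" convention, see below). With
$m = \min(b, c)$:

* Sørensen family (PhyloSor when $a,b,c$ are branch lengths):
  $\beta_{tot} = \dfrac{b + c}{2a + b + c}$, turnover
  $\beta_{turn} = \dfrac{m}{a + m}$ (the Simpson dissimilarity);
* Jaccard family (UniFrac):
  $\beta_{tot} = \dfrac{b + c}{a + b + c}$, turnover
  $\beta_{turn} = \dfrac{2m}{a + 2m}$.

The third component is defined by subtraction,
$\beta_{PD} = \beta_{tot} - \beta_{turn}$ (nestedness-resultant for CBD). The
turnover component is what the dissimilarity *would be* if both communities
had the same PD (richness); the PD component is the remainder, attributable
to the PD (richness) gradient between them. Two structural facts drive all
the diagnostics in this package:

* turnover depends only on $(a, m)$, so inflating the larger unique
  component moves total and PD-difference but never turnover;
* a fully nested pair ($m = 0$) has turnover exactly 0 — all of its
  dissimilarity is gradient-driven.

The branch partition itself is computed through Faith's PD on rooted
subtrees: $a = PD_j + PD_k - PD_{j \cup k}$, $b = PD_{j\cup k} - PD_k$,
$c = PD_{j\cup k} - PD_j$. The test suite checks this identity against an
independent per-edge enumeration oracle on a thousand random trees.

```{r toy}
ex <- pbd_example("pd_gradient")
pairwise_pbd(ex$tree, ex$comm, family = "sorensen")[1:5, ]
```

In this six-community example (communities B–F nested with steadily growing
unique branch length), the total dissimilarity from A rises along A-B … A-F
while the turnover component stays pinned at $1/6$: the entire gradient is a
PD effect.

## Conventions and numerical choices

**Root-inclusive PD.** A community's branch set includes the basal edges
down to the designated root. This is the convention under which the worked
eight-tip examples reproduce (a four-tip basal clade of the unit-length
balanced tree has PD 7, not 6), and it makes `faith_pd` of the full tip set
equal the total tree length. Communities on opposite basal clades therefore
share *no* branches and score PhyloSor = 1.

**Subtraction, not closed forms.** The PD/nestedness component is computed
as `total - turnover`, which makes additivity exact in floating point; the
published closed forms are kept as independent oracles in the tests
(agreement to 1e-12). The tie $b = c$ yields a PD component of exactly 0, no
tolerance involved.

**Degenerate inputs.** An all-zero partition is an undefined-index error in
the scalar functions. In the pairwise drivers an empty site produces `NA`
rows with a warning instead of failing the whole matrix. Missing branch
lengths in newick input are an error by default (an explicit
`missing_lengths = "zero"` substitutes 0), because silent defaults corrupt
PD sums. Zero-length edges are legal and contribute nothing. A basal
multifurcation is accepted as rooted at the listed node, with a warning.

**Matching table to tree** is exact-string on species names; species absent
from the tree are an error unless `prune_missing = TRUE` drops them with a
count. Abundance values collapse to presence/absence with a notice, since
every index here is incidence-based.

## The null model

Observed PBD is confounded with CBD (they correlate strongly; see the
simulation below), so "is this pair phylogenetically unusual?" must be asked
*conditionally on composition*. The null model permutes species labels
across the tips of the regional tree — topology, branch lengths and the
community table itself are untouched, so per-site richness and every
compositional index are conserved *bit-exactly*, while the phylogenetic
position of each species is randomized. One shuffled tree serves all site
pairs in a randomization, which is mathematically equivalent to permuting
the species columns of the table.

The standardized effect size for each pair/index/component is
$SES = (X_{obs} - \overline{X}_{null}) / sd(X_{null})$, with $|SES| > 1.96$
flagged as non-random. Choices worth recording:

* `null_sd` is the **sample** standard deviation ($n-1$ denominator), the
  common choice in community phylogenetics; the convention is recorded in
  an `sd_type` output column so the alternative is auditable.
* The observed value is **not** appended to the null distribution (pure
  Monte-Carlo null, matching the SES definition above).
* A degenerate null (`sd = 0`, e.g. any star tree, where tip shuffling is a
  symmetry of the metric) yields `ses = NA` with both significance flags
  `FALSE`, rather than an infinity.
* The default is 9999 randomizations; the examples and tests use 49–999,
  which is ample for the structural assertions they make.

```{r ses}
ses <- ses_pbd(ex$tree, ex$comm, n_rand = 199, seed = 1, family = "sorensen")
head(ses[ses$component == "total", c("site_i", "site_j", "observed", "null_mean", "null_sd", "ses")])
```

## The simulators and what they do (and do not) emulate

`run_simulation_study()` rebuilds the theoretical study: community pairs
with $a, b, c$ drawn independently uniform on `[abc_min, abc_max]` (defaults
1–100) from a regional pool of `pool_size` species (default 100), placed on
one random tree per tree model, 10,000 pairs by default.

* **Feasibility.** A triple with $a+b+c$ exceeding the pool cannot be
  realized with distinct species; the whole triple is redrawn until
  feasible. This keeps the three marginals uniform conditional on
  feasibility. (Roughly 16% of raw draws are feasible at the defaults, so
  accepted marginals are concentrated below the nominal maximum — a
  property of the stated design itself, not of this implementation.)
* **Tree models.** The Yule generator is the constant-rate pure-birth
  process (via `ape::rphylo` with zero extinction), producing relatively
  balanced trees; the PDA generator draws uniformly over labeled rooted
  topologies (via `ape::rtopology`, whose uniformity the test suite checks
  by chi-square over the complete 3- and 4-tip topology sets), producing
  markedly less balanced trees (Colless imbalance, also contrasted in the
  tests).
* **Branch lengths.** How lengths should be assigned to simulated
  *topologies* is genuinely open. Standalone, `yule_tree()` defaults to its
  natural exponential waiting-time (ultrametric) lengths and `pda_tree()`
  to unit lengths. Inside the study, however, a **single**
  `branch_length_mode` (default `"unit"`) is applied to both trees, so
  that the Yule-vs-PDA comparison isolates tree *shape* rather than mixing
  it with a branch-length-distribution difference.
* **One regional tree per model per study**, not per pair: pair-to-pair
  variation reflects community sampling on a fixed regional phylogeny, as
  in an empirical dataset.

At the default scale the study reproduces the published correlation
structure: PhyloSor tracks Sørensen at $r \approx 0.93$–0.95 and UniFrac
tracks Jaccard slightly higher; PBD totals computed on the Yule versus the
PDA tree for the same community pairs correlate above 0.95, their turnover
and PD components somewhat lower. The acceptance test asserts these inside
the tolerance bands appropriate to a stochastic, tree-realization-dependent
quantity.

What the generator deliberately does **not** emulate: spatial or
environmental structure in community assembly (membership is exchangeable
given $(a,b,c)$), abundance information, tree shapes beyond the two models,
and non-ultrametric rate variation. Passing the simulation tests therefore
says the *decomposition machinery and its invariants* behave correctly under
the stated sampling design — not that real assemblages satisfy that design.

## Worked fixtures

The three `pbd_example()` datasets are small synthetic reconstructions used
across docs and tests: the balanced eight-tip unit-length tree with
clustered (two basal clades; PhyloSor 1, PD 7 each) and interleaved (one tip
per cherry; PhyloSor 0.4, PD 10 each) community pairs, and a ten-species
tree with six communities whose nine pairwise branch partitions — (5,1,1),
(5,1,4), (5,1,5), (5,1,7), (5,1,8), (6,0,3), (6,0,4), (6,0,6), (6,0,7) —
reproduce the published worked table at three decimals. The published table
mixes rounding and truncation in its last digit (e.g. 0.166 for $1/6$, and
components derived from already-rounded entries), so comparisons are made to
one unit in the third decimal. Copies of the fixtures ship as plain newick
and CSV under `inst/extdata/`.

## Problem sizes used in the checks

The test suite runs the additivity/bounds sweep on $10^5$ random partitions,
the per-edge oracle on 1000 random trees of up to 12 tips, the
composition-conservation guard across 999 permutations, and the full
10,000-pair simulation study on 100-tip trees — a few tens of seconds in
total on one core.

## Known limitations

Only pairwise (two-community) decompositions are provided; multi-site
generalizations, abundance-weighted UniFrac variants and nearest-taxon
metrics are out of scope. Tree inference, dating and rerooting are the job
of upstream tools; trees are consumed as given. The CLI reads strict newick
and delimited incidence tables only.
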