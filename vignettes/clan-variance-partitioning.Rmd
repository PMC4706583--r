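---
title: "Diversity and variance partitioning along a taxonomic lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity and variance partitioning along a taxonomic lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clanova)
```

## The model

`clanova` quantifies how an aligned protein family diversified along a
taxonomic lineage. Three statistics carry the analysis.

**p-distance.** For two aligned sequences the p-distance is the proportion
of comparable sites at which they differ. It is the rawest possible
distance: no substitution-model correction, so it saturates (for amino
acids, toward 0.95 under equal exchangeability) and it underestimates the
true number of substitutions at high divergence. That is a deliberate
choice — within-clan and between-clan comparisons use the same biased
scale, and the statistic stays defined and comparable for arbitrarily
diverged families where model-corrected distances blow up.

**Per-taxon diversity.** Within a clan of n members, each member's average
p-distance to the other n − 1 members is computed; the clan is summarised
by the mean ± sample SD of those per-sequence averages. The mean of the
per-sequence averages equals the mean of all within-clan pairwise
distances (each pair appears in exactly two rows), a property asserted
numerically in the test suite. Clans with n < 2 are reported with blank
statistics rather than dropped.

**Variance partitioning.** At a taxonomy node whose children are k clans
of sizes $n_i$ (total $N$), the per-sequence averages $y_{ij}$ are fed to
the one-way random-effects (model II) ANOVA for unequal group sizes:

$$MS_{among} = \frac{\sum_i n_i(\bar y_i - \bar y)^2}{k-1},\qquad
  MS_{within} = \frac{\sum_i \sum_j (y_{ij} - \bar y_i)^2}{N-k},$$
$$n_0 = \frac{N - \sum_i n_i^2/N}{k-1},\qquad
  \hat\sigma^2_A = \max\!\left(0,\ \frac{MS_{among}-MS_{within}}{n_0}\right),$$

with the inter-clan share reported as
$100\,\hat\sigma^2_A/(\hat\sigma^2_A + MS_{within})$. The model treats the
clans as a random sample of clans and assumes exchangeable, homoscedastic
within-clan deviations. Per-sequence averages computed from a shared
distance matrix are not strictly independent, so the percentages are
descriptive variance shares, not inputs to an F test — consistent with
reporting only the two portions of a pie.

A large inter-clan share at a node says the family's diversity respects
the clan boundary there (vertical descent); a small share with substantial
total diversity says the clans are mutually entangled, the signature
horizontal transfer leaves both in the variance components and in
mixed-clan clusters of the accompanying neighbor-joining tree.

## Design choices

Several aspects were genuinely open and are resolved as follows.

* **Observation unit.** The values partitioned at a node are the
  per-sequence average p-distances computed *within that node's member
  set* ("node-local"). This matches the per-sequence averages that define
  the rank summaries and gives one observation per sequence. The
  alternative — raw pairwise distances as observations — is available via
  `partition_lineage(..., observations = "pairwise")` but is non-default:
  pairwise distances are doubly non-independent, and the classical
  unequal-size one-way layout expects one value per unit. Node-local
  values also mean a clan's observations change as one moves down the
  lineage; partitioning at a node always uses the information visible at
  that node.
* **Kingdom rank.** Prokaryote records in standard databases carry no
  kingdom. The completeness rule therefore requires the kingdom only for
  eukaryotes (`strict_kingdom = FALSE`, the default, with the strict
  variant exposed); for kept prokaryotes the kingdom is back-filled with
  the superkingdom name as a pass-through clan so that the taxonomy is a
  uniform eight-rank tree. A pass-through node has one child and is
  reported `not_available` rather than partitioned.
* **Gap policy.** Pairwise deletion is the default: it uses the most data
  per pair and keeps distant pairs defined. `X` (undetermined residue) is
  treated as missing, like a gap, because the p-distance is defined over
  determined amino-acid sites. Complete deletion is available for strict
  column-set comparability across all pairs.
* **Truncation.** A negative among-clan component (possible whenever
  $MS_{among} < MS_{within}$) is truncated to zero, standard model II
  practice. Truncation inflates the *mean* of the null distribution of
  the inter-clan share, which is why null behaviour is characterised by
  the median (see below).
* **Percentage denominator.** $\hat\sigma^2_A + MS_{within}$ — the two
  components of the one-way model — so the shares always sum to 100.
* **Eligibility.** A node is partitioned when it has ≥ 2 child clans,
  $N > k$, and at least one clan with $n_i \ge 2$ (within df ≥ 1).
  Singleton clans are retained — they contribute to the among-clan sum of
  squares. Ineligible nodes are reported with their reason, never
  silently dropped.
* **Group comparison.** `compare_groups()` computes the two-sample t test
  from summary statistics; Welch (Satterthwaite df) is the default since
  clan variances are rarely equal, with the pooled form available.
* **Neighbor joining.** NJ and Newick I/O are delegated to `ape`; a
  negative reconstructed branch is clamped to zero with its deficit
  shifted to the sister branch, preserving path lengths through the
  parent as far as possible. Bootstrap supports are bipartition
  frequencies over alignment-column resamples rebuilt with the same gap
  policy; a replicate in which some pair has no comparable site is
  dropped and counted, and the support denominator is the number of
  successful replicates. Exact topological agreement with any particular
  aligner/NJ implementation is not a contract; agreement is checked at
  the bipartition level and, on additive matrices, through exact
  path-length recovery.

## The simulator and what it does (not) emulate

`simulate_family()` evolves a uniform random root sequence down a
configurable taxonomy under the 20-state equal-rates model: on a branch of
length $d$ (expected substitutions per site) each site changes with
probability $p(d) = \frac{19}{20}\!\left(1-e^{-\frac{20}{19}d}\right)$ and
then takes one of the 19 other residues uniformly. Because this is the
transition probability of the compound Poisson process, branch lengths
compose additively, and `expected_p(d)` is an exact calibration oracle for
the observed p-distance at total path length $d$.

Defaults are one kingdom, two clans per internal rank, and 1–4 organisms
per genus (uneven clan sizes), with per-rank branch lengths
(kingdom 0.15, phylum 0.30, class 0.15, order 0.10, family 0.10,
genus 0.08, organism 0.18 substitutions/site) chosen so group-mean
p-distances span roughly 0.3 within genera to 0.8 across phyla — the range
typical of deep protein-family surveys. Horizontal transfer is modelled as
whole-sequence replacement of a recipient leaf by a copy of a donor from a
different family, followed by a small independent divergence (0.05 by
default): crude, but it produces exactly the mixed-clan signatures the
variance partition and the tree are meant to detect, and increasing the
event count measurably erodes the inter-clan share at the crossed nodes
(a directional property in the test suite).

The simulator deliberately omits indels (gap handling is exercised by
`mask_gaps()`, which masks residues independently so a pair's expected
comparable-site count is $L(1-f)^2$), rate heterogeneity across sites,
non-uniform amino-acid exchangeabilities, and selection. Passing tests
therefore demonstrate that the statistics recover the structure of data
generated under *this* model — they do not certify alignment quality,
model misspecification behaviour, or biological interpretation on real
families.

## Numerical and scale choices

All randomised checks run at fixed seeds. Exact oracles (brute-force
sums of squares, per-pair hand counting of distances, path-length
recovery on additive matrices) are held to 1e-10 or tighter; stochastic
checks use three Monte-Carlo standard deviations around closed-form
expectations. Problem sizes — alignments of 3–10 sequences for oracle
sweeps, pair simulations at L = 2000 with 50 replicates per divergence
level, recovery layouts with 20 clans of 10–14 members (N ≥ 200), 1000
null replicates, and synthetic families of ~70–90 sequences at L = 150–400
for end-to-end runs — were chosen as the smallest scales at which the
Monte-Carlo error bands are meaningfully narrow.

Degenerate inputs are contracts, not errors: a pair with no comparable
sites yields a flagged `NA` distance (fatal only when a tree is requested),
a singleton clan yields blank summary statistics, equal clan means yield a
truncated zero component, and two equal-size clans give $n_0 = n$.
NJ tie-breaks follow the deterministic order of the canonical taxon
ordering, so a fixed seed yields byte-identical Newick output.

## Limitations

The inter-clan share is a descriptive proxy: it cannot separate horizontal
transfer from rate variation, convergence, or taxonomic misannotation, and
saturation compresses between-clan signal at deep nodes (visible in the
simulator at phylum-level divergences). Unbalanced sampling of clans — the
rule in curated databases — affects the per-sequence averages through clan
size, which is why the unequal-size $n_0$ correction matters and why
results at sparsely sampled nodes should be read alongside their reported
sizes. The pipeline computes distances within whatever alignment it is
given; cross-superkingdom comparisons inherit the alignment's choices.
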