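# clanova

Taxonomic diversity and inter-/intra-clan variance partitioning for aligned
protein families.

## The problem

Large enzyme families — amylases are the motivating case — are scattered
across the whole tree of life, and their sequences diverge at very different
rates in different taxonomic groups. Two questions recur when such a family
is surveyed: *how diverse is the family within each named taxon* (phylum,
class, order, family, genus), and *does the diversity sit mostly between
sister taxa or within them*? The first is a direct measure of how much room
a lineage has explored; the second is a proxy for the mode of transmission,
because variance concentrated *between* clans is the signature of vertical
descent while variance spread *within* clans (or clans entangled in the
phylogeny) points to horizontal gene transfer.

`clanova` implements this analysis as a reusable pipeline:

1. **Pairwise p-distance.** For two aligned sequences, `p` is the proportion
   of comparable amino-acid sites at which they differ. Under the default
   *pairwise deletion* policy a site is comparable when both positions carry
   one of the 20 standard residues (`-` gaps and `X` are excluded per pair);
   *complete deletion* is available as an option.
2. **Per-taxon diversity.** For every clan at every rank, each member's
   average p-distance to the other members is computed; the clan is
   summarised by the mean ± SD (sample SD, n−1) of these per-sequence
   averages — the numbers behind rank-by-rank diversity heatmaps.
3. **Variance partitioning.** At every bifurcation of the taxonomy the
   per-sequence averages are partitioned into an among-clan and a
   within-clan component by the one-way random-effects (model II) ANOVA for
   unequal group sizes. With clan sizes *n&#7522;* (total *N*, *k* clans):

   - SS_among = Σ n&#7522; (ȳ&#7522; − ȳ)², MS_among = SS_among/(k−1)
   - SS_within = Σ&#7522; Σ&#11388; (y&#7522;&#11388; − ȳ&#7522;)², MS_within = SS_within/(N−k)
   - n₀ = (N − Σ n&#7522;²/N)/(k−1)
   - σ̂²_A = max(0, (MS_among − MS_within)/n₀)
   - pct_inter = 100 · σ̂²_A / (σ̂²_A + MS_within), pct_intra = 100 − pct_inter

4. **Neighbor-joining trees** (Saitou–Nei, via `ape`) from the p-distance
   matrix, with alignment-column bootstrap supports and Newick output.
5. **A seeded simulator** of protein families evolving over a configurable
   taxonomy under a 20-state equal-rates substitution model (expected
   p-distance `p(d) = (19/20)(1 − e^(−20d/19))`), with optional
   horizontal-transfer events, so every stage can be validated against
   known truth.

## Worked example

```r
library(clanova)

sim <- simulate_family(sim_config(seq_length = 400, hgt_events = 2, seed = 101))
flt <- filter_complete_lineage(sim$alignment, sim$lineages)
#> complete-lineage filter: kept 73/73 (Synthkingdom=73)
M   <- distance_matrix(flt$kept)              # pairwise deletion by default
tax <- build_taxonomy(flt$lineages)

rank_table(M, tax, "phylum")
#>          rank     taxon  n mean_p   sd_p
#> phylum  phylum phylum_01 37  0.611 0.0400
#> phylum1 phylum phylum_02 36  0.619 0.0388
```

Both simulated phyla contain 36–37 sequences whose average mutual
p-distance is ≈ 0.61: a deeply diverged family, comparable across clans.
Partitioning along the lineage:

```r
parts <- partition_lineage(M, tax)
head(parts[parts$status == "ok",
           c("node", "child_rank", "k", "N", "pct_inter", "pct_intra")], 4)
#>                 node child_rank k  N pct_inter pct_intra
#> 2 kingdom:kingdom_01     phylum 2 73     14.24     85.76
#> 3   phylum:phylum_01      class 2 37     14.89     85.11
#> 4   phylum:phylum_02      class 2 36     22.25     77.75
#> 5     class:class_01      order 2 18      0.00    100.00
```

At the deepest split only 14 % of the diversity lies *between* the two
phyla — saturation plus the two injected transfer events blur the clan
boundary — while most of it is carried within clans. The scalar engine on a
textbook two-clan layout ({1,2,3} vs {7,8}):

```r
partition(c(1, 2, 3, 7, 8), c("clanA", "clanA", "clanA", "clanB", "clanB"))
#>    n0 ms_among ms_within sigma2_among pct_inter pct_intra
#> 1 2.4     36.3  0.833333      14.7778   94.6619   5.33808
```

Trees: `nj_tree(M)` returns an `ape::phylo`;
`bootstrap_supports(flt$kept, B = 1000, seed = 1)` adds bipartition
supports; `write_newick()` / `read_newick()` serialize them.
`run_pipeline(run_config(...))` chains dedup → lineage filter → taxonomy →
distances → rank tables → partitions → tree into one output directory with
a JSON manifest, and `inst/cli/clanova.R` exposes the same steps as shell
subcommands (`simulate | pdist | summarize | partition | tree | run`).

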