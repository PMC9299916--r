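---
title: "Clustering herbicide modes of action by shared resistant weeds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering herbicide modes of action by shared resistant weeds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moaclust)
```

## The problem

Weed species worldwide have evolved resistance to herbicides, and an
increasing fraction of them resist herbicides of two or more *modes of
action* (MoAs) — the physiological or biochemical targets through which a
herbicide kills plants, classified into numbered HRAC groups (group 2 = ALS
inhibitors, group 1 = ACCase inhibitors, and so on). Each multi-resistant
species links the MoAs it resists, so the worldwide record of resistance
induces structure over MoAs themselves: which targets tend to fail
together? moaclust turns species-level resistance records into that
MoA-level structure and asks whether it is driven mainly by how *prevalent*
resistance to each MoA is, or by *similarity* in what the herbicides do.

Two caveats shape the whole design. First, the records capture the
*potential* for multiple resistance: the data do not distinguish one
population resistant to several MoAs from several populations each
resistant to one, nor cross-resistance (one mechanism, many MoAs) from true
multiple resistance. Second, the species-level matrix underlying the
published ten-MoA analysis derives from a dated snapshot of a live
database and is not redistributable; the package therefore bundles the
published ten-by-ten proximity matrix as a fixture
(`table1_proximity()`) and provides a synthetic generator so every stage
can be tested end to end.

## Pipeline and model

1. **Ingest.** Records `(species, growth form, HRAC group)` become a binary
   incidence matrix: MoAs as rows, species as columns, cell 1 if resistance
   of that species to that MoA has ever been recorded. Duplicate records
   collapse; labels sort in C collation so all later tie-breaking is
   reproducible. Species names are matched as trimmed, case-folded strings;
   no synonym resolution is attempted, so distinct spellings of one taxon
   remain distinct taxa.
2. **Consolidate.** The three carotenoid-biosynthesis HRAC groups (12, 13,
   27) are merged by logical OR into one MoA, then species resistant to
   fewer than 2 MoAs and MoAs with fewer than 10 resistant species are
   dropped.
3. **Proximity.** Between-MoA similarity is the Jaccard index
   $J(A,B) = |A \cap B| / |A \cup B|$ on resistant-species sets. Jaccard is
   the right coefficient for *asymmetric* binary data: a species resistant
   to neither MoA says nothing about their relatedness and is excluded,
   while matches and mismatches among present species weigh equally.
4. **Cluster.** Agglomerative clustering on the distance $d = 1 - J$ with
   complete linkage (furthest neighbour): the distance between clusters is
   the maximum pairwise member distance, which yields compact,
   small-diameter clusters and a monotone merge-height sequence. The
   number of clusters is chosen from the agglomeration schedule (see
   below).
5. **Networks.** Two weighted graphs over the same MoAs: the *prevalence*
   network (edge weight = number of species resistant to both MoAs) and
   the *proximity* network (edge weight = Jaccard similarity). Their
   agreement is the Pearson correlation over all $\binom{n}{2}$ unordered
   pairs, zero-weight pairs included — with 10 MoAs, df $= 45 - 2 = 43$.
6. **Statistics.** Per-species MoA-count distributions by growth form,
   Mood's median test for the monocot/dicot comparison, and the Pearson
   correlation between a MoA's prevalence and the percentage of its
   resistant species that are multi-resistant.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_moas_per_species` | 2 | species filter: keep multi-resistant species |
| `min_species_per_moa` | 10 | MoA filter: keep well-represented MoAs |
| `iterate_to_fixed_point` | off | repeat both filters until stable |
| selection `method` | `balanced_no_singleton` | how k is chosen |
| `k_range` | 2–5 | candidate cluster counts |
| `ties` (median test) | `"below"` | values at the grand median count as low |

### Filter order and the fixed point

"Keep multi-resistant species, keep MoAs with ten or more resistant
species" is ambiguous about order and iteration. The default applies the
species filter first, then the MoA filter, once each, in sentence order;
the MoA threshold is thereby counted among multi-resistant species only.
A single pass can strand species below the species threshold after a MoA
is removed, so `iterate_to_fixed_point = TRUE` repeats both passes until
the output satisfies both thresholds simultaneously. Both modes are
first-class and the `filter_report()` records exactly what was dropped at
each pass, so the discrepancy between modes is always visible rather than
silently resolved.

### Choosing the number of clusters

The agglomeration coefficient is defined here as the merge height on the
$1 - J$ scale — a reproducible, monotone quantity. The proprietary
statistics package in which such analyses are often run scales its
published agglomeration coefficients differently and does not document
how, so elbow plots here are comparable in shape but not unit-for-unit
with such output.

Two selection rules are provided. `max_gap` is the textbook elbow: the k
with the largest coefficient drop between $k-1$ and $k$ clusters.
`balanced_no_singleton` formalizes the visual corroboration practised with
dendrograms — clusters of similar size, none consisting of a single item:
among candidate cuts with no singleton, it maximizes the smallest-to-largest
cluster size ratio, ties resolving to the smaller (more parsimonious) k.
On the bundled ten-MoA tree the two rules disagree: `max_gap` on the
$1-J$ coefficient prefers k = 2, while `balanced_no_singleton` selects
k = 3 (the cuts at 4 and 5 contain singletons, and 3 clusters of sizes
4/3/3 beat 2 of sizes 7/3). Both scores are reported in
`select_k()` diagnostics; `balanced_no_singleton` is the default because
singleton "clusters" of MoAs have no rotational-management interpretation.

```{r table1}
dend <- agglomerate(to_distance(table1_proximity()))
sel <- select_k(dend)
sel
split(names(cut_dendrogram(dend, sel$k)), cut_dendrogram(dend, sel$k))
```

### Numerical choices

* **Distance convention**: $d = 1 - J$, the Jaccard distance (a metric).
* **Tie-breaking**: at equal linkage distance the pair with the
  lexicographically smallest (left, right) representative labels merges
  first; label order uses C collation everywhere. Ties are compared with
  exact floating-point equality, which is safe because complete-linkage
  updates only ever take maxima of existing values.
* **Degenerate inputs**: empty species sets make the Jaccard index
  undefined and raise an error rather than returning 0; constant weight
  vectors make the network correlation undefined and do likewise; a filter
  that eliminates every row or column fails naming the offending
  threshold.
* **Median-test ties**: values equal to the grand median count as "at or
  below", a common convention; no continuity correction by default. Both
  are configurable because the convention used for the published
  database-wide test is unknown — and indeed its printed statistic/P pair
  is not consistent with any two-group chi-square median test at 1 df, a
  discrepancy this package documents rather than reverse-engineers.

## The synthetic generator

`generate_incidence()` draws, for each species, a MoA count $m$ from a
categorical distribution over 1–10, a home cluster (probability
proportional to the cluster's share of prevalence weight), and then $m$
distinct MoAs: each pick comes from the remaining home-cluster MoAs with
probability `p_within`, otherwise from the other clusters, always weighted
by per-MoA prevalence weights. With `p_between = 0` a species never leaves
its home cluster (its count truncates at the cluster size), which is what
makes exact-recovery tests meaningful.

Defaults were chosen once to emulate the scale of a consolidated
real-world extract and then frozen:

* `moa_count_distribution = (.08, .30, .27, .15, .08, .05, .045, .012,
  .008, .005)` — median 3, with 2.5% of species resistant to 8+ MoAs,
  echoing the few extreme grass generalists in the real record;
* `paperlike` preset: 10 MoAs in planted clusters of sizes 4/3/3, 110
  species (≈100 multi-resistant survive filtering), `p_within = 0.8`, and
  a prevalence gradient of roughly 6:1 across MoAs;
* `prevalence_driven` preset: one undifferentiated cluster with strongly
  skewed weights — co-occurrence structure from prevalence alone;
* `similarity_driven` preset: three tight clusters (`p_within = 0.95`)
  with uniform weights — structure from shared targets alone.

The generator reproduces the *scale and marginals* of real extracts
(counts, gradients, planted block structure) but not their biology: no
phylogenetic correlation between species, no geography or crop system, no
temporal accumulation of records, and cluster membership is exchangeable
within a cluster. Passing recovery tests on synthetic data therefore
demonstrates that the pipeline recovers structure of the planted kind at
realistic sizes — not that real resistance data contain such structure.

A note on recovery behaviour: the adjusted Rand index of planted-cluster
recovery decreases as `p_between` grows only up to the uniform-sampling
point (`p_between` ≈ 0.6 for these cluster sizes). Beyond it, species
actively avoid their home cluster, which is itself detectable structure,
and recovery improves again. Monotonicity checks therefore run on the
preference-to-uniform range.

## Validation strategy and problem sizes

Every core computation is tested against an independent oracle:
Jaccard proximities against an explicit per-species counting loop (and
vegan's binary Jaccard distances); the complete-linkage agglomeration
against a brute-force reference that rescans all cluster pairs at every
step, on 100 random instances of up to 7 items, and against
`stats::hclust` heights; partitions for nestedness across all k. Mood's
median test is checked against a hand-built contingency table and holds
its nominal type-I error (0.05 ± 0.02) over 2,000 null replicates of two
groups of 100; parametric Pearson P values agree with a 10,000-shuffle
permutation null within Monte-Carlo error. Generator calibration is
verified at 5,000 species (goodness of fit of the MoA-count marginal) and
10,000 species (realized prevalence within 3σ of expectation); recovery
monotonicity uses 20 replicates at each of five mixing levels with ~110
species each. These sizes keep the whole suite under half a minute while
leaving each check well-powered.

## Known limitations

* Species identity is string-based; taxonomic synonyms inflate the species
  count and dilute proximities.
* Population- and case-level information is deliberately collapsed; the
  pipeline measures potential, not frequency, of multiple resistance.
* The Pearson correlation between networks treats the $\binom{n}{2}$
  pairs as independent, which they are not (each MoA participates in
  $n-1$ pairs); a Mantel-style permutation test would be the stricter
  alternative and is left as an extension.
* Force-directed layouts are out of scope; exports (GraphML, GEXF, edge
  lists) carry raw weights so external tools can draw publication
  figures, and the built-in plot uses a deterministic circular layout.
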