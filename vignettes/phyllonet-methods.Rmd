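---
title: "Community structure of a seasonal phyllosphere: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community structure of a seasonal phyllosphere: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllonet)
```

phyllonet analyses 16S rRNA OTU count tables from leaf-surface (phyllosphere)
and air samples collected across plant-species habitats and seasons. This
vignette is the package's account of the science: the models and procedures
implemented, the tunable parameters and their defaults, what the synthetic
community generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The data model

The central object is an `otu_table`: a non-negative integer read-count
matrix (rows = OTUs clustered at 97% sequence similarity, columns = samples)
together with per-sample metadata (`source` leaf/air, `habitat` = plant
species or `"air"`, `season` summer/winter) and optional per-OTU taxonomy.
The reference design has nine plant-species habitats sampled in both
seasons plus one air sample per season: 20 samples.

Normalisation follows the conventional amplicon workflow, in this order:

1. **Singleton removal** — OTUs with a single read in the whole dataset are
   dropped before anything else; such OTUs are overwhelmingly sequencing
   artefacts.
2. **Rarefaction** — every sample is subsampled *without replacement* to a
   common depth (default: the minimum sample total; the reference design
   uses 5038 reads). A single draw per seed, not an average over draws:
   this matches the subsample semantics of the standard mothur-style
   pipeline. The seed defaults to 0 and is recorded in the table's
   provenance. A replicate-draw analysis can be emulated by mapping over
   seeds, but is deliberately not the default.
3. **Taxon exclusion** — after normalisation, chloroplast-derived OTUs and
   OTUs unclassified at the domain level are removed by label matching on
   the taxonomy.

## Alpha diversity and seasonal comparison

Per sample: richness $S$, Shannon $H=-\sum p\ln p$ (natural log), Simpson
$1-D=1-\sum p^2$, and Pielou's evenness $J=H/\ln S$ (undefined at $S=1$).
The natural log is the default because $J=H/\ln S$ then equals 1 exactly for
any uniform composition; the base is configurable.

Seasonal contrasts are two-sided paired t-tests matched by habitat
(`paired_season_test()`), giving $df = n_\text{pairs}-1 = 8$ for nine
habitats. Two degenerate cases are handled explicitly: when one season is
identically zero across habitats the test degrades to a one-sample t-test
of the other season against zero, and a zero-variance difference vector is
reported as an exact tie ($t=0, p=1$ when the seasons are identical;
$t$ undefined and flagged otherwise). Per-taxon comparisons
(`seasonal_taxon_comparison()`) are reported without multiple-testing
correction, mirroring the conventional presentation of such tables; treat
the per-taxon p-values descriptively.

## Abundance classes, occupancy, and Levins niche breadth

An OTU is **abundant** when it holds more than 1% of all reads in the
dataset and **rare** below 0.1%; both inequalities are strict, so an OTU
sitting exactly on a threshold falls in the unnamed middle class, which the
package labels *intermediate*. The same rule applied within a sample gives
*locally abundant/rare* calls.

**Occupancy** counts the habitats (seasons pooled) where an OTU is detected
at one read or more; an OTU present on all nine species is *universal*, and
air presence is tracked separately (occupancy zero + air flag = an OTU seen
only in the air).

**Levins niche breadth** for OTU $j$:

$$B_j = \frac{1}{\sum_{i=1}^{N} p_{ij}^2},$$

where $p_{ij}$ is the share of OTU $j$'s reads found in sample $i$ and $N$
is the number of samples. $B_j$ runs from 1 (confined to one sample) to $N$
(perfectly even spread). OTUs with $B_j > 10$ are classified generalists
and $B_j < 5$ specialists (strict; the conventional cutoffs for this
index), the band $[5, 10]$ again *intermediate*. Row-share normalisation is
the standard resource-state proportion; on a rarefied table it coincides
with normalising by relative abundances. Whether air samples belong in $N$
is a genuine design fork: the default includes all samples, and
`leaf_only = TRUE` restricts the universe to the 18 leaf samples; at these
thresholds the choice rarely moves a call because air holds only two of 20
samples.

The `classification_summary()` table aggregates counts with percentage
cells computed against the total OTU count (overall) or against the
phyllosphere/air OTU counts (within-group), rounded half-away-from-zero to
integers — the rounding rule that reproduces standard summary-table
presentations (e.g. 17.64% → 18, 43.84% → 44).

## Bray–Curtis clustering and SIMPER

Sample dissimilarity is Bray–Curtis on rarefied counts,
$d(x,y)=\sum_k |x_k-y_k| / \sum_k (x_k+y_k)$, with no transformation:
the analysis tradition this package follows clusters on abundance directly.
Clustering is agglomerative group-average (UPGMA), the default of the
PRIMER lineage of community-ecology software. Ties in agglomeration are
broken toward the pair containing the lexicographically smallest sample
label (samples are sorted before clustering), making the tree deterministic
and input-order invariant. Cuts are expressed as percent similarity
($s$% groups samples connected by merges strictly below height $1-s/100$).

SIMPER decomposes the average within-cluster similarity: for each sample
pair, $S = 100\,(1-d)$ splits exactly into per-OTU contributions
$100 \cdot 2\min(x_k,y_k)/\sum_m (x_m+y_m)$; per-cluster contributions are
means over pairs and sum to the cluster's average similarity to machine
precision (a conservation identity the test suite asserts at $10^{-9}$).
The *discriminating set* collects OTUs in decreasing contribution order
until 90% cumulative contribution (configurable — the convention does not
pin the exact cutoff). OTUs in exactly one cluster's discriminating set
(`simper_sole_discriminants()`) operationalise "solely responsible" taxa;
this is an interpretation, as no formal rule exists. Between-group
dissimilarity is decomposed analogously with $|x_k-y_k|$ terms and is
cross-checked against vegan's SIMPER in the tests.

## MIC co-occurrence networks

The association between two OTUs' abundance vectors is the Maximal
Information Coefficient: over all grid shapes $(a,b)$ with $a,b\ge 2$ and
$ab \le \max(n^{0.6}, 4)$,

$$\mathrm{MIC} = \max_{(a,b)} \frac{\max_G I(x,y;G_{a\times b})}{\log_2 \min(a,b)},$$

with cuts allowed only between distinct data values, so tied observations
(frequent in counts) share a cell. The floor of 4 on the grid budget keeps
a 2×2 grid admissible at small $n$, where $n^{0.6}$ alone would admit none.

Two search strategies are implemented:

- **exact** (default): for each shape, every row partition is enumerated and
  the optimal column partition found by dynamic programming, using the fact
  that $I = H(\text{rows}) - \sum_c \frac{n_c}{n} H(\text{rows}\mid c)$ is
  additive over column segments. At the sample counts community tables
  produce (tens of samples) the admissible grids are tiny and this is both
  exact and fast. The test suite verifies it against an independent
  brute-force enumeration of all grid partitions.
- **approx**: the classical MINE heuristic — equipartition one axis, optimise
  the other by the same dynamic programme over clump boundaries (at most
  $c \cdot a$ superclumps, $c = 15$), in both orientations. Provided for
  large-$n$ use; it can only undershoot the exact score.

An edge is drawn when MIC exceeds 0.5 (strictly) *and* the Spearman rank
correlation is positive: MIC measures strength but is sign-blind, so
positivity of the association is enforced separately. Permutation p-values
(`mic_pvalue()`, add-one estimator) are available but the operative filter
is the MIC threshold. Network construction refuses groups of fewer than
5 samples by default — MIC on a handful of points is degenerate — and the
floor is an explicit argument because the support over which such networks
are computed is a genuine open choice.

Network topology is summarised by twelve Cytoscape-style parameters
(nodes, edges, mean local clustering coefficient with degree-<2 nodes
contributing 0, components, diameter and radius of the largest component,
degree centralization $\frac{N}{N-2}(k_{max}/(N-1) - \text{density})$,
ordered reachable-pair count, characteristic path length, mean degree,
density, and degree heterogeneity $\mathrm{sd}(k)/\bar{k}$ with population
sd), reported to 3 decimals. The null model is the uniform $G(n,m)$ random
graph at the observed node and edge counts (`random_network()`, replicate
summaries via `random_network_summary()`); a degree-preserving rewiring
null (`rewired_network()`) is the alternative mode. Density, mean degree
and (for connected graphs) the shortest-path count are identities in
$N$ and $E$, so observed and null networks share them by construction —
the informative contrasts are clustering, path length, and heterogeneity.

## The synthetic community generator

`generate_community()` draws OTU tables with the statistical structure the
analysis assumes, plus ground-truth labels, so every downstream stage is
testable without external data. Per sample, counts are one multinomial draw
of `depth` reads from expected relative abundances assembled as
*lognormal base abundance × habitat-occupancy mask × seasonal activity ×
per-sample heterogeneity*. Defaults encode the reference design: 9 habitats
× 2 seasons + 2 air samples, depth 5038, 890 OTUs, lognormal(0, 2) base
abundances (a few dominant, many very rare taxa).

Planted roles, with their classification bands built in:

- **generalists** (1.1%, i.e. 10 of 890) occupy all habitats in both
  seasons and take the *top* abundance ranks — generalist taxa in such
  systems are the ubiquitous dominants. Expected breadth ≈ 18 of 20.
- **specialists** (88.5%) occupy exactly one habitat; seasonal activity
  (below) leaves them in 1–2 samples, expected breadth ≤ 4.
- **background** (intermediate) OTUs occupy 3–4 habitats in both seasons;
  with possible air presence their expected breadth spans 6–10 — inside
  the intermediate band whichever way the air draws fall.
- an **air-only** block (21 OTUs) appears in no habitat.

Summer-enriched richness is carried by specialist season-activity: winter
presence probability 0.55, summer presence $\min(1, 0.55 \times f)$ with
`summer_richness_factor` $f = 1.6$ — the ratio of the reference design's
summer to winter mean richness. Air samples mix the thinned pooled leaf
community (each leaf OTU is airborne with probability 0.25; ubiquitous
generalists always) with the air-only block at equal expected weight
(`air_only_weight = 0.5`), making air species-poor and compositionally
distinct. Per-OTU-per-sample lognormal heterogeneity (`sample_noise_sd =
0.3`) adds realistic sample-to-sample variation; the value is chosen so the
effective-sample-count factor $e^{-\sigma^2} = 0.91$ cannot push any role's
expected breadth across a classification threshold.

`summer_association_sd` (default 0 = off) plants a dense positive
co-occurrence block: a shared lognormal factor per summer leaf sample
multiplies the generalist block, so those OTUs rise and fall together
across summer samples. It is off by default so the plain design is exactly
what the recovery analyses see; switching it on is how the network
null-model contrast is exercised.

`recovery_report()` scores the Levins calls against the planted roles.
Air-only OTUs carry no phyllosphere niche role and are excluded; planted
OTUs that were never sampled cannot be classified and are counted
separately rather than as misses. On the *structural* expectation (the
design's expected proportions before heterogeneity and sampling), recovery
is perfect by construction — the package's tests assert this noise-free
limit alongside the sampled-data recovery rates.

**What the generator does not emulate.** No phylogenetic or sequence-level
structure; taxonomy labels are decorative draws. Realized per-sample
richness (~80 summer / ~65 winter at the defaults) sits well below the
reference design's ~234/146 because a lognormal(0,2) community sampled at
depth 5038 leaves much of the rare tail unobserved; the seasonal *ordering*
— what the validation asserts — is robust. Between-sample Bray–Curtis
dissimilarities are likewise milder than real phyllosphere data (shared
dominants compress them), so cluster cuts at the 20–35% similarity levels
meaningful for field data usually return a single cluster on synthetic
tables; cluster-level machinery is exercised at higher cut levels. Passing
tests on this generator demonstrate correctness of the estimators and the
detectability of planted structure — not that real communities satisfy the
generator's assumptions.

## Numerical choices and degenerate inputs

- Percentages in summary tables: round half away from zero to integers;
  unit conversions to 3 significant figures; topology to 3 decimals.
- Rarefaction depth exceeding a sample's total, metadata missing for a
  sample, all-zero samples, non-integer counts: hard errors naming the
  offender. All-singleton tables and absent taxonomy: warnings with empty
  or unchanged results.
- Constant vectors give MIC 0 with a warning; network construction below
  the minimum group size is refused rather than silently degraded.
- All stochastic steps (rarefaction, generation, permutation tests, null
  draws) take explicit integer seeds and are exactly reproducible.
- Problem sizes in the test suite (seed counts, replicate counts) are
  chosen to exercise each property at statistical power appropriate for a
  default test run; the acceptance script uses 50-seed batteries for the
  synthetic-recovery analyses and 200 random pairs for the MIC oracle
  comparison.

## Known limitations

- Exact MIC is exponential in grid size through the row-partition
  enumeration; beyond roughly 50–100 samples switch `method = "approx"`.
- The paired t-tests assume approximate normality of habitat differences;
  with nine pairs this is an approximation the package inherits from the
  analysis tradition it implements.
- SIMPER discriminating sets depend on the cumulative cutoff (default
  90%); "sole responsibility" of a taxon for a cluster is a set-difference
  interpretation, not an inferential statement.
- The G(n,m) null conditions on node and edge counts only; a
  degree-preserving null is provided but no further constrained ensembles.
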